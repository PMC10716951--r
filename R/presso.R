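# Core MR-PRESSO computation shared by the exported wrappers.
#
# Observed residual sum of squares: RSS = sum_j w_j (Gamma_j - b_(-j) *
# gamma_j)^2, where b_(-j) is the IVW estimate computed without SNP j and
# w_j = se_Gamma_j^-2 (the IVW regression weights). The null distribution
# is built by drawing, n_sim times, Gamma*_j ~ N(b_(-j) gamma_j,
# se_Gamma_j^2) and gamma*_j ~ N(gamma_j, se_gamma_j^2) and recomputing
# RSS (including the leave-one-out estimates) on the simulated data.
# SNPs are put in a canonical (variant_id) order before any random draw, so
# results do not depend on input row order.
presso_core <- function(H, n_sim, seed) {
  J <- nrow(H)
  if (J < 4) stop("MR-PRESSO requires at least 4 SNPs", call. = FALSE)
  if (n_sim < 1000) stop("MR-PRESSO requires n_sim >= 1000", call. = FALSE)
  ord <- order(H$variant_id)
  g <- H$gamma[ord]
  sg <- H$se_gamma[ord]
  G <- H$Gamma[ord]
  sG <- H$se_Gamma[ord]
  id <- H$variant_id[ord]
  w <- sG^-2

  loo_beta <- function(gv, Gv) {
    num <- w * gv * Gv
    den <- w * gv^2
    (sum(num) - num) / (sum(den) - den)
  }

  b_loo <- loo_beta(g, G)
  contrib_obs <- w * (G - b_loo * g)^2
  rss_obs <- sum(contrib_obs)

  with_seed(seed, {
    g_star <- matrix(rnorm(n_sim * J, mean = rep(g, each = n_sim),
                           sd = rep(sg, each = n_sim)), n_sim, J)
    mu_star <- rep(b_loo * g, each = n_sim)
    G_star <- matrix(rnorm(n_sim * J, mean = mu_star,
                           sd = rep(sG, each = n_sim)), n_sim, J)
  })

  W <- rep(w, each = n_sim)
  num <- matrix(W, n_sim, J) * g_star * G_star
  den <- matrix(W, n_sim, J) * g_star^2
  b_loo_star <- (rowSums(num) - num) / (rowSums(den) - den)
  contrib_star <- matrix(W, n_sim, J) * (G_star - b_loo_star * g_star)^2
  rss_star <- rowSums(contrib_star)

  global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  exceed <- colSums(contrib_star >= matrix(contrib_obs, n_sim, J, byrow = TRUE))
  p_snp <- (1 + exceed) / (n_sim + 1)

  # Map back to the input row order.
  inv <- match(H$variant_id, id)
  list(rss_obs = rss_obs, global_p = global_p,
       p_snp = p_snp[inv], variant_id = id[inv],
       n_sim = n_sim, seed = seed)
}

#' MR-PRESSO global heterogeneity test
#'
#' Simulation-based test of whether the observed residual sum of squares
#' around the leave-one-out IVW fits exceeds what sampling error alone
#' produces, indicating horizontal pleiotropy somewhere in the instrument
#' set.
#'
#' @param H a [harmonized_set] with at least 4 SNPs.
#' @param n_sim number of null simulations (>= 1000; default 5000).
#' @param seed integer seed; the same seed gives bitwise-identical results.
#' @return List with `rss_obs` and `global_p`; the p-value's lower bound is
#'   `1 / (n_sim + 1)`.
#' @export
presso_global <- function(H, n_sim = 5000, seed) {
  core <- presso_core(H, n_sim, seed)
  list(rss_obs = core$rss_obs, global_p = core$global_p)
}

#' MR-PRESSO per-SNP outlier test
#'
#' Compares each SNP's observed contribution to the residual sum of
#' squares with its simulated null contributions. SNPs whose
#' Bonferroni-adjusted p-value falls below `alpha` are flagged as
#' pleiotropic outliers.
#'
#' @inheritParams presso_global
#' @param alpha significance level applied after Bonferroni adjustment
#'   (default 0.05).
#' @return Data frame with columns `variant_id`, `p`, `outlier`.
#' @export
presso_outlier <- function(H, n_sim = 5000, seed, alpha = 0.05) {
  core <- presso_core(H, n_sim, seed)
  data.frame(variant_id = core$variant_id, p = core$p_snp,
             outlier = pmin(1, core$p_snp * nrow(H)) < alpha,
             stringsAsFactors = FALSE)
}

#' Outlier-corrected IVW estimate
#'
#' Refits the multiplicative random-effects IVW estimate after removing
#' the flagged outlier SNPs; with an empty outlier list this equals the
#' plain IVW estimate (the method tag still records that outlier
#' correction was applied).
#'
#' @param H a [harmonized_set].
#' @param outliers character vector of variant ids to remove; must be a
#'   strict subset leaving at least 2 SNPs.
#' @return An `mr_estimate` with method `"MRPRESSO_corrected"`.
#' @export
presso_correct <- function(H, outliers = character()) {
  stopifnot(all(outliers %in% H$variant_id))
  keep <- !(H$variant_id %in% outliers)
  if (sum(keep) < 2) {
    stop("presso_correct: outlier removal leaves fewer than 2 SNPs", call. = FALSE)
  }
  fit <- mr_ivw(h_subset(H, keep))
  fit$method <- "MRPRESSO_corrected"
  fit
}

#' MR-PRESSO: global test, outlier detection and corrected estimate
#'
#' Runs the global residual-sum-of-squares test, the per-SNP outlier test
#' (Bonferroni-adjusted p < `alpha`), and the outlier-corrected IVW
#' estimate in one call, sharing a single set of null simulations.
#'
#' @inheritParams presso_global
#' @param alpha outlier declaration level after Bonferroni adjustment.
#' @return Object of class `mr_presso`: list with `rss_obs`, `global_p`,
#'   `per_snp` (data frame `variant_id`, `p`), `outliers`, `corrected`
#'   (an `mr_estimate`), `n_sim`, `seed`.
#' @export
mr_presso <- function(H, n_sim = 5000, seed, alpha = 0.05) {
  if (missing(seed)) stop("mr_presso: an explicit seed is required", call. = FALSE)
  core <- presso_core(H, n_sim, seed)
  flagged <- core$variant_id[pmin(1, core$p_snp * nrow(H)) < alpha]
  # Never remove so many SNPs that the corrected fit is undefined.
  if (nrow(H) - length(flagged) < 2) {
    flagged <- head(core$variant_id[order(core$p_snp)], nrow(H) - 2)
  }
  corrected <- presso_correct(H, flagged)
  structure(list(rss_obs = core$rss_obs, global_p = core$global_p,
                 per_snp = data.frame(variant_id = core$variant_id,
                                      p = core$p_snp, stringsAsFactors = FALSE),
                 outliers = flagged, corrected = corrected,
                 n_sim = core$n_sim, seed = core$seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (n_sim = %d, seed = %d)\n", x$n_sim, x$seed))
  cat(sprintf("  Global test: RSS = %.3f, p = %.4g\n", x$rss_obs, x$global_p))
  if (length(x$outliers) > 0) {
    cat("  Outliers:", paste(x$outliers, collapse = ", "), "\n")
  } else {
    cat("  No outliers detected\n")
  }
  cat(sprintf("  Corrected IVW: beta = %.4f (SE %.4f), p = %.3g, %d SNPs\n",
              x$corrected$beta, x$corrected$se, x$corrected$pval,
              x$corrected$n_snp))
  invisible(x)
}

#' Serialize an MR-PRESSO result as JSON
#'
#' @param x an `mr_presso` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presso <- function(x, path) {
  stopifnot(inherits(x, "mr_presso"))
  payload <- list(
    rss_obs = x$rss_obs, global_p = x$global_p, n_sim = x$n_sim,
    seed = x$seed, outliers = as.list(x$outliers),
    per_snp = lapply(seq_len(nrow(x$per_snp)), function(i) {
      list(snp = x$per_snp$variant_id[i], p = x$per_snp$p[i])
    }),
    corrected = list(beta = x$corrected$beta, se = x$corrected$se,
                     pval = x$corrected$pval, n_snp = x$corrected$n_snp)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
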