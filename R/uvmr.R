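new_mr_estimate <- function(method, beta, se, n_snp, binary = FALSE,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_p = NA_real_,
                            q_stat = NA_real_, q_df = NA_real_, q_p = NA_real_,
                            mean_f = NA_real_,
                            exposure = NA_character_, outcome = NA_character_) {
  est <- list(
    method = method, beta = beta, se = se,
    pval = z_pval(beta, se), n_snp = n_snp,
    or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
    intercept = intercept, intercept_se = intercept_se, intercept_p = intercept_p,
    q_stat = q_stat, q_df = q_df, q_p = q_p,
    mean_f = mean_f, exposure = exposure, outcome = outcome
  )
  if (isTRUE(binary) && is.finite(se)) {
    est$or <- exp(beta)
    est$or_lo <- exp(beta - 1.96 * se)
    est$or_hi <- exp(beta + 1.96 * se)
  }
  structure(est, class = "mr_estimate")
}

est_meta <- function(H) {
  list(binary = identical(attr(H, "outcome_type"), "binary"),
       exposure = attr(H, "exposure_label") %||% NA_character_,
       outcome = attr(H, "outcome_label") %||% NA_character_)
}

#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio for SNP j is the outcome association divided by the
#' exposure association, `Gamma_j / gamma_j`. Its standard error is either
#' first order, `se_Gamma / |gamma|` (the dominant convention, and what
#' feeds the IVW weights), or second order,
#' `sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)`, which
#' additionally propagates the exposure-side sampling error.
#'
#' @param H a [harmonized_set].
#' @param se_order `"first"` or `"second"`.
#' @return Data frame with columns `variant_id`, `ratio`, `se_ratio` and
#'   `weight` (`= se_ratio^-2`).
#' @export
wald_ratio <- function(H, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  if (any(H$gamma == 0)) {
    stop("wald_ratio: degenerate instrument with gamma = 0: ",
         paste(H$variant_id[H$gamma == 0], collapse = ", "), call. = FALSE)
  }
  ratio <- H$Gamma / H$gamma
  se_ratio <- if (se_order == "first") {
    H$se_Gamma / abs(H$gamma)
  } else {
    sqrt(H$se_Gamma^2 / H$gamma^2 + H$Gamma^2 * H$se_gamma^2 / H$gamma^4)
  }
  data.frame(variant_id = H$variant_id, ratio = ratio, se_ratio = se_ratio,
             weight = se_ratio^-2, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Combines the per-SNP Wald ratios into one causal estimate by
#' inverse-variance weighting; this is algebraically identical to a
#' weighted regression of `Gamma` on `gamma` through the origin with
#' weights `se_Gamma^-2` (when `se_order = "first"`). The default
#' `multiplicative_random` model inflates the fixed-effect standard error
#' by `max(1, sqrt(Q / (J - 1)))`, the multiplicative over-dispersion
#' (random-effects) convention of mainstream two-sample MR software.
#' Cochran's Q, its p-value, and the mean instrument F-statistic are
#' attached as diagnostics.
#'
#' With a single SNP the function falls back to the Wald ratio with a
#' message.
#'
#' @param H a [harmonized_set].
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @param se_order Wald-ratio SE order, see [wald_ratio()].
#' @return An object of class `mr_estimate`.
#' @export
mr_ivw <- function(H, model = c("multiplicative_random", "fixed"),
                   se_order = c("first", "second")) {
  model <- match.arg(model)
  se_order <- match.arg(se_order)
  meta <- est_meta(H)
  J <- nrow(H)
  r <- wald_ratio(H, se_order)
  if (J < 2) {
    message("mr_ivw: fewer than 2 SNPs; returning the single Wald ratio")
    return(new_mr_estimate("WaldRatio", r$ratio, r$se_ratio, n_snp = 1L,
                           binary = meta$binary, mean_f = mean_f_statistic(H),
                           exposure = meta$exposure, outcome = meta$outcome))
  }
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- sum(w)^-0.5
  q <- sum(w * (r$ratio - beta)^2)
  q_df <- J - 1
  se <- if (model == "fixed") se_fixed else se_fixed * max(1, sqrt(q / q_df))
  new_mr_estimate("IVW", beta, se, n_snp = J, binary = meta$binary,
                  q_stat = q, q_df = q_df,
                  q_p = pchisq(q, q_df, lower.tail = FALSE),
                  mean_f = mean_f_statistic(H),
                  exposure = meta$exposure, outcome = meta$outcome)
}

# Weighted least squares via the normal equations on the QR of sqrt(w) X.
# Returns coefficients, their covariance scale (X'WX)^-1, and weighted RSS.
wls_fit <- function(X, y, w) {
  sw <- sqrt(w)
  qr_fit <- qr(X * sw)
  coefs <- qr.coef(qr_fit, y * sw)
  fitted <- as.vector(X %*% coefs)
  rss <- sum(w * (y - fitted)^2)
  xtwx_inv <- chol2inv(qr.R(qr_fit))
  list(coef = coefs, xtwx_inv = xtwx_inv, rss = rss, rank = qr_fit$rank)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with a freely estimated intercept, after orienting every
#' SNP so that `gamma >= 0` (Egger regression is not orientation
#' invariant; this is the canonical convention). The slope is the causal
#' estimate; a non-zero intercept indicates directional horizontal
#' pleiotropy. Both standard errors carry the multiplicative residual
#' inflation `max(1, sqrt(Q_egger / (J - 2)))`.
#'
#' @param H a [harmonized_set] with at least 3 SNPs.
#' @return An `mr_estimate` with `intercept`, `intercept_se`, `intercept_p`
#'   fields populated.
#' @export
mr_egger <- function(H) {
  meta <- est_meta(H)
  J <- nrow(H)
  if (J < 3) stop("mr_egger: at least 3 SNPs required", call. = FALSE)
  sgn <- ifelse(H$gamma < 0, -1, 1)
  x <- H$gamma * sgn
  y <- H$Gamma * sgn
  w <- H$se_Gamma^-2
  fit <- wls_fit(cbind(intercept = 1, slope = x), y, w)
  q_df <- J - 2
  infl <- max(1, sqrt(fit$rss / q_df))
  ses <- sqrt(diag(fit$xtwx_inv)) * infl
  new_mr_estimate("Egger", fit$coef[["slope"]], ses[2], n_snp = J,
                  binary = meta$binary,
                  intercept = fit$coef[["intercept"]], intercept_se = ses[1],
                  intercept_p = z_pval(fit$coef[["intercept"]], ses[1]),
                  q_stat = fit$rss, q_df = q_df,
                  q_p = pchisq(fit$rss, q_df, lower.tail = FALSE),
                  mean_f = mean_f_statistic(H),
                  exposure = meta$exposure, outcome = meta$outcome)
}

# Weighted-median point estimate from ratio estimates: linear interpolation
# of the sorted ratios at normalized cumulative weight 0.5 (midpoint
# convention).
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- weight[ord] / sum(weight)
  cum <- cumsum(w) - w / 2
  if (length(b) == 1) return(b)
  approx(cum, b, xout = 0.5, rule = 2, ties = "ordered")$y
}

# Parametric bootstrap SE shared by the median and mode estimators:
# resample per-SNP effects from normal distributions centred at the
# observed values with the reported SEs, recompute the point estimate.
bootstrap_se <- function(H, point_fun, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  if (n_boot < 100) {
    warning("bootstrap_se: n_boot < 100 gives an unstable standard error",
            call. = FALSE)
  }
  J <- nrow(H)
  with_seed(seed, {
    est <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      g <- rnorm(J, H$gamma, H$se_gamma)
      G <- rnorm(J, H$Gamma, H$se_Gamma)
      est[b] <- point_fun(g, G)
    }
    sd(est)
  })
}

#' Weighted median estimator
#'
#' The 50% weighted percentile of the per-SNP Wald ratios, consistent when
#' more than half of the total weight comes from valid instruments. The
#' standard error is obtained by parametric bootstrap: per-SNP exposure and
#' outcome effects are resampled from normal distributions with their
#' reported standard errors and the estimator recomputed.
#'
#' @param H a [harmonized_set] with at least 3 SNPs.
#' @param n_boot bootstrap draws (default 1000). Values below 100 trigger a
#'   warning; `n_boot = 0` skips the bootstrap (SE and p reported as `NA`),
#'   which is useful in large simulation studies that only need the point
#'   estimate.
#' @param seed integer seed for the bootstrap (mandatory for
#'   reproducibility).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(H, n_boot = 1000, seed) {
  meta <- est_meta(H)
  J <- nrow(H)
  if (J < 3) stop("mr_weighted_median: at least 3 SNPs required", call. = FALSE)
  r <- wald_ratio(H, "first")
  point <- weighted_median_point(r$ratio, r$weight)
  se <- bootstrap_se(H, function(g, G) {
    keep <- g != 0
    weighted_median_point(G[keep] / g[keep], (g[keep] / H$se_Gamma[keep])^2)
  }, n_boot, seed)
  new_mr_estimate("WeightedMedian", point, se, n_snp = J, binary = meta$binary,
                  mean_f = mean_f_statistic(H),
                  exposure = meta$exposure, outcome = meta$outcome)
}

# Kernel-density mode of the ratio estimates on a fixed grid.
mode_point <- function(ratio, weight, phi, grid_n = 512) {
  n <- length(ratio)
  h <- phi * 0.9 * mad(ratio) * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # All ratios (essentially) identical: degenerate density.
    return(median(ratio))
  }
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  w <- weight / sum(weight)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - ratio) / h)) / h, numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted)
#'
#' Estimates the causal effect as the mode of the smoothed empirical
#' density of the per-SNP Wald ratios, i.e. the centre of the largest
#' cluster of SNPs with similar causal estimates; consistent when the
#' largest such cluster consists of valid instruments. A normal kernel is
#' used with bandwidth `phi` times a modified Silverman rule on the median
#' absolute deviation scale, `0.9 * mad(ratio) * J^(-1/5)`; the density is
#' maximized over a 512-point grid spanning the ratios plus/minus three
#' bandwidths. The simple mode weights every SNP equally; the weighted mode
#' weights each kernel by the SNP's inverse-variance weight. Standard
#' errors come from the same parametric bootstrap as
#' [mr_weighted_median()].
#'
#' @param H a [harmonized_set] with at least 3 SNPs.
#' @param weighted logical; `FALSE` for the simple mode.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot,seed see [mr_weighted_median()].
#' @return An `mr_estimate` with method `"SimpleMode"` or `"WeightedMode"`.
#' @export
mr_mode <- function(H, weighted = FALSE, phi = 1, n_boot = 1000, seed) {
  meta <- est_meta(H)
  J <- nrow(H)
  if (J < 3) stop("mr_mode: at least 3 SNPs required", call. = FALSE)
  if (phi <= 0) stop("mr_mode: phi must be positive", call. = FALSE)
  r <- wald_ratio(H, "first")
  wts <- if (weighted) r$weight else rep(1, J)
  point <- mode_point(r$ratio, wts, phi)
  se <- bootstrap_se(H, function(g, G) {
    keep <- g != 0
    ratio <- G[keep] / g[keep]
    w <- if (weighted) (g[keep] / H$se_Gamma[keep])^2 else rep(1, sum(keep))
    mode_point(ratio, w, phi)
  }, n_boot, seed)
  new_mr_estimate(if (weighted) "WeightedMode" else "SimpleMode",
                  point, se, n_snp = J, binary = meta$binary,
                  mean_f = mean_f_statistic(H),
                  exposure = meta$exposure, outcome = meta$outcome)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - beta_ref)^2` over the per-SNP Wald ratios, with
#' first-order inverse-variance weights; the p-value is the chi-square
#' upper tail on `J - 1` degrees of freedom.
#'
#' @param H a [harmonized_set] with at least 2 SNPs.
#' @param beta_ref reference causal estimate (defaults to the IVW point
#'   estimate).
#' @return List with elements `q`, `df`, `p`.
#' @export
cochran_q <- function(H, beta_ref = NULL) {
  J <- nrow(H)
  stopifnot(J >= 2)
  r <- wald_ratio(H, "first")
  if (is.null(beta_ref)) beta_ref <- sum(r$weight * r$ratio) / sum(r$weight)
  q <- sum(r$weight * (r$ratio - beta_ref)^2)
  list(q = q, df = J - 1, p = pchisq(q, J - 1, lower.tail = FALSE))
}

#' Mean instrument F-statistic
#'
#' Mean over SNPs of `gamma_j^2 / se_gamma_j^2`, the conventional summary
#' of instrument strength (values above ~10 indicate adequate strength).
#'
#' @param H a [harmonized_set].
#' @return Numeric scalar.
#' @export
mean_f_statistic <- function(H) {
  stopifnot(nrow(H) >= 1)
  mean(H$gamma^2 / H$se_gamma^2)
}

#' Leave-one-out IVW analysis
#'
#' Refits the multiplicative random-effects IVW estimate with each SNP
#' excluded in turn, to gauge the influence of individual variants.
#'
#' @param H a [harmonized_set] with at least 3 SNPs.
#' @return Data frame with one row per excluded SNP: `excluded_snp`,
#'   `beta`, `se`, `pval`.
#' @export
leave_one_out <- function(H) {
  J <- nrow(H)
  stopifnot(J >= 3)
  rows <- lapply(seq_len(J), function(j) {
    fit <- mr_ivw(h_subset(H, -j))
    data.frame(excluded_snp = H$variant_id[j], beta = fit$beta, se = fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
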