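#' Fit the univariable MR estimator battery
#'
#' One call fits the primary IVW estimate together with the standard
#' sensitivity battery — MR-Egger, weighted median, simple mode, weighted
#' mode and (optionally) MR-PRESSO — on a harmonized exposure/outcome SNP
#' set, the layout reported by two-sample MR studies.
#'
#' @param H a [harmonized_set].
#' @param n_boot parametric-bootstrap draws for the median/mode standard
#'   errors (default 1000; 0 skips them).
#' @param seed integer seed controlling every stochastic component
#'   (bootstrap and PRESSO); mandatory, so results are reproducible by
#'   construction.
#' @param phi mode bandwidth multiplier, see [mr_mode()].
#' @param presso logical; also run [mr_presso()] (requires >= 4 SNPs).
#' @param n_sim MR-PRESSO simulation count (default 5000).
#' @param se_order Wald-ratio SE order feeding the IVW weights.
#' @return An object of class `mr_fit`: a list with elements `estimates`
#'   (named list of `mr_estimate`), `presso` (an `mr_presso` object or
#'   `NULL`), `H`, and `loo` (left `NULL` until [leave_one_out()] is
#'   requested). Methods: `print`, `summary`, `coef`, `confint`, `plot`,
#'   `as.data.frame`.
#' @export
#' @examples
#' set.seed(1)
#' H <- harmonized_set(
#'   gamma = rnorm(30, 0.1, 0.02), se_gamma = rep(0.01, 30),
#'   Gamma = rnorm(30, 0.03, 0.01), se_Gamma = rep(0.01, 30)
#' )
#' fit <- mr_fit(H, n_boot = 100, seed = 7, presso = FALSE)
#' coef(fit)
mr_fit <- function(H, n_boot = 1000, seed, phi = 1, presso = TRUE,
                   n_sim = 5000, se_order = c("first", "second")) {
  stopifnot(inherits(H, "harmonized_set"))
  if (missing(seed)) stop("mr_fit: an explicit seed is required", call. = FALSE)
  se_order <- match.arg(se_order)
  estimates <- list(
    IVW = mr_ivw(H, se_order = se_order),
    Egger = mr_egger(H),
    SimpleMode = mr_mode(H, weighted = FALSE, phi = phi, n_boot = n_boot,
                         seed = seed + 1L),
    WeightedMedian = mr_weighted_median(H, n_boot = n_boot, seed = seed + 2L),
    WeightedMode = mr_mode(H, weighted = TRUE, phi = phi, n_boot = n_boot,
                           seed = seed + 3L)
  )
  presso_fit <- NULL
  if (presso && nrow(H) >= 4) {
    presso_fit <- mr_presso(H, n_sim = n_sim, seed = seed + 4L)
    estimates$MRPRESSO <- presso_fit$corrected
  }
  structure(list(estimates = estimates, presso = presso_fit, H = H, loo = NULL),
            class = "mr_fit")
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  out <- t(vapply(object$estimates, function(e) {
    c(e$beta - z * e$se, e$beta + z * e$se)
  }, numeric(2)))
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             pval = x$pval, or = x$or, or_lo95 = x$or_lo, or_hi95 = x$or_hi,
             q = x$q_stat, q_df = x$q_df, q_p = x$q_p,
             egger_intercept = x$intercept,
             egger_intercept_se = x$intercept_se,
             egger_intercept_p = x$intercept_p,
             mean_f = x$mean_f,
             exposure = x$exposure, outcome = x$outcome,
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(x$estimates, as.data.frame))
  rownames(out) <- NULL
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs): beta = %.4f (SE %.4f), p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$pval))
  if (is.finite(x$or)) {
    cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f)\n", x$or, x$or_lo, x$or_hi))
  }
  if (is.finite(x$intercept)) {
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' @export
print.mr_fit <- function(x, ...) {
  iv <- x$estimates$IVW
  cat(sprintf("Two-sample MR: %s -> %s (%d SNPs, mean F = %.1f)\n",
              iv$exposure, iv$outcome, iv$n_snp, iv$mean_f))
  df <- as.data.frame(x)
  show <- df[, c("method", "n_snp", "beta", "se", "pval")]
  if (any(is.finite(df$or))) {
    show$`OR (95% CI)` <- ifelse(is.finite(df$or),
                                 sprintf("%.2f (%.2f-%.2f)", df$or, df$or_lo95, df$or_hi95),
                                 "")
  }
  print(show, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  iv <- object$estimates$IVW
  eg <- object$estimates$Egger
  cat(sprintf("Two-sample MR: %s -> %s\n", iv$exposure, iv$outcome))
  cat(sprintf("Instruments: %d SNPs, mean F-statistic %.1f\n", iv$n_snp, iv$mean_f))
  cat(sprintf("Heterogeneity: Cochran's Q = %.2f on %d df (p = %.3g)\n",
              iv$q_stat, iv$q_df, iv$q_p))
  cat(sprintf("Pleiotropy: Egger intercept = %.4f (p = %.3g)\n",
              eg$intercept, eg$intercept_p))
  if (!is.null(object$presso)) {
    cat(sprintf("MR-PRESSO: global p = %.3g, %d outlier(s)\n",
                object$presso$global_p, length(object$presso$outliers)))
  }
  cat("\n")
  print(object)
  invisible(object)
}

#' Scatter plot of a univariable MR fit
#'
#' Plots the per-SNP outcome associations against the exposure
#' associations with 1-SE error bars and overlays the fitted IVW (through
#' the origin) and MR-Egger lines.
#'
#' @param x an `mr_fit` object.
#' @param ... passed to `plot()`.
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  H <- x$H
  sgn <- ifelse(H$gamma < 0, -1, 1)
  g <- H$gamma * sgn
  G <- H$Gamma * sgn
  plot(g, G, pch = 19, cex = 0.6,
       xlab = "SNP effect on exposure", ylab = "SNP effect on outcome", ...)
  segments(g, G - H$se_Gamma, g, G + H$se_Gamma, col = "grey60")
  segments(g - H$se_gamma, G, g + H$se_gamma, G, col = "grey60")
  abline(0, x$estimates$IVW$beta, col = "firebrick", lwd = 2)
  abline(x$estimates$Egger$intercept, x$estimates$Egger$beta,
         col = "steelblue", lwd = 2, lty = 2)
  legend("topleft", legend = c("IVW", "MR-Egger"), col = c("firebrick", "steelblue"),
         lty = c(1, 2), lwd = 2, bty = "n")
  invisible(x)
}

#' Write an MR estimator battery as a TSV table
#'
#' One row per method with columns `method, n_snp, beta, se, pval, or,
#' or_lo95, or_hi95, q, q_df, q_p, egger_intercept, egger_intercept_se,
#' egger_intercept_p, mean_f, exposure, outcome`.
#'
#' @param fit an `mr_fit` object (or a data frame already in that layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(fit, path) {
  df <- if (is.data.frame(fit)) fit else as.data.frame(fit)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
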