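#' Product-of-coefficients indirect effect with delta-method SE
#'
#' In two-step MR mediation, `beta1` is the causal effect of the exposure
#' on the mediator (UVMR) and `beta2` the direct effect of the mediator on
#' the outcome adjusted for the exposure (MVMR). The indirect effect is
#' the product `beta1 * beta2`, with first-order delta-method standard
#' error `sqrt(beta1^2 se2^2 + beta2^2 se1^2)` (no cross term, the
#' dominant convention in two-step MR).
#'
#' @param beta1,se1 exposure-to-mediator effect and SE.
#' @param beta2,se2 mediator-to-outcome (exposure-adjusted) effect and SE.
#' @return List with `indirect` and `se_indirect`.
#' @export
mediation_effect <- function(beta1, se1, beta2, se2) {
  stopifnot(se1 >= 0, se2 >= 0)
  list(indirect = beta1 * beta2,
       se_indirect = sqrt(beta1^2 * se2^2 + beta2^2 * se1^2))
}

#' Mediation proportion with truncation at 0%
#'
#' The proportion of the total effect explained by a mediator is the
#' indirect effect divided by the total effect. A negative raw proportion
#' is truncated to 0 (the lowest value at which a mediation proportion is
#' defined) and flagged. The standard error uses the first-order ratio
#' delta method treating the indirect and total effects as independent:
#' `|raw| * sqrt(se_indirect^2 / indirect^2 + se_total^2 / total^2)`
#' (0 when `indirect = 0`); it describes the untruncated ratio.
#'
#' @param indirect,se_indirect indirect effect and SE (see
#'   [mediation_effect()]).
#' @param total,se_total total causal effect of exposure on outcome (UVMR)
#'   and SE; `total` must be non-zero.
#' @return List with `proportion` (a fraction, in `[0, 1]` under
#'   truncation), `se_proportion` and logical `truncated`.
#' @export
mediation_proportion <- function(indirect, se_indirect, total, se_total) {
  if (total == 0) {
    stop("mediation_proportion: total effect is zero; proportion undefined",
         call. = FALSE)
  }
  raw <- indirect / total
  se <- if (indirect == 0) 0 else
    abs(raw) * sqrt(se_indirect^2 / indirect^2 + se_total^2 / total^2)
  list(proportion = max(raw, 0), se_proportion = se, truncated = raw < 0)
}

#' Benjamini-Hochberg false discovery rate q-values
#'
#' Step-up FDR adjustment: `q_i` is the smallest value of `m * p_(j) / j`
#' over ranks `j` with `p_(j) >= p_(i)`, mapped back to input order.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, order-matched to `pvals`.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Grade the strength of causal evidence for one MR association
#'
#' Applies the evidence-grading rule used for candidate screening: an IVW
#' estimate with `p < 0.05`, FDR `q < 0.05` and support from at least one
#' sensitivity analysis (a sensitivity estimate with `p < 0.05` and the
#' same effect direction as the IVW estimate) is graded `"causal"`; with
#' `p < 0.05` but `q >= 0.05` or no sensitivity support, `"suggestive"`;
#' otherwise `"none"`.
#'
#' @param ivw an `mr_estimate` (the IVW fit).
#' @param fdr_q FDR q-value for this test within its candidate family.
#' @param sensitivity list of `mr_estimate` objects from sensitivity
#'   methods on the same exposure/outcome pair.
#' @return List of class `evidence_grade` with `label` (`"causal"`,
#'   `"suggestive"` or `"none"`), `ivw_p`, `fdr_q`,
#'   `n_sensitivity_support`.
#' @export
grade_evidence <- function(ivw, fdr_q, sensitivity = list()) {
  stopifnot(inherits(ivw, "mr_estimate"))
  support <- vapply(sensitivity, function(s) {
    isTRUE(is.finite(s$pval) && s$pval < 0.05 && sign(s$beta) == sign(ivw$beta))
  }, logical(1))
  n_support <- sum(support)
  label <- if (!is.finite(ivw$pval) || ivw$pval >= 0.05) {
    "none"
  } else if (fdr_q < 0.05 && n_support >= 1) {
    "causal"
  } else {
    "suggestive"
  }
  structure(list(label = label, ivw_p = ivw$pval, fdr_q = fdr_q,
                 n_sensitivity_support = n_support),
            class = "evidence_grade")
}

#' @export
print.evidence_grade <- function(x, ...) {
  cat(sprintf("Evidence: %s (IVW p = %.3g, q = %.3g, %d supporting sensitivity)\n",
              x$label, x$ivw_p, x$fdr_q, x$n_sensitivity_support))
  invisible(x)
}

#' Screen candidate mediators and quantify mediation for those qualifying
#'
#' Applies the three screening criteria to each candidate mediator of an
#' exposure-outcome association:
#'
#' 1. the exposure is causally associated with the mediator — the step-1
#'    UVMR estimate is graded at least suggestive, with FDR computed
#'    across the whole candidate battery (one family);
#' 2. the mediator has a direct causal effect on the outcome independently
#'    of the exposure — step-2 MV-IVW `p < 0.05`;
#' 3. the total effect and the mediating effect (`beta1 * beta2`) share
#'    the same direction.
#'
#' Mediation proportions (with delta-method SEs and 0% truncation) are
#' computed for qualified candidates only.
#'
#' @param candidates named list, one element per candidate mediator, each
#'   a list with elements `step1` (`mr_estimate`, exposure -> mediator
#'   IVW), `step2` (`mr_estimate`, mediator -> outcome MV-IVW adjusted for
#'   the exposure), `total` (`mr_estimate`, exposure -> outcome IVW) and
#'   optionally `sensitivity` (list of `mr_estimate`s supporting step 1).
#' @return Data frame of class `mediation_screen`, one row per candidate:
#'   `mediator`, `beta1`, `se1`, `beta2`, `se2`, `indirect`,
#'   `se_indirect`, `total`, `se_total`, `proportion`, `se_proportion`,
#'   `truncated`, `qualified`, `failed_criteria` (comma-separated subset
#'   of "1","2","3"), `step1_q`, `grade`.
#' @export
screen_mediators <- function(candidates) {
  if (length(candidates) == 0) {
    return(structure(empty_mediation_df(), class = c("mediation_screen", "data.frame")))
  }
  labels <- names(candidates) %||% paste0("mediator", seq_along(candidates))
  p1 <- vapply(candidates, function(cand) cand$step1$pval, numeric(1))
  # extreme z-statistics underflow to p = 0; clamp to the smallest double
  q1 <- bh_fdr(pmax(p1, .Machine$double.xmin))

  rows <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    grade <- grade_evidence(cand$step1, q1[i], cand$sensitivity %||% list())
    b1 <- cand$step1$beta; s1 <- cand$step1$se
    b2 <- cand$step2$beta; s2 <- cand$step2$se
    tot <- cand$total$beta; s_tot <- cand$total$se
    med <- mediation_effect(b1, s1, b2, s2)

    failed <- character(0)
    if (grade$label == "none") failed <- c(failed, "1")
    if (!is.finite(cand$step2$pval) || cand$step2$pval >= 0.05) failed <- c(failed, "2")
    if (sign(med$indirect) != sign(tot)) failed <- c(failed, "3")
    qualified <- length(failed) == 0

    prop <- if (qualified) {
      mediation_proportion(med$indirect, med$se_indirect, tot, s_tot)
    } else {
      list(proportion = NA_real_, se_proportion = NA_real_, truncated = NA)
    }
    data.frame(mediator = labels[i], beta1 = b1, se1 = s1, beta2 = b2, se2 = s2,
               indirect = med$indirect, se_indirect = med$se_indirect,
               total = tot, se_total = s_tot,
               proportion = prop$proportion, se_proportion = prop$se_proportion,
               truncated = prop$truncated, qualified = qualified,
               failed_criteria = paste(failed, collapse = ","),
               step1_q = q1[i], grade = grade$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mediation_screen", "data.frame"))
}

empty_mediation_df <- function() {
  data.frame(mediator = character(), beta1 = numeric(), se1 = numeric(),
             beta2 = numeric(), se2 = numeric(), indirect = numeric(),
             se_indirect = numeric(), total = numeric(), se_total = numeric(),
             proportion = numeric(), se_proportion = numeric(),
             truncated = logical(), qualified = logical(),
             failed_criteria = character(), step1_q = numeric(),
             grade = character(), stringsAsFactors = FALSE)
}

#' Write a mediation screening table as TSV
#'
#' Columns mirror the three-panel mediation display: step-1 and step-2
#' effects, indirect and total effects, and mediation proportions in
#' percent.
#'
#' @param x a `mediation_screen` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mediation <- function(x, path) {
  out <- as.data.frame(x)
  out$proportion_pct <- 100 * out$proportion
  out$proportion_se_pct <- 100 * out$se_proportion
  out$proportion <- NULL
  out$se_proportion <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
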