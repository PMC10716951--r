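#' Build a multivariable MR instrument set
#'
#' Takes the union of SNPs genome-wide significant in any of the K
#' exposures, clumps the union keyed on the smallest p-value across
#' exposures, harmonizes every trait to the first exposure's effect-allele
#' convention, and drops SNPs missing in any trait (logged in the
#' `dropped` attribute).
#'
#' @param exposures list of two or more [summary_stats] objects; the first
#'   is the reference exposure whose allele convention anchors the set.
#' @param outcome a [summary_stats] object.
#' @param ld pairwise r^2 records, or `NULL`.
#' @param criteria an [instrument_criteria] object.
#' @param palindrome_policy,eaf_window passed to [harmonize()].
#' @return Object of class `mvmr_set`: data frame with `variant_id`, one
#'   `gamma_<label>` / `se_gamma_<label>` pair per exposure, `Gamma`,
#'   `se_Gamma`; attributes `exposure_labels`, `outcome_label`,
#'   `outcome_type`, `dropped`.
#' @export
build_mvmr_set <- function(exposures, outcome, ld = NULL,
                           criteria = instrument_criteria(),
                           palindrome_policy = "drop_ambiguous",
                           eaf_window = 0.08) {
  stopifnot(is.list(exposures), length(exposures) >= 2)
  K <- length(exposures)
  labels <- vapply(exposures, function(e) attr(e, "trait_label"), character(1))

  # Union of genome-wide significant SNPs across exposures, each SNP keyed
  # on its smallest p-value for the clumping rank.
  sig <- lapply(exposures, function(e) {
    as.data.frame(e)[e$pval < criteria$p_threshold,
                     c("variant_id", "chrom", "pos", "pval"), drop = FALSE]
  })
  union_df <- do.call(rbind, sig)
  if (nrow(union_df) == 0) {
    stop("build_mvmr_set: no SNPs pass p < ", format(criteria$p_threshold),
         " in any exposure", call. = FALSE)
  }
  agg <- stats::aggregate(pval ~ variant_id + chrom + pos, data = union_df, FUN = min)
  rank_stats <- structure(
    data.frame(variant_id = agg$variant_id, chrom = agg$chrom, pos = agg$pos,
               pval = agg$pval, stringsAsFactors = FALSE),
    class = c("summary_stats", "data.frame"), trait_label = "union")
  kept <- ld_clump(rank_stats, ld, criteria)

  dropped <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  log_drop <- function(ids, reason) {
    if (length(ids) > 0) {
      dropped <<- rbind(dropped, data.frame(variant_id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }

  # Harmonize each non-reference trait to the reference exposure's
  # orientation; each harmonize() call contributes its own drop log.
  per_trait <- list()
  ids <- kept
  for (k in seq_len(K)) {
    if (k == 1) {
      df <- as.data.frame(exposures[[1]])
      m <- match(ids, df$variant_id)
      present <- !is.na(m)
      log_drop(ids[!present], "missing_in_exposure")
      ids <- ids[present]
      per_trait[[k]] <- data.frame(variant_id = ids,
                                   gamma = df$beta[m[present]],
                                   se = df$se[m[present]],
                                   stringsAsFactors = FALSE)
    } else {
      h <- tryCatch(
        harmonize(subset_variants(exposures[[1]], ids), exposures[[k]],
                  palindrome_policy = palindrome_policy, eaf_window = eaf_window),
        error = function(e) NULL)
      hd <- if (is.null(h)) {
        data.frame(variant_id = ids, reason = "missing_in_exposure")
      } else {
        attr(h, "dropped")
      }
      if (nrow(hd) > 0) {
        hd$reason <- "missing_in_exposure"
        dropped <- rbind(dropped, hd)
      }
      if (is.null(h)) {
        stop("build_mvmr_set: no overlap with exposure '", labels[k], "'",
             call. = FALSE)
      }
      ids <- intersect(ids, h$variant_id)
      per_trait[[k]] <- data.frame(variant_id = h$variant_id,
                                   gamma = h$Gamma, se = h$se_Gamma,
                                   stringsAsFactors = FALSE)
    }
  }
  h_out <- harmonize(subset_variants(exposures[[1]], ids), outcome,
                     palindrome_policy = palindrome_policy,
                     eaf_window = eaf_window)
  if (nrow(attr(h_out, "dropped")) > 0) {
    dropped <- rbind(dropped, attr(h_out, "dropped"))
  }
  ids <- intersect(ids, h_out$variant_id)

  out <- data.frame(variant_id = ids, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    m <- match(ids, per_trait[[k]]$variant_id)
    out[[paste0("gamma_", labels[k])]] <- per_trait[[k]]$gamma[m]
    out[[paste0("se_gamma_", labels[k])]] <- per_trait[[k]]$se[m]
  }
  m <- match(ids, h_out$variant_id)
  out$Gamma <- h_out$Gamma[m]
  out$se_Gamma <- h_out$se_Gamma[m]
  out <- out[complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL

  if (nrow(out) < K + 2) {
    stop("build_mvmr_set: only ", nrow(out), " SNPs remain for ", K,
         " exposures; the model is under-identified", call. = FALSE)
  }
  structure(out,
            class = c("mvmr_set", "data.frame"),
            exposure_labels = labels,
            outcome_label = attr(outcome, "trait_label"),
            outcome_type = attr(outcome, "trait_type"),
            dropped = dropped)
}

#' Assemble a multivariable MR set from aligned effect matrices
#'
#' Simulation/testing constructor bypassing allele harmonization.
#'
#' @param gammas J x K matrix of SNP-exposure effects (one column per
#'   exposure).
#' @param se_gammas J x K matrix of their standard errors.
#' @param Gamma,se_Gamma SNP-outcome effects and standard errors.
#' @param variant_id SNP identifiers.
#' @param exposure_labels length-K character vector.
#' @param outcome_label,outcome_type outcome annotation.
#' @return An `mvmr_set` object.
#' @export
mvmr_set <- function(gammas, se_gammas, Gamma, se_Gamma,
                     variant_id = paste0("snp", seq_len(nrow(gammas))),
                     exposure_labels = paste0("X", seq_len(ncol(gammas))),
                     outcome_label = "outcome", outcome_type = "continuous") {
  gammas <- as.matrix(gammas)
  se_gammas <- as.matrix(se_gammas)
  stopifnot(ncol(gammas) >= 2, all(dim(gammas) == dim(se_gammas)),
            nrow(gammas) == length(Gamma), length(Gamma) == length(se_Gamma),
            ncol(gammas) == length(exposure_labels))
  out <- data.frame(variant_id = as.character(variant_id), stringsAsFactors = FALSE)
  for (k in seq_len(ncol(gammas))) {
    out[[paste0("gamma_", exposure_labels[k])]] <- gammas[, k]
    out[[paste0("se_gamma_", exposure_labels[k])]] <- se_gammas[, k]
  }
  out$Gamma <- Gamma
  out$se_Gamma <- se_Gamma
  structure(out,
            class = c("mvmr_set", "data.frame"),
            exposure_labels = exposure_labels,
            outcome_label = outcome_label,
            outcome_type = outcome_type,
            dropped = data.frame(variant_id = character(), reason = character()))
}

mvmr_design <- function(M) {
  labels <- attr(M, "exposure_labels")
  X <- as.matrix(as.data.frame(M)[paste0("gamma_", labels)])
  colnames(X) <- labels
  X
}

mvmr_wls <- function(M, intercept = FALSE, orient_first = FALSE) {
  labels <- attr(M, "exposure_labels")
  K <- length(labels)
  J <- nrow(M)
  X <- mvmr_design(M)
  y <- M$Gamma
  w <- M$se_Gamma^-2
  if (orient_first) {
    sgn <- ifelse(X[, 1] < 0, -1, 1)
    X <- X * sgn
    y <- y * sgn
  }
  # Exactly-zero exposure columns carry no information: drop them and
  # report NA coefficients (the remaining fit is the reduced model).
  zero_col <- apply(X, 2, function(col) all(col == 0))
  Xa <- if (intercept) cbind(`(intercept)` = 1, X[, !zero_col, drop = FALSE]) else
    X[, !zero_col, drop = FALSE]
  p <- ncol(Xa)
  if (J <= p) stop("mvmr: fewer SNPs than parameters", call. = FALSE)
  sw <- sqrt(w)
  cond <- kappa(Xa * sw, exact = TRUE)
  if (!is.finite(cond) || cond > 1e8) {
    stop(sprintf("mvmr: near-collinear exposure design (condition number %.3g)",
                 cond), call. = FALSE)
  }
  fit <- wls_fit(Xa, y, w)
  df <- J - p
  infl <- max(1, sqrt(fit$rss / df))
  ses <- sqrt(diag(fit$xtwx_inv)) * infl

  full_coef <- setNames(rep(NA_real_, K), labels)
  full_se <- setNames(rep(NA_real_, K), labels)
  keep_labels <- labels[!zero_col]
  offset <- if (intercept) 1 else 0
  full_coef[keep_labels] <- fit$coef[offset + seq_along(keep_labels)]
  full_se[keep_labels] <- ses[offset + seq_along(keep_labels)]
  list(coef = full_coef, se = full_se,
       intercept = if (intercept) fit$coef[[1]] else NA_real_,
       intercept_se = if (intercept) ses[1] else NA_real_,
       q = fit$rss, q_df = df, n_snp = J, cond = cond)
}

mvmr_estimates <- function(fit, M, method) {
  labels <- attr(M, "exposure_labels")
  binary <- identical(attr(M, "outcome_type"), "binary")
  ests <- lapply(seq_along(labels), function(k) {
    e <- new_mr_estimate(method, fit$coef[[k]], fit$se[[k]], n_snp = fit$n_snp,
                         binary = binary,
                         intercept = fit$intercept, intercept_se = fit$intercept_se,
                         intercept_p = z_pval(fit$intercept, fit$intercept_se),
                         q_stat = fit$q, q_df = fit$q_df,
                         q_p = pchisq(fit$q, fit$q_df, lower.tail = FALSE),
                         exposure = labels[k],
                         outcome = attr(M, "outcome_label"))
    e
  })
  names(ests) <- labels
  ests
}

#' Multivariable IVW estimate (MV-IVW)
#'
#' Weighted multiple regression of the outcome associations on the K
#' exposure-association columns with no intercept and weights
#' `se_Gamma^-2`; each coefficient is the direct effect of that exposure
#' conditional on the others. Standard errors carry the multiplicative
#' residual inflation `max(1, sqrt(Q / (J - K)))`. A near-collinear design
#' (condition number > 1e8) raises an error reporting the condition
#' number; an exactly-zero exposure column is dropped with an `NA`
#' coefficient, reducing to the smaller model.
#'
#' @param M an `mvmr_set` (from [build_mvmr_set()] or [mvmr_set()]).
#' @return Named list of `mr_estimate` objects, one per exposure.
#' @export
mv_ivw <- function(M) {
  stopifnot(inherits(M, "mvmr_set"))
  fit <- mvmr_wls(M, intercept = FALSE)
  mvmr_estimates(fit, M, "MV-IVW")
}

#' Multivariable MR-Egger estimate
#'
#' As [mv_ivw()] but with a freely estimated intercept, after orienting
#' every SNP so that the first-listed exposure's association is
#' non-negative; the intercept's p-value indicates directional pleiotropy.
#'
#' @param M an `mvmr_set`.
#' @return Named list of `mr_estimate` objects (each carrying the shared
#'   intercept fields), one per exposure.
#' @export
mv_egger <- function(M) {
  stopifnot(inherits(M, "mvmr_set"))
  if (nrow(M) < length(attr(M, "exposure_labels")) + 3) {
    stop("mv_egger: needs at least K + 3 SNPs", call. = FALSE)
  }
  fit <- mvmr_wls(M, intercept = TRUE, orient_first = TRUE)
  mvmr_estimates(fit, M, "MVMR-Egger")
}

#' Fit multivariable MR (MV-IVW with MVMR-Egger check)
#'
#' @param M an `mvmr_set`.
#' @return Object of class `mvmr_fit` with elements `ivw` and `egger`
#'   (each a named list of per-exposure `mr_estimate`s) and `M`.
#'   Methods: `print`, `coef`, `as.data.frame`.
#' @export
mvmr_fit <- function(M) {
  structure(list(ivw = mv_ivw(M),
                 egger = if (nrow(M) >= length(attr(M, "exposure_labels")) + 3)
                   mv_egger(M) else NULL,
                 M = M),
            class = "mvmr_fit")
}

#' @export
coef.mvmr_fit <- function(object, ...) {
  vapply(object$ivw, function(e) e$beta, numeric(1))
}

#' @export
as.data.frame.mvmr_fit <- function(x, ...) {
  rows <- c(lapply(x$ivw, as.data.frame),
            if (!is.null(x$egger)) lapply(x$egger, as.data.frame))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("exposure", "method", "n_snp", "beta", "se", "pval", "or", "or_lo95",
          "or_hi95", "egger_intercept", "egger_intercept_se",
          "egger_intercept_p", "q", "q_df", "q_p", "outcome")]
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("Multivariable MR: {%s} -> %s (%d SNPs)\n",
              paste(attr(x$M, "exposure_labels"), collapse = ", "),
              attr(x$M, "outcome_label"), nrow(x$M)))
  df <- as.data.frame(x)
  print(df[, c("exposure", "method", "beta", "se", "pval")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
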