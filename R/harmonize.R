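COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) unname(COMPLEMENT[ea]) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations to the exposure's effect-allele
#' convention, SNP by SNP. When the outcome's effect/other alleles are
#' swapped relative to the exposure (directly or on the opposite strand),
#' the outcome beta sign is flipped. Palindromic SNPs (A/T or C/G), whose
#' strand cannot be resolved from the alleles alone, are handled per
#' `palindrome_policy`:
#'
#' * `"drop_ambiguous"` (default): every palindromic SNP is dropped —
#'   the conservative convention.
#' * `"infer_by_eaf"`: orientation is inferred from allele frequency; the
#'   SNP is kept when both frequencies fall outside the ambiguity band
#'   `[0.5 - eaf_window, 0.5 + eaf_window]`, oriented so that minor alleles
#'   agree, and dropped as ambiguous otherwise (including missing `eaf`).
#'
#' Irreconcilable allele pairs (e.g. A/G vs A/C) and exposure SNPs absent
#' from the outcome are dropped with reasons, never raised as errors.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param palindrome_policy `"drop_ambiguous"` or `"infer_by_eaf"`.
#' @param eaf_window half-width of the frequency ambiguity band around 0.5;
#'   must lie in (0, 0.5). The default 0.08 treats eaf in \[0.42, 0.58\] as
#'   ambiguous.
#'
#' @return A data frame of class `harmonized_set` with columns
#'   `variant_id`, `gamma`, `se_gamma` (SNP-exposure effect and SE),
#'   `Gamma`, `se_Gamma` (SNP-outcome effect and SE, on the exposure's
#'   effect allele), plus `chrom`, `pos`, `pval_exposure`. Attributes:
#'   `exposure_label`, `outcome_label`, `outcome_type`, `exposure_type`,
#'   and `dropped` (data frame `variant_id`, `reason` with reasons among
#'   `allele_mismatch`, `palindromic_ambiguous`, `missing_in_outcome`).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "infer_by_eaf"),
                      eaf_window = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  palindrome_policy <- match.arg(palindrome_policy)
  if (!(eaf_window > 0 && eaf_window < 0.5)) {
    stop("harmonize: eaf_window must lie in (0, 0.5)", call. = FALSE)
  }

  dropped <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids) > 0) {
      dropped <<- rbind(dropped, data.frame(variant_id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }

  idx <- match(exposure$variant_id, outcome$variant_id)
  drop(exposure$variant_id[is.na(idx)], "missing_in_outcome")
  exp_df <- as.data.frame(exposure)[!is.na(idx), , drop = FALSE]
  out_df <- as.data.frame(outcome)[idx[!is.na(idx)], , drop = FALSE]

  n <- nrow(exp_df)
  keep <- logical(n)
  flip <- logical(n)
  if (n > 0) {
    e_ea <- exp_df$effect_allele; e_oa <- exp_df$other_allele
    o_ea <- out_df$effect_allele; o_oa <- out_df$other_allele
    pal <- is_palindromic(e_ea, e_oa)

    same <- (o_ea == e_ea & o_oa == e_oa) |
      (unname(COMPLEMENT[o_ea]) == e_ea & unname(COMPLEMENT[o_oa]) == e_oa)
    swapped <- (o_ea == e_oa & o_oa == e_ea) |
      (unname(COMPLEMENT[o_ea]) == e_oa & unname(COMPLEMENT[o_oa]) == e_ea)

    # Non-palindromic SNPs: orientation resolved by allele identity alone.
    ok <- !pal & (same | swapped)
    keep[ok] <- TRUE
    flip[ok] <- swapped[ok] & !same[ok]
    drop(exp_df$variant_id[!pal & !ok], "allele_mismatch")

    # Palindromic SNPs: same/swapped are indistinguishable (a strand flip
    # converts one into the other), so alleles must at least be compatible.
    pal_ok <- pal & (same | swapped)
    drop(exp_df$variant_id[pal & !pal_ok], "allele_mismatch")
    if (palindrome_policy == "drop_ambiguous") {
      drop(exp_df$variant_id[pal_ok], "palindromic_ambiguous")
    } else {
      eaf_e <- exp_df$eaf
      eaf_o <- out_df$eaf
      # The outcome file's stated effect allele may be the exposure's other
      # allele; compare frequencies on the exposure's effect allele.
      eaf_o_aligned <- ifelse(swapped & !same, 1 - eaf_o, eaf_o)
      clear <- !is.na(eaf_e) & !is.na(eaf_o) &
        abs(eaf_e - 0.5) > eaf_window & abs(eaf_o - 0.5) > eaf_window
      resolvable <- pal_ok & clear
      drop(exp_df$variant_id[pal_ok & !clear], "palindromic_ambiguous")
      keep[resolvable] <- TRUE
      # Minor alleles agree => effect alleles already on the same strand
      # orientation; disagree => the outcome effect allele is really the
      # exposure's other allele.
      flip[resolvable] <- (eaf_e[resolvable] < 0.5) != (eaf_o_aligned[resolvable] < 0.5)
    }
  }

  exp_keep <- exp_df[keep, , drop = FALSE]
  out_keep <- out_df[keep, , drop = FALSE]
  flip <- flip[keep]
  if (nrow(exp_keep) == 0) {
    stop("harmonize: no shared SNPs with resolvable orientation between '",
         attr(exposure, "trait_label"), "' and '", attr(outcome, "trait_label"),
         "'", call. = FALSE)
  }

  h <- data.frame(
    variant_id = exp_keep$variant_id,
    chrom = exp_keep$chrom,
    pos = exp_keep$pos,
    gamma = exp_keep$beta,
    se_gamma = exp_keep$se,
    Gamma = ifelse(flip, -out_keep$beta, out_keep$beta),
    se_Gamma = out_keep$se,
    pval_exposure = exp_keep$pval,
    stringsAsFactors = FALSE
  )
  rownames(h) <- NULL
  structure(h,
            class = c("harmonized_set", "data.frame"),
            exposure_label = attr(exposure, "trait_label"),
            outcome_label = attr(outcome, "trait_label"),
            exposure_type = attr(exposure, "trait_type"),
            outcome_type = attr(outcome, "trait_type"),
            dropped = dropped)
}

#' Assemble a harmonized set directly from aligned effect estimates
#'
#' Convenience constructor for simulation studies and tests where the
#' exposure and outcome effects are already on a shared effect-allele
#' convention.
#'
#' @param variant_id character vector of SNP identifiers.
#' @param gamma,se_gamma SNP-exposure effects and standard errors.
#' @param Gamma,se_Gamma SNP-outcome effects and standard errors.
#' @param exposure_label,outcome_label trait labels.
#' @param outcome_type `"binary"` or `"continuous"`; binary outcomes are
#'   reported as odds ratios by the estimators.
#' @return A `harmonized_set` object.
#' @export
harmonized_set <- function(gamma, se_gamma, Gamma, se_Gamma,
                           variant_id = paste0("snp", seq_along(gamma)),
                           exposure_label = "exposure",
                           outcome_label = "outcome",
                           outcome_type = "continuous") {
  stopifnot(length(gamma) == length(se_gamma),
            length(gamma) == length(Gamma),
            length(gamma) == length(se_Gamma),
            all(se_gamma > 0), all(se_Gamma > 0))
  h <- data.frame(variant_id = as.character(variant_id),
                  chrom = NA_character_, pos = NA_integer_,
                  gamma = gamma, se_gamma = se_gamma,
                  Gamma = Gamma, se_Gamma = se_Gamma,
                  pval_exposure = z_pval(gamma, se_gamma),
                  stringsAsFactors = FALSE)
  structure(h,
            class = c("harmonized_set", "data.frame"),
            exposure_label = exposure_label,
            outcome_label = outcome_label,
            exposure_type = "continuous",
            outcome_type = outcome_type,
            dropped = data.frame(variant_id = character(), reason = character()))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s, %d SNPs (%d dropped)\n",
              attr(x, "exposure_label"), attr(x, "outcome_label"),
              nrow(x), nrow(attr(x, "dropped"))))
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Write a harmonized set (and its dropped-SNP companion) as TSV
#'
#' The main table has columns `SNP, GAMMA, SE_GAMMA, GAMMA_OUT,
#' SE_GAMMA_OUT`; dropped SNPs and their reasons go to
#' `<path>.dropped.tsv`.
#'
#' @param h a `harmonized_set`.
#' @param path output path for the main table.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  stopifnot(inherits(h, "harmonized_set"))
  out <- data.frame(SNP = h$variant_id, GAMMA = h$gamma, SE_GAMMA = h$se_gamma,
                    GAMMA_OUT = h$Gamma, SE_GAMMA_OUT = h$se_Gamma)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dropped <- attr(h, "dropped")
  write.table(dropped, paste0(path, ".dropped.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Subset rows of a harmonized set, preserving attributes.
h_subset <- function(h, i) {
  out <- as.data.frame(h)[i, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(h)
  structure(out,
            class = attrs$class,
            exposure_label = attrs$exposure_label,
            outcome_label = attrs$outcome_label,
            exposure_type = attrs$exposure_type,
            outcome_type = attrs$outcome_type,
            dropped = attrs$dropped)
}
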