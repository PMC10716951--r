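#' Instrument selection criteria
#'
#' @param p_threshold genome-wide significance threshold for instrument
#'   inclusion (default `5e-8`).
#' @param r2_threshold pairwise LD cut-off: a SNP is kept only if its r^2
#'   with every already-kept SNP inside the window is strictly below this
#'   value (default `0.001`).
#' @param window_kb clumping window in kilobases; two SNPs are "within the
#'   window" when they share a chromosome and `|pos_i - pos_j| <=
#'   window_kb * 1000` (default `10000`).
#' @return A list of class `instrument_criteria`.
#' @export
instrument_criteria <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                                window_kb = 10000) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold > 0, r2_threshold < 1,
            window_kb > 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb),
            class = "instrument_criteria")
}

#' Read pairwise LD information
#'
#' Accepts either a three-column tab-separated pair list (`SNP_A`, `SNP_B`,
#' `R2`) or a square r^2 matrix with variant identifiers as header and row
#' labels. Returns the pair-list representation used by [ld_clump()]. Pairs
#' absent from the input are treated as r^2 = 0 downstream.
#'
#' @param path path to a tab-separated file.
#' @return data frame with columns `SNP_A`, `SNP_B`, `R2`.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("read_ld: file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (all(c("SNP_A", "SNP_B", "R2") %in% names(raw))) {
    return(data.frame(SNP_A = as.character(raw$SNP_A),
                      SNP_B = as.character(raw$SNP_B),
                      R2 = as.numeric(raw$R2), stringsAsFactors = FALSE))
  }
  # Square-matrix form: first column holds row labels.
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!identical(colnames(m), ids)) {
    stop("read_ld: matrix row and column labels disagree", call. = FALSE)
  }
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(SNP_A = ids[pairs[, 1]], SNP_B = ids[pairs[, 2]],
             R2 = as.numeric(m[pairs]), stringsAsFactors = FALSE)
}

# Hash of pairwise r2 values keyed on the sorted id pair.
ld_lookup <- function(ld) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (!is.null(ld) && nrow(ld) > 0) {
    a <- pmin(ld$SNP_A, ld$SNP_B)
    b <- pmax(ld$SNP_A, ld$SNP_B)
    keys <- paste(a, b, sep = "\r")
    for (i in seq_along(keys)) assign(keys[i], ld$R2[i], envir = env)
  }
  function(x, y) {
    key <- paste(min(x, y), max(x, y), sep = "\r")
    if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env) else 0
  }
}

#' Greedy LD clumping
#'
#' Selects approximately independent SNPs: candidates are ranked by
#' ascending p-value (ties broken lexicographically on `variant_id` for
#' determinism) and accepted greedily; a SNP is accepted iff its r^2 with
#' every already-accepted SNP on the same chromosome within `window_kb` is
#' strictly below `r2_threshold`. Pairs missing from `ld` count as r^2 = 0,
#' so absent LD evidence never discards an instrument.
#'
#' @param stats a [summary_stats] object (non-empty input required only in
#'   the sense that an empty table yields an empty result).
#' @param ld pairwise r^2 records as returned by [read_ld()], or `NULL`.
#' @param criteria an [instrument_criteria] object; only `r2_threshold` and
#'   `window_kb` are used here.
#' @return Character vector of retained `variant_id`s, in selection order.
#' @export
ld_clump <- function(stats, ld = NULL, criteria = instrument_criteria()) {
  stopifnot(inherits(criteria, "instrument_criteria"))
  if (nrow(stats) == 0) return(character())
  ord <- order(stats$pval, stats$variant_id)
  id <- stats$variant_id[ord]
  chrom <- stats$chrom[ord]
  pos <- as.numeric(stats$pos[ord])
  r2 <- ld_lookup(ld)
  window_bp <- criteria$window_kb * 1000

  kept <- integer(0)
  for (i in seq_along(id)) {
    ok <- TRUE
    for (j in kept) {
      if (identical(chrom[i], chrom[j]) && abs(pos[i] - pos[j]) <= window_bp &&
          r2(id[i], id[j]) >= criteria$r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  id[kept]
}

#' Select genetic instruments by significance filtering and clumping
#'
#' Filters to SNPs with `pval < p_threshold`, optionally restricts to a
#' given variant list (e.g. fetal-only or maternal-only instrument classes),
#' then applies greedy LD clumping.
#'
#' @param stats a [summary_stats] object.
#' @param ld pairwise r^2 records, or `NULL`.
#' @param criteria an [instrument_criteria] object.
#' @param restrict_to optional character vector of variant ids; selection is
#'   intersected with this list before clumping.
#' @return A [summary_stats] object containing the selected instruments.
#' @export
select_instruments <- function(stats, ld = NULL, criteria = instrument_criteria(),
                               restrict_to = NULL) {
  stopifnot(inherits(stats, "summary_stats"), inherits(criteria, "instrument_criteria"))
  candidates <- stats[stats$pval < criteria$p_threshold, , drop = FALSE]
  if (!is.null(restrict_to)) {
    candidates <- candidates[candidates$variant_id %in% restrict_to, , drop = FALSE]
  }
  if (nrow(candidates) == 0) {
    stop("select_instruments: no SNPs pass p < ", format(criteria$p_threshold),
         " for trait '", attr(stats, "trait_label"), "'", call. = FALSE)
  }
  kept <- ld_clump(subset_variants(stats, candidates$variant_id), ld, criteria)
  subset_variants(stats, kept)
}
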