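#' Construct a validated GWAS summary-statistics table
#'
#' A `summary_stats` object is a data frame of per-variant association
#' records for a single trait, the basic currency of two-sample MR. Rows
#' that violate the record invariants (non-positive standard error, p-value
#' outside (0, 1], malformed alleles, allele frequency outside \[0, 1\]) are
#' removed and collected, with reasons, in the `rejects` attribute rather
#' than silently dropped.
#'
#' @param x data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf` (may be `NA`), `beta`, `se`,
#'   `pval`, `n`.
#' @param trait_label character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`; binary traits carry
#'   effects on the log-odds scale.
#' @param unit_note free-text unit annotation (e.g. `"1-SD"`, `"log-odds"`).
#'
#' @return A data frame of class `summary_stats` with attributes
#'   `trait_label`, `trait_type`, `unit_note` and `rejects` (a data frame
#'   with columns `variant_id`, `reason`).
#' @seealso [read_gwas_table()], [harmonize()], [select_instruments()]
#' @export
#' @examples
#' ss <- summary_stats(
#'   data.frame(
#'     variant_id = c("rs1", "rs2"), chrom = c("1", "2"),
#'     pos = c(1000L, 2000L), effect_allele = c("A", "C"),
#'     other_allele = c("G", "T"), eaf = c(0.3, 0.4),
#'     beta = c(0.05, -0.02), se = c(0.01, 0.01),
#'     pval = c(1e-8, 0.04), n = c(10000L, 10000L)
#'   ),
#'   trait_label = "exposure", trait_type = "continuous"
#' )
summary_stats <- function(x, trait_label, trait_type = c("continuous", "binary"),
                          unit_note = "") {
  trait_type <- match.arg(trait_type)
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("summary_stats: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[required]
  x$variant_id <- as.character(x$variant_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) x[[col]] <- as.numeric(x[[col]])
  x$pos <- as.integer(x$pos)
  x$n <- as.integer(x$n)

  dup <- unique(x$variant_id[duplicated(x$variant_id)])
  if (length(dup) > 0) {
    stop("summary_stats: duplicate variant_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(x))
  bad_allele <- !(x$effect_allele %in% bases) | !(x$other_allele %in% bases)
  reason[is.na(reason) & bad_allele] <- "invalid allele"
  same_allele <- !bad_allele & x$effect_allele == x$other_allele
  reason[is.na(reason) & same_allele] <- "effect allele equals other allele"
  reason[is.na(reason) & (is.na(x$se) | x$se <= 0)] <- "nonpositive se"
  reason[is.na(reason) & (is.na(x$pval) | x$pval <= 0 | x$pval > 1)] <- "pval outside (0,1]"
  reason[is.na(reason) & (is.na(x$beta) | !is.finite(x$beta))] <- "missing beta"
  reason[is.na(reason) & !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)] <- "eaf outside [0,1]"
  reason[is.na(reason) & (is.na(x$n) | x$n <= 0)] <- "nonpositive n"

  rejects <- data.frame(variant_id = x$variant_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  x <- x[is.na(reason), , drop = FALSE]
  rownames(x) <- NULL

  structure(x,
            class = c("summary_stats", "data.frame"),
            trait_label = trait_label,
            trait_type = trait_type,
            unit_note = unit_note,
            rejects = rejects)
}

#' Read a GWAS summary-statistics table from a delimited text file
#'
#' Reads a tab-separated table with a header row and maps its columns onto
#' the canonical schema `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`.
#' Files using different column names are accommodated through `dialect`,
#' a named character vector mapping canonical names to the file's names.
#' Missing allele frequencies are encoded as `NA`.
#'
#' @param path path to a tab-separated file.
#' @param trait_label,trait_type,unit_note passed to [summary_stats()].
#' @param dialect named character vector; names are the canonical column
#'   names (`SNP`, `CHR`, ...), values the corresponding column names in the
#'   file. Unmentioned columns are assumed to use canonical names.
#' @param proxy_map optional data frame with columns `original_id`,
#'   `proxy_id`: variant identifiers are renamed `proxy_id -> original_id`
#'   before validation, so tables in which unavailable variants were
#'   replaced by pre-resolved LD proxies line up with the exposure table.
#'
#' @return A [summary_stats] object; rejected rows are recorded in its
#'   `rejects` attribute.
#' @export
read_gwas_table <- function(path, trait_label, trait_type = c("continuous", "binary"),
                            unit_note = "", dialect = NULL, proxy_map = NULL) {
  if (!file.exists(path)) stop("read_gwas_table: file not found: ", path, call. = FALSE)
  canonical <- c(SNP = "SNP", CHR = "CHR", POS = "POS", EA = "EA", OA = "OA",
                 EAF = "EAF", BETA = "BETA", SE = "SE", P = "P", N = "N")
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), names(canonical))
    if (length(unknown) > 0) {
      stop("read_gwas_table: unknown dialect key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    canonical[names(dialect)] <- dialect
  }
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
  missing_cols <- canonical[!(canonical %in% names(raw))]
  if (length(missing_cols) > 0) {
    stop("read_gwas_table: column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- data.frame(
    variant_id = raw[[canonical[["SNP"]]]],
    chrom = raw[[canonical[["CHR"]]]],
    pos = raw[[canonical[["POS"]]]],
    effect_allele = raw[[canonical[["EA"]]]],
    other_allele = raw[[canonical[["OA"]]]],
    eaf = raw[[canonical[["EAF"]]]],
    beta = raw[[canonical[["BETA"]]]],
    se = raw[[canonical[["SE"]]]],
    pval = raw[[canonical[["P"]]]],
    n = raw[[canonical[["N"]]]],
    stringsAsFactors = FALSE
  )
  if (!is.null(proxy_map)) {
    stopifnot(all(c("original_id", "proxy_id") %in% names(proxy_map)))
    idx <- match(x$variant_id, proxy_map$proxy_id)
    x$variant_id[!is.na(idx)] <- proxy_map$original_id[idx[!is.na(idx)]]
  }
  summary_stats(x, trait_label = trait_label, trait_type = trait_type,
                unit_note = unit_note)
}

#' Write a summary-statistics table in the canonical TSV dialect
#'
#' @param x a [summary_stats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  out <- data.frame(SNP = x$variant_id, CHR = x$chrom, POS = x$pos,
                    EA = x$effect_allele, OA = x$other_allele, EAF = x$eaf,
                    BETA = x$beta, SE = x$se, P = x$pval, N = x$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s%s), %d variants\n",
              attr(x, "trait_label"), attr(x, "trait_type"),
              if (nzchar(attr(x, "unit_note"))) paste0(", ", attr(x, "unit_note")) else "",
              nrow(x)))
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej) > 0) {
    cat(sprintf("  %d row(s) rejected at validation (see attr(., 'rejects'))\n", nrow(rej)))
  }
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# Subset a summary_stats object by variant id, preserving attributes.
subset_variants <- function(x, ids) {
  keep <- x$variant_id %in% ids
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("summary_stats", "data.frame"),
            trait_label = attr(x, "trait_label"),
            trait_type = attr(x, "trait_type"),
            unit_note = attr(x, "unit_note"),
            rejects = attr(x, "rejects"))
}
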