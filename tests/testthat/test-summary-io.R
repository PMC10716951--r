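make_table <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1000L, 2000L, 5000L),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.2, NA),
    beta = c(0.1, -0.05, 0.02),
    se = c(0.01, 0.02, 0.01),
    pval = c(1e-10, 1e-4, 0.5),
    n = c(10000L, 10000L, 10000L),
    stringsAsFactors = FALSE
  )
}

test_that("a well-formed table reads back identically, with zero rejects", {
  tab <- make_table()
  ss <- summary_stats(tab, "bw", "continuous", "1-SD")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 3)
  expect_equal(nrow(attr(ss, "rejects")), 0)
  expect_equal(ss$beta, tab$beta)
  expect_equal(attr(ss, "trait_label"), "bw")
})

test_that("invalid rows are rejected with reasons, not silently dropped", {
  tab <- make_table()
  tab$se[2] <- 0
  tab <- rbind(tab, data.frame(variant_id = "rs4", chrom = "3", pos = 1L,
                               effect_allele = "A", other_allele = "A",
                               eaf = 0.5, beta = 0.1, se = 0.01, pval = 0.1,
                               n = 100L))
  tab <- rbind(tab, data.frame(variant_id = "rs5", chrom = "3", pos = 2L,
                               effect_allele = "A", other_allele = "G",
                               eaf = 0.5, beta = 0.1, se = 0.01, pval = 0,
                               n = 100L))
  ss <- summary_stats(tab, "bw")
  rej <- attr(ss, "rejects")
  expect_equal(nrow(ss), 2)
  expect_setequal(rej$variant_id, c("rs2", "rs4", "rs5"))
  expect_equal(rej$reason[rej$variant_id == "rs2"], "nonpositive se")
  expect_equal(rej$reason[rej$variant_id == "rs4"], "effect allele equals other allele")
  expect_equal(rej$reason[rej$variant_id == "rs5"], "pval outside (0,1]")
})

test_that("duplicate variant ids raise an error naming them", {
  tab <- make_table()
  tab$variant_id[2] <- "rs1"
  expect_error(summary_stats(tab, "bw"), "duplicate.*rs1")
})

test_that("reading a TSV honours column-order shuffles and dialect remaps", {
  tab <- make_table()
  ss0 <- summary_stats(tab, "bw")

  f1 <- tempfile(fileext = ".tsv")
  write_gwas_table(ss0, f1)
  ss1 <- read_gwas_table(f1, "bw")
  expect_equal(as.data.frame(ss1), as.data.frame(ss0))

  # Shuffled columns + nonstandard names, mapped via dialect.
  f2 <- tempfile(fileext = ".tsv")
  out <- data.frame(pvalue = tab$pval, rsid = tab$variant_id, CHR = tab$chrom,
                    POS = tab$pos, effect = tab$beta, stderr = tab$se,
                    EA = tab$effect_allele, OA = tab$other_allele,
                    EAF = tab$eaf, N = tab$n)
  write.table(out, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  ss2 <- read_gwas_table(f2, "bw", dialect = c(SNP = "rsid", BETA = "effect",
                                               SE = "stderr", P = "pvalue"))
  expect_equal(as.data.frame(ss2), as.data.frame(ss0))
})

test_that("a missing mandatory column is reported by name", {
  f <- tempfile(fileext = ".tsv")
  tab <- make_table()
  ss <- summary_stats(tab, "bw")
  write_gwas_table(ss, f)
  txt <- readLines(f)
  txt[1] <- sub("\tSE\t", "\tSTDERR\t", txt[1])
  writeLines(txt, f)
  expect_error(read_gwas_table(f, "bw"), "SE")
})

test_that("proxy map renames variants before validation", {
  f <- tempfile(fileext = ".tsv")
  tab <- make_table()
  write_gwas_table(summary_stats(tab, "bw"), f)
  ss <- read_gwas_table(f, "bw",
                        proxy_map = data.frame(original_id = "rs99",
                                               proxy_id = "rs2"))
  expect_true("rs99" %in% ss$variant_id)
  expect_false("rs2" %in% ss$variant_id)
})

# --- harmonization -----------------------------------------------------

h_pair <- function(exp_rows, out_rows) {
  blank <- list(chrom = "1", eaf = 0.3, se = 0.01, pval = 0.01, n = 1000L)
  build <- function(rows) {
    df <- do.call(rbind, lapply(seq_along(rows), function(i) {
      r <- modifyList(blank, rows[[i]])
      data.frame(variant_id = r$variant_id, chrom = r$chrom, pos = i * 1000L,
                 effect_allele = r$ea, other_allele = r$oa, eaf = r$eaf,
                 beta = r$beta, se = r$se, pval = r$pval, n = r$n,
                 stringsAsFactors = FALSE)
    }))
    df
  }
  list(exposure = summary_stats(build(exp_rows), "exp"),
       outcome = summary_stats(build(out_rows), "out"))
}

test_that("swapped outcome alleles flip the outcome beta sign", {
  p <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "G", beta = 0.10)),
              list(list(variant_id = "rs1", ea = "G", oa = "A", beta = -0.05)))
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$Gamma, 0.05)
  expect_equal(h$gamma, 0.10)
})

test_that("strand-complement coding is recognized for non-palindromic SNPs", {
  # outcome coded on the opposite strand: A/G vs T/C, same orientation.
  p <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "G", beta = 0.10)),
              list(list(variant_id = "rs1", ea = "T", oa = "C", beta = 0.07)))
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$Gamma, 0.07)
  # opposite strand AND swapped: C/T vs A/G.
  p2 <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "G", beta = 0.10)),
               list(list(variant_id = "rs1", ea = "C", oa = "T", beta = 0.07)))
  h2 <- harmonize(p2$exposure, p2$outcome)
  expect_equal(h2$Gamma, -0.07)
})

test_that("palindromic SNPs are dropped under drop_ambiguous", {
  p <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "T", beta = 0.1, eaf = 0.5),
                   list(variant_id = "rs2", ea = "A", oa = "G", beta = 0.2)),
              list(list(variant_id = "rs1", ea = "A", oa = "T", beta = 0.1, eaf = 0.5),
                   list(variant_id = "rs2", ea = "A", oa = "G", beta = 0.2)))
  h <- harmonize(p$exposure, p$outcome, palindrome_policy = "drop_ambiguous")
  expect_equal(h$variant_id, "rs2")
  dropped <- attr(h, "dropped")
  expect_equal(dropped$reason[dropped$variant_id == "rs1"], "palindromic_ambiguous")
})

test_that("infer_by_eaf keeps clearly-oriented palindromic SNPs", {
  # Both frequencies on the same (minor) side: retained, same orientation.
  # Oracle: of the four orientation hypotheses (same/flipped x strand),
  # only "same" is consistent with eaf 0.10 vs 0.12.
  p <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "T", beta = 0.1, eaf = 0.10)),
              list(list(variant_id = "rs1", ea = "A", oa = "T", beta = 0.06, eaf = 0.12)))
  h <- harmonize(p$exposure, p$outcome, palindrome_policy = "infer_by_eaf",
                 eaf_window = 0.08)
  expect_equal(h$Gamma, 0.06)

  # Opposite sides of 0.5: the outcome effect allele is really the
  # exposure's other allele; the beta must flip.
  p2 <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "T", beta = 0.1, eaf = 0.10)),
               list(list(variant_id = "rs1", ea = "A", oa = "T", beta = 0.06, eaf = 0.88)))
  h2 <- harmonize(p2$exposure, p2$outcome, palindrome_policy = "infer_by_eaf",
                  eaf_window = 0.08)
  expect_equal(h2$Gamma, -0.06)

  # Ambiguous frequency: dropped even under infer_by_eaf.
  p3 <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "T", beta = 0.1, eaf = 0.50)),
               list(list(variant_id = "rs1", ea = "A", oa = "T", beta = 0.06, eaf = 0.50)))
  expect_error(harmonize(p3$exposure, p3$outcome, palindrome_policy = "infer_by_eaf"),
               "no shared SNPs")
})

test_that("irreconcilable alleles drop the SNP with allele_mismatch", {
  p <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "G", beta = 0.1),
                   list(variant_id = "rs2", ea = "A", oa = "G", beta = 0.2)),
              list(list(variant_id = "rs1", ea = "A", oa = "C", beta = 0.1),
                   list(variant_id = "rs2", ea = "A", oa = "G", beta = 0.2)))
  h <- harmonize(p$exposure, p$outcome)
  dropped <- attr(h, "dropped")
  expect_equal(dropped$reason[dropped$variant_id == "rs1"], "allele_mismatch")
  expect_equal(h$variant_id, "rs2")
})

test_that("exposure SNPs absent from the outcome are logged as missing", {
  p <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "G", beta = 0.1),
                   list(variant_id = "rs2", ea = "C", oa = "T", beta = 0.2)),
              list(list(variant_id = "rs2", ea = "C", oa = "T", beta = 0.2)))
  h <- harmonize(p$exposure, p$outcome)
  dropped <- attr(h, "dropped")
  expect_equal(dropped$reason[dropped$variant_id == "rs1"], "missing_in_outcome")
})

test_that("zero shared SNPs is an error", {
  p <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "G", beta = 0.1)),
              list(list(variant_id = "rs9", ea = "A", oa = "G", beta = 0.1)))
  expect_error(harmonize(p$exposure, p$outcome), "no shared SNPs")
})

test_that("harmonization is idempotent and exposure/outcome-symmetric", {
  set.seed(42)
  n <- 40
  ea <- sample(c("A", "C"), n, replace = TRUE)
  oa <- ifelse(ea == "A", "G", "T")
  base <- data.frame(variant_id = sprintf("rs%02d", 1:n), chrom = "1",
                     pos = (1:n) * 1000L, effect_allele = ea, other_allele = oa,
                     eaf = runif(n, 0.05, 0.45), beta = rnorm(n, 0, 0.1),
                     se = runif(n, 0.005, 0.02), pval = runif(n), n = 50000L,
                     stringsAsFactors = FALSE)
  outc <- base
  swap <- runif(n) < 0.5
  outc$effect_allele[swap] <- oa[swap]
  outc$other_allele[swap] <- ea[swap]
  outc$beta <- rnorm(n, 0, 0.05)
  outc$eaf <- ifelse(swap, 1 - base$eaf, base$eaf) # frequency follows the allele
  e <- summary_stats(base, "exp")
  o <- summary_stats(outc, "out")
  h1 <- harmonize(e, o)

  # Idempotence: re-harmonizing the already-aligned pair changes nothing.
  o_aligned <- outc
  o_aligned$effect_allele <- base$effect_allele
  o_aligned$other_allele <- base$other_allele
  o_aligned$beta <- h1$Gamma
  o_aligned$eaf <- base$eaf
  h2 <- harmonize(e, summary_stats(o_aligned, "out"))
  expect_equal(h2$Gamma, h1$Gamma)
  expect_equal(h2$gamma, h1$gamma)

  # Symmetry: swapping the exposure/outcome roles transposes the pairs.
  h_rev <- harmonize(o, e)
  m <- match(h1$variant_id, h_rev$variant_id)
  expect_false(anyNA(m))
  # Effects in h_rev are on o's allele convention; flip where o was coded
  # on the swapped allele relative to e.
  sgn <- ifelse(swap[match(h1$variant_id, base$variant_id)], -1, 1)
  expect_equal(h_rev$gamma[m] * sgn, h1$Gamma)
  expect_equal(h_rev$Gamma[m] * sgn, h1$gamma)
})

test_that("harmonized sets round-trip to TSV with a dropped-SNP companion", {
  p <- h_pair(list(list(variant_id = "rs1", ea = "A", oa = "G", beta = 0.1),
                   list(variant_id = "rs2", ea = "A", oa = "T", beta = 0.2)),
              list(list(variant_id = "rs1", ea = "A", oa = "G", beta = 0.05),
                   list(variant_id = "rs2", ea = "A", oa = "T", beta = 0.2)))
  h <- harmonize(p$exposure, p$outcome)
  f <- tempfile(fileext = ".tsv")
  write_harmonized(h, f)
  main <- read.delim(f)
  expect_equal(names(main), c("SNP", "GAMMA", "SE_GAMMA", "GAMMA_OUT", "SE_GAMMA_OUT"))
  comp <- read.delim(paste0(f, ".dropped.tsv"))
  expect_equal(comp$reason, "palindromic_ambiguous")
})
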