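# Independent oracles used to cross-check the estimators. These are kept
# deliberately naive and separate from the package's own algebra.

# Generic weighted least squares via stats::lm. Returns coefficients and
# standard errors rescaled to the multiplicative over-dispersion model
# (residual variance max(1, Q/df)) used by the MR estimators.
wls_oracle <- function(X, y, w, intercept = FALSE) {
  X <- as.matrix(X)
  df_dat <- as.data.frame(X)
  names(df_dat) <- paste0("x", seq_len(ncol(X)))
  df_dat$y <- y
  form <- if (intercept) {
    stats::as.formula(paste("y ~", paste(names(df_dat)[seq_len(ncol(X))], collapse = "+")))
  } else {
    stats::as.formula(paste("y ~ 0 +", paste(names(df_dat)[seq_len(ncol(X))], collapse = "+")))
  }
  fit <- stats::lm(form, data = df_dat, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  se_unit <- sm$coefficients[, "Std. Error"] / sigma   # sqrt(diag((X'WX)^-1))
  list(coef = stats::coef(fit), se = se_unit * max(1, sigma))
}

# IVW as WLS through the origin with weights se_Gamma^-2 (algebraically
# identical to inverse-variance weighting of first-order Wald ratios).
ivw_oracle <- function(H) {
  wls_oracle(matrix(H$gamma, ncol = 1), H$Gamma, H$se_Gamma^-2)
}

egger_oracle <- function(H) {
  sgn <- ifelse(H$gamma < 0, -1, 1)
  wls_oracle(matrix(H$gamma * sgn, ncol = 1), H$Gamma * sgn, H$se_Gamma^-2,
             intercept = TRUE)
}

# Brute-force greedy clump: independent re-implementation working on a
# full r2 matrix.
clump_oracle <- function(stats, ld, r2_threshold, window_kb) {
  ord <- order(stats$pval, stats$variant_id)
  s <- stats[ord, , drop = FALSE]
  n <- nrow(s)
  r2 <- matrix(0, n, n)
  if (!is.null(ld) && nrow(ld) > 0) {
    for (i in seq_len(nrow(ld))) {
      a <- match(ld$SNP_A[i], s$variant_id)
      b <- match(ld$SNP_B[i], s$variant_id)
      if (!is.na(a) && !is.na(b)) {
        r2[a, b] <- ld$R2[i]
        r2[b, a] <- ld$R2[i]
      }
    }
  }
  kept <- integer(0)
  for (i in seq_len(n)) {
    conflict <- FALSE
    for (j in kept) {
      same_chr <- identical(s$chrom[i], s$chrom[j])
      close <- abs(as.numeric(s$pos[i]) - as.numeric(s$pos[j])) <= window_kb * 1000
      if (same_chr && close && r2[i, j] >= r2_threshold) conflict <- TRUE
    }
    if (!conflict) kept <- c(kept, i)
  }
  s$variant_id[kept]
}

# Brute-force Benjamini-Hochberg step-up: q_i = min over ranks j with
# p_(j) >= p_(i) of m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Brute-force weighted percentile (midpoint convention) built from an
# explicit piecewise-linear inverse CDF.
wmedian_oracle <- function(ratio, weight, prob = 0.5) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- weight[ord] / sum(weight)
  mid <- cumsum(w) - w / 2
  if (prob <= mid[1]) return(b[1])
  if (prob >= mid[length(b)]) return(b[length(b)])
  i <- max(which(mid <= prob))
  b[i] + (b[i + 1] - b[i]) * (prob - mid[i]) / (mid[i + 1] - mid[i])
}

# Dense-grid kernel-density argmax oracle for the mode estimators.
kde_argmax_oracle <- function(ratio, weight, phi, grid_n = 20001) {
  n <- length(ratio)
  h <- phi * 0.9 * stats::mad(ratio) * n^(-1 / 5)
  if (h <= 0) return(stats::median(ratio))
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  w <- weight / sum(weight)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - ratio) / h)) / h,
                 numeric(1))
  grid[which.max(dens)]
}

# Random harmonized set for oracle comparisons.
random_h <- function(J, seed, binary = FALSE) {
  set.seed(seed)
  harmonized_set(
    gamma = stats::rnorm(J, 0.05, 0.02),
    se_gamma = stats::runif(J, 0.002, 0.01),
    Gamma = stats::rnorm(J, 0.015, 0.01),
    se_Gamma = stats::runif(J, 0.002, 0.01),
    outcome_type = if (binary) "binary" else "continuous"
  )
}

# Random summary_stats table for clumping tests.
random_stats <- function(n, seed, n_chrom = 2, pos_range = 3e7) {
  set.seed(seed)
  summary_stats(data.frame(
    variant_id = sprintf("rs%03d", sample(n)),
    chrom = as.character(sample(seq_len(n_chrom), n, replace = TRUE)),
    pos = sample.int(pos_range, n),
    effect_allele = "A", other_allele = "G",
    eaf = stats::runif(n, 0.05, 0.5),
    beta = stats::rnorm(n, 0, 0.05),
    se = stats::runif(n, 0.005, 0.02),
    pval = stats::runif(n)^3,
    n = 100000L
  ), trait_label = "trait", trait_type = "continuous")
}

# Random pairwise LD among a set of variant ids.
random_ld <- function(ids, seed, density = 0.4) {
  set.seed(seed)
  if (length(ids) < 2) {
    return(data.frame(SNP_A = character(), SNP_B = character(), R2 = numeric()))
  }
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < density
  data.frame(SNP_A = pairs[1, keep], SNP_B = pairs[2, keep],
             R2 = stats::runif(sum(keep)), stringsAsFactors = FALSE)
}

# Instruments-and-harmonize shortcut for simulated datasets: selects the
# exposure's genome-wide significant, clumped instruments and harmonizes
# them against the outcome table.
sim_harmonized <- function(sim, outcome = sim$outcome) {
  ivs <- select_instruments(sim$exposure, NULL, instrument_criteria())
  harmonize(ivs, outcome)
}
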