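#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Defines the full generative model for a three-trait causal chain
#' exposure -> mediator -> outcome, plus a direct exposure -> outcome
#' path, with per-SNP summary statistics carrying sampling error scaled by
#' sample size. Defaults emulate a birthweight-style study: exposure and
#' outcome GWAS at consortium scale, an outcome on the log-odds scale,
#' strong selected instruments, and a causal chain whose total effect is
#' `log(1.40) = 0.336` with a 25% mediated fraction.
#'
#' @param n_snp number of exposure instruments (default 120).
#' @param n_snp_mediator number of mediator-specific instruments, needed
#'   for multivariable (step-2) analyses (default 80).
#' @param maf_range range of minor-allele frequencies, drawn uniformly.
#' @param gamma_dist list `mean`, `sd`: distribution of true per-allele
#'   instrument effects (trait SD units per allele).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes driving the
#'   standard-error scale `se = 1 / sqrt(2 maf (1 - maf) n)`.
#' @param beta_xm true causal effect of exposure on mediator.
#' @param beta_my true direct effect of mediator on outcome (log-odds).
#' @param beta_xy_direct true direct (non-mediated) effect of exposure on
#'   outcome (log-odds). The total effect is
#'   `beta_xy_direct + beta_xm * beta_my`.
#' @param pleiotropy list with `type` (`"none"`, `"balanced"` or
#'   `"directional"`), `mean` and `sd` of the per-SNP direct (pleiotropic)
#'   outcome effects, and `frac`, the fraction of exposure instruments
#'   carrying them (default 1). Balanced pleiotropy has mean 0 and
#'   satisfies the InSIDE assumption by construction (effects drawn
#'   independently of instrument strength).
#' @param outlier list `count`, `displacement_sd`: number of exposure
#'   instruments whose outcome association is displaced by
#'   `displacement_sd` outcome standard errors (for outlier-detection
#'   studies). `count` must stay below `n_snp / 4`.
#' @param class_fractions named vector `fetal_only`, `maternal_only`,
#'   `shared` partitioning the exposure instruments into genome-of-origin
#'   classes; must sum to 1. Defaults 0.41 / 0.23 / 0.36 (the 51:29:44
#'   split of 124 birthweight instruments).
#' @param exact logical; `TRUE` reports the true effects as the observed
#'   betas (the infinite-sample limit; SEs are still reported), useful for
#'   exactness tests.
#' @param seed integer seed; mandatory. The same configuration and seed
#'   reproduce the tables bitwise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snp = 120,
                       n_snp_mediator = 80,
                       maf_range = c(0.1, 0.4),
                       gamma_dist = list(mean = 0.05, sd = 0.01),
                       n_exposure = 297356,
                       n_mediator = 450243,
                       n_outcome = 638000,
                       beta_xm = 0.5,
                       beta_my = 0.168,
                       beta_xy_direct = 0.252,
                       pleiotropy = list(type = "none", mean = 0, sd = 0, frac = 1),
                       outlier = list(count = 0, displacement_sd = 0),
                       class_fractions = c(fetal_only = 0.41, maternal_only = 0.23,
                                           shared = 0.36),
                       exact = FALSE,
                       seed) {
  if (missing(seed)) stop("sim_config: an explicit seed is required", call. = FALSE)
  pleiotropy <- modifyList(list(type = "none", mean = 0, sd = 0, frac = 1),
                           pleiotropy)
  outlier <- modifyList(list(count = 0, displacement_sd = 0), outlier)
  cfg <- list(n_snp = as.integer(n_snp), n_snp_mediator = as.integer(n_snp_mediator),
              maf_range = maf_range, gamma_dist = gamma_dist,
              n_exposure = n_exposure, n_mediator = n_mediator,
              n_outcome = n_outcome, beta_xm = beta_xm, beta_my = beta_my,
              beta_xy_direct = beta_xy_direct, pleiotropy = pleiotropy,
              outlier = outlier, class_fractions = class_fractions,
              exact = isTRUE(exact), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_snp < 4) stop("sim_config: n_snp must be >= 4", call. = FALSE)
  if (cfg$n_snp_mediator < 0) stop("sim_config: n_snp_mediator must be >= 0", call. = FALSE)
  if (!(length(cfg$maf_range) == 2 && cfg$maf_range[1] > 0 &&
        cfg$maf_range[2] <= 0.5 && cfg$maf_range[1] <= cfg$maf_range[2])) {
    stop("sim_config: maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  for (nm in c("n_exposure", "n_mediator", "n_outcome")) {
    if (cfg[[nm]] <= 0) stop("sim_config: ", nm, " must be positive", call. = FALSE)
  }
  if (!cfg$pleiotropy$type %in% c("none", "balanced", "directional")) {
    stop("sim_config: pleiotropy$type must be none, balanced or directional",
         call. = FALSE)
  }
  if (cfg$pleiotropy$frac < 0 || cfg$pleiotropy$frac > 1) {
    stop("sim_config: pleiotropy$frac must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8) {
    stop("sim_config: class_fractions must sum to 1", call. = FALSE)
  }
  if (cfg$outlier$count >= cfg$n_snp / 4) {
    stop("sim_config: outlier count must stay below n_snp / 4", call. = FALSE)
  }
  invisible(cfg)
}

# se of a per-allele regression coefficient for a standardized trait.
gwas_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

#' Simulate multi-trait GWAS summary statistics with known ground truth
#'
#' Generates per-SNP summary statistics for an exposure, a mediator and a
#' (binary, log-odds scale) outcome under the causal chain encoded in the
#' configuration. Exposure instruments affect the mediator through the
#' exposure (`beta_xm * gamma`) and the outcome through both the direct
#' and mediated paths (`(beta_xy_direct + beta_my * beta_xm) * gamma`),
#' plus any pleiotropic or planted-outlier displacement; mediator-specific
#' instruments affect only the mediator (and hence the outcome via
#' `beta_my`). Observed betas are drawn from `Normal(truth, se^2)` with
#' `se = 1 / sqrt(2 maf (1 - maf) n_trait)`; p-values are two-sided
#' normal. SNP positions are spaced far apart on alternating chromosomes
#' so the panel is LD-free unless LD is supplied separately.
#'
#' @param config a [sim_config] object.
#' @return List with elements `exposure`, `mediator`, `outcome` (each a
#'   [summary_stats]) and `truth`, a list with `true_total`,
#'   `true_indirect`, `true_proportion`, `outlier_ids`, and `per_snp`, a
#'   data frame of per-SNP true effects (`class`, `role`, `fetal_effect`,
#'   `maternal_effect`, `beta_x`, `beta_m`, `beta_y`, `alpha`, `outlier`).
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  J <- cfg$n_snp
  Jm <- cfg$n_snp_mediator
  total <- J + Jm

  with_seed(cfg$seed, {
    id <- sprintf("snp%04d", seq_len(total))
    chrom <- as.character(rep_len(1:22, total))
    pos <- integer(total)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      pos[i] <- 1000000L + (seq_along(i) - 1L) * 25000000L
    }
    maf <- runif(total, cfg$maf_range[1], cfg$maf_range[2])

    # True per-allele effects.
    role <- rep(c("exposure_iv", "mediator_iv"), c(J, Jm))
    g_raw <- rnorm(total, cfg$gamma_dist$mean, cfg$gamma_dist$sd)
    beta_x <- ifelse(role == "exposure_iv", g_raw, 0)
    gamma_m_own <- ifelse(role == "mediator_iv", g_raw, 0)

    # Genome-of-origin classes for the exposure instruments; fetal-only
    # instruments have zero maternal-path effect and vice versa. Shared
    # instruments split their effect between the two paths.
    class <- rep(NA_character_, total)
    class[role == "exposure_iv"] <- sample(
      names(cfg$class_fractions), J, replace = TRUE, prob = cfg$class_fractions)
    fetal <- ifelse(class %in% c("fetal_only"), beta_x,
                    ifelse(class %in% "shared", beta_x / 2, 0))
    maternal <- ifelse(class %in% c("maternal_only"), beta_x,
                       ifelse(class %in% "shared", beta_x / 2, 0))

    # Horizontal pleiotropy: direct SNP-outcome effects on a fraction of
    # the exposure instruments, drawn independently of instrument strength.
    alpha <- numeric(total)
    if (cfg$pleiotropy$type != "none" && cfg$pleiotropy$frac > 0) {
      n_pleio <- round(cfg$pleiotropy$frac * J)
      idx <- sample(seq_len(J), n_pleio)
      mu <- if (cfg$pleiotropy$type == "balanced") 0 else cfg$pleiotropy$mean
      alpha[idx] <- rnorm(n_pleio, mu, cfg$pleiotropy$sd)
    }

    true_total <- cfg$beta_xy_direct + cfg$beta_xm * cfg$beta_my
    beta_m <- cfg$beta_xm * beta_x + gamma_m_own
    beta_y <- cfg$beta_xy_direct * beta_x + cfg$beta_my * beta_m + alpha

    se_x <- gwas_se(maf, cfg$n_exposure)
    se_m <- gwas_se(maf, cfg$n_mediator)
    se_y <- gwas_se(maf, cfg$n_outcome)

    obs <- function(truth, se) if (cfg$exact) truth else rnorm(total, truth, se)
    bx <- obs(beta_x, se_x)
    bm <- obs(beta_m, se_m)
    by <- obs(beta_y, se_y)

    # Planted outliers: displace the observed outcome association of
    # randomly chosen exposure instruments.
    outlier_ids <- character(0)
    is_outlier <- logical(total)
    if (cfg$outlier$count > 0) {
      pick <- sample(seq_len(J), cfg$outlier$count)
      shift <- sample(c(-1, 1), cfg$outlier$count, replace = TRUE) *
        cfg$outlier$displacement_sd * se_y[pick]
      by[pick] <- by[pick] + shift
      outlier_ids <- id[pick]
      is_outlier[pick] <- TRUE
    }
  })

  make_stats <- function(beta, se, label, type, unit) {
    summary_stats(data.frame(
      variant_id = id, chrom = chrom, pos = pos,
      effect_allele = "A", other_allele = "G", eaf = maf,
      beta = beta, se = se, pval = z_pval(beta, se),
      n = switch(label, exposure = cfg$n_exposure, mediator = cfg$n_mediator,
                 cfg$n_outcome),
      stringsAsFactors = FALSE
    ), trait_label = label, trait_type = type, unit_note = unit)
  }

  truth <- list(
    true_total = cfg$beta_xy_direct + cfg$beta_xm * cfg$beta_my,
    true_indirect = cfg$beta_xm * cfg$beta_my,
    true_proportion = if (cfg$beta_xy_direct + cfg$beta_xm * cfg$beta_my != 0) {
      (cfg$beta_xm * cfg$beta_my) / (cfg$beta_xy_direct + cfg$beta_xm * cfg$beta_my)
    } else {
      NA_real_
    },
    outlier_ids = outlier_ids,
    per_snp = data.frame(variant_id = id, class = class, role = role,
                         maf = maf, fetal_effect = fetal,
                         maternal_effect = maternal,
                         beta_x = beta_x, beta_m = beta_m, beta_y = beta_y,
                         alpha = alpha, outlier = is_outlier,
                         stringsAsFactors = FALSE),
    config = cfg
  )

  list(exposure = make_stats(bx, se_x, "exposure", "continuous", "1-SD"),
       mediator = make_stats(bm, se_m, "mediator", "continuous", "1-SD"),
       outcome = make_stats(by, se_y, "outcome", "binary", "log-odds"),
       truth = truth)
}

#' Simulate a multi-candidate mediator battery
#'
#' Generates one exposure, one outcome and `n_candidates` candidate
#' mediator traits over a shared SNP panel, for screening-specificity
#' studies. The first `n_true` candidates follow the configuration's
#' causal chain (exposure affects them with `beta_xm`, they affect the
#' outcome with `beta_my`); the remaining candidates are null — they have
#' their own genetic instruments (drawn from `gamma_dist`) but no causal
#' connection to either the exposure or the outcome.
#'
#' @param config a [sim_config]; `n_snp_mediator` instruments are
#'   generated per candidate.
#' @param n_candidates total number of candidate mediators (default 6).
#' @param n_true number of true mediators among them (default 1).
#' @return List with `exposure`, `outcome` ([summary_stats]), `mediators`
#'   (list of [summary_stats], names `M1`, `M2`, ...), and `truth`
#'   (including `true_mediators`, the labels of the causal candidates).
#' @export
simulate_candidate_battery <- function(config, n_candidates = 6, n_true = 1) {
  stopifnot(inherits(config, "sim_config"), n_candidates >= 1,
            n_true >= 0, n_true <= n_candidates)
  cfg <- config
  J <- cfg$n_snp
  Jm <- cfg$n_snp_mediator
  total <- J + n_candidates * Jm
  labels <- paste0("M", seq_len(n_candidates))
  is_true <- seq_len(n_candidates) <= n_true

  with_seed(cfg$seed, {
    id <- sprintf("snp%04d", seq_len(total))
    chrom <- as.character(rep_len(1:22, total))
    pos <- integer(total)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      pos[i] <- 1000000L + (seq_along(i) - 1L) * 25000000L
    }
    maf <- runif(total, cfg$maf_range[1], cfg$maf_range[2])
    owner <- rep(c("exposure", labels), c(J, rep(Jm, n_candidates)))
    g_raw <- rnorm(total, cfg$gamma_dist$mean, cfg$gamma_dist$sd)

    beta_x <- ifelse(owner == "exposure", g_raw, 0)
    true_total <- cfg$beta_xy_direct + cfg$beta_xm * cfg$beta_my
    beta_y <- cfg$beta_xy_direct * beta_x +
      cfg$beta_my * cfg$beta_xm * beta_x
    beta_med <- matrix(0, total, n_candidates)
    for (k in seq_len(n_candidates)) {
      own <- owner == labels[k]
      beta_med[own, k] <- g_raw[own]
      if (is_true[k]) {
        beta_med[, k] <- beta_med[, k] + cfg$beta_xm * beta_x
        beta_y <- beta_y + cfg$beta_my * g_raw * own
      }
    }

    se_x <- gwas_se(maf, cfg$n_exposure)
    se_m <- gwas_se(maf, cfg$n_mediator)
    se_y <- gwas_se(maf, cfg$n_outcome)
    obs <- function(truth, se) if (cfg$exact) truth else rnorm(total, truth, se)
    bx <- obs(beta_x, se_x)
    by <- obs(beta_y, se_y)
    bmed <- vapply(seq_len(n_candidates),
                   function(k) obs(beta_med[, k], se_m), numeric(total))
  })

  make_stats <- function(beta, se, label, type, unit, n) {
    summary_stats(data.frame(
      variant_id = id, chrom = chrom, pos = pos,
      effect_allele = "A", other_allele = "G", eaf = maf,
      beta = beta, se = se, pval = z_pval(beta, se), n = n,
      stringsAsFactors = FALSE
    ), trait_label = label, trait_type = type, unit_note = unit)
  }

  mediators <- lapply(seq_len(n_candidates), function(k) {
    make_stats(bmed[, k], se_m, labels[k], "continuous", "1-SD", cfg$n_mediator)
  })
  names(mediators) <- labels

  list(
    exposure = make_stats(bx, se_x, "exposure", "continuous", "1-SD", cfg$n_exposure),
    outcome = make_stats(by, se_y, "outcome", "binary", "log-odds", cfg$n_outcome),
    mediators = mediators,
    truth = list(true_total = cfg$beta_xy_direct + cfg$beta_xm * cfg$beta_my,
                 true_indirect = cfg$beta_xm * cfg$beta_my,
                 true_mediators = labels[is_true],
                 owner = data.frame(variant_id = id, owner = owner,
                                    stringsAsFactors = FALSE),
                 config = cfg)
  )
}

#' Displace outcome associations of chosen SNPs (planted outliers)
#'
#' Standalone version of the outlier-planting step: shifts the outcome
#' betas of `count` randomly chosen exposure instruments by
#' `displacement_sd` times their standard error (random sign) and records
#' the chosen ids in the truth record.
#'
#' @param outcome a [summary_stats] object for the outcome.
#' @param truth truth record from [simulate_summary_stats()].
#' @param count number of SNPs to displace; must stay below a quarter of
#'   the exposure-instrument count.
#' @param displacement_sd displacement magnitude in outcome SEs.
#' @param seed integer seed.
#' @return List with modified `outcome` and updated `truth`.
#' @export
plant_outliers <- function(outcome, truth, count, displacement_sd, seed) {
  stopifnot(inherits(outcome, "summary_stats"))
  exposure_ivs <- truth$per_snp$variant_id[truth$per_snp$role == "exposure_iv"]
  if (count >= length(exposure_ivs) / 4) {
    stop("plant_outliers: count must stay below a quarter of the instruments",
         call. = FALSE)
  }
  if (count == 0) return(list(outcome = outcome, truth = truth))
  with_seed(seed, {
    pick <- sample(exposure_ivs, count)
    sgn <- sample(c(-1, 1), count, replace = TRUE)
  })
  i <- match(pick, outcome$variant_id)
  outcome$beta[i] <- outcome$beta[i] + sgn * displacement_sd * outcome$se[i]
  outcome$pval[i] <- z_pval(outcome$beta[i], outcome$se[i])
  truth$outlier_ids <- union(truth$outlier_ids, pick)
  truth$per_snp$outlier[truth$per_snp$variant_id %in% pick] <- TRUE
  list(outcome = outcome, truth = truth)
}

#' Simulate block-structured pairwise LD
#'
#' Groups SNPs into blocks: within-block r^2 is drawn from a Beta
#' distribution (default Beta(9, 1), strongly correlated), between-block
#' r^2 is 0 (omitted from the pair list). Positions place consecutive
#' block members `spacing_kb` apart and separate blocks by `gap_kb`, so a
#' clumping window can be configured to fall within or across blocks.
#'
#' @param block_sizes integer vector, one entry per block (each >= 1).
#' @param r2_shape1,r2_shape2 Beta parameters for within-block r^2.
#' @param chrom chromosome label given to all SNPs.
#' @param spacing_kb within-block spacing in kb (default 10).
#' @param gap_kb gap between consecutive blocks in kb (default 20000,
#'   beyond the default 10,000 kb clumping window).
#' @param seed integer seed.
#' @return List with `snps` (data frame `variant_id`, `chrom`, `pos`,
#'   `block`) and `ld` (data frame `SNP_A`, `SNP_B`, `R2`).
#' @export
simulate_ld_blocks <- function(block_sizes, r2_shape1 = 9, r2_shape2 = 1,
                               chrom = "1", spacing_kb = 10, gap_kb = 20000,
                               seed) {
  stopifnot(all(block_sizes >= 1))
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  id <- sprintf("ld%04d", seq_len(n))
  pos <- integer(n)
  cur <- 1000000L
  for (i in seq_len(n)) {
    if (i > 1) {
      cur <- cur + if (block[i] == block[i - 1]) as.integer(spacing_kb * 1000) else
        as.integer(gap_kb * 1000)
    }
    pos[i] <- cur
  }
  pairs <- list()
  with_seed(seed, {
    for (b in unique(block)) {
      members <- which(block == b)
      if (length(members) < 2) next
      combs <- utils::combn(members, 2)
      r2 <- stats::rbeta(ncol(combs), r2_shape1, r2_shape2)
      pairs[[length(pairs) + 1]] <- data.frame(
        SNP_A = id[combs[1, ]], SNP_B = id[combs[2, ]], R2 = r2,
        stringsAsFactors = FALSE)
    }
  })
  ld <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(SNP_A = character(), SNP_B = character(), R2 = numeric())
  list(snps = data.frame(variant_id = id, chrom = chrom, pos = pos,
                         block = block, stringsAsFactors = FALSE),
       ld = ld)
}

#' Write a simulated dataset (tables, truth and config) to a directory
#'
#' Emits the three trait tables in the canonical TSV dialect plus JSON
#' side-cars for the ground truth and the generating configuration.
#'
#' @param sim result of [simulate_summary_stats()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gwas_table(sim$exposure, file.path(dir, "exposure.tsv"))
  write_gwas_table(sim$mediator, file.path(dir, "mediator.tsv"))
  write_gwas_table(sim$outcome, file.path(dir, "outcome.tsv"))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
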