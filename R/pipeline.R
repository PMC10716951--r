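log_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

#' Assemble and validate a pipeline configuration
#'
#' The configuration drives the two analysis phases: Phase 1 estimates the
#' total causal effect of each exposure variant (e.g. overall,
#' fetal-specific, maternal-specific instrument lists) on each outcome
#' with the full sensitivity battery; Phase 2 screens candidate mediators
#' and quantifies mediation proportions.
#'
#' @param x either a path to a JSON configuration file or a named list
#'   with elements:
#'   * `exposures`: list of `list(label, file, type, unit, restrict_to)`
#'     where `restrict_to` is an optional path to a one-column text file
#'     of variant ids (an instrument-class list);
#'   * `outcomes`: list of `list(label, file, type, unit)`;
#'   * `mediators`: list of `list(label, file, type, unit)` (may be
#'     empty for Phase-1-only runs);
#'   * `ld_file`: optional path to pairwise LD records;
#'   * `criteria`: list `p_threshold`, `r2_threshold`, `window_kb`;
#'   * `settings`: list `n_boot`, `n_sim`, `phi`, `seed` (seed is
#'     mandatory — no silent clock seeding);
#'   * `out_dir`: output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = FALSE) else x
  stopifnot(is.list(cfg))
  if (is.null(cfg$mediators)) cfg$mediators <- list()
  cfg$criteria <- do.call(instrument_criteria, modifyList(
    list(p_threshold = 5e-8, r2_threshold = 0.001, window_kb = 10000),
    cfg$criteria %||% list()))
  cfg$settings <- modifyList(list(n_boot = 1000, n_sim = 5000, phi = 1),
                             cfg$settings %||% list())
  if (is.null(cfg$settings$seed)) {
    stop("pipeline_config: settings$seed must be set explicitly", call. = FALSE)
  }
  if (is.null(cfg$out_dir)) stop("pipeline_config: out_dir is required", call. = FALSE)
  for (role in c("exposures", "outcomes")) {
    if (length(cfg[[role]]) == 0) {
      stop("pipeline_config: at least one entry required in ", role, call. = FALSE)
    }
  }
  for (spec in c(cfg$exposures, cfg$outcomes, cfg$mediators)) {
    if (is.null(spec$label) || is.null(spec$file)) {
      stop("pipeline_config: every trait spec needs label and file", call. = FALSE)
    }
    if (!file.exists(spec$file)) {
      stop("pipeline_config: file not found for '", spec$label, "': ", spec$file,
           call. = FALSE)
    }
    rt <- spec$restrict_to
    if (!is.null(rt) && is.character(rt) && length(rt) == 1 && !file.exists(rt)) {
      stop("pipeline_config: restrict_to file not found for '", spec$label, "'",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$ld_file) && !file.exists(cfg$ld_file)) {
    stop("pipeline_config: ld_file not found: ", cfg$ld_file, call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

read_trait <- function(spec) {
  read_gwas_table(spec$file,
                  trait_label = spec$label,
                  trait_type = spec$type %||% "continuous",
                  unit_note = spec$unit %||% "",
                  dialect = spec$dialect)
}

read_restrict <- function(spec) {
  rt <- spec$restrict_to
  if (is.null(rt)) return(NULL)
  if (is.character(rt) && length(rt) == 1 && file.exists(rt)) {
    return(readLines(rt))
  }
  unlist(rt)
}

#' Phase 1: total causal effects with the full sensitivity battery
#'
#' For every exposure variant x outcome pair: select instruments
#' (significance filter, optional instrument-class restriction, LD
#' clumping), harmonize, and fit IVW plus the five sensitivity analyses
#' (MR-Egger, simple mode, weighted median, weighted mode, MR-PRESSO),
#' heterogeneity and instrument-strength diagnostics, leave-one-out, and
#' an evidence grade. Writes one estimator-battery TSV and one
#' leave-one-out TSV per pair plus a JSON side-car holding every estimate,
#' the seed and the configuration.
#'
#' @param config a [pipeline_config] (or something coercible by it).
#' @return A list of class `phase1_report`: per pair (named
#'   `"<exposure>::<outcome>"`), elements `fit` (an `mr_fit`), `loo`,
#'   `grade`, `instruments`.
#' @export
run_phase1 <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ld <- if (!is.null(cfg$ld_file)) read_ld(cfg$ld_file) else NULL
  seed <- cfg$settings$seed

  report <- list()
  pair_idx <- 0L
  for (exp_spec in cfg$exposures) {
    exposure <- read_trait(exp_spec)
    restrict <- read_restrict(exp_spec)
    for (out_spec in cfg$outcomes) {
      pair_idx <- pair_idx + 1L
      key <- paste0(exp_spec$label, "::", out_spec$label)
      result <- tryCatch({
        outcome <- read_trait(out_spec)
        ivs <- select_instruments(exposure, ld, cfg$criteria, restrict_to = restrict)
        H <- harmonize(ivs, outcome)
        log_msg("phase1 %s: %d instruments after selection, %d harmonized",
                key, nrow(ivs), nrow(H))
        fit <- mr_fit(H, n_boot = cfg$settings$n_boot, seed = seed + 17L * pair_idx,
                      phi = cfg$settings$phi, presso = nrow(H) >= 4,
                      n_sim = cfg$settings$n_sim)
        loo <- if (nrow(H) >= 3) leave_one_out(H) else NULL
        list(fit = fit, loo = loo, instruments = ivs$variant_id)
      }, error = function(e) {
        stop("phase1 [", key, "]: ", conditionMessage(e), call. = FALSE)
      })
      report[[key]] <- result
    }
  }

  # Evidence grading: FDR family = the outcome battery within each exposure.
  for (exp_spec in cfg$exposures) {
    keys <- paste0(exp_spec$label, "::",
                   vapply(cfg$outcomes, `[[`, character(1), "label"))
    pvals <- vapply(keys, function(k) report[[k]]$fit$estimates$IVW$pval, numeric(1))
    qvals <- bh_fdr(pmax(pvals, .Machine$double.xmin))
    for (i in seq_along(keys)) {
      fit <- report[[keys[i]]]$fit
      sens <- fit$estimates[setdiff(names(fit$estimates), "IVW")]
      report[[keys[i]]]$grade <- grade_evidence(fit$estimates$IVW, qvals[i], sens)
    }
  }

  for (key in names(report)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", key)
    res <- report[[key]]
    write_mr_results(res$fit, file.path(cfg$out_dir, paste0("phase1_", slug, ".tsv")))
    if (!is.null(res$loo)) {
      write.table(res$loo, file.path(cfg$out_dir, paste0("phase1_", slug, "_loo.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    sidecar <- list(
      pair = key, seed = seed,
      criteria = unclass(cfg$criteria), settings = cfg$settings,
      estimates = lapply(res$fit$estimates, function(e) unclass(e)),
      presso = if (!is.null(res$fit$presso)) list(
        rss_obs = res$fit$presso$rss_obs, global_p = res$fit$presso$global_p,
        outliers = as.list(res$fit$presso$outliers)) else NULL,
      grade = unclass(res$grade),
      instruments = as.list(res$instruments)
    )
    jsonlite::write_json(sidecar, file.path(cfg$out_dir, paste0("phase1_", slug, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(report, class = "phase1_report")
}

#' Phase 2: candidate-mediator screening and mediation quantification
#'
#' For every exposure x outcome pair of the Phase-1 report and every
#' candidate mediator: step 1 fits UVMR of the exposure on the mediator
#' (with MR-Egger and weighted median as sensitivity support); step 2 fits
#' MV-IVW of the outcome on mediator and exposure jointly (with
#' MVMR-Egger as robustness check) and extracts the mediator's direct
#' effect. Candidates are screened on the three mediation criteria with
#' FDR computed across the full candidate battery per pair (one family),
#' and mediation proportions with delta-method SEs are computed for
#' qualified candidates. Candidates without usable instruments are
#' excluded with a logged reason; the run continues.
#'
#' @param config a [pipeline_config].
#' @param phase1 the [run_phase1()] report.
#' @return A list of class `phase2_report`: per pair, a `mediation_screen`
#'   data frame (also written as TSV + JSON side-car).
#' @export
run_phase2 <- function(config, phase1) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  stopifnot(inherits(phase1, "phase1_report"))
  if (length(cfg$mediators) == 0) {
    stop("run_phase2: no candidate mediators configured", call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ld <- if (!is.null(cfg$ld_file)) read_ld(cfg$ld_file) else NULL
  seed <- cfg$settings$seed

  report <- list()
  for (exp_spec in cfg$exposures) {
    exposure <- read_trait(exp_spec)
    restrict <- read_restrict(exp_spec)
    ivs <- select_instruments(exposure, ld, cfg$criteria, restrict_to = restrict)
    for (out_spec in cfg$outcomes) {
      key <- paste0(exp_spec$label, "::", out_spec$label)
      total_est <- phase1[[key]]$fit$estimates$IVW
      outcome <- read_trait(out_spec)
      candidates <- list()
      excluded <- list()
      for (m_idx in seq_along(cfg$mediators)) {
        med_spec <- cfg$mediators[[m_idx]]
        cand <- tryCatch({
          mediator <- read_trait(med_spec)
          H1 <- harmonize(ivs, mediator)
          step_seed <- seed + 1000L + 7L * m_idx
          step1 <- mr_ivw(H1)
          sens <- list(mr_egger(H1),
                       mr_weighted_median(H1, n_boot = cfg$settings$n_boot,
                                          seed = step_seed))
          M <- build_mvmr_set(list(exposure, mediator), outcome, ld, cfg$criteria)
          mv <- mvmr_fit(M)
          step2 <- mv$ivw[[med_spec$label]]
          list(step1 = step1, step2 = step2, total = total_est,
               sensitivity = sens, mvmr = mv)
        }, error = function(e) {
          log_msg("phase2 %s: candidate '%s' excluded: %s", key, med_spec$label,
                  conditionMessage(e))
          excluded[[med_spec$label]] <<- conditionMessage(e)
          NULL
        })
        if (!is.null(cand)) candidates[[med_spec$label]] <- cand
      }
      screen <- screen_mediators(candidates)
      slug <- gsub("[^A-Za-z0-9]+", "_", key)
      write_mediation(screen, file.path(cfg$out_dir, paste0("phase2_", slug, ".tsv")))
      sidecar <- list(
        pair = key, seed = seed,
        excluded = excluded,
        candidates = lapply(candidates, function(cand) list(
          step1 = unclass(cand$step1), step2 = unclass(cand$step2),
          total = unclass(cand$total))),
        screen = screen
      )
      jsonlite::write_json(sidecar,
                           file.path(cfg$out_dir, paste0("phase2_", slug, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
      report[[key]] <- screen
    }
  }
  structure(report, class = "phase2_report")
}
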