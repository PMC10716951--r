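test_that("Wald ratios match hand computations for both SE orders", {
  h <- harmonized_set(gamma = 0.5, se_gamma = 0.1, Gamma = 0.25, se_Gamma = 0.05)
  r <- wald_ratio(h, "first")
  expect_equal(r$ratio, 0.5)
  expect_equal(r$se_ratio, 0.1)
  expect_equal(r$weight, 100)

  h0 <- harmonized_set(gamma = 1, se_gamma = 0.1, Gamma = 0, se_Gamma = 0.1)
  r0 <- wald_ratio(h0, "first")
  expect_equal(r0$ratio, 0)
  expect_equal(r0$se_ratio, 0.1)

  # second order: sqrt(0.2^2/4 + 1 * 0.01 / 16) = sqrt(0.010625)
  h2 <- harmonized_set(gamma = 2, se_gamma = 0.1, Gamma = 1, se_Gamma = 0.2)
  r2 <- wald_ratio(h2, "second")
  expect_equal(r2$se_ratio, sqrt(0.010625))

  hz <- harmonized_set(gamma = c(1, 0), se_gamma = c(0.1, 0.1),
                       Gamma = c(0.1, 0.1), se_Gamma = c(0.1, 0.1),
                       variant_id = c("a", "zero"))
  expect_error(wald_ratio(hz), "zero")
})

test_that("IVW reproduces hand-computed weighted means and Q", {
  # homogeneous ratios: beta = common ratio, Q = 0, random = fixed SE
  h <- harmonized_set(gamma = c(1, 2, 4), se_gamma = rep(0.01, 3),
                      Gamma = c(0.4, 0.8, 1.6), se_Gamma = c(1, 2, 4))
  fit_f <- mr_ivw(h, model = "fixed")
  fit_r <- mr_ivw(h, model = "multiplicative_random")
  expect_equal(fit_f$beta, 0.4)
  expect_equal(fit_r$beta, 0.4)
  expect_equal(fit_f$q_stat, 0)
  expect_equal(fit_r$se, fit_f$se)
  expect_equal(fit_r$q_df, 2)

  # two SNPs, ratios {1,3} with ratio SEs {1,1}:
  # beta = 2, fixed se = 1/sqrt(2), Q = 2, random se = 1
  h2 <- harmonized_set(gamma = c(1, 1), se_gamma = rep(0.01, 2),
                       Gamma = c(1, 3), se_Gamma = c(1, 1))
  f2 <- mr_ivw(h2, model = "fixed")
  r2 <- mr_ivw(h2, model = "multiplicative_random")
  expect_equal(f2$beta, 2)
  expect_equal(f2$se, 1 / sqrt(2))
  expect_equal(f2$q_stat, 2)
  expect_equal(r2$se, 1)
})

test_that("IVW equals weighted regression of Gamma on gamma through the origin", {
  for (seed in 1:6) {
    H <- random_h(40, seed)
    fit <- mr_ivw(H)
    oracle <- ivw_oracle(H)
    expect_equal(fit$beta, unname(oracle$coef), tolerance = 1e-12)
    expect_equal(fit$se, unname(oracle$se), tolerance = 1e-12)
  }
})

test_that("IVW is invariant to joint sign flips and equals the plain mean under equal weights", {
  H <- random_h(25, 3)
  flip <- rep(c(1, -1), length.out = 25)
  Hf <- harmonized_set(gamma = H$gamma * flip, se_gamma = H$se_gamma,
                       Gamma = H$Gamma * flip, se_Gamma = H$se_Gamma)
  expect_equal(mr_ivw(Hf)$beta, mr_ivw(H)$beta, tolerance = 1e-12)

  He <- harmonized_set(gamma = rep(2, 5), se_gamma = rep(0.1, 5),
                       Gamma = c(0.2, 0.4, 0.6, 0.8, 1.4), se_Gamma = rep(0.3, 5))
  r <- wald_ratio(He)
  expect_equal(mr_ivw(He)$beta, mean(r$ratio), tolerance = 1e-12)
})

test_that("a single SNP falls back to the Wald ratio with a message", {
  h <- harmonized_set(gamma = 0.5, se_gamma = 0.1, Gamma = 0.25, se_Gamma = 0.05)
  expect_message(fit <- mr_ivw(h), "Wald")
  expect_equal(fit$method, "WaldRatio")
  expect_equal(fit$beta, 0.5)
})

test_that("MR-Egger recovers exact lines and matches the WLS oracle", {
  g <- seq(0.02, 0.2, length.out = 10)
  h <- harmonized_set(gamma = g, se_gamma = rep(0.01, 10),
                      Gamma = 0.02 + 0.3 * g, se_Gamma = rep(0.05, 10))
  fit <- mr_egger(h)
  expect_equal(fit$intercept, 0.02, tolerance = 1e-10)
  expect_equal(fit$beta, 0.3, tolerance = 1e-10)

  h0 <- harmonized_set(gamma = g, se_gamma = rep(0.01, 10),
                       Gamma = 0.3 * g, se_Gamma = rep(0.05, 10))
  fit0 <- mr_egger(h0)
  expect_equal(fit0$intercept, 0, tolerance = 1e-12)
  # with an exactly-zero intercept the slope equals the IVW estimate
  expect_equal(fit0$beta, mr_ivw(h0)$beta, tolerance = 1e-10)

  for (seed in 11:16) {
    H <- random_h(30, seed)
    fe <- mr_egger(H)
    oracle <- egger_oracle(H)
    expect_equal(fe$intercept, unname(oracle$coef[1]), tolerance = 1e-10)
    expect_equal(fe$beta, unname(oracle$coef[2]), tolerance = 1e-10)
    expect_equal(fe$intercept_se, unname(oracle$se[1]), tolerance = 1e-10)
    expect_equal(fe$se, unname(oracle$se[2]), tolerance = 1e-10)
  }
  expect_error(mr_egger(random_h(2, 1)), "3 SNPs")
})

test_that("the weighted median interpolates cumulative weights correctly", {
  # all ratios equal
  h_eq <- harmonized_set(gamma = rep(1, 3), se_gamma = rep(0.1, 3),
                         Gamma = rep(0.7, 3), se_Gamma = c(0.1, 0.2, 0.3))
  expect_equal(mr_weighted_median(h_eq, n_boot = 0)$beta, 0.7)

  # equal weights: the plain median
  h_med <- harmonized_set(gamma = rep(1, 3), se_gamma = rep(0.1, 3),
                          Gamma = c(1, 2, 9), se_Gamma = rep(1, 3))
  expect_equal(mr_weighted_median(h_med, n_boot = 0)$beta, 2)

  # weights {0.6, 0.2, 0.2}: estimate inside [1, 2], equal to the
  # brute-force weighted-percentile oracle
  w <- c(0.6, 0.2, 0.2)
  h_w <- harmonized_set(gamma = sqrt(w), se_gamma = rep(0.1, 3),
                        Gamma = c(1, 2, 3) * sqrt(w), se_Gamma = rep(1, 3))
  est <- mr_weighted_median(h_w, n_boot = 0)$beta
  expect_gte(est, 1)
  expect_lte(est, 2)
  expect_equal(est, wmedian_oracle(c(1, 2, 3), w))
})

test_that("weighted median equals the percentile oracle on random instances", {
  for (seed in 21:40) {
    H <- random_h(sample(5:60, 1), seed)
    r <- wald_ratio(H)
    expect_equal(mr_weighted_median(H, n_boot = 0)$beta,
                 wmedian_oracle(r$ratio, r$weight), tolerance = 1e-12)
  }
})

test_that("a tied majority of weight pins the weighted median exactly", {
  # six SNPs sharing ratio 2 carry 72% of the weight, spread so the
  # cumulative midpoint span covers 0.5
  ratios <- c(0.5, rep(2, 6), 5)
  w <- c(0.14, rep(0.12, 6), 0.14)
  h <- harmonized_set(gamma = sqrt(w), se_gamma = rep(0.01, 8),
                      Gamma = ratios * sqrt(w), se_Gamma = rep(1, 8))
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 2)
})

test_that("mode estimators find the dominant cluster", {
  h_const <- harmonized_set(gamma = rep(1, 4), se_gamma = rep(0.1, 4),
                            Gamma = rep(0.7, 4), se_Gamma = rep(0.1, 4))
  expect_equal(mr_mode(h_const, n_boot = 0)$beta, 0.7)

  ratios <- c(0.99, 1.00, 1.01, 5.0)
  h <- harmonized_set(gamma = rep(1, 4), se_gamma = rep(0.1, 4),
                      Gamma = ratios, se_Gamma = rep(1, 4))
  simple <- mr_mode(h, weighted = FALSE, phi = 1, n_boot = 0)$beta
  expect_lt(abs(simple - 1.0), 0.05)
  expect_equal(simple, kde_argmax_oracle(ratios, rep(1, 4), 1), tolerance = 0.01)

  # 94% of the weight on the 5.0 SNP drags the weighted mode there
  w <- c(0.02, 0.02, 0.02, 0.94)
  hw <- harmonized_set(gamma = sqrt(w), se_gamma = rep(0.1, 4),
                       Gamma = ratios * sqrt(w), se_Gamma = rep(1, 4))
  weighted <- mr_mode(hw, weighted = TRUE, phi = 1, n_boot = 0)$beta
  expect_lt(abs(weighted - 5.0), 0.05)
  expect_equal(weighted, kde_argmax_oracle(ratios, w, 1), tolerance = 0.01)
})

test_that("Cochran's Q matches hand values and the chi-square oracle", {
  h <- harmonized_set(gamma = c(1, 1), se_gamma = rep(0.01, 2),
                      Gamma = c(1, 3), se_Gamma = c(1, 1))
  q <- cochran_q(h, beta_ref = 2)
  expect_equal(q$q, 2)
  expect_equal(q$df, 1)
  expect_equal(q$p, pchisq(2, 1, lower.tail = FALSE))

  h_hom <- harmonized_set(gamma = c(1, 2), se_gamma = rep(0.01, 2),
                          Gamma = c(0.4, 0.8), se_Gamma = c(1, 1))
  q_hom <- cochran_q(h_hom)
  expect_equal(q_hom$q, 0)
  expect_equal(q_hom$p, 1)
})

test_that("mean F-statistic averages per-SNP strength and scales quadratically", {
  h1 <- harmonized_set(gamma = 0.1, se_gamma = 0.01, Gamma = 0, se_Gamma = 1)
  expect_equal(mean_f_statistic(h1), 100)
  h2 <- harmonized_set(gamma = c(0.1, 0.06), se_gamma = c(0.01, 0.01),
                       Gamma = c(0, 0), se_Gamma = c(1, 1))
  expect_equal(mean_f_statistic(h2), 68)
  h3 <- harmonized_set(gamma = c(0.1, 0.06), se_gamma = c(0.02, 0.02),
                       Gamma = c(0, 0), se_Gamma = c(1, 1))
  expect_equal(mean_f_statistic(h3), 68 / 4)
})

test_that("leave-one-out isolates influential variants", {
  h_hom <- harmonized_set(gamma = rep(1, 5), se_gamma = rep(0.01, 5),
                          Gamma = rep(0.4, 5), se_Gamma = rep(0.1, 5))
  loo <- leave_one_out(h_hom)
  expect_equal(nrow(loo), 5)
  expect_equal(loo$beta, rep(mr_ivw(h_hom)$beta, 5))

  set.seed(7)
  J <- 20
  g <- rnorm(J, 0.1, 0.02)
  G <- 0.4 * g + rnorm(J, 0, 0.005)
  G[J] <- 0.4 * g[J] + 10 * 0.005 * 10   # planted outlier
  h_out <- harmonized_set(gamma = g, se_gamma = rep(0.005, J),
                          Gamma = G, se_Gamma = rep(0.005, J))
  loo2 <- leave_one_out(h_out)
  expect_equal(nrow(loo2), J)
  # the row excluding the outlier is the one closest to the truth 0.4
  best <- which.min(abs(loo2$beta - 0.4))
  expect_equal(loo2$excluded_snp[best], h_out$variant_id[J])
})

test_that("bootstrap SEs are seed-reproducible and warn when underpowered", {
  H <- random_h(12, 5)
  a <- mr_weighted_median(H, n_boot = 200, seed = 42)
  b <- mr_weighted_median(H, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(H, n_boot = 200, seed = 43)
  expect_false(identical(a$se, c$se))
  expect_warning(mr_mode(H, n_boot = 50, seed = 1), "n_boot")
})

test_that("mr_fit assembles the method battery with OR-scale reporting", {
  set.seed(9)
  J <- 30
  g <- rnorm(J, 0.1, 0.02)
  H <- harmonized_set(gamma = g, se_gamma = rep(0.005, J),
                      Gamma = 0.3 * g + rnorm(J, 0, 0.01),
                      se_Gamma = rep(0.01, J), outcome_type = "binary")
  fit <- mr_fit(H, n_boot = 100, seed = 2, presso = TRUE, n_sim = 1000)
  expect_setequal(names(fit$estimates),
                  c("IVW", "Egger", "SimpleMode", "WeightedMedian",
                    "WeightedMode", "MRPRESSO"))
  iv <- fit$estimates$IVW
  expect_equal(iv$or, exp(iv$beta))
  expect_equal(iv$or_lo, exp(iv$beta - 1.96 * iv$se))
  expect_equal(iv$or_hi, exp(iv$beta + 1.96 * iv$se))
  expect_equal(iv$q_df, J - 1)
  expect_equal(fit$estimates$Egger$q_df, J - 2)

  df <- as.data.frame(fit)
  expect_equal(nrow(df), 6)
  expect_true(all(c("method", "n_snp", "beta", "se", "pval", "or", "or_lo95",
                    "or_hi95", "q", "q_df", "q_p", "egger_intercept",
                    "egger_intercept_p", "mean_f") %in% names(df)))
  expect_equal(unname(coef(fit)["IVW"]), iv$beta)
  ci <- confint(fit)
  expect_equal(unname(ci["IVW", 1]), iv$beta - qnorm(0.975) * iv$se)
  expect_output(print(fit), "IVW")
  expect_output(summary(fit), "Cochran")
})
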