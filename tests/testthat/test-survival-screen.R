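test_that("single-feature Cox fit handles degenerate and monotone inputs", {
  sv <- toy_surv(c(5, 10, 15, 20, 25, 30), c(1, 1, 1, 1, 0, 1))
  const <- stats::setNames(rep(2, 6), sv$patient_id)
  row <- cox_fit_single(const, sv)
  expect_false(row$converged)
  expect_false(row$selected)

  expect_error(cox_fit_single(rnorm(3), toy_surv(c(1, 2, 3), c(1, 0, 0))),
               "degenerate")

  # noisy event-order rank: strong monotone risk (exact rank would separate
  # perfectly and push beta to infinity)
  set.seed(4)
  n <- 40
  tt <- sort(sample(1000, n))
  sv2 <- toy_surv(tt, rep(1, n))
  feat <- stats::setNames(rank(-tt) + rnorm(n, sd = 8), sv2$patient_id)
  row2 <- cox_fit_single(feat, sv2)
  expect_true(row2$converged)
  expect_lt(row2$p_value, 0.01)
  expect_gt(abs(row2$beta), 1)

  # negating the feature flips beta, leaves the p-value unchanged
  row3 <- cox_fit_single(-feat, sv2)
  expect_equal(row3$beta, -row2$beta, tolerance = 1e-8)
  expect_equal(row3$p_value, row2$p_value, tolerance = 1e-8)
})

test_that("Cox score test equals the 2-group log-rank statistic without ties", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 60
    tt <- sample(10000, n)                       # unique times, no ties
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) < 2) ev[1:2] <- 1
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1] <- 1 - x[1]
    sv <- toy_surv(tt, ev)
    row <- cox_fit_single(stats::setNames(x, sv$patient_id), sv)
    lr <- logrank_test(sv, stats::setNames(x + 1L, sv$patient_id), k = 2)
    expect_lt(abs(row$score_chi2 - lr$chi2), 1e-8)
  }
})

test_that("Kaplan-Meier estimator matches the product-limit closed form", {
  km <- km_estimate(toy_surv(1:4, rep(1, 4)))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median_survival, 2)

  flat <- km_estimate(toy_surv(c(10, 20, 30), c(0, 0, 0)))
  expect_length(flat$time, 0)
  expect_true(is.na(flat$median_survival))

  one <- km_estimate(toy_surv(7, 1))
  expect_equal(one$surv, 0)
  expect_equal(one$median_survival, 7)

  # with no censoring the KM curve is the empirical survival function
  set.seed(2)
  tt <- sample(500, 30)
  km2 <- km_estimate(toy_surv(tt, rep(1, 30)))
  emp <- vapply(km2$time, function(t) mean(tt > t), numeric(1))
  expect_equal(km2$surv, emp)
})

test_that("k-sample log-rank matches a direct O-E oracle and is label-invariant", {
  # identical groups: chi2 = 0, p = 1
  tt <- c(10, 20, 30, 40); ev <- c(1, 0, 1, 1)
  sv <- toy_surv(c(tt, tt + 0), c(ev, ev), sprintf("s%02d", 1:8))
  same <- logrank_test(sv, stats::setNames(rep(1:2, each = 4), sv$patient_id))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  # fully separated event times are significant; chi2 equals the O-E oracle
  sv2 <- toy_surv(c(1, 2, 3, 10, 11, 12), rep(1, 6))
  g2 <- stats::setNames(rep(1:2, each = 3), sv2$patient_id)
  lr2 <- logrank_test(sv2, g2)
  expect_lt(lr2$p_value, 0.05)
  expect_equal(lr2$chi2,
               naive_logrank_chi2(sv2$time_days, sv2$event, g2[sv2$patient_id]),
               tolerance = 1e-10)

  # random 3-group data against the oracle; relabeling leaves p unchanged
  set.seed(9)
  for (rep in 1:5) {
    n <- 30
    sv3 <- toy_surv(sample(200, n), rbinom(n, 1, 0.8))
    g3 <- stats::setNames(sample(1:3, n, replace = TRUE), sv3$patient_id)
    while (length(unique(g3)) < 3) g3 <- stats::setNames(sample(1:3, n, TRUE),
                                                         sv3$patient_id)
    lr3 <- logrank_test(sv3, g3)
    expect_equal(lr3$chi2,
                 naive_logrank_chi2(sv3$time_days, sv3$event, g3[sv3$patient_id]),
                 tolerance = 1e-8)
    relab <- stats::setNames(c(2L, 3L, 1L)[g3], names(g3))
    expect_equal(logrank_test(sv3, relab)$p_value, lr3$p_value, tolerance = 1e-10)
  }

  expect_error(logrank_test(sv2, stats::setNames(rep(1L, 6), sv2$patient_id), k = 1),
               "k >= 2")
  expect_error(logrank_test(sv2, stats::setNames(c(1L, 1L, 1L, 1L, 1L, 3L),
                                                 sv2$patient_id), k = 3),
               "non-empty")
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(21)
  n <- 60
  sv <- toy_surv(sample(1000, n), rbinom(n, 1, 0.6))
  base <- rep(1:2, each = n / 2)
  p <- replicate(500, logrank_test(sv, stats::setNames(sample(base),
                                                       sv$patient_id))$p_value)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("feature screening selects planted prognostic features and errors on empty selection", {
  set.seed(31)
  ok <- 0
  for (s in 1:10) {
    cfg <- simulation_config(n_patients = 150, k_true = 2,
                             platform_dims = c(protein = 200),
                             frac_informative = 0.1, effect_size = 1.5,
                             hazard_per_subtype = c(0.006, 0.002),  # 3x ratio
                             censor_rate = 0.3,
                             platform_coverage = c(protein = 1), seed = s)
    co <- simulate_cohort(cfg)
    scr <- screen_features(co$matrices$protein, co$survival)
    planted <- co$planted_features$protein
    frac <- mean(planted %in% scr$screen$feature_id[scr$screen$selected])
    if (frac >= 0.8) ok <- ok + 1
  }
  expect_gte(ok, 6)  # 10-seed majority

  co2 <- simulate_cohort(simulation_config(
    n_patients = 60, k_true = 2, platform_dims = c(protein = 30),
    hazard_per_subtype = c(0.01, 0.002), platform_coverage = c(protein = 1),
    seed = 1))
  expect_error(screen_features(co2$matrices$protein, co2$survival, alpha = 0),
               "empty selection")
})

test_that("BH adjustment is exposed behind a flag", {
  set.seed(5)
  co <- simulate_cohort(simulation_config(
    n_patients = 200, k_true = 2, platform_dims = c(protein = 150),
    effect_size = 2, hazard_per_subtype = c(0.008, 0.001),
    platform_coverage = c(protein = 1), seed = 5))
  raw <- screen_features(co$matrices$protein, co$survival, adjust = "none")
  bh <- screen_features(co$matrices$protein, co$survival, adjust = "BH")
  expect_lte(sum(bh$screen$selected), sum(raw$screen$selected))
  expect_true("p_adjusted" %in% names(bh$screen))
})
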