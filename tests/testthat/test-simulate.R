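test_that("simulation is reproducible from config + seed", {
  cfg <- cohort_sim_config(n = 200)
  a <- simulate_cohort(cfg, seed = 501)
  b <- simulate_cohort(cfg, seed = 501)
  expect_identical(a, b)
  c_ <- simulate_cohort(cfg, seed = 502)
  expect_false(identical(a, c_))
})

test_that("volume and dose means match the truncated-normal oracle", {
  coh <- simulate_cohort(cohort_sim_config(n = 10000), seed = 503)
  mu_v <- truncnorm_mean(16.60, 6.38, 8.19, 42.00)
  mu_d <- truncnorm_mean(41.79, 11.02, 10.31, 51.46)
  se_v <- sd(coh$volume_cc) / 100
  se_d <- sd(coh$dmean_gy) / 100
  expect_lt(abs(mean(coh$volume_cc) - mu_v), 3 * se_v)
  expect_lt(abs(mean(coh$dmean_gy) - mu_d), 3 * se_d)
  # printed ranges are hard bounds
  expect_true(all(coh$volume_cc >= 8.19 & coh$volume_cc <= 42.00))
  expect_true(all(coh$dmean_gy >= 10.31 & coh$dmean_gy <= 51.46))
})

test_that("the collinear cluster is built in and bounded metrics are valid", {
  coh <- simulate_cohort(cohort_sim_config(n = 10000), seed = 504)
  expect_gt(spearman_rho(coh$dmean_gy, coh$v40), 0.8)
  expect_gt(spearman_rho(coh$dmean_gy, coh$dmin_gy), 0.8)
  expect_lt(abs(spearman_rho(coh$dmean_gy, coh$fx_dose_gy)), 0.8)
  expect_lt(abs(spearman_rho(coh$dmean_gy, coh$v10)), 0.8)
  vx <- as.matrix(coh[, paste0("v", c(10, 20, 30, 40, 45, 50, 60, 70))])
  expect_true(all(vx >= 0 & vx <= 100))
  expect_true(all(apply(vx, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(coh$dmin_gy <= coh$dmean_gy))
  expect_true(all(coh$dmean_gy <= coh$dmax_gy))
  expect_true(all(coh$outcome_12m %in% 0:1))
  expect_false(anyDuplicated(coh$id) > 0)
})

test_that("event incidence equals the cohort mean of the true NTCP", {
  cfg <- cohort_sim_config(n = 10000)
  coh <- simulate_cohort(cfg, seed = 505)
  p_true <- ntcp(cfg$true_model, coh$dmean_gy, coh$volume_cc)
  mc_se <- sqrt(mean(p_true) * (1 - mean(p_true)) / nrow(coh))
  expect_lt(abs(mean(coh$outcome_12m) - mean(p_true)), 4 * mc_se)
  # and lands near the observed 12-month incidence of ~0.35
  expect_lt(abs(mean(coh$outcome_12m) - 0.35), 0.08)
})

test_that("infeasible truncation bounds are rejected", {
  expect_error(cohort_sim_config(volume_range = c(20, 10)), "range")
  expect_error(cohort_sim_config(volume_mean = 50), "bracket")
})

test_that("ellipsoid phantom volume matches the analytic value", {
  ph <- simulate_phantom(semi_axes = c(20, 15, 25), spacing = c(1, 1, 1))
  analytic <- 4 / 3 * pi * 20 * 15 * 25 / 1000  # 31.42 cc
  expect_equal(volume_cc(ph$mask, ph$grid), analytic, tolerance = 0.02)
})

test_that("uniform and gradient phantom fields behave as designed", {
  ph <- simulate_phantom(field = "uniform", dose_hi = 44)
  met <- dose_metrics(ph$grid, ph$mask, n_fractions = 22)
  expect_equal(met$d_mean, 44)
  expect_equal(met$d_min, 44)

  grad <- simulate_phantom(field = "gradient", dose_lo = 0, dose_hi = 60)
  metg <- dose_metrics(grad$grid, grad$mask, n_fractions = 30)
  # ellipsoid centered on the lattice: mean = dose at the center = 30 Gy
  expect_equal(metg$d_mean, 30, tolerance = 1e-6)
  # voxel-enumeration oracle on the masked gradient doses
  orc <- oracle_metrics(grad$grid$values[grad$mask$include],
                        prod(grad$grid$spacing), 30)
  expect_equal(metg$d_mean, orc$d_mean)
  expect_equal(metg$vx, orc$vx)

  two <- simulate_phantom(field = "two_level", dose_lo = 20, dose_hi = 40)
  expect_setequal(unique(as.vector(two$grid$values)), c(20, 40))
})

test_that("an ellipsoid that does not fit the lattice is rejected", {
  expect_error(simulate_phantom(shape = c(10, 10, 10),
                                semi_axes = c(20, 15, 25)),
               "does not fit")
})

test_that("recovery experiment reports bias, coverage and selection", {
  res <- recovery_experiment(cohort_sim_config(n = 600), n_reps = 8,
                             seed = 506, selection = TRUE)
  expect_equal(res$n_reps, 8)
  expect_equal(res$n_failed, 0)
  expect_true(all(is.finite(res$bias)))
  expect_true(all(res$coverage >= 0 & res$coverage <= 1))
  expect_true(res$selection_freq >= 0 && res$selection_freq <= 1)
  expect_named(res$bias, c("b0", "b_dmean", "b_volume"))
})

test_that("a null true model gives a flat fitted NTCP", {
  cfg <- cohort_sim_config(n = 4000, true_model = ntcp_model(-0.6, 0, 0))
  coh <- simulate_cohort(cfg, seed = 507)
  fit <- ntcp_fit(outcome_12m ~ dmean_gy + volume_cc, coh)
  mc_se <- sqrt(plogis(-0.6) * (1 - plogis(-0.6)) / 4000)
  expect_lt(abs(mean(fitted(fit)) - plogis(-0.6)), 4 * mc_se)
  expect_lt(abs(coef(fit)["dmean_gy"]), 0.02)
})
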