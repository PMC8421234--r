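test_that("Spearman correlation handles the canonical cases", {
  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  # hand rank computation: d^2 = (0,1,1,1,1), rho = 1 - 6*4/120 = 0.8
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)), 0.8)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("univariate screen flags a real dose effect and keeps order", {
  coh <- simulate_cohort(cohort_sim_config(n = 1000), seed = 201)
  scr <- univariate_screen(coh, c("dmean_gy", "age", "volume_cc"))
  expect_equal(scr$factor, c("dmean_gy", "age", "volume_cc"))
  expect_lt(scr$p_value[scr$factor == "dmean_gy"], 0.05)
  expect_lt(scr$p_value[scr$factor == "volume_cc"], 0.05)
  expect_gt(scr$odds_ratio[scr$factor == "dmean_gy"], 1)
  expect_lt(scr$odds_ratio[scr$factor == "volume_cc"], 1)
  expect_true(all(scr$ci_low <= scr$odds_ratio &
                    scr$odds_ratio <= scr$ci_high))
})

test_that("a zero-variance factor yields a failure record, not an abort", {
  coh <- simulate_cohort(cohort_sim_config(n = 200), seed = 202)
  coh$flat <- 1
  scr <- univariate_screen(coh, c("flat", "dmean_gy"))
  expect_false(is.na(scr$error[scr$factor == "flat"]))
  expect_true(is.na(scr$error[scr$factor == "dmean_gy"]))
  expect_true(is.na(scr$p_value[scr$factor == "flat"]))
})

test_that("duplicated columns form a two-member cluster", {
  coh <- simulate_cohort(cohort_sim_config(n = 300), seed = 203)
  coh$dmean_copy <- coh$dmean_gy
  cl <- correlation_clusters(coh, c("dmean_gy", "dmean_copy", "age"))
  sizes <- sort(lengths(cl$clusters))
  expect_equal(sizes, c(1L, 2L))
  pair <- cl$clusters[[which(lengths(cl$clusters) == 2L)]]
  expect_setequal(pair, c("dmean_gy", "dmean_copy"))
})

test_that("independent factors stay singletons", {
  set.seed(204)
  coh <- data.frame(a = rnorm(400), b = rnorm(400), c = rnorm(400),
                    outcome_12m = rbinom(400, 1, 0.4))
  cl <- correlation_clusters(coh, c("a", "b", "c"))
  expect_equal(lengths(cl$clusters), rep(1L, 3))
  expect_setequal(cl$representatives, c("a", "b", "c"))
})

test_that("the simulated dose-metric block clusters around Dmean", {
  coh <- simulate_cohort(cohort_sim_config(n = 2000), seed = 205)
  facs <- c("age", "volume_cc", "dmin_gy", "dmax_gy", "dmean_gy",
            "fx_dose_gy", paste0("v", c(10, 20, 30, 40, 45, 50, 60, 70)))
  cl <- correlation_clusters(coh, facs)
  dm <- cl$clusters[[which(vapply(cl$clusters,
                                  function(m) "dmean_gy" %in% m,
                                  logical(1)))]]
  expect_setequal(dm, c("dmean_gy", "dmin_gy",
                        paste0("v", c(20, 30, 40, 45, 50))))
  expect_true("dmean_gy" %in% cl$representatives)
})

test_that("undefined correlations are warned about and treated as no edge", {
  set.seed(206)
  coh <- data.frame(a = rnorm(50), flat = rep(3, 50),
                    outcome_12m = rbinom(50, 1, 0.5))
  expect_warning(cl <- correlation_clusters(coh, c("a", "flat")),
                 "undefined")
  expect_equal(lengths(cl$clusters), rep(1L, 2))
})

test_that("forward selection picks a strong single predictor first", {
  set.seed(207)
  n <- 600
  d <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  d$outcome_12m <- rbinom(n, 1, plogis(1.5 * d$signal))
  sel <- forward_select(d, c("noise1", "signal", "noise2"))
  expect_equal(sel$selection$added[1], "signal")
  expect_true("signal" %in% sel$selected)
})

test_that("forward selection never admits a candidate at p >= p_enter and is reproducible", {
  set.seed(208)
  n_intercept_only <- 0L
  for (i in 1:30) {
    n <- 400
    d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                    outcome_12m = rbinom(n, 1, 0.35))
    sel <- forward_select(d, c("a", "b", "c"))
    if (nrow(sel$selection)) {
      expect_true(all(sel$selection$p_value < 0.05))
    } else {
      n_intercept_only <- n_intercept_only + 1L
      expect_equal(unname(coef(sel)), qlogis(mean(d$outcome_12m)),
                   tolerance = 1e-6)
    }
  }
  # under the null, most replicates should select nothing
  expect_gt(n_intercept_only, 18)

  coh <- simulate_cohort(cohort_sim_config(n = 800), seed = 209)
  s1 <- forward_select(coh, c("age", "dmean_gy", "volume_cc"))
  s2 <- forward_select(coh, c("age", "dmean_gy", "volume_cc"))
  expect_identical(s1$selection, s2$selection)
  expect_identical(coef(s1), coef(s2))
})

test_that("forward selection on the generating factors recovers dose and volume", {
  coh <- simulate_cohort(cohort_sim_config(n = 2000), seed = 210)
  sel <- forward_select(coh, c("age", "dmean_gy", "volume_cc"))
  expect_setequal(sel$selected, c("dmean_gy", "volume_cc"))
})
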