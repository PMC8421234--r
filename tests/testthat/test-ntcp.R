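test_that("linear predictor reproduces hand-evaluated values", {
  m <- published_ntcp_model()
  # intercept limit: dose and volume contributions vanish
  expect_equal(linear_predictor(m, 0, 1e-9), -1.385, tolerance = 1e-6)
  # cohort means: -1.385 + 0.093*41.79 - 0.188*16.60 = -0.61933
  expect_equal(linear_predictor(m, 41.79, 16.60), -0.61933,
               tolerance = 1e-6)
  # dose solving S = 0 at the median volume
  expect_equal(linear_predictor(m, 48.45, 16.60), 0, tolerance = 1e-2)
  expect_error(linear_predictor(m, -1, 16.6), "dmean")
  expect_error(linear_predictor(m, 40, 0), "volume")
})

test_that("NTCP is the logistic of S with the right limits", {
  m0 <- ntcp_model(0, 0.1, -0.1)
  expect_equal(ntcp(m0, 1, 1), 0.5)  # S = 0
  m <- published_ntcp_model()
  expect_equal(ntcp(m, 16.79, 16.60), 0.05, tolerance = 1e-3)
  expect_equal(ntcp(m, 41.79, 16.60), 0.35, tolerance = 1e-3)
  expect_equal(ntcp(m, 1e6, 16.60), 1)
  expect_equal(predict(m, 41.79, 16.60, type = "link"),
               linear_predictor(m, 41.79, 16.60))
})

test_that("odds ratios reproduce the published per-unit values", {
  expect_equal(odds_ratio(0), 1)
  expect_equal(round(odds_ratio(-0.188), 3), 0.829)
  expect_equal(round(odds_ratio(0.093), 3), 1.097)
  or <- odds_ratio(0.093, se = 0.038)
  expect_equal(unname(or["odds_ratio"]), exp(0.093))
  expect_equal(unname(or["ci_low"]), exp(0.093 - qnorm(0.975) * 0.038))
  expect_true(or["ci_low"] < or["odds_ratio"] &&
                or["odds_ratio"] < or["ci_high"])
  expect_error(odds_ratio(0.1, se = -1), "se")
})

test_that("tolerance dose inverts the model in closed form", {
  m <- published_ntcp_model()
  # (logit(p) + 1.385 + 0.188 * 16.60) / 0.093
  expect_equal(tolerance_dose(m, 16.60, 0.05), 16.78883, tolerance = 1e-6)
  expect_equal(tolerance_dose(m, 16.60, 0.10), 24.82339, tolerance = 1e-6)
  expect_error(tolerance_dose(ntcp_model(0, 0, -0.1), 16.6, 0.05),
               "b_dmean")
  expect_error(tolerance_dose(m, 16.6, 1.2), "p")
})

test_that("tolerance_dose and ntcp are exact inverses", {
  set.seed(301)
  for (i in 1:25) {
    m <- ntcp_model(runif(1, -3, 1), runif(1, 0.02, 0.3),
                    runif(1, -0.4, -0.05))
    v <- runif(1, 5, 40)
    p <- runif(3, 0.01, 0.9)
    td <- suppressWarnings(tolerance_dose(m, v, p))
    ok <- td >= 0
    expect_true(all(abs(p[ok] - ntcp(m, td[ok], v)) < 1e-12))
    # round trip the other way
    d <- runif(1, 5, 60)
    expect_equal(suppressWarnings(tolerance_dose(m, v, ntcp(m, d, v))), d,
                 tolerance = 1e-9)
  }
})

test_that("negative tolerance doses are flagged as extrapolation", {
  m <- published_ntcp_model()
  expect_warning(td <- tolerance_dose(m, 5, 0.001), "extrapolation")
  expect_true(any(attr(td, "extrapolated")))
})

test_that("NTCP curves are monotone and strictly ordered by volume", {
  m <- published_ntcp_model()
  cur <- ntcp_curve(m, volumes = c(10, 15, 20, 25), dose_range = c(0, 60),
                    step = 0.5)
  wide <- reshape(as.data.frame(cur), idvar = "dose_gy",
                  timevar = "volume_cc", direction = "wide")
  # smaller volume strictly above larger volume at every dose
  expect_true(all(wide$ntcp.10 > wide$ntcp.15))
  expect_true(all(wide$ntcp.15 > wide$ntcp.20))
  expect_true(all(wide$ntcp.20 > wide$ntcp.25))
  for (v in c(10, 15, 20, 25))
    expect_true(all(diff(cur$ntcp[cur$volume_cc == v]) > 0))
  # curve passes through (TD(p), p)
  td10 <- tolerance_dose(m, 16.6, 0.10)
  cur2 <- ntcp_curve(m, 16.6, c(td10, td10 + 1), step = td10)
  expect_equal(cur2$ntcp[1], 0.10, tolerance = 1e-12)
  expect_error(ntcp_curve(m, 16.6, c(10, 5)), "dose_range")
})

test_that("model evaluation is pure and sign-consistent", {
  m <- published_ntcp_model()
  expect_identical(ntcp(m, 37.123, 14.56), ntcp(m, 37.123, 14.56))
  set.seed(302)
  d <- sort(runif(40, 0, 70))
  v <- sort(runif(40, 5, 40))
  expect_true(all(diff(ntcp(m, d, 16.6)) > 0))   # increasing in dose
  expect_true(all(diff(ntcp(m, 41.79, v)) < 0))  # decreasing in volume
})

test_that("as_ntcp_model maps a cohort fit onto the parameter object", {
  coh <- simulate_cohort(cohort_sim_config(n = 1500), seed = 303)
  fit <- ntcp_fit(outcome_12m ~ dmean_gy + volume_cc, coh)
  m <- as_ntcp_model(fit)
  expect_s3_class(m, "ntcp_model")
  expect_equal(ntcp(m, 40, 16), unname(
    predict(fit, data.frame(dmean_gy = 40, volume_cc = 16))))
  fit2 <- ntcp_fit(outcome_12m ~ age, coh)
  expect_error(as_ntcp_model(fit2), "coefficients")
})
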