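# survival registry construction and calibration

test_that("calibrated strata hit their 75%-survival anchors exactly", {
  reg <- shared_registry
  t75 <- default_t75_targets()
  for (s in names(t75)) {
    q <- surv_quantile(registry_dist(reg, s), 0.25) / 365.25
    expect_equal(q, unname(t75[s]), tolerance = 1e-6, label = s)
  }
  # printed anchors: SECA I 2.64 y, palliative chemotherapy 1.18 y
  expect_equal(surv_quantile(registry_dist(reg, "SECA1"), 0.25) / 365.25,
               2.64, tolerance = 1e-6)
  expect_equal(surv_quantile(registry_dist(reg, "palliative"), 0.25) / 365.25,
               1.18, tolerance = 1e-6)
})

test_that("exponential calibration has the closed-form scale T / ln(4/3)", {
  sp <- c(stats::setNames(rep(1, 9), names(default_t75_targets())))
  reg <- calibrate_registry(family = "exponential", shape_policy = sp, lt = shared_lt)
  d <- registry_dist(reg, "HCC")
  expect_equal(unname(d$params["scale"]), 2.20 * 365.25 / log(4 / 3),
               tolerance = 1e-9)
})

test_that("recalibrating from achieved quantiles is idempotent", {
  reg <- shared_registry
  achieved <- vapply(names(default_t75_targets()), function(s)
    surv_quantile(registry_dist(reg, s), 0.25) / 365.25, numeric(1))
  sp <- vapply(names(achieved), function(s) {
    d <- registry_dist(reg, s)
    unname(d$params[1]) # log-logistic shape
  }, numeric(1))
  reg2 <- calibrate_registry(targets = achieved, shape_policy = sp,
                             lt = shared_lt)
  expect_equal(reg2$par2, reg$par2, tolerance = 1e-9)
  expect_equal(reg2$par1, reg$par1, tolerance = 1e-9)
})

test_that("all required strata are present and validated", {
  reg <- shared_registry
  expect_silent(liversim:::validate_registry(reg))
  expect_error(registry_dist(reg, "nope"), "missing stratum")
  broken <- reg[reg$stratum != "palliative", ]
  expect_error(liversim:::validate_registry(broken), "palliative")
  # CRLM waiting-list strata default to the HCC ones
  expect_equal(reg$par1[reg$stratum == "wl_death:CRLM"],
               reg$par1[reg$stratum == "wl_death:HCC"])
})

test_that("unattainable targets fail loudly", {
  bad <- default_t75_targets()
  bad["HCC"] <- -1
  expect_error(calibrate_registry(targets = bad, lt = shared_lt))
})

test_that("the registry round-trips through its CSV format", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry(shared_registry, f)
  reg2 <- read_registry(f)
  expect_equal(as.data.frame(reg2), as.data.frame(shared_registry),
               tolerance = 1e-12)
  expect_error(read_registry(write_life_table(shared_lt, f)), "columns")
})

test_that("shape policy reproduces the life-expectancy anchors it encodes", {
  sp <- default_shape_policy(shared_lt)
  reach <- default_reach()
  # palliative: unconditional anchor 2.48 y at age 57 (no queue, reach 1)
  d <- liversim:::dist_from_t75("loglogistic", sp[["palliative"]],
                                1.18 * 365.25)
  expect_equal(expected_treated_life_years(d, 57, shared_lt), 2.48,
               tolerance = 1e-6)
  # SECA II anchor: 13.12 y conditional on reaching long-term survival
  d2 <- liversim:::dist_from_t75("loglogistic", sp[["SECA2"]], 5.06 * 365.25)
  expect_equal(expected_treated_life_years(d2, 57, shared_lt),
               13.12 / reach[["SECA2"]], tolerance = 1e-6)
  # Status Quo strata share one shape solving the mixture anchor
  expect_equal(unname(sp["HCC"]), unname(sp["PSC"]))
  mix <- default_patient_mix()
  ages <- diagnosis_ages()
  t75 <- default_t75_targets()
  le <- sum(vapply(names(mix), function(dg) {
    dd <- liversim:::dist_from_t75("loglogistic", sp[[dg]], t75[[dg]] * 365.25)
    mix[[dg]] * expected_treated_life_years(dd, ages[[dg]], shared_lt)
  }, numeric(1)))
  expect_equal(le, 15.28 / reach[["SQ"]], tolerance = 1e-6)
})

test_that("the frozen calibration constants are fixed points of their loops", {
  # death/dropout hazard: a short recalibration lands near the default
  rate <- calibrate_wl_rate(replications = 150, iterations = 2,
                            crlm_per_year = 2)
  expect_lt(abs(rate - default_wl_rate()), 0.03)
  # reach fractions: one cheap pass stays near the frozen values
  r <- calibrate_reach(reach = default_reach(), replications = 250,
                       lt = shared_lt)
  expect_lt(max(abs(r - default_reach())), 0.05)
})

test_that("weibull uncertainty swap preserves both anchor quantiles", {
  reg2 <- liversim:::swap_to_weibull(shared_registry, "SECA2")
  d0 <- registry_dist(shared_registry, "SECA2")
  d1 <- registry_dist(reg2, "SECA2")
  expect_equal(d1$family, "weibull")
  expect_equal(surv_quantile(d1, 0.25), surv_quantile(d0, 0.25), tolerance = 1e-9)
  expect_equal(surv_quantile(d1, 0.5), surv_quantile(d0, 0.5), tolerance = 1e-9)
  # thinner tail: poorer long-term survival
  expect_lt(surv_surv(d1, 10 * 365.25), surv_surv(d0, 10 * 365.25))
})
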