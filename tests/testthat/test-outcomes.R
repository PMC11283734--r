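# life-years accounting, net benefit, break-even, uncertainty variants

test_that("the background switch keeps short survivors and reroutes long ones", {
  d <- registry_dist(shared_registry, "SECA2") # cap_years = 10
  # a draw below the cap passes through unchanged
  u_low <- surv_cdf(d, 4.2 * 365.25)
  expect_equal(posttransplant_death_time(d, shared_lt, 57, u_low), 4.2,
               tolerance = 1e-9)
  # a long draw against a closing table dies within the switch year
  lt_force <- life_table(57:67, c(rep(0, 10), 1))
  u_high <- surv_cdf(d, 30 * 365.25)
  got <- posttransplant_death_time(d, lt_force, 57, u_high, u_bg = 0.4)
  expect_true(got >= 10 && got < 11)
})

test_that("expected life-years decompose as E[min(T,10)] + S(10) e(age+10)", {
  d <- registry_dist(shared_registry, "SECA2")
  analytic <- expected_treated_life_years(d, 57, shared_lt)
  u1 <- withr::with_seed(41, runif(1e5))
  u2 <- withr::with_seed(42, runif(1e5))
  t_days <- surv_quantile(d, u1)
  cap <- 10 * 365.25
  over <- t_days > cap
  ly <- t_days / 365.25
  ly[over] <- 10 + lt_sample_remaining(shared_lt, 67, u2[over])
  ly[!over] <- pmin(ly[!over], 10)
  expect_lt(abs(mean(ly) - analytic), 0.05)
  # and the scalar pathway agrees with the vectorized composition
  expect_equal(posttransplant_death_time(d, shared_lt, 57, u1[1], u2[1]),
               ly[1], tolerance = 1e-12)
})

test_that("palliative life-years reproduce their calibration target", {
  us <- withr::with_seed(43, runif(2e4))
  ub <- withr::with_seed(44, runif(2e4))
  ly <- vapply(seq_along(us), function(i)
    palliative_life_years(shared_registry, shared_lt, us[i], ub[i]),
    numeric(1))
  expect_lt(abs(mean(ly) - 2.48), 0.05)
  # 75% survive at least the printed 1.18 years
  expect_lt(abs(mean(ly >= 1.18) - 0.75), 0.01)
})

test_that("net benefit is gained minus lost and zero for identical outcomes", {
  cfg <- fast_config(30, seed = 51)
  base <- run_experiment(base_scenario(strategy = 1, crlm_per_year = 2), cfg)
  s2 <- run_experiment(base_scenario(strategy = 2, crlm_per_year = 2), cfg)
  nb <- net_benefit(list(s2), base)
  expect_equal(nb$net, nb$gained - nb$lost)
  # strategy 2 at zero CRLM equals the baseline queue: zero everywhere
  s0 <- run_experiment(base_scenario(strategy = 2, crlm_per_year = 0), cfg)
  base0 <- base
  nb0 <- net_benefit(list(s0), base0)
  expect_equal(nb0$gained, 0)
  expect_equal(nb0$lost, 0, tolerance = 1e-9)
  # mismatched seeds are refused
  s2b <- run_experiment(base_scenario(strategy = 2, crlm_per_year = 2),
                        fast_config(30, seed = 52))
  expect_error(net_benefit(list(s2b), base), "common random numbers")
})

test_that("find_break_even locates peaks and crossings", {
  curve <- tibble::tibble(crlm_per_year = 0:10,
                          net = c(0, 10, 18, 24, 28, 30, 29, 26, 5, -3, -8))
  expect_equal(find_break_even(curve)$peak_n, 5)
  expect_equal(find_break_even(curve)$break_even_n, 9)
  up <- tibble::tibble(crlm_per_year = 0:10, net = c(0, seq(10, 100, 10)))
  expect_true(is.na(find_break_even(up)$break_even_n))
  neg <- tibble::tibble(crlm_per_year = 1:10, net = -(1:10))
  expect_equal(find_break_even(neg)$break_even_n, 1)
})

test_that("uncertainty variants apply the documented substitutions", {
  sc <- base_scenario(strategy = 2, crlm_per_year = 2)
  best <- run_uncertainty(sc, "best-case-livers")
  expect_equal(best$liver_interarrival_days, 365 / 121) # ~3.017 d
  worst <- run_uncertainty(sc, "worst-case-livers")
  expect_equal(worst$liver_interarrival_days, 365 / 103) # ~3.544 d
  swp <- run_uncertainty(sc, "seca-weibull")
  expect_equal(registry_dist(swp$registry, "SECA2")$family, "weibull")
  expect_equal(registry_dist(swp$registry, "SECA1")$family, "weibull")
  expect_equal(registry_dist(swp$registry, "palliative")$family, "loglogistic")
  pal <- run_uncertainty(sc, "palliative-weibull")
  expect_equal(registry_dist(pal$registry, "palliative")$family, "weibull")
  better <- run_uncertainty(sc, "better-sq-survival")
  psc <- registry_dist(better$registry, "PSC")
  for (s in c("HCC", "AC", "Others")) {
    expect_equal(registry_dist(better$registry, s)$params, psc$params)
  }
  expect_error(run_uncertainty(sc, "unknown-variant"))
})

test_that("poorer-survival variants move life expectancy the expected way", {
  cfg <- fast_config(60, seed = 61)
  sc <- base_scenario(strategy = 2, crlm_per_year = 2, criteria = "SECA2")
  g0 <- glance(run_experiment(sc, cfg))
  g_weib <- glance(run_experiment(run_uncertainty(sc, "seca-weibull"), cfg))
  expect_lt(g_weib$mean_le_crlm, g0$mean_le_crlm)
  g_best <- glance(run_experiment(run_uncertainty(sc, "best-case-livers"), cfg))
  expect_lt(g_best$median_wait_overall, g0$median_wait_overall)
})
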