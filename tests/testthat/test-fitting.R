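# censored maximum likelihood and model selection

true_pars <- list(
  exponential = c(scale = 800),
  weibull = c(shape = 1.5, scale = 1000),
  loglogistic = c(shape = 2, scale = 600),
  lognormal = c(meanlog = 6.2, sdlog = 0.8),
  gompertz = c(rate = 0.0008, shape = 0.0015)
)

test_that("exponential MLE equals the closed form, censored or not", {
  coh <- generate_cohort("exponential", c(scale = 800), n = 400, seed = 2)
  f <- fit_parametric(coh, "exponential")
  expect_equal(unname(f$params["scale"]), mean(coh$time), tolerance = 1e-9)
  cens <- generate_cohort("exponential", c(scale = 800), n = 400,
                          censor_time = 700, seed = 2)
  fc <- fit_parametric(cens, "exponential")
  expect_equal(unname(fc$params["scale"]),
               sum(cens$time) / sum(cens$event), tolerance = 1e-9)
  # information criteria identities (k = 1)
  expect_equal(fc$aic, 2 - 2 * fc$loglik)
  expect_equal(fc$bic, log(400) - 2 * fc$loglik)
})

test_that("every family recovers its parameters within 10% at n = 2000", {
  for (fam in names(true_pars)) {
    coh <- generate_cohort(fam, true_pars[[fam]], n = 2000, seed = 11)
    f <- fit_parametric(coh, fam)
    rel <- abs(f$params - true_pars[[fam]]) / abs(true_pars[[fam]])
    expect_lt(max(rel), 0.10, label = fam)
  }
})

test_that("fitted parameters are a local likelihood maximum", {
  coh <- generate_cohort("weibull", c(shape = 1.5, scale = 1000), n = 1000,
                         seed = 3, censor_time = 2500)
  f <- fit_parametric(coh, "weibull")
  ll <- function(p) liversim:::surv_loglik("weibull", p, coh$time, coh$event)
  for (eps in c(0.98, 1.02)) {
    for (which in 1:2) {
      p <- f$params
      p[which] <- p[which] * eps
      expect_lt(ll(p), f$loglik + 1e-6)
    }
  }
})

test_that("censoring is handled like survreg's (independent route)", {
  skip_if_not_installed("survival")
  coh <- generate_cohort("weibull", c(shape = 1.3, scale = 900), n = 1500,
                         censor_time = 1200, seed = 8)
  mine <- fit_parametric(coh, "weibull")
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = coh,
                          dist = "weibull")
  expect_equal(unname(mine$params["shape"]), 1 / sr$scale, tolerance = 1e-3)
  expect_equal(unname(mine$params["scale"]), exp(unname(coef(sr))),
               tolerance = 1e-3)
  expect_equal(mine$loglik, as.numeric(logLik(sr)), tolerance = 1e-6)
  # and the log-logistic route
  coh2 <- generate_cohort("loglogistic", c(shape = 2, scale = 600), n = 1500,
                          censor_time = 2000, seed = 9)
  mine2 <- fit_parametric(coh2, "loglogistic")
  sr2 <- survival::survreg(survival::Surv(time, event) ~ 1, data = coh2,
                           dist = "loglogistic")
  expect_equal(unname(mine2$params["shape"]), 1 / sr2$scale, tolerance = 1e-3)
  expect_equal(unname(mine2$params["scale"]), exp(unname(coef(sr2))),
               tolerance = 1e-3)
})

test_that("degenerate inputs raise the documented errors", {
  coh <- generate_cohort("exponential", c(scale = 100), n = 50, seed = 1)
  allcens <- coh
  allcens$event <- FALSE
  expect_error(fit_parametric(allcens, "exponential"), "censored")
  expect_error(fit_parametric(coh[1:5, ], "weibull"), "at least 10")
})

test_that("select_model minimizes the criterion with documented tie-breaks", {
  coh <- generate_cohort("loglogistic", c(shape = 2, scale = 600), n = 300,
                         seed = 4)
  fits <- fit_survival_families(coh)
  best <- select_model(fits, "aic")
  crit <- vapply(fits, function(f) f$aic, numeric(1))
  expect_equal(best$aic, min(crit))
  # single-element list returns that element
  expect_identical(select_model(fits["weibull"], "bic"), fits$weibull)
  expect_error(select_model(list()), "no fits")
  # ties break toward fewer parameters, then family order
  f1 <- fits$exponential; f2 <- fits$weibull
  f2$aic <- f1$aic
  expect_identical(select_model(list(f2, f1), "aic")$family, "exponential")
})

test_that("AIC selects the generating log-logistic family most of the time", {
  wins <- 0L
  for (s in 1:100) {
    coh <- generate_cohort("loglogistic", c(shape = 2, scale = 600),
                           n = 2000, seed = 1000 + s)
    # an occasional non-convergence of a rival family is fine: selection
    # operates on whichever fits succeeded
    fits <- suppressWarnings(fit_survival_families(coh))
    if (select_model(fits, "aic")$family == "loglogistic") wins <- wins + 1L
  }
  expect_gte(wins, 70)
})

test_that("recovery bias stays below 5% at n = 5000 (averaged over seeds)", {
  n_seeds <- 50
  for (fam in names(true_pars)) {
    est <- matrix(0, n_seeds, length(true_pars[[fam]]))
    for (s in seq_len(n_seeds)) {
      coh <- generate_cohort(fam, true_pars[[fam]], n = 5000, seed = 7000 + s)
      est[s, ] <- fit_parametric(coh, fam)$params
    }
    bias <- abs(colMeans(est) - true_pars[[fam]]) / abs(true_pars[[fam]])
    expect_lt(max(bias), 0.05, label = fam)
  }
})

test_that("tidy and glance follow broom conventions", {
  coh <- generate_cohort("weibull", c(shape = 1.5, scale = 1000), n = 200,
                         seed = 5)
  f <- fit_parametric(coh, "weibull")
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, c("shape", "scale"))
  gl <- glance(f)
  expect_equal(gl$nobs, 200)
  expect_equal(gl$AIC, 4 - 2 * gl$logLik)
})
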