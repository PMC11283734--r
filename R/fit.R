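#' Censored maximum-likelihood fitting of parametric survival families
#'
#' Fits one of the five supported families to right-censored data by maximum
#' likelihood: events contribute the log density, censored observations the
#' log survival. The exponential uses its closed-form MLE (scale = total time
#' at risk / number of events); the other families are maximized numerically
#' (Nelder-Mead followed by BFGS polish on log-transformed positive
#' parameters).
#'
#' @param data Data frame with columns `time` (positive, days) and `event`
#'   (logical or 0/1, `TRUE` = observed death, `FALSE` = right-censored).
#' @param family One of the five families, see [surv_dist()].
#' @return A `parsurv_fit`: family, fitted `params`, `loglik`, `aic`
#'   (`2k - 2logL`), `bic` (`k log n - 2logL` with `n` the number of
#'   observations, censored included), sample size `n`, number of events, and
#'   the fitted [surv_dist()] in `$dist`.
#' @examples
#' set.seed(1)
#' coh <- generate_cohort("weibull", c(shape = 1.5, scale = 1000), n = 500, seed = 1)
#' fit_parametric(coh, "weibull")
#' @export
fit_parametric <- function(data, family) {
  family <- match.arg(family, surv_families())
  time <- data$time
  event <- as.logical(data$event)
  n <- length(time)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be positive and finite", call. = FALSE)
  }
  if (!any(event)) stop("all observations censored; cannot fit", call. = FALSE)

  if (family == "exponential") {
    scale <- sum(time) / sum(event)
    params <- c(scale = scale)
    ll <- surv_loglik(family, params, time, event)
    est <- list(params = params, loglik = ll, convergence = 0L)
  } else {
    est <- fit_numeric_mle(family, time, event)
  }
  k <- length(surv_param_names(family))
  structure(list(
    family = family,
    params = est$params,
    loglik = est$loglik,
    aic = 2 * k - 2 * est$loglik,
    bic = k * log(n) - 2 * est$loglik,
    n = n,
    n_events = sum(event),
    convergence = est$convergence,
    dist = do.call(surv_dist, c(list(family), as.list(est$params)))
  ), class = "parsurv_fit")
}

surv_loglik <- function(family, params, time, event) {
  d <- structure(list(family = family, params = params), class = "surv_dist")
  ll <- sum(surv_logdens(d, time[event]))
  if (any(!event)) ll <- ll + sum(log(pmax(surv_surv(d, time[!event]), 1e-300)))
  ll
}

fit_numeric_mle <- function(family, time, event) {
  start <- mle_start(family, time, event)
  to_par <- mle_transform(family)
  nll <- function(theta) {
    params <- to_par$from(theta)
    ok <- tryCatch({ check_surv_params(family, params); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(1e12)
    ll <- surv_loglik(family, params, time, event)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  o1 <- stats::optim(to_par$to(start), nll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  o2 <- tryCatch(
    stats::optim(o1$par, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) o1)
  o <- if (o2$value <= o1$value) o2 else o1
  if (!is.finite(o$value) || o$value >= 1e12) {
    stop("maximum-likelihood fit failed to converge for family '", family, "'",
         call. = FALSE)
  }
  list(params = to_par$from(o$par), loglik = -o$value,
       convergence = o$convergence)
}

mle_start <- function(family, time, event) {
  m <- sum(time) / sum(event) # exponential-equivalent mean
  lt <- log(time[event])
  switch(family,
    weibull = c(shape = 1.2, scale = m),
    loglogistic = c(shape = 1.5, scale = stats::median(time[event])),
    lognormal = c(meanlog = mean(lt), sdlog = max(stats::sd(lt), 0.1)),
    gompertz = c(rate = 1 / m, shape = 0.1 / m)
  )
}

mle_transform <- function(family) {
  if (family == "lognormal") {
    list(to = function(p) c(p[["meanlog"]], log(p[["sdlog"]])),
         from = function(th) c(meanlog = th[1], sdlog = exp(th[2])))
  } else if (family == "gompertz") {
    # shape may be negative; rate is positive
    list(to = function(p) c(log(p[["rate"]]), p[["shape"]]),
         from = function(th) c(rate = exp(th[1]), shape = th[2]))
  } else {
    nm <- c("shape", "scale")
    list(to = function(p) log(p[nm]),
         from = function(th) stats::setNames(exp(th), nm))
  }
}

#' Fit all (or several) families to one data set
#'
#' @inheritParams fit_parametric
#' @param families Character vector of families to fit.
#' @return Named list of `parsurv_fit` objects; families whose fit fails are
#'   dropped with a warning.
#' @export
fit_survival_families <- function(data, families = surv_families()) {
  fits <- list()
  for (f in families) {
    res <- tryCatch(fit_parametric(data, f), error = function(e) e)
    if (inherits(res, "error")) {
      warning("fit failed for ", f, ": ", conditionMessage(res), call. = FALSE)
    } else {
      fits[[f]] <- res
    }
  }
  fits
}

#' Select the best-fitting family by information criterion
#'
#' Returns the fit minimizing AIC or BIC. Ties are broken by the smaller
#' number of free parameters, then by the fixed family order of
#' `surv_families()`.
#'
#' @param fits List of `parsurv_fit` objects on the same data.
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `parsurv_fit`.
#' @export
select_model <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  crit <- vapply(fits, function(f) f[[criterion]], numeric(1))
  k <- vapply(fits, function(f) length(f$params), numeric(1))
  ord <- match(vapply(fits, function(f) f$family, character(1)), surv_families())
  fits[[order(crit, k, ord)[1]]]
}

#' @export
print.parsurv_fit <- function(x, ...) {
  cat("<parsurv_fit> ", x$family, " (n = ", x$n, ", events = ", x$n_events, ")\n",
      sep = "")
  cat("  ", paste(names(x$params), signif(x$params, 6), sep = " = ",
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  logLik = %.3f, AIC = %.3f, BIC = %.3f\n", x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Tidy a parametric survival fit
#' @param x A `parsurv_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter. `glance()`: one-row model summary.
#' @export
tidy.parsurv_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.parsurv_fit
#' @export
glance.parsurv_fit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$loglik, AIC = x$aic,
                 BIC = x$bic, nobs = x$n, n_events = x$n_events)
}
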