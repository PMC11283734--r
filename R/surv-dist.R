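#' Parametric survival distributions
#'
#' `surv_dist()` builds a parametric survival distribution from one of five
#' families. All time scales are in **days**. The supported families and their
#' parameterizations are:
#'
#' * `exponential`: `scale` (mean), survival \eqn{S(t) = \exp(-t/scale)}.
#' * `weibull`: `shape`, `scale`, \eqn{S(t) = \exp(-(t/scale)^{shape})}.
#' * `loglogistic`: `shape`, `scale`, \eqn{S(t) = 1/(1 + (t/scale)^{shape})};
#'   the scale is the median.
#' * `lognormal`: `meanlog`, `sdlog` of `log(t)`.
#' * `gompertz`: `rate` (a), `shape` (b), hazard \eqn{h(t) = a e^{b t}},
#'   \eqn{S(t) = \exp(-(a/b)(e^{bt} - 1))}. The shape may be negative, in
#'   which case the distribution is defective (a fraction \eqn{e^{a/b}} never
#'   fails) and quantiles beyond the attainable mass are `Inf`. Gompertz
#'   conventions differ across texts; this one is stated explicitly because it
#'   is the one used everywhere in the package.
#'
#' `cap_years` is carried as metadata: it marks the horizon (in years) after
#' which the posttransplant pathway switches to life-table background
#' mortality. The distribution functions themselves ignore it; the switch is
#' applied by [posttransplant_death_time()].
#'
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gompertz"`.
#' @param ... Named family parameters, see above.
#' @param cap_years Optional positive horizon in years (metadata only).
#' @return An object of class `surv_dist`.
#' @examples
#' d <- surv_dist("exponential", scale = 100)
#' surv_quantile(d, 0.5) # 100 * log(2)
#' @export
surv_dist <- function(family, ..., cap_years = NULL) {
  family <- match.arg(family, surv_families())
  params <- c(...)
  need <- surv_param_names(family)
  if (!setequal(names(params), need)) {
    stop("family '", family, "' needs parameters: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  params <- params[need]
  check_surv_params(family, params)
  if (!is.null(cap_years)) {
    stopifnot(is.numeric(cap_years), length(cap_years) == 1L, cap_years > 0)
  }
  structure(list(family = family, params = params, cap_years = cap_years),
            class = "surv_dist")
}

#' @export
print.surv_dist <- function(x, ...) {
  cat("<surv_dist> ", x$family, ": ",
      paste(names(x$params), signif(x$params, 6), sep = " = ", collapse = ", "),
      if (!is.null(x$cap_years)) paste0(" [cap ", x$cap_years, " y]"), "\n", sep = "")
  invisible(x)
}

surv_families <- function() {
  c("exponential", "weibull", "loglogistic", "lognormal", "gompertz")
}

surv_param_names <- function(family) {
  switch(family,
    exponential = "scale",
    weibull = c("shape", "scale"),
    loglogistic = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    gompertz = c("rate", "shape")
  )
}

check_surv_params <- function(family, params) {
  if (any(!is.finite(params))) stop("non-finite parameters", call. = FALSE)
  bad <- switch(family,
    exponential = params[["scale"]] <= 0,
    weibull = params[["shape"]] <= 0 || params[["scale"]] <= 0,
    loglogistic = params[["shape"]] <= 0 || params[["scale"]] <= 0,
    lognormal = params[["sdlog"]] <= 0,
    gompertz = params[["rate"]] <= 0
  )
  if (bad) stop("invalid parameters for family '", family, "'", call. = FALSE)
  invisible(TRUE)
}

#' Survival, distribution and quantile functions
#'
#' `surv_surv()` evaluates \eqn{S(t)}, `surv_cdf()` evaluates
#' \eqn{F(t) = 1 - S(t)} and `surv_quantile()` its inverse. Quantiles use the
#' closed forms of each family, so `surv_cdf(d, surv_quantile(d, p)) == p` to
#' floating point accuracy.
#'
#' @param dist A [surv_dist()].
#' @param t Non-negative times in days.
#' @param p Probabilities in `[0, 1)`.
#' @return Numeric vector.
#' @export
surv_cdf <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  1 - surv_surv(dist, t)
}

#' @rdname surv_cdf
#' @export
surv_surv <- function(dist, t) {
  p <- dist$params
  switch(dist$family,
    exponential = exp(-t / p[["scale"]]),
    weibull = exp(-(t / p[["scale"]])^p[["shape"]]),
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    lognormal = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    gompertz = {
      a <- p[["rate"]]; b <- p[["shape"]]
      if (abs(b) < 1e-12) exp(-a * t) else exp(-(a / b) * expm1(b * t))
    }
  )
}

#' @rdname surv_cdf
#' @export
surv_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)", call. = FALSE)
  pr <- dist$params
  switch(dist$family,
    exponential = -pr[["scale"]] * log1p(-p),
    weibull = pr[["scale"]] * (-log1p(-p))^(1 / pr[["shape"]]),
    loglogistic = pr[["scale"]] * (p / (1 - p))^(1 / pr[["shape"]]),
    lognormal = stats::qlnorm(p, pr[["meanlog"]], pr[["sdlog"]]),
    gompertz = {
      a <- pr[["rate"]]; b <- pr[["shape"]]
      if (abs(b) < 1e-12) {
        -log1p(-p) / a
      } else {
        arg <- 1 - (b / a) * log1p(-p)
        out <- ifelse(arg > 0, log(pmax(arg, .Machine$double.xmin)) / b, Inf)
        # defective tail (b < 0): mass beyond 1 - exp(a/b) is never reached
        out
      }
    }
  )
}

#' Log density, used by the censored likelihoods
#' @noRd
surv_logdens <- function(dist, t) {
  p <- dist$params
  switch(dist$family,
    exponential = -log(p[["scale"]]) - t / p[["scale"]],
    weibull = stats::dweibull(t, p[["shape"]], p[["scale"]], log = TRUE),
    loglogistic = {
      sh <- p[["shape"]]; sc <- p[["scale"]]
      z <- (t / sc)^sh
      log(sh) - log(sc) + (sh - 1) * (log(t) - log(sc)) - 2 * log1p(z)
    },
    lognormal = stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]], log = TRUE),
    gompertz = {
      a <- p[["rate"]]; b <- p[["shape"]]
      if (abs(b) < 1e-12) log(a) - a * t else log(a) + b * t - (a / b) * expm1(b * t)
    }
  )
}

#' Draw event times from a survival distribution
#'
#' Inverse-transform sampling: each draw is `surv_quantile(dist, u)`. Either
#' supply `u` (deterministic, used by the simulation engine and in tests) or a
#' number of draws `n`, in which case uniforms come from the R session RNG.
#'
#' @param dist A [surv_dist()].
#' @param n Number of draws (ignored when `u` is given).
#' @param u Optional uniform draws in `[0, 1)`.
#' @return Times in days.
#' @export
surv_sample <- function(dist, n = 1, u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  surv_quantile(dist, u)
}

#' Restricted mean survival time
#'
#' Mean of `min(T, horizon)` in days, by numerical integration of the survival
#' function. Used by the calibration of shape parameters to life-expectancy
#' anchors.
#'
#' @param dist A [surv_dist()].
#' @param horizon Upper limit in days.
#' @return Days.
#' @export
surv_rmst <- function(dist, horizon) {
  stopifnot(horizon > 0)
  stats::integrate(function(t) surv_surv(dist, t), 0, horizon,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}
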