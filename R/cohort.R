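#' Generate a synthetic time-to-event cohort
#'
#' Stand-in for individual patient data reconstructed from published survival
#' curves: draws `n` event times from a known parametric family, optionally
#' with administrative right-censoring at `censor_time`. The event flag is
#' `FALSE` iff the observation is censored. Regeneration with the same seed is
#' bit-identical; the draw uses an isolated RNG state and does not disturb the
#' session RNG.
#'
#' @param family,params Family name and named parameter vector, see
#'   [surv_dist()].
#' @param n Cohort size.
#' @param censor_time Optional censoring time in days (`NULL` = none).
#' @param seed Integer seed.
#' @return Tibble with columns `time`, `event`; the generating truth is kept
#'   in attributes `true_family`, `true_params`, `seed`.
#' @export
generate_cohort <- function(family, params, n, censor_time = NULL, seed = 1L) {
  stopifnot(n >= 1)
  dist <- do.call(surv_dist, c(list(family), as.list(params)))
  u <- withr::with_seed(seed, stats::runif(n))
  t_true <- surv_quantile(dist, u)
  t_true <- pmax(t_true, .Machine$double.xmin) # strictly positive
  if (is.null(censor_time)) {
    out <- tibble::tibble(time = t_true, event = TRUE)
  } else {
    stopifnot(censor_time > 0)
    out <- tibble::tibble(time = pmin(t_true, censor_time),
                          event = t_true <= censor_time)
  }
  attr(out, "true_family") <- family
  attr(out, "true_params") <- params
  attr(out, "seed") <- seed
  out
}
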