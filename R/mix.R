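#' Default donor-liver blood-type mix
#'
#' The donor mix is the population blood-type distribution with small
#' adjustments, calibrated with [calibrate_liver_mix()] so that the simulated
#' blood-type-specific median waiting times under the base case reproduce the
#' model's validation surface (A 32, B 53, AB 21, O 106 days). The frozen
#' values below were produced by that closed-loop calibration at the package
#' defaults; a test re-runs a short calibration to confirm they are a fixed
#' point.
#'
#' @return Named probabilities (A, B, AB, O) summing to 1.
#' @export
default_liver_mix <- function() {
  c(A = 0.470, B = 0.075, AB = 0.020, O = 0.435)
}

#' Calibrate the donor blood-type mix to target median waits
#'
#' Seeded greedy coordinate search on the probability simplex: repeatedly
#' moves probability mass `step` between blood types (within ±10 percentage
#' points of the base mix), accepting moves that reduce the summed absolute
#' deviation between simulated and target median waits by blood type, halving
#' `step` when no move helps, until `sim_budget` short simulations are spent.
#' Calibration uses its own fixed seed, so it never perturbs experiment
#' streams.
#'
#' @param targets Named target median waits in days (A, B, AB, O).
#' @param base_mix Starting donor mix (population blood-type distribution).
#' @param sim_budget Maximum number of simulation evaluations.
#' @param scenario Scenario template whose `liver_mix` is being calibrated
#'   (strategy-1 base case by default).
#' @param replications Replications per evaluation (short runs).
#' @param seed Dedicated calibration seed.
#' @param step Initial probability step.
#' @param tol_days Stop early when every type's deviation is below this.
#' @return The calibrated mix with attributes `achieved` (simulated medians),
#'   `loss`, `evals`, and `budget_exhausted` (TRUE when the search ran out of
#'   budget while improvements were still being found).
#' @export
calibrate_liver_mix <- function(targets = c(A = 32, B = 53, AB = 21, O = 106),
                                base_mix = default_blood_mix(),
                                sim_budget = 60,
                                scenario = NULL,
                                replications = 120,
                                seed = 424242L,
                                step = 0.02,
                                tol_days = 2) {
  stopifnot(all(targets > 0))
  check_mix(base_mix, c("A", "B", "AB", "O"))
  bts <- c("A", "B", "AB", "O")
  targets <- targets[bts]
  base_mix <- base_mix[bts]
  if (is.null(scenario)) scenario <- scenario_config(strategy = 1)
  cfg <- replication_config(replications = replications, seed = seed)
  evals <- 0L
  simulate_medians <- function(mix) {
    sc <- scenario
    sc$liver_mix <- mix
    evals <<- evals + 1L
    g <- glance(run_experiment(sc, cfg))
    c(A = g$median_wait_A, B = g$median_wait_B,
      AB = g$median_wait_AB, O = g$median_wait_O)
  }
  loss_of <- function(med) sum(abs(med - targets))

  cur <- base_mix
  med <- simulate_medians(cur)
  best_loss <- loss_of(med)
  if (all(abs(med - targets) <= tol_days)) {
    return(structure(cur, achieved = med, loss = best_loss, evals = evals,
                     budget_exhausted = FALSE))
  }
  improved_last_pass <- TRUE
  while (evals < sim_budget && step >= 0.0024) {
    improved <- FALSE
    for (i in seq_along(bts)) {
      for (j in seq_along(bts)) {
        if (i == j || evals >= sim_budget) next
        cand <- cur
        cand[i] <- cand[i] - step
        cand[j] <- cand[j] + step
        if (cand[i] < 0) next
        if (any(abs(cand - base_mix) > 0.10 + 1e-12)) next
        m2 <- simulate_medians(cand)
        l2 <- loss_of(m2)
        if (l2 < best_loss - 1e-9) {
          cur <- cand; med <- m2; best_loss <- l2; improved <- TRUE
        }
      }
    }
    if (all(abs(med - targets) <= tol_days)) break
    if (!improved) step <- step / 2
    improved_last_pass <- improved
  }
  exhausted <- evals >= sim_budget && improved_last_pass
  if (exhausted) {
    warning("calibration budget exhausted; returning best mix found",
            call. = FALSE)
  }
  structure(cur, achieved = med, loss = best_loss, evals = evals,
            budget_exhausted = exhausted)
}
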