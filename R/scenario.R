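#' Scenario configuration
#'
#' Describes one policy scenario of the waiting-list model. Strategy 1 keeps
#' CRLM patients off the list (they receive palliative chemotherapy and are
#' simulated as a parallel, non-queue cohort at the same arrival rate so that
#' per-group comparisons use matched cohorts); strategy 2 lists them under the
#' chosen eligibility criteria. `crlm_per_year = 0` is legal under either
#' strategy, and strategy 2 with zero CRLM arrivals reproduces strategy 1
#' bit-identically under shared seeds.
#'
#' @param strategy 1 (CRLM not eligible) or 2 (CRLM listed).
#' @param crlm_per_year Annual CRLM arrivals, 0..10; the interarrival mean is
#'   `365 / crlm_per_year` days.
#' @param criteria `"SECA1"` or `"SECA2"`: which trial survival stratum CRLM
#'   transplant recipients draw from.
#' @param patient_interarrival_days,liver_interarrival_days Exponential
#'   interarrival means (defaults 3.55 and 3.18 days).
#' @param registry Survival registry, see [survival_registry]; defaults to
#'   [default_registry()].
#' @param liver_mix Blood-type mix of donor livers (A, B, AB, O); defaults to
#'   the calibrated mix [default_liver_mix()].
#' @param patient_blood_mix Blood-type mix of patients (population mix).
#' @param patient_mix Diagnosis mix of Status Quo patients.
#' @param p_retransplant_listed,p_retransplant_qualify,p_withdraw
#'   Retransplant listing and qualification probabilities and the destined
#'   withdrawal fraction per listing spell.
#' @param abo_rule `"compatible"` (default) or `"identical"` blood-group
#'   matching. Identical matching cannot reproduce the observed waiting-time
#'   vector (see the methods vignette), so the compatible rule is the base
#'   case.
#' @param life_table Background-mortality life table.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(strategy = 1,
                            crlm_per_year = 0,
                            criteria = c("SECA2", "SECA1"),
                            patient_interarrival_days = 3.55,
                            liver_interarrival_days = 3.18,
                            registry = default_registry(),
                            liver_mix = default_liver_mix(),
                            patient_blood_mix = default_blood_mix(),
                            patient_mix = default_patient_mix(),
                            p_retransplant_listed = 0.134,
                            p_retransplant_qualify = 0.749,
                            p_withdraw = 0.06,
                            abo_rule = c("compatible", "identical"),
                            life_table = synthetic_norway_life_table()) {
  criteria <- match.arg(criteria)
  abo_rule <- match.arg(abo_rule)
  stopifnot(strategy %in% c(1, 2),
            crlm_per_year >= 0, crlm_per_year <= 10,
            patient_interarrival_days > 0, liver_interarrival_days > 0,
            p_retransplant_listed >= 0, p_retransplant_listed <= 1,
            p_retransplant_qualify >= 0, p_retransplant_qualify <= 1,
            p_withdraw >= 0, p_withdraw < 1)
  check_mix(liver_mix, c("A", "B", "AB", "O"))
  check_mix(patient_blood_mix, c("A", "B", "AB", "O"))
  check_mix(patient_mix, sq_diagnoses())
  validate_registry(registry)
  structure(list(
    strategy = as.integer(strategy),
    crlm_per_year = crlm_per_year,
    criteria = criteria,
    patient_interarrival_days = patient_interarrival_days,
    liver_interarrival_days = liver_interarrival_days,
    registry = registry,
    liver_mix = liver_mix,
    patient_blood_mix = patient_blood_mix,
    patient_mix = patient_mix,
    p_retransplant_listed = p_retransplant_listed,
    p_retransplant_qualify = p_retransplant_qualify,
    p_withdraw = p_withdraw,
    abo_rule = abo_rule,
    life_table = life_table
  ), class = "scenario_config")
}

check_mix <- function(mix, names_needed) {
  if (!setequal(names(mix), names_needed)) {
    stop("mix must have names: ", paste(names_needed, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(mix) - 1) > 1e-9) stop("mix must sum to 1", call. = FALSE)
  if (any(mix < 0)) stop("mix entries must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Replication configuration
#'
#' Burn-in, enrollment window, replication count and the named RNG streams.
#' The defaults are the base-case analysis settings: a 1,900-day burn-in
#' (entities listed during burn-in compete for livers but are excluded from
#' outcome ledgers), a 10-year (3,650-day) enrollment window whose listings
#' are tracked to death, and averaging over replications (7,000 in the full
#' base case; interactive and test runs use fewer).
#'
#' Four independent named streams derive from the master seed: `arrivals`,
#' `attributes`, `pretransplant`, `posttransplant`. Overriding one stream
#' seed leaves draws on the other streams bit-identical, which is what makes
#' common-random-number comparisons across strategies work.
#'
#' @param replications Number of replications (>= 1).
#' @param burn_in_days,enrollment_days Window definition in days.
#' @param seed Master seed (integer).
#' @param stream_seeds Optional named overrides for any of the four streams.
#' @return A `replication_config` list.
#' @export
replication_config <- function(replications = 500,
                               burn_in_days = 1900,
                               enrollment_days = 3650,
                               seed = 1L,
                               stream_seeds = NULL) {
  stopifnot(replications >= 1, burn_in_days >= 0, enrollment_days > 0)
  streams <- c("arrivals", "attributes", "pretransplant", "posttransplant")
  ss <- stats::setNames(vapply(streams, function(s) derive_seed(seed, s),
                               numeric(1)), streams)
  if (!is.null(stream_seeds)) {
    stopifnot(all(names(stream_seeds) %in% streams))
    ss[names(stream_seeds)] <- stream_seeds
  }
  structure(list(replications = as.integer(replications),
                 burn_in_days = burn_in_days,
                 enrollment_days = enrollment_days,
                 seed = as.integer(seed),
                 stream_seeds = ss),
            class = "replication_config")
}

# deterministic 31-bit stream seed from (master seed, stream name); plain
# modular arithmetic, exact in doubles (all intermediates < 2^53)
derive_seed <- function(seed, stream) {
  h <- 97
  for (ch in utf8ToInt(stream)) h <- (h * 8121 + ch) %% 2147483647
  ((seed %% 2147483647) * 48271 + h * 16807) %% 2147483629 + 1
}
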