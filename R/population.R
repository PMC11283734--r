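#' Arrival and attribute assignment primitives
#'
#' The entity generators are Poisson point processes: interarrival times are
#' exponential with the given mean (3.55 d for currently eligible patients,
#' 3.18 d for donor livers, 365/n d for n CRLM patients per year).
#' `next_arrival()` converts a uniform draw into the next interarrival gap.
#'
#' @param interarrival_mean Mean interarrival time in days (> 0).
#' @param u Uniform draws in `[0, 1)`.
#' @return Days until the next arrival.
#' @export
next_arrival <- function(interarrival_mean, u) {
  if (interarrival_mean <= 0) stop("interarrival mean must be > 0", call. = FALSE)
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)", call. = FALSE)
  -interarrival_mean * log1p(-u)
}

assign_categorical <- function(u, mix, levels_order) {
  if (abs(sum(mix) - 1) > 1e-9) stop("mix must sum to 1", call. = FALSE)
  mix <- mix[levels_order]
  cs <- cumsum(unname(mix))
  vapply(u, function(ui) {
    levels_order[min(which(ui < cs), length(levels_order))]
  }, character(1))
}

#' Assign a liver-disease diagnosis from the national case mix
#'
#' Categorical draw in the fixed order HCC, PBC, PSC, ALF, AC, Others
#' (13.7%, 6.7%, 18%, 8.3%, 10.1% and the 43.2% complement by default),
#' deterministic given `u`. Identical to the assignment rule inside the
#' simulation engine.
#'
#' @param u Uniform draws in `[0, 1)`.
#' @param mix Named probabilities over the six diagnoses.
#' @return Character vector of diagnoses.
#' @export
assign_diagnosis <- function(u, mix = default_patient_mix()) {
  assign_categorical(u, mix, sq_diagnoses())
}

#' Assign a blood type
#'
#' Categorical draw in the fixed order A, B, AB, O (population mix 49%, 8%,
#' 4%, 39%).
#'
#' @inheritParams assign_diagnosis
#' @param mix Named probabilities over A, B, AB, O.
#' @export
assign_blood_type <- function(u, mix = default_blood_mix()) {
  assign_categorical(u, mix, c("A", "B", "AB", "O"))
}

#' Construct a patient record
#'
#' R-level mirror of the engine's patient generator, mostly useful for
#' inspection and tests: assigns diagnosis (CRLM patients always have
#' diagnosis CRLM), blood type, the diagnosis-specific age (61 for HCC, 43
#' for PSC and ALF, 57 otherwise including CRLM), the ALF priority flag, and
#' the tracking flag (listed inside the enrollment window).
#'
#' @param group `"StatusQuo"` or `"CRLM"`.
#' @param clock Listing time in days.
#' @param config A [replication_config()] (defines the tracking window).
#' @param u_blood,u_diag Uniform draws.
#' @param scenario A [scenario_config()]; CRLM patients are only generated
#'   for the waiting list under strategy 2.
#' @return One-row tibble.
#' @export
make_patient <- function(group = c("StatusQuo", "CRLM"), clock, scenario,
                         config, u_blood, u_diag = 0) {
  group <- match.arg(group)
  if (group == "CRLM" && scenario$strategy == 1) {
    stop("CRLM patients are not listed under strategy 1 ",
         "(they follow the palliative pathway)", call. = FALSE)
  }
  diagnosis <- if (group == "CRLM") "CRLM"
               else assign_diagnosis(u_diag, scenario$patient_mix)
  tibble::tibble(
    group = group,
    diagnosis = diagnosis,
    blood_type = assign_blood_type(u_blood, scenario$patient_blood_mix),
    age_at_listing = unname(diagnosis_ages()[diagnosis]),
    listing_time = clock,
    priority = diagnosis == "ALF",
    tracked = clock >= config$burn_in_days &&
      clock < config$burn_in_days + config$enrollment_days
  )
}
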