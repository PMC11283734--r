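FAMILY_CODES <- c(exponential = 0L, weibull = 1L, loglogistic = 2L,
                  lognormal = 3L, gompertz = 4L)
BT_LEVELS <- c("A", "B", "AB", "O")
DIAG_LEVELS <- c("HCC", "PBC", "PSC", "ALF", "AC", "Others", "CRLM")
OUTCOME_LEVELS <- c("palliative", "transplant", "death", "dropout",
                    "withdrawal", "waiting")

dist_matrix_row <- function(registry, stratum) {
  d <- registry_dist(registry, stratum)
  c(FAMILY_CODES[[d$family]], unname(d$params[1]),
    if (length(d$params) > 1) unname(d$params[2]) else NA_real_,
    if (is.null(d$cap_years)) NA_real_ else d$cap_years)
}

engine_scenario <- function(scenario, config) {
  reg <- scenario$registry
  crlm_stratum <- scenario$criteria
  diag7 <- DIAG_LEVELS
  post <- t(vapply(c(sq_diagnoses(), crlm_stratum),
                   function(s) dist_matrix_row(reg, s), numeric(4)))
  wld <- t(vapply(paste0("wl_death:", diag7),
                  function(s) dist_matrix_row(reg, s), numeric(4)))
  wlr <- t(vapply(paste0("wl_dropout:", diag7),
                  function(s) dist_matrix_row(reg, s), numeric(4)))
  pall <- matrix(dist_matrix_row(reg, "palliative"), nrow = 1)
  lt <- scenario$life_table
  list(
    burn_in_days = config$burn_in_days,
    enrollment_days = config$enrollment_days,
    strategy = scenario$strategy,
    mean_sq = scenario$patient_interarrival_days,
    mean_crlm = if (scenario$crlm_per_year > 0) 365 / scenario$crlm_per_year else 0,
    mean_liver = scenario$liver_interarrival_days,
    patient_blood_mix = unname(scenario$patient_blood_mix[BT_LEVELS]),
    liver_mix = unname(scenario$liver_mix[BT_LEVELS]),
    patient_mix = unname(scenario$patient_mix[sq_diagnoses()]),
    ages = unname(diagnosis_ages()[DIAG_LEVELS]),
    p_retransplant_listed = scenario$p_retransplant_listed,
    p_retransplant_qualify = scenario$p_retransplant_qualify,
    p_withdraw = scenario$p_withdraw,
    withdraw_delay_mean = 30,
    identical_abo = scenario$abo_rule == "identical",
    post_dists = post,
    wl_death_dists = wld,
    wl_dropout_dists = wlr,
    palliative_dist = pall,
    lt_qx = lt$qx,
    lt_min_age = lt$age[1]
  )
}

STAT_NAMES <- c(
  "enlisted_sq", "enlisted_crlm", "first_tx_sq", "first_tx_crlm",
  "retransplants", "withdrawals_sq", "withdrawals_crlm",
  "deaths_dropouts_sq", "deaths_dropouts_crlm", "retrans_nonqualified",
  "livers_window", "exports_window",
  "median_wait_A", "median_wait_B", "median_wait_AB", "median_wait_O",
  "median_wait_overall", "min_wait", "max_wait", "mean_wait",
  "mean_le_sq", "mean_le_crlm", "total_ly_sq", "total_ly_crlm",
  "avg_waiting", "n_spells_window", "sum_spell_days",
  "still_waiting_tracked")

#' Run a waiting-list experiment
#'
#' Runs `config$replications` independent replications of the scenario and
#' aggregates them. Each replication simulates the burn-in plus enrollment
#' window and keeps generating arrivals until every tracked patient (listed
#' inside the window) has left the list; tracked patients are then followed
#' to death for life-year accounting. Results are deterministic given the
#' master seed.
#'
#' @param scenario A [scenario_config()].
#' @param config A [replication_config()].
#' @param collect_logs If `TRUE`, keep the per-replication exit logs
#'   (memory-heavy; meant for small runs and diagnostics).
#' @return An `lt_experiment`: `$replications` (tibble, one row per
#'   replication, one column per outcome), `$scenario`, `$config`, and
#'   `$logs` when requested. See [glance.lt_experiment()] for the aggregated
#'   summary.
#' @export
run_experiment <- function(scenario, config = replication_config(),
                          collect_logs = FALSE) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(config, "replication_config"))
  es <- engine_scenario(scenario, config)
  res <- cpp_run_experiment(es, as.list(config$stream_seeds),
                            config$replications, collect_logs)
  stats <- tibble::as_tibble(stats::setNames(as.data.frame(res$stats),
                                             STAT_NAMES))
  if (any(stats$still_waiting_tracked > 0)) {
    stop("simulation stall: tracked patients never left the waiting list ",
         "(all exit processes disabled?)", call. = FALSE)
  }
  structure(list(replications = stats,
                 scenario = scenario,
                 config = config,
                 logs = if (collect_logs) lapply(res$logs, decode_log)),
            class = "lt_experiment")
}

#' Run a single replication and return its ledger
#'
#' Convenience wrapper around the engine for one replication with the full
#' exit log: one row per waiting-list spell (or palliative episode), with
#' listing and exit day, outcome, and realized life-years at the patient's
#' final resolution. The log can be written to CSV with
#' [readr::write_csv()].
#'
#' @inheritParams run_experiment
#' @param replication Which replication index to run (0-based internally;
#'   give the same value to reproduce a row of [run_experiment()]).
#' @return List with `ledger` (tibble) and `stats` (named numeric vector).
#' @export
run_replication <- function(scenario, config = replication_config(),
                            replication = 1) {
  stopifnot(replication >= 1, replication <= config$replications)
  es <- engine_scenario(scenario, config)
  res <- cpp_run_experiment(es, as.list(config$stream_seeds),
                            as.integer(replication), TRUE)
  i <- as.integer(replication)
  list(ledger = decode_log(res$logs[[i]]),
       stats = stats::setNames(res$stats[i, ], STAT_NAMES))
}

decode_log <- function(df) {
  tibble::tibble(
    id = df$id,
    group = c("StatusQuo", "CRLM")[df$group + 1L],
    diagnosis = DIAG_LEVELS[df$diagnosis + 1L],
    blood_type = BT_LEVELS[df$blood_type + 1L],
    priority = df$priority == 1L,
    matchable = df$matchable == 1L,
    spell = df$spell,
    listed = df$listed,
    exited = df$exited,
    wait_days = df$exited - df$listed,
    outcome = OUTCOME_LEVELS[df$outcome + 1L],
    tracked = df$tracked == 1L,
    life_years = df$life_years
  )
}

#' Scripted mini-replication (deterministic forced paths)
#'
#' Testing and illustration hook: supply the exact arrivals instead of
#' Poisson streams. `patients` needs columns `time`, `group` ("StatusQuo" or
#' "CRLM"), `diag`, `bt`, `t_death`, `t_dropout` (competing exit offsets in
#' days, `Inf` for none), `withdrawer` (logical), `withdraw_delay`, and
#' optional fate draws `u_retrans`, `u_qualify`, `u_surv`, `u_bg` in `[0,1)`
#' (NA = draw from the posttransplant stream). `livers` needs `time`, `bt`.
#'
#' @param scenario,config As in [run_experiment()].
#' @param patients,livers Data frames as described.
#' @return As [run_replication()].
#' @export
run_scripted <- function(scenario, config, patients, livers) {
  defaults <- list(withdrawer = FALSE, withdraw_delay = Inf,
                   u_retrans = NA_real_, u_qualify = NA_real_,
                   u_surv = NA_real_, u_bg = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(patients[[nm]])) patients[[nm]] <- defaults[[nm]]
  }
  pa <- data.frame(
    time = patients$time,
    group = ifelse(patients$group == "CRLM", 1L, 0L),
    diag = match(patients$diag, DIAG_LEVELS) - 1L,
    bt = match(patients$bt, BT_LEVELS) - 1L,
    t_death = patients$t_death,
    t_dropout = patients$t_dropout,
    withdrawer = as.integer(patients$withdrawer),
    withdraw_delay = patients$withdraw_delay,
    u_retrans = patients$u_retrans,
    u_qualify = patients$u_qualify,
    u_surv = patients$u_surv,
    u_bg = patients$u_bg
  )
  li <- data.frame(time = livers$time, bt = match(livers$bt, BT_LEVELS) - 1L)
  es <- engine_scenario(scenario, config)
  res <- cpp_run_scripted(es, as.list(config$stream_seeds), pa, li)
  list(ledger = decode_log(res$logs[[1]]),
       stats = stats::setNames(res$stats[1, ], STAT_NAMES))
}
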