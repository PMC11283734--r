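#' Sweep the number of CRLM patients added per year
#'
#' Runs strategy 2 at each CRLM load in `n_range` plus the strategy-1
#' baseline, all under common random numbers (shared master seed), and
#' assembles the net-benefit curve, the waiting-time surface and the
#' secondary-outcome table.
#'
#' @param n_range Integer CRLM loads (patients/year), e.g. `0:10`.
#' @param criteria `"SECA1"` or `"SECA2"` eligibility/survival assumption.
#' @param config A [replication_config()].
#' @param scenario Scenario template (strategy and `crlm_per_year` are
#'   overridden per run).
#' @param baseline_crlm_per_year CRLM arrival rate of the strategy-1
#'   palliative comparator cohort (default 2, the expected Norwegian SECA-II
#'   volume; the per-patient palliative life expectancy is insensitive to
#'   it).
#' @return An `lt_sweep`: `$curve` ([net_benefit()] tibble), `$waits`
#'   (median waits by blood type per load), `$outcomes` (annualized counts
#'   per load), `$experiments`, `$baseline`.
#' @export
sweep_crlm <- function(n_range = 0:10,
                       criteria = c("SECA2", "SECA1"),
                       config = replication_config(),
                       scenario = NULL,
                       baseline_crlm_per_year = 2) {
  criteria <- match.arg(criteria)
  if (is.null(scenario)) scenario <- scenario_config(strategy = 2,
                                                     criteria = criteria)
  base_sc <- scenario
  base_sc$strategy <- 1L
  base_sc$crlm_per_year <- baseline_crlm_per_year
  baseline <- run_experiment(base_sc, config)
  experiments <- lapply(n_range, function(n) {
    sc <- scenario
    sc$strategy <- 2L
    sc$criteria <- criteria
    sc$crlm_per_year <- n
    run_experiment(sc, config)
  })
  names(experiments) <- as.character(n_range)
  curve <- net_benefit(experiments, baseline)
  waits <- purrr::map_dfr(experiments, function(e) {
    g <- glance(e)
    tibble::tibble(crlm_per_year = e$scenario$crlm_per_year,
                   A = g$median_wait_A, B = g$median_wait_B,
                   AB = g$median_wait_AB, O = g$median_wait_O,
                   overall = g$median_wait_overall)
  })
  outcomes <- purrr::map_dfr(experiments, function(e) {
    g <- glance(e)
    tibble::tibble(crlm_per_year = e$scenario$crlm_per_year,
                   first_transplants = g$first_transplants,
                   retransplants = g$retransplants,
                   withdrawals = g$withdrawals,
                   deaths_dropouts_sq = g$deaths_dropouts_sq,
                   deaths_dropouts_crlm = g$deaths_dropouts_crlm,
                   exported_livers = g$exports_per_year,
                   avg_number_waiting = g$avg_waiting)
  })
  structure(list(curve = curve, waits = waits, outcomes = outcomes,
                 experiments = experiments, baseline = baseline,
                 criteria = criteria),
            class = "lt_sweep")
}

#' @export
print.lt_sweep <- function(x, ...) {
  cat("<lt_sweep> ", x$criteria, ", CRLM loads ",
      paste(range(x$curve$crlm_per_year), collapse = "-"), "\n", sep = "")
  print(x$curve)
  invisible(x)
}

#' Internal validation against the published waiting-list statistics
#'
#' Runs the strategy-1 base case and compares the simulated outcomes with
#' the registry statistics reported for Norway (annual listings, transplant
#' activity, liver supply, withdrawals, queue length, and median waiting
#' times by blood type). A row passes when the simulated value falls within
#' the reported empirical range, or within `rel_tol` of the point value when
#' no range was reported.
#'
#' @param config A [replication_config()].
#' @param scenario Strategy-1 scenario (defaults to the base case).
#' @param rel_tol Relative tolerance for point comparisons.
#' @return Tibble with columns `outcome`, `model`, `reported`, `lo`, `hi`,
#'   `pass`.
#' @export
validate_model <- function(config = replication_config(),
                           scenario = NULL, rel_tol = 0.15) {
  if (is.null(scenario)) scenario <- scenario_config(strategy = 1)
  stopifnot(scenario$strategy == 1)
  g <- glance(run_experiment(scenario, config))
  ref <- tibble::tribble(
    ~outcome,                  ~model,                  ~reported, ~lo,  ~hi,
    "enlisted_per_year",       g$enlisted_sq,           103,       81,   119,
    "first_transplants",       g$first_transplants,     81,        72,   88,
    "retransplants",           g$retransplants,         12,        8,    19,
    "withdrawals",             g$withdrawals,           7,         5,    13,
    "deaths_dropouts",         g$deaths_dropouts_sq,    5,         3,    7,
    "livers_per_year",         g$livers_per_year,       114,       NA,   NA,
    "exported_livers",         g$exports_per_year,      22,        20,   28,
    "avg_number_waiting",      g$avg_waiting,           22,        15,   34,
    "median_wait_A",           g$median_wait_A,         32,        26,   42,
    "median_wait_B",           g$median_wait_B,         48,        40,   63,
    "median_wait_AB",          g$median_wait_AB,        21,        14,   26,
    "median_wait_O",           g$median_wait_O,         92,        66,   111,
    "median_wait_overall",     g$median_wait_overall,   40,        26,   62
  )
  dplyr::mutate(ref, pass = ifelse(
    is.na(.data$lo),
    abs(.data$model - .data$reported) <= rel_tol * .data$reported,
    .data$model >= .data$lo & .data$model <= .data$hi))
}

#' Plot the net-benefit curve
#'
#' Life-years gained by CRLM patients (positive bars), lost by Status Quo
#' patients (negative bars) and the net (line) against the number of CRLM
#' patients listed per year.
#'
#' @param object An `lt_netbenefit` from [net_benefit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lt_netbenefit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object), lost = -.data$lost),
    c("gained", "lost"), names_to = "component", values_to = "life_years")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$crlm_per_year)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$life_years,
                                   fill = .data$component),
                      position = "identity", alpha = 0.7) +
    ggplot2::geom_line(data = tibble::as_tibble(object),
                       ggplot2::aes(y = .data$net)) +
    ggplot2::geom_point(data = tibble::as_tibble(object),
                        ggplot2::aes(y = .data$net)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = object$crlm_per_year) +
    ggplot2::labs(x = "CRLM patients listed per year",
                  y = "Life-years over the 10-y window",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot median waiting time by blood type across CRLM loads
#'
#' @param sweep An `lt_sweep` from [sweep_crlm()].
#' @return A ggplot.
#' @export
plot_waiting_times <- function(sweep) {
  df <- tidyr::pivot_longer(sweep$waits, c("A", "B", "AB", "O", "overall"),
                            names_to = "blood_type", values_to = "median_wait")
  ggplot2::ggplot(df, ggplot2::aes(.data$crlm_per_year, .data$median_wait,
                                   color = .data$blood_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "CRLM patients listed per year",
                  y = "Median waiting time (days)", color = "Blood type") +
    ggplot2::theme_minimal()
}

#' Run manifests: reproducible provenance records
#'
#' `run_manifest()` captures every resolved parameter of an experiment (tool
#' version, seeds, window, scenario parameters, registry and life table);
#' `write_manifest()` stores it as JSON and `rerun_manifest()` reruns the
#' experiment from such a file, bit-identically.
#'
#' @param experiment An `lt_experiment`.
#' @return `run_manifest()`: a list; `rerun_manifest()`: an `lt_experiment`.
#' @export
run_manifest <- function(experiment) {
  sc <- experiment$scenario
  cfg <- experiment$config
  list(
    tool = "liversim",
    version = as.character(utils::packageVersion("liversim")),
    config = list(replications = cfg$replications,
                  burn_in_days = cfg$burn_in_days,
                  enrollment_days = cfg$enrollment_days,
                  seed = cfg$seed,
                  stream_seeds = as.list(cfg$stream_seeds)),
    scenario = list(strategy = sc$strategy,
                    crlm_per_year = sc$crlm_per_year,
                    criteria = sc$criteria,
                    patient_interarrival_days = sc$patient_interarrival_days,
                    liver_interarrival_days = sc$liver_interarrival_days,
                    p_retransplant_listed = sc$p_retransplant_listed,
                    p_retransplant_qualify = sc$p_retransplant_qualify,
                    p_withdraw = sc$p_withdraw,
                    abo_rule = sc$abo_rule,
                    liver_mix = as.list(sc$liver_mix),
                    patient_blood_mix = as.list(sc$patient_blood_mix),
                    patient_mix = as.list(sc$patient_mix)),
    registry = as.data.frame(sc$registry),
    life_table = as.data.frame(sc$life_table[c("age", "qx")])
  )
}

#' @rdname run_manifest
#' @param manifest A manifest list.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
rerun_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- scenario_config(
    strategy = m$scenario$strategy,
    crlm_per_year = m$scenario$crlm_per_year,
    criteria = m$scenario$criteria,
    patient_interarrival_days = m$scenario$patient_interarrival_days,
    liver_interarrival_days = m$scenario$liver_interarrival_days,
    registry = tibble::as_tibble(m$registry),
    liver_mix = unlist(m$scenario$liver_mix),
    patient_blood_mix = unlist(m$scenario$patient_blood_mix),
    patient_mix = unlist(m$scenario$patient_mix),
    p_retransplant_listed = m$scenario$p_retransplant_listed,
    p_retransplant_qualify = m$scenario$p_retransplant_qualify,
    p_withdraw = m$scenario$p_withdraw,
    abo_rule = m$scenario$abo_rule,
    life_table = life_table(m$life_table$age, m$life_table$qx)
  )
  cfg <- replication_config(
    replications = m$config$replications,
    burn_in_days = m$config$burn_in_days,
    enrollment_days = m$config$enrollment_days,
    seed = m$config$seed,
    stream_seeds = unlist(m$config$stream_seeds)
  )
  run_experiment(sc, cfg)
}
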