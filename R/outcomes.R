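#' Posttransplant death time with the 10-year background switch
#'
#' Death times are drawn from the disease-specific posttransplant
#' distribution via its quantile function; a patient still alive at the
#' distribution's `cap_years` horizon (10 years in the base case) switches to
#' life-table background mortality at their attained age — no excess
#' transplant-associated mortality is assumed beyond the horizon.
#'
#' @param dist Posttransplant [surv_dist()] (scale in days) with `cap_years`
#'   set; without a cap the raw draw is returned.
#' @param lt A [life_table()].
#' @param age_at_transplant Years.
#' @param u Uniform draw for the survival time.
#' @param u_bg Uniform draw for the background remaining lifetime (used only
#'   when the switch fires).
#' @return Years from transplant to death.
#' @export
posttransplant_death_time <- function(dist, lt, age_at_transplant, u,
                                      u_bg = 0.5) {
  t_days <- surv_quantile(dist, u)
  cap <- dist$cap_years
  if (is.null(cap) || t_days <= cap * DAYS_PER_YEAR) {
    return(t_days / DAYS_PER_YEAR)
  }
  cap + lt_sample_remaining(lt, age_at_transplant + cap, u_bg)
}

#' Palliative-pathway life-years
#'
#' Life-years for a CRLM patient under standard-of-care palliative
#' chemotherapy: a draw from the palliative stratum, subject to the same
#' >10-year background switch, with no transplant pathway.
#'
#' @param registry Survival registry holding a `palliative` stratum.
#' @inheritParams posttransplant_death_time
#' @param age Age at treatment start (CRLM median, 57).
#' @export
palliative_life_years <- function(registry, lt, u, u_bg = 0.5, age = 57) {
  posttransplant_death_time(registry_dist(registry, "palliative"),
                            lt, age, u, u_bg)
}

#' Summaries of a waiting-list experiment
#'
#' `tidy()` returns the replication-averaged outcome table (one row per
#' outcome with the mean and the min/max across replications; counts are
#' annualized over the enrollment window). `glance()` returns the same
#' quantities as a one-row tibble for programming.
#'
#' @param x An `lt_experiment` from [run_experiment()].
#' @param ... Unused.
#' @export
tidy.lt_experiment <- function(x, ...) {
  g <- experiment_stats(x)
  tibble::tibble(outcome = names(g$mean), estimate = unname(g$mean),
                 min = unname(g$min), max = unname(g$max))
}

#' @rdname tidy.lt_experiment
#' @export
glance.lt_experiment <- function(x, ...) {
  g <- experiment_stats(x)
  tibble::as_tibble(as.list(g$mean))
}

experiment_stats <- function(x) {
  r <- x$replications
  years <- x$config$enrollment_days / 365
  annual <- c("enlisted_sq", "enlisted_crlm", "first_tx_sq", "first_tx_crlm",
              "retransplants", "withdrawals_sq", "withdrawals_crlm",
              "deaths_dropouts_sq", "deaths_dropouts_crlm",
              "retrans_nonqualified", "livers_window", "exports_window")
  out_mean <- out_min <- out_max <- c()
  add <- function(name, v) {
    out_mean[name] <<- mean(v, na.rm = TRUE)
    out_min[name] <<- suppressWarnings(min(v, na.rm = TRUE))
    out_max[name] <<- suppressWarnings(max(v, na.rm = TRUE))
  }
  for (nm in annual) {
    target <- sub("_window$", "_per_year", nm)
    if (!grepl("_window$", nm)) target <- nm
    add(target, r[[nm]] / years)
  }
  add("first_transplants", (r$first_tx_sq + r$first_tx_crlm) / years)
  add("withdrawals", (r$withdrawals_sq + r$withdrawals_crlm) / years)
  for (nm in c("median_wait_A", "median_wait_B", "median_wait_AB",
               "median_wait_O", "median_wait_overall", "mean_wait",
               "mean_le_sq", "mean_le_crlm", "total_ly_sq", "total_ly_crlm",
               "avg_waiting")) {
    add(nm, r[[nm]])
  }
  add("enrolled_sq", r$enlisted_sq)      # raw counts over the window
  add("enrolled_crlm", r$enlisted_crlm)
  pooled_min <- suppressWarnings(min(r$min_wait, na.rm = TRUE))
  pooled_max <- suppressWarnings(max(r$max_wait, na.rm = TRUE))
  out_mean["min_wait"] <- out_min["min_wait"] <- out_max["min_wait"] <- pooled_min
  out_mean["max_wait"] <- out_min["max_wait"] <- out_max["max_wait"] <- pooled_max
  list(mean = out_mean, min = out_min, max = out_max)
}

#' @export
print.lt_experiment <- function(x, ...) {
  cat("<lt_experiment> strategy ", x$scenario$strategy,
      ", CRLM/year ", x$scenario$crlm_per_year,
      " (", x$scenario$criteria, "), ",
      x$config$replications, " replications\n", sep = "")
  print(tidy(x), n = 30)
  invisible(x)
}

#' Life-years gained, lost and net across CRLM loads
#'
#' Combines strategy-2 experiments at increasing CRLM arrival rates with the
#' strategy-1 baseline into the net-benefit curve: life-years gained by CRLM
#' patients (their mean life expectancy under transplantation minus under
#' palliative chemotherapy, times the number enrolled over the window),
#' life-years lost by Status Quo patients (baseline minus scenario life
#' expectancy, times their enrollment), and the net difference. Experiments
#' must share the master seed and window (common random numbers), or the
#' comparison is refused.
#'
#' @param experiments List of strategy-2 `lt_experiment`s (any order; each
#'   contributes one point at its `crlm_per_year`). A strategy-2 run at 0
#'   CRLM/year contributes the trivial zero point.
#' @param baseline Strategy-1 `lt_experiment` with `crlm_per_year > 0` (its
#'   parallel palliative cohort provides the counterfactual CRLM life
#'   expectancy).
#' @return An `lt_netbenefit` tibble: `crlm_per_year`, `le_sq`, `le_crlm`,
#'   `gained`, `lost`, `net` (life-years over the enrollment window;
#'   `net = gained - lost` by construction).
#' @export
net_benefit <- function(experiments, baseline) {
  stopifnot(inherits(baseline, "lt_experiment"),
            baseline$scenario$strategy == 1)
  if (baseline$scenario$crlm_per_year <= 0) {
    stop("baseline must include a palliative CRLM cohort (crlm_per_year > 0)",
         call. = FALSE)
  }
  base_g <- glance(baseline)
  for (e in experiments) {
    stopifnot(inherits(e, "lt_experiment"), e$scenario$strategy == 2)
    if (e$config$seed != baseline$config$seed ||
        e$config$enrollment_days != baseline$config$enrollment_days ||
        e$config$burn_in_days != baseline$config$burn_in_days) {
      stop("experiments and baseline must share seed and window ",
           "(common random numbers)", call. = FALSE)
    }
  }
  rows <- purrr::map_dfr(experiments, function(e) {
    g <- glance(e)
    le_crlm <- if (e$scenario$crlm_per_year > 0) g$mean_le_crlm else NA_real_
    gained <- if (e$scenario$crlm_per_year > 0) {
      (g$mean_le_crlm - base_g$mean_le_crlm) * g$enrolled_crlm
    } else 0
    lost <- (base_g$mean_le_sq - g$mean_le_sq) * g$enrolled_sq
    tibble::tibble(crlm_per_year = e$scenario$crlm_per_year,
                   le_sq = g$mean_le_sq, le_crlm = le_crlm,
                   gained = gained, lost = lost, net = gained - lost)
  })
  rows <- dplyr::arrange(rows, .data$crlm_per_year)
  class(rows) <- c("lt_netbenefit", class(rows))
  attr(rows, "le_palliative") <- base_g$mean_le_crlm
  attr(rows, "le_sq_baseline") <- base_g$mean_le_sq
  rows
}

#' Peak and break-even points of a net-benefit curve
#'
#' The peak is the CRLM load with the largest net life-years; the break-even
#' point is the smallest load at which net life-years cross to zero or below
#' (`NA` when the curve stays positive over its range).
#'
#' @param curve An `lt_netbenefit` from [net_benefit()].
#' @return List with `peak_n` and `break_even_n` (`NA` if no crossing).
#' @export
find_break_even <- function(curve) {
  pos <- curve[curve$crlm_per_year >= 1, ]
  if (nrow(pos) == 0) stop("curve must cover crlm_per_year >= 1", call. = FALSE)
  peak <- pos$crlm_per_year[which.max(pos$net)]
  cross <- pos$crlm_per_year[pos$net <= 0]
  list(peak_n = peak,
       break_even_n = if (length(cross)) min(cross) else NA_integer_)
}

#' Structural and scenario uncertainty analyses
#'
#' Applies one of the published uncertainty variants to a scenario and reruns
#' the experiment:
#'
#' * `"seca-weibull"`: posttransplant survival of both SECA strata swapped
#'   from log-logistic to a Weibull matched at the same median and
#'   75%-survival quantiles (a thinner tail, hence poorer long-term
#'   survival).
#' * `"palliative-weibull"`: the same swap for the palliative stratum.
#' * `"best-case-livers"` / `"worst-case-livers"`: 121 / 103 livers per year
#'   (interarrival mean rescaled to 365/N days).
#' * `"better-sq-survival"`: every Status Quo diagnosis assigned the PSC
#'   stratum, the diagnosis with the best posttransplant survival.
#'
#' @param scenario A [scenario_config()].
#' @param variant One of the names above.
#' @param config A [replication_config()]; when `NULL` the modified scenario
#'   is returned instead of being run.
#' @return An `lt_experiment`, or the modified scenario when `config` is
#'   `NULL`.
#' @export
run_uncertainty <- function(scenario, variant, config = NULL) {
  variant <- match.arg(variant, c("seca-weibull", "palliative-weibull",
                                  "best-case-livers", "worst-case-livers",
                                  "better-sq-survival"))
  sc <- scenario
  if (variant == "seca-weibull") {
    for (s in c("SECA1", "SECA2")) {
      sc$registry <- swap_to_weibull(sc$registry, s)
    }
  } else if (variant == "palliative-weibull") {
    sc$registry <- swap_to_weibull(sc$registry, "palliative")
  } else if (variant == "best-case-livers") {
    sc$liver_interarrival_days <- 365 / 121
  } else if (variant == "worst-case-livers") {
    sc$liver_interarrival_days <- 365 / 103
  } else if (variant == "better-sq-survival") {
    psc <- sc$registry[sc$registry$stratum == "PSC", ]
    for (s in setdiff(sq_diagnoses(), "PSC")) {
      i <- which(sc$registry$stratum == s)
      sc$registry[i, c("family", "par1", "par2", "cap_years")] <-
        psc[, c("family", "par1", "par2", "cap_years")]
    }
  }
  if (is.null(config)) return(sc)
  run_experiment(sc, config)
}

# Weibull with the same 50% and 75% survival times as `stratum`'s current
# distribution (two quantiles pin both parameters)
swap_to_weibull <- function(registry, stratum) {
  d <- registry_dist(registry, stratum)
  q50 <- surv_quantile(d, 0.5)
  q25 <- surv_quantile(d, 0.25)
  k <- log(log(4 / 3) / log(2)) / log(q25 / q50)
  lam <- q50 / (log(2))^(1 / k)
  wd <- surv_dist("weibull", shape = k, scale = lam, cap_years = d$cap_years)
  i <- which(registry$stratum == stratum)
  registry[i, ] <- registry_row(stratum, wd)
  registry
}
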