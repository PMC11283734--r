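#' Competing pretransplant exit times for a new listing spell
#'
#' Every listing spell carries three competing pretransplant exits: death and
#' dropout times drawn from the diagnosis-specific waiting-list strata of the
#' registry, and withdrawal. Withdrawal is a per-listing Bernoulli: a fixed
#' fraction of listings (6% in the base case) is destined to withdraw
#' independently of waiting time; destined withdrawers are never matched to a
#' liver and leave after a short exponential delay. The earliest of the
#' competing times determines the candidate exit event; a liver match before
#' that time preempts it.
#'
#' @param registry Survival registry with `wl_death:`/`wl_dropout:` strata
#'   for the diagnosis.
#' @param diagnosis Diagnosis name (HCC, PBC, PSC, ALF, AC, Others, CRLM).
#' @param u Named uniform draws: `withdraw` (Bernoulli), `delay`, `death`,
#'   `dropout`.
#' @param p_withdraw Destined-withdrawal fraction per listing.
#' @param withdraw_delay_mean Mean of the withdrawal delay in days.
#' @return List with `death`, `dropout`, `withdrawal` (days from listing,
#'   `Inf` when not destined), `exit_days`, `exit_kind`, and `matchable`.
#' @export
schedule_pretransplant_exits <- function(registry, diagnosis, u,
                                         p_withdraw = 0.06,
                                         withdraw_delay_mean = 30) {
  stopifnot(all(c("withdraw", "delay", "death", "dropout") %in% names(u)))
  d_death <- registry_dist(registry, paste0("wl_death:", diagnosis))
  d_drop <- registry_dist(registry, paste0("wl_dropout:", diagnosis))
  withdrawer <- u[["withdraw"]] < p_withdraw
  t_w <- if (withdrawer) -withdraw_delay_mean * log1p(-u[["delay"]]) else Inf
  t_d <- surv_quantile(d_death, u[["death"]])
  t_r <- surv_quantile(d_drop, u[["dropout"]])
  times <- c(death = t_d, dropout = t_r, withdrawal = t_w)
  k <- names(times)[which.min(times)]
  list(death = t_d, dropout = t_r, withdrawal = t_w,
       exit_days = unname(times[k]), exit_kind = k,
       matchable = !withdrawer)
}

#' Match an arriving liver against the waiting list
#'
#' The allocation rule of the matching module: among patients eligible for
#' the donor blood group (identical-type matching by default; optionally
#' AB0-compatible), choose the longest-waiting *priority* patient (acute
#' liver failure or a retransplant listing) if any priority patient is
#' eligible, otherwise the longest-waiting eligible patient. Ties in waiting
#' time break by listing order. If no eligible patient exists the liver is
#' exported.
#'
#' @param waitlist Data frame of waiting patients with columns `blood_type`,
#'   `priority` (logical), `listing_time` (days); optional `matchable`
#'   (destined withdrawers are skipped) and `exit_time` (patients whose
#'   competing exit precedes `clock` are no longer on the list).
#' @param liver_bt Donor blood type (`"A"`, `"B"`, `"AB"`, `"O"`).
#' @param clock Arrival time of the liver.
#' @param rule `"identical"` or `"compatible"`.
#' @return Row index of the matched patient, or `NA` (exported).
#' @export
match_liver <- function(waitlist, liver_bt, clock = Inf,
                        rule = c("identical", "compatible")) {
  rule <- match.arg(rule)
  recipients <- if (rule == "identical") liver_bt else switch(liver_bt,
    O = c("O", "A", "B", "AB"), A = c("A", "AB"), B = c("B", "AB"), AB = "AB")
  ok <- waitlist$blood_type %in% recipients
  if ("matchable" %in% names(waitlist)) ok <- ok & waitlist$matchable
  if ("exit_time" %in% names(waitlist)) ok <- ok & waitlist$exit_time > clock
  if (!any(ok)) return(NA_integer_)
  idx <- which(ok)
  pri <- idx[waitlist$priority[idx]]
  pool <- if (length(pri)) pri else idx
  pool[which.min(waitlist$listing_time[pool])]
}
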