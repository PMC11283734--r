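# shared fixtures: cheap configurations so unit tests stay fast

fast_config <- function(replications = 50, seed = 42, ...) {
  replication_config(replications = replications, seed = seed, ...)
}

# registry/life table are deterministic; build once per test session
shared_lt <- synthetic_norway_life_table()
shared_registry <- default_registry(shared_lt)

base_scenario <- function(...) {
  args <- list(...)
  if (is.null(args$registry)) args$registry <- shared_registry
  if (is.null(args$life_table)) args$life_table <- shared_lt
  do.call(scenario_config, args)
}

# scripted-mode scenario: no burn-in, 1000-day window
scripted_config <- function() {
  replication_config(replications = 1, seed = 1, burn_in_days = 0,
                     enrollment_days = 1000)
}

scripted_patient <- function(time, group = "StatusQuo", diag = "PBC",
                             bt = "A", t_death = Inf, t_dropout = Inf,
                             withdrawer = FALSE, withdraw_delay = Inf,
                             u_retrans = 0.99, u_qualify = NA_real_,
                             u_surv = 0.5, u_bg = 0.5) {
  data.frame(time = time, group = group, diag = diag, bt = bt,
             t_death = t_death, t_dropout = t_dropout,
             withdrawer = withdrawer, withdraw_delay = withdraw_delay,
             u_retrans = u_retrans, u_qualify = u_qualify,
             u_surv = u_surv, u_bg = u_bg)
}

scripted_livers <- function(time, bt = "A") data.frame(time = time, bt = bt)
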