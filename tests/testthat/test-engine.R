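# discrete-event core: forced paths, determinism, stream structure

test_that("a lone patient waits exactly until the first compatible liver", {
  sc <- base_scenario(strategy = 1, p_withdraw = 0)
  r <- run_scripted(sc, scripted_config(),
                    scripted_patient(time = 10, bt = "A"),
                    scripted_livers(time = 250, bt = "A"))
  tx <- r$ledger[r$ledger$outcome == "transplant", ]
  expect_equal(nrow(tx), 1)
  expect_equal(tx$wait_days, 240)
  expect_equal(unname(r$stats["first_tx_sq"]), 1)
  expect_equal(unname(r$stats["median_wait_overall"]), 240)
})

test_that("a scheduled death never fires once the patient is transplanted", {
  sc <- base_scenario(strategy = 1, p_withdraw = 0)
  r <- run_scripted(sc, scripted_config(),
                    scripted_patient(time = 0, t_death = 50, bt = "A"),
                    scripted_livers(time = 10, bt = "A"))
  expect_equal(r$ledger$outcome, "transplant")
  expect_equal(unname(r$stats["deaths_dropouts_sq"]), 0)
})

test_that("competing exits remove patients before a late liver arrives", {
  sc <- base_scenario(strategy = 1, p_withdraw = 0)
  r <- run_scripted(sc, scripted_config(),
                    scripted_patient(time = 0, t_death = 30, t_dropout = 80,
                                     bt = "A"),
                    scripted_livers(time = 100, bt = "A"))
  expect_equal(r$ledger$outcome, "death")
  expect_equal(r$ledger$exited, 30)
  expect_equal(r$ledger$life_years, 0) # death at removal
  expect_equal(unname(r$stats["exports_window"]), 1) # the liver left unused
})

test_that("priority patients are served first within a blood group", {
  sc <- base_scenario(strategy = 1, p_withdraw = 0)
  pats <- rbind(
    scripted_patient(time = 0, diag = "PSC", bt = "A"),  # waits 100 d
    scripted_patient(time = 99, diag = "ALF", bt = "A")) # waits 1 d, priority
  r <- run_scripted(sc, scripted_config(), pats, scripted_livers(100, "A"))
  tx <- r$ledger[r$ledger$outcome == "transplant", ]
  expect_equal(tx$diagnosis, "ALF")
})

test_that("among equals the longest-waiting patient is matched", {
  sc <- base_scenario(strategy = 1, p_withdraw = 0)
  pats <- rbind(scripted_patient(time = 70, bt = "A"),
                scripted_patient(time = 90, bt = "A"))
  r <- run_scripted(sc, scripted_config(), pats, scripted_livers(100, "A"))
  tx <- r$ledger[r$ledger$outcome == "transplant", ]
  expect_equal(tx$listed, 70)
  expect_equal(tx$wait_days, 30)
})

test_that("the ABO rule gates donor-recipient combinations", {
  sc_id <- base_scenario(strategy = 1, p_withdraw = 0, abo_rule = "identical")
  sc_co <- base_scenario(strategy = 1, p_withdraw = 0, abo_rule = "compatible")
  p <- scripted_patient(time = 0, bt = "AB")
  # identical: an O liver cannot go to an AB patient
  r1 <- run_scripted(sc_id, scripted_config(), p, scripted_livers(10, "O"))
  expect_equal(unname(r1$stats["exports_window"]), 1)
  # compatible: it can
  r2 <- run_scripted(sc_co, scripted_config(), p, scripted_livers(10, "O"))
  expect_equal(unname(r2$stats["first_tx_sq"]), 1)
  # compatible never allows AB -> O
  r3 <- run_scripted(sc_co, scripted_config(),
                     scripted_patient(time = 0, bt = "O"),
                     scripted_livers(10, "AB"))
  expect_equal(unname(r3$stats["exports_window"]), 1)
})

test_that("forced retransplantation gives one patient two transplants", {
  sc <- base_scenario(strategy = 1, p_withdraw = 0)
  p <- scripted_patient(time = 0, bt = "A", u_retrans = 0, u_qualify = 0,
                        u_surv = 0.5)
  r <- run_scripted(sc, scripted_config(), p,
                    scripted_livers(c(10, 40), "A"))
  lg <- r$ledger
  expect_equal(sum(lg$outcome == "transplant"), 2)
  expect_equal(unname(r$stats["first_tx_sq"]), 1)
  expect_equal(unname(r$stats["retransplants"]), 1)
  # the relisted spell carries priority
  expect_true(lg$priority[lg$spell == 1])
})

test_that("retransplant non-qualifiers die at removal with wait-free life-years", {
  sc <- base_scenario(strategy = 1, p_withdraw = 0)
  p <- scripted_patient(time = 0, bt = "A", u_retrans = 0, u_qualify = 0.9)
  r <- run_scripted(sc, scripted_config(), p, scripted_livers(10, "A"))
  expect_equal(unname(r$stats["retrans_nonqualified"]), 1)
  expect_equal(unname(r$stats["mean_le_sq"]), 0)
})

test_that("posttransplant survival equals the R-side quantile pathway", {
  sc <- base_scenario(strategy = 1, p_withdraw = 0)
  for (u in c(0.2, 0.5, 0.9, 0.985)) {
    p <- scripted_patient(time = 0, diag = "HCC", bt = "A",
                          u_retrans = 0.99, u_surv = u, u_bg = 0.37)
    r <- run_scripted(sc, scripted_config(), p, scripted_livers(10, "A"))
    want <- posttransplant_death_time(registry_dist(shared_registry, "HCC"),
                                      shared_lt, 61, u, u_bg = 0.37)
    expect_equal(unname(r$stats["mean_le_sq"]), want, tolerance = 1e-10)
  }
})

test_that("destined withdrawers are never matched and exit on their delay", {
  sc <- base_scenario(strategy = 1)
  p <- scripted_patient(time = 0, bt = "A", withdrawer = TRUE,
                        withdraw_delay = 5)
  r <- run_scripted(sc, scripted_config(), p, scripted_livers(2, "A"))
  expect_equal(r$ledger$outcome, "withdrawal")
  expect_equal(r$ledger$exited, 5)
  expect_equal(unname(r$stats["withdrawals_sq"]), 1)
  expect_equal(unname(r$stats["exports_window"]), 1)
})

test_that("with no exit risks a patient simply waits for a transplant", {
  sc <- base_scenario(strategy = 1, p_withdraw = 0)
  p <- scripted_patient(time = 0, bt = "B") # t_death = t_dropout = Inf
  r <- run_scripted(sc, scripted_config(), p, scripted_livers(900, "B"))
  expect_equal(r$ledger$outcome, "transplant")
  expect_equal(r$ledger$wait_days, 900)
})

test_that("zero arrival rates produce an empty ledger", {
  sc <- base_scenario(strategy = 1, patient_interarrival_days = 1e9,
                      liver_interarrival_days = 1e9)
  e <- run_experiment(sc, fast_config(3))
  expect_true(all(e$replications$enlisted_sq == 0))
  expect_true(all(e$replications$livers_window == 0))
  expect_true(all(is.na(e$replications$median_wait_overall)))
})

test_that("experiments are bit-identical under the same master seed", {
  sc <- base_scenario(strategy = 2, crlm_per_year = 3)
  e1 <- run_experiment(sc, fast_config(20, seed = 77))
  e2 <- run_experiment(sc, fast_config(20, seed = 77))
  expect_identical(e1$replications, e2$replications)
  e3 <- run_experiment(sc, fast_config(20, seed = 78))
  expect_false(identical(e1$replications, e3$replications))
})

test_that("replications = 1 yields exactly that replication's ledger stats", {
  sc <- base_scenario(strategy = 1)
  e <- run_experiment(sc, replication_config(replications = 1, seed = 12))
  r <- run_replication(sc, replication_config(replications = 1, seed = 12))
  expect_equal(unlist(e$replications[1, ]), r$stats)
})

test_that("rng streams are independent: posttransplant seed never touches arrivals", {
  sc <- base_scenario(strategy = 1)
  cfgA <- replication_config(replications = 1, seed = 3)
  cfgB <- replication_config(replications = 1, seed = 3,
                             stream_seeds = c(posttransplant = 999))
  r1 <- run_replication(sc, cfgA)
  r2 <- run_replication(sc, cfgB)
  horizon <- 5550 # arrivals inside the deterministic window
  listings <- function(r) {
    x <- r$ledger[r$ledger$spell == 0 & r$ledger$listed < horizon, ]
    x[order(x$listed), c("listed", "blood_type", "diagnosis")]
  }
  expect_identical(listings(r1), listings(r2))
  expect_false(isTRUE(all.equal(r1$stats["mean_le_sq"], r2$stats["mean_le_sq"])))
})

test_that("event times in the ledger are non-decreasing within a replication", {
  r <- run_replication(base_scenario(strategy = 1),
                       replication_config(replications = 1, seed = 8))
  lg <- r$ledger
  expect_true(all(lg$exited >= lg$listed, na.rm = TRUE))
  # spell starts are ordered per patient
  by_pat <- split(lg$listed, lg$id)
  expect_true(all(vapply(by_pat, function(x) all(diff(x) >= 0), logical(1))))
})

test_that("a simulation with listings but no livers and no exits stalls loudly", {
  reg <- shared_registry
  # disable death/dropout entirely
  reg$par1[grepl("^wl_", reg$stratum)] <- 1e12
  sc <- base_scenario(strategy = 1, registry = reg, p_withdraw = 0,
                      liver_interarrival_days = 1e9)
  expect_error(run_experiment(sc, fast_config(2)), "stall")
})
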