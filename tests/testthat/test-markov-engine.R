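test_that("transition matrices are row-stochastic with absorbing deaths", {
  for (p in list(pp_config(), pp15_config(), toy_param_set())) {
    for (arm in c("icd", "no_icd")) {
      for (phase in c("initial", "replacement")) {
        for (cyc in c(1L, 200L)) {
          M <- build_transition_matrix(p, arm, phase, cycle = cyc)
          expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
          expect_true(all(M >= 0 & M <= 1))
          dead <- grep("^dead_", rownames(M))
          expect_true(all(M[cbind(dead, dead)] == 1))
        }
      }
    }
  }
})

test_that("degenerate inputs give the identity matrix up to the forced tunnel exit", {
  p <- inert_param_set()
  M <- build_transition_matrix(p, "no_icd", "initial")
  expect_equal(unname(M), diag(nrow(M)))
  # the complication state must exit after one cycle even with all hazards
  # zero, so its row returns to the well state instead of staying put
  Mi <- build_transition_matrix(p, "icd", "initial")
  expect_equal(Mi["complication", "well_initial"], 1)
  off_tunnel <- setdiff(rownames(Mi), "complication")
  expect_equal(unname(Mi[off_tunnel, ]),
               unname(diag(nrow(Mi))[match(off_tunnel, rownames(Mi)), ]))
})

test_that("well-to-well probability equals one minus the cause-specific sum", {
  p <- constant_hazard(pp15_config())
  M <- build_transition_matrix(p, "no_icd", "initial")
  expect_equal(M["well", "well"], 1 - (0.0028 + 0.0021 + 0.0010 + 0.0014))
})

test_that("zero discontinuation probability blocks the pathway out of complications", {
  p <- toy_param_set(shock_discontinue = 0)
  for (phase in c("initial", "replacement")) {
    M <- build_transition_matrix(p, "icd", phase)
    expect_equal(M["complication", "discontinued"], 0)
  }
  tr <- run_cohort_trace(p, "icd")
  expect_equal(max(tr$trace[, "discontinued"]), 0)
})

test_that("complication state is a one-cycle tunnel", {
  p <- pp15_config()
  for (phase in c("initial", "replacement")) {
    M <- build_transition_matrix(p, "icd", phase)
    expect_equal(M["complication", "complication"], 0)
  }
})

test_that("the trace reproduces the matrix product cycle by cycle", {
  p <- pp15_config()
  ri <- p$structural$device_replacement_interval_months
  tr <- run_cohort_trace(p, "icd")
  for (t in c(1L, 50L, ri - 1L, ri, ri + 1L, 2L * ri, 400L)) {
    occ <- tr$trace[t, ]
    phase <- if (t <= ri && t %% ri != 0L) "initial" else "replacement"
    if (t %% ri == 0L) {
      wells <- occ[["well_initial"]] + occ[["well_replacement"]]
      occ[["well_initial"]] <- 0
      occ[["well_replacement"]] <- wells
    }
    M <- build_transition_matrix(p, "icd", phase, cycle = t)
    expect_equal(drop(occ %*% M), tr$trace[t + 1L, ], tolerance = 1e-12)
  }
})

test_that("an inert cohort stays entirely well", {
  p <- inert_param_set()
  for (arm in c("icd", "no_icd")) {
    tr <- run_cohort_trace(p, arm)
    well <- if (arm == "icd") "well_initial" else "well"
    alive <- tr$trace[, well] + if (arm == "icd") tr$trace[, "well_replacement"] else 0
    expect_equal(unname(alive), rep(1, nrow(tr$trace)))
  }
})

test_that("constant-hazard life expectancy matches the geometric closed form", {
  q <- 0.01
  p <- inert_param_set()
  p$mortality_no_icd$sudden_cardiac$value <- q
  tr <- run_cohort_trace(p, "no_icd")
  eff <- accrue_qalys(tr, p)
  closed_form <- sum((1 - q)^(1:420)) / 12
  expect_equal(eff$undiscounted$life_years, closed_form, tolerance = 1e-9)
  expect_equal(closed_form, 8.127, tolerance = 1e-3)
})

test_that("event schedule matches hand-computed expectations", {
  # shocks: expected count per cycle = well occupancy x (p_cont + p_disc)
  p <- toy_param_set(mortality_icd = rep(0, 4), mortality_no_icd = rep(0, 4),
                     event_probs = FALSE, op_death = 0)
  tr <- run_cohort_trace(p, "icd")
  sched <- build_event_schedule(tr, p)
  expect_equal(sched$shock_continue[2], 0.0034)
  expect_equal(sched$shock_discontinue[2], 0.0001)
  expect_equal(sched$shock_continue[3], 0.0034 * tr$trace[2, "well_initial"])

  # without event probabilities, only implants and replacements remain
  p0 <- inert_param_set()
  s0 <- build_event_schedule(run_cohort_trace(p0, "icd"), p0)
  expect_equal(sum(s0$shock_continue) + sum(s0$infection) +
               sum(s0$lead_replacement) + sum(s0$lead_dislodgement) +
               sum(s0$discontinuation), 0)
  expect_equal(s0$initial_implant[1], 1)
  expect_equal(sum(s0$device_replacement > 0), floor(420 / 72))

  # replacement interval beyond the horizon: no replacement events
  p1 <- inert_param_set(horizon = 71L)
  s1 <- build_event_schedule(run_cohort_trace(p1, "icd"), p1)
  expect_equal(sum(s1$device_replacement), 0)

  # replacements fall only on interval multiples, on the surviving wells
  p2 <- toy_param_set()
  tr2 <- run_cohort_trace(p2, "icd")
  s2 <- build_event_schedule(tr2, p2)
  hit <- which(s2$device_replacement > 0) - 1L
  expect_true(all(hit %% 72 == 0))
  expect_equal(s2$device_replacement[s2$cycle == 72],
               tr2$trace[72, "well_initial"] + tr2$trace[72, "well_replacement"])
})

test_that("engine invariants hold across randomized parameter sets", {
  fixtures <- generate_fixture_param_sets(25, seed = 99)
  for (p in fixtures) {
    p$structural$horizon_months <- 240L
    for (arm in c("icd", "no_icd")) {
      tr <- run_cohort_trace(p, arm)
      expect_equal(unname(rowSums(tr$trace)), rep(1, 241L), tolerance = 1e-9)
      dead <- rowSums(tr$trace[, grepl("^dead_", tr$states), drop = FALSE])
      expect_true(all(diff(dead) >= -1e-12))
    }
  }
})

test_that("cause-wise lower mortality dominates in survival at every cycle", {
  fixtures <- generate_fixture_param_sets(6, seed = 7)
  for (p in fixtures) {
    p$structural$horizon_months <- 240L
    worse <- p
    for (cz in worse$mortality_no_icd$causes) {
      worse$mortality_no_icd[[cz]]$value <-
        min(0.2, worse$mortality_no_icd[[cz]]$value * 1.7)
    }
    a <- run_cohort_trace(p, "no_icd")$trace[, "well"]
    b <- run_cohort_trace(worse, "no_icd")$trace[, "well"]
    expect_true(all(a - b >= -1e-12))
  }
})

test_that("background mortality modes raise deaths and respect entry age", {
  p <- pp15_config()
  off <- constant_hazard(p)
  alive <- function(q, arm = "no_icd") {
    tr <- run_cohort_trace(q, arm)
    rowSums(tr$trace[, !grepl("^dead_", tr$states), drop = FALSE])
  }
  a_off <- alive(off); a_exc <- alive(p)
  add <- p; add$structural$background_mortality_mode <- "additive"
  a_add <- alive(add)
  expect_true(all(a_exc <= a_off + 1e-12))
  expect_true(all(a_add <= a_exc + 1e-12))
  # excess mode adds nothing at entry age, so early cycles are nearly unaffected
  expect_equal(a_exc[13], a_off[13], tolerance = 2e-3)
  expect_lt(a_exc[421], a_off[421] - 0.01)
})
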