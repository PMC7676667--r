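# Patient-level Monte Carlo simulator.
#
# Draws individual trajectories cycle by cycle from the exact per-cycle
# probability objects of the cohort engine (same .engine_inputs /
# .bg_hazard_monthly internals), so any disagreement between the two engines
# beyond Monte-Carlo error indicates an accrual or bookkeeping bug rather
# than parameterization drift. Patients are advanced cycle-synchronously in
# vectorized draws from a single seeded stream.

# integer state codes, ICD arm: 1 well_initial, 2 well_replacement,
# 3 complication, 4 discontinued, 5..8 dead causes, 9 dead_operative,
# 10 dead_background. no-ICD arm: 1 well, 5..8 dead causes, 10 dead_background.

#' Simulate individual patient trajectories
#'
#' @param p A valid `param_set`.
#' @param arm `"icd"` or `"no_icd"`.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; the ledger is fully reproducible from it.
#' @return A `patient_ledger`: per-patient discounted/undiscounted cost,
#'   life-years and QALYs, death cause and cycle (NA when censored at the
#'   horizon), per-cycle aggregated state counts, and the parameter
#'   fingerprint.
#' @export
simulate_patients <- function(p, arm = c("icd", "no_icd"), n, seed) {
  arm <- match.arg(arm)
  stopifnot(n >= 1)
  viol <- validate_param_set(p)
  if (nrow(viol)) {
    stop("invalid param_set: ", paste(viol$field, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  H <- p$structural$horizon_months
  s <- p$structural
  inp <- .engine_inputs(p, arm)
  hb <- .bg_hazard_monthly(p, seq_len(H))
  d <- discount_factor(s$annual_discount_rate, seq_len(H))
  cst <- p$costs
  u_well <- p$utilities$annual_utility_well$value / 12
  u_comp <- p$utilities$utility_complication_state$value / 12
  decrement <- p$utilities$complication_decrement *
    p$utilities$complication_decrement_duration_days / 365.25
  event_cost <- c(shock_continue = cst$inappropriate_shock,
                  shock_discontinue = cst$inappropriate_shock,
                  lead_replacement = cst$lead_replacement,
                  lead_dislodgement = cst$lead_dislodgement,
                  infection = cst$infection + cst$generator_removal)

  state <- rep(1L, n)
  pending <- integer(n)       # complication event type (1..5) while in tunnel
  cost_u <- cost_d <- qaly_u <- qaly_d <- ly_u <- ly_d <- numeric(n)
  death_cycle <- rep(NA_integer_, n)
  states <- state_space(p, arm)
  counts <- matrix(0L, H + 1L, 10L)

  if (arm == "icd") {
    cost_u[] <- cst$implant_initial
    cost_d[] <- cst$implant_initial
    op <- stats::runif(n) < inp$op_death
    state[op] <- 9L
    death_cycle[op] <- 0L
  }
  counts[1L, ] <- tabulate(state, 10L)

  for (t in seq_len(H)) {
    phase <- if (t <= inp$ri && t %% inp$ri != 0L) "initial" else "replacement"
    dt <- d[t]
    if (arm == "icd" && t %% inp$ri == 0L) {
      w <- state == 1L | state == 2L
      if (s$apply_operative_death_at_replacement %||% FALSE) {
        od <- w & (stats::runif(n) < inp$op_death)
        cost_u[w] <- cost_u[w] + cst$implant_replacement
        cost_d[w] <- cost_d[w] + cst$implant_replacement * dt
        state[od] <- 9L; death_cycle[od] <- t
        w <- w & !od
      } else {
        cost_u[w] <- cost_u[w] + cst$implant_replacement
        cost_d[w] <- cost_d[w] + cst$implant_replacement * dt
      }
      state[w] <- 2L
    }

    new_state <- state
    # well states: competing causes of death, background, complication entry
    for (w in if (arm == "icd") c(1L, 2L) else 1L) {
      idx <- which(state == w)
      if (!length(idx)) next
      comp <- if (arm == "icd") {
        inp$comp[[if (w == 1L) "initial" else "replacement"]]
      } else {
        numeric(5L)
      }
      m <- if (arm == "icd") inp$m_icd else inp$m_no
      breaks <- cumsum(c(m, hb[t], comp))
      k <- findInterval(stats::runif(length(idx)), breaks) + 1L
      dead <- k <= 4L
      new_state[idx[dead]] <- 4L + k[dead]
      death_cycle[idx[dead]] <- t
      bg <- k == 5L
      new_state[idx[bg]] <- 10L
      death_cycle[idx[bg]] <- t
      if (arm == "icd") {
        ev <- k >= 6L & k <= 10L
        if (any(ev)) {
          type <- k[ev] - 5L
          new_state[idx[ev]] <- 3L
          pending[idx[ev]] <- type
          cost_u[idx[ev]] <- cost_u[idx[ev]] + event_cost[type]
          cost_d[idx[ev]] <- cost_d[idx[ev]] + event_cost[type] * dt
          qaly_u[idx[ev]] <- qaly_u[idx[ev]] - decrement
          qaly_d[idx[ev]] <- qaly_d[idx[ev]] - decrement * dt
        }
      }
    }
    if (arm == "icd") {
      # complication tunnel: forced exit after one cycle
      idx <- which(state == 3L)
      if (length(idx)) {
        breaks <- cumsum(c(inp$m_icd, hb[t]))
        k <- findInterval(stats::runif(length(idx)), breaks) + 1L
        dead <- k <= 4L
        new_state[idx[dead]] <- 4L + k[dead]
        death_cycle[idx[dead]] <- t
        bg <- k == 5L
        new_state[idx[bg]] <- 10L
        death_cycle[idx[bg]] <- t
        surv <- k == 6L
        to_disc <- surv & pending[idx] == 2L   # discontinued-therapy shocks
        new_state[idx[to_disc]] <- 4L
        back <- surv & !to_disc
        new_state[idx[back]] <- if (phase == "initial") 1L else 2L
        pending[idx] <- 0L
      }
      # discontinued therapy: conventional-arm mortality
      idx <- which(state == 4L)
      if (length(idx)) {
        breaks <- cumsum(c(inp$m_no, hb[t]))
        k <- findInterval(stats::runif(length(idx)), breaks) + 1L
        dead <- k <= 4L
        new_state[idx[dead]] <- 4L + k[dead]
        death_cycle[idx[dead]] <- t
        bg <- k == 5L
        new_state[idx[bg]] <- 10L
        death_cycle[idx[bg]] <- t
      }
    }
    state <- new_state
    counts[t + 1L, ] <- tabulate(state, 10L)

    alive <- state <= 4L
    ly_u[alive] <- ly_u[alive] + 1 / 12
    ly_d[alive] <- ly_d[alive] + dt / 12
    in_comp <- state == 3L
    in_well <- alive & !in_comp
    mcost <- cst$monthly_inpatient + cst$monthly_outpatient
    cost_u[alive] <- cost_u[alive] + mcost
    cost_d[alive] <- cost_d[alive] + mcost * dt
    qaly_u[in_well] <- qaly_u[in_well] + u_well
    qaly_d[in_well] <- qaly_d[in_well] + u_well * dt
    qaly_u[in_comp] <- qaly_u[in_comp] + u_comp
    qaly_d[in_comp] <- qaly_d[in_comp] + u_comp * dt
  }

  cause_labels <- c("well_or_censored", "well_or_censored", "complication",
                    "well_or_censored",
                    paste0("dead_", p[[if (arm == "icd") "mortality_icd" else
                                       "mortality_no_icd"]]$causes),
                    "dead_operative", "dead_background")
  structure(list(
    arm = arm, n = as.integer(n), seed = seed,
    patients = data.frame(
      patient_id = seq_len(n),
      cost_undiscounted = cost_u, cost_discounted = cost_d,
      life_years_undiscounted = ly_u, life_years_discounted = ly_d,
      qalys_undiscounted = qaly_u, qalys_discounted = qaly_d,
      death_cause = ifelse(is.na(death_cycle), NA_character_,
                           cause_labels[state]),
      death_cycle = death_cycle
    ),
    state_counts = counts, states = states,
    fingerprint = param_fingerprint(p)
  ), class = "patient_ledger")
}

#' @export
print.patient_ledger <- function(x, ...) {
  cat("<patient_ledger>", x$arm, "arm,", x$n, "patients, seed", x$seed, "\n")
  cat(sprintf("  mean discounted cost NT$%s, LY %.2f, QALY %.2f; died: %.1f%%\n",
              format(round(mean(x$patients$cost_discounted)), big.mark = ","),
              mean(x$patients$life_years_discounted),
              mean(x$patients$qalys_discounted),
              100 * mean(!is.na(x$patients$death_cycle))))
  invisible(x)
}

# microsim state-count column for an aggregate of cohort states
.sim_alive <- function(ledger) rowSums(ledger$state_counts[, 1:4, drop = FALSE])

#' Agreement report between microsimulation and cohort engine
#'
#' Compares, per quantity (alive fraction at selected cycles, discounted
#' cost, life-years and QALYs), the microsimulation mean against the
#' deterministic cohort value with a Monte-Carlo z-score. All `|z| <= 3`
#' counts as a pass; below 1000 patients the report flags insufficient
#' precision instead of a verdict.
#'
#' @param ledger A `patient_ledger`.
#' @param arm_result The matching `arm_result`.
#' @param trace The matching `cohort_trace`.
#' @param check_cycles Cycle indices at which alive fractions are compared.
#' @return A `sim_agreement` report: data frame of quantities plus a verdict.
#' @export
compare_to_cohort <- function(ledger, arm_result, trace,
                              check_cycles = c(60L, 120L, 240L, 420L)) {
  stopifnot(inherits(ledger, "patient_ledger"), inherits(arm_result, "arm_result"),
            inherits(trace, "cohort_trace"))
  if (!identical(ledger$fingerprint, trace$fingerprint) ||
      !identical(arm_result$fingerprint, trace$fingerprint)) {
    stop("parameter fingerprints do not match across inputs", call. = FALSE)
  }
  if (!identical(ledger$arm, trace$arm)) stop("arms differ", call. = FALSE)
  n <- ledger$n
  H <- nrow(trace$trace) - 1L
  check_cycles <- check_cycles[check_cycles <= H]

  rows <- list()
  alive_states <- !grepl("^dead_", trace$states)
  cohort_alive <- rowSums(trace$trace[, alive_states, drop = FALSE])
  sim_alive <- .sim_alive(ledger) / n
  for (tc in check_cycles) {
    pc <- cohort_alive[tc + 1L]
    se <- sqrt(max(pc * (1 - pc), 1e-12) / n)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("alive_fraction_cycle_", tc),
      simulated = sim_alive[tc + 1L], cohort = pc, mc_se = se,
      z = (sim_alive[tc + 1L] - pc) / se)
  }
  for (q in c("cost_discounted", "life_years_discounted", "qalys_discounted")) {
    x <- ledger$patients[[q]]
    se <- stats::sd(x) / sqrt(n)
    target <- switch(q,
      cost_discounted = arm_result$discounted$cost,
      life_years_discounted = arm_result$discounted$life_years,
      qalys_discounted = arm_result$discounted$qalys)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = q, simulated = mean(x), cohort = target, mc_se = se,
      z = (mean(x) - target) / se)
  }
  report <- do.call(rbind, rows)
  verdict <- if (n < 1000L) "insufficient_precision"
    else if (all(abs(report$z) <= 3)) "pass" else "fail"
  structure(list(report = report, verdict = verdict, n = n),
            class = "sim_agreement")
}

#' @export
print.sim_agreement <- function(x, ...) {
  cat("<sim_agreement>", x$verdict, "at n =", x$n, "\n")
  print(transform(x$report, z = round(z, 2)), row.names = FALSE)
  invisible(x)
}

#' Randomized valid parameter sets for property-based testing
#'
#' Probabilities log-uniform in [1e-4, 5e-2], costs uniform within the
#' magnitudes of the packaged configurations, utilities uniform in
#' [0.4, 1.0]; background mortality off. Every generated set passes
#' [validate_param_set()].
#'
#' @param n Number of parameter sets (>= 1).
#' @param seed Integer seed.
#' @return List of `param_set`s.
#' @export
generate_fixture_param_sets <- function(n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  rprob <- function(k = 1L) exp(stats::runif(k, log(1e-4), log(5e-2)))
  one <- function(i) {
    pop <- sample(c("PP", "1.5PP"), 1L)
    causes <- if (pop == "PP") {
      c("sudden_cardiac", "heart_failure", "other_cardiac", "non_cardiac")
    } else {
      c("sudden_cardiac", "non_sudden_cardiac", "non_cardiac", "unknown")
    }
    mort <- function() {
      blk <- list(causes = causes)
      for (cz in causes) {
        v <- rprob()
        blk[[cz]] <- list(value = v, se = v / 4, dist = "beta")
      }
      blk
    }
    evf <- function(basis) {
      v <- rprob()
      list(value = v, se = v / 4, dist = "beta", basis = basis)
    }
    p <- structure(list(
      population = pop,
      mortality_icd = mort(), mortality_no_icd = mort(),
      events = list(
        operative_death_initial = evf("per_implant"),
        shock_continue = evf("monthly"), shock_discontinue = evf("monthly"),
        lead_replacement_initial = evf("monthly"),
        lead_replacement_replacement = evf("monthly"),
        lead_dislodgement_initial = evf("annual"),
        lead_dislodgement_replacement = evf("annual"),
        infection_initial = evf("phase_lifetime"),
        infection_replacement = evf("phase_lifetime")
      ),
      costs = list(
        implant_initial = stats::runif(1, 3e5, 9e5),
        implant_replacement = stats::runif(1, 1e5, 5e5),
        lead_replacement = stats::runif(1, 2e4, 1e5),
        infection = stats::runif(1, 3e5, 1e6),
        lead_dislodgement = stats::runif(1, 2e4, 1e5),
        generator_removal = stats::runif(1, 2e4, 1e5),
        inappropriate_shock = stats::runif(1, 100, 2000),
        monthly_inpatient = stats::runif(1, 2000, 12000),
        monthly_outpatient = stats::runif(1, 200, 2000)
      ),
      utilities = list(
        annual_utility_well = list(value = stats::runif(1, 0.4, 1.0),
                                   se = 0.02, dist = "beta"),
        utility_complication_state = list(value = stats::runif(1, 0.4, 1.0),
                                          se = 0.02, dist = "beta"),
        complication_decrement = 0.096,
        complication_decrement_duration_days = 3.5
      ),
      structural = list(
        horizon_months = 420L,
        annual_discount_rate = 0.01375,
        cohort_size = 1000L,
        device_replacement_interval_months =
          sample(c(24L, 36L, 48L, 72L, 96L, 120L), 1L),
        wtp_threshold = 2100000,
        apply_operative_death_at_replacement = FALSE,
        half_cycle_correction = FALSE,
        background_mortality_mode = "off"
      )
    ), class = "param_set")
    p
  }
  lapply(seq_len(n), one)
}

#' Export a patient ledger as CSV
#'
#' @param ledger A `patient_ledger`.
#' @param path Output CSV path (one row per patient).
#' @return `path` invisibly.
#' @export
write_ledger_csv <- function(ledger, path) {
  stopifnot(inherits(ledger, "patient_ledger"))
  utils::write.csv(ledger$patients, path, row.names = FALSE)
  invisible(path)
}
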