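# Deterministic Markov cohort engine.
#
# Two arms. The ICD arm has well states for the initial and the replacement
# device phase (they differ in complication hazards), a one-cycle complication
# tunnel, a discontinued-therapy state that reverts to conventional-therapy
# mortality, and absorbing death states (four causes, operative death at
# implant, and an optional age-indexed background cause). The no-ICD arm has a
# single well state and the death states. Time runs in monthly cycles.

.ARM_LEVELS <- c("icd", "no_icd")

#' State names of one arm's state space
#'
#' @param p A `param_set` (cause names come from its mortality blocks).
#' @param arm `"icd"` or `"no_icd"`.
#' @return Character vector of state names, deaths last.
#' @export
state_space <- function(p, arm = c("icd", "no_icd")) {
  arm <- match.arg(arm)
  causes <- if (arm == "icd") p$mortality_icd$causes else p$mortality_no_icd$causes
  dead <- c(paste0("dead_", causes), "dead_operative", "dead_background")
  if (arm == "icd") {
    c("well_initial", "well_replacement", "complication", "discontinued", dead)
  } else {
    c("well", dead)
  }
}

# Monthly hazard from a declared-basis probability. phase_lifetime values are
# spread over one device phase (the replacement interval) as a constant hazard.
.monthly_hazard <- function(value, basis, phase_months) {
  switch(basis,
    monthly = value,
    annual = 1 - (1 - value)^(1 / 12),
    phase_lifetime = 1 - (1 - value)^(1 / phase_months),
    per_implant = value,
    stop("unknown time basis: ", basis, call. = FALSE)
  )
}

# Static per-arm engine inputs: cause vectors, per-phase complication entry
# hazards split by event type, and tunnel routing fractions.
.engine_inputs <- function(p, arm) {
  ri <- p$structural$device_replacement_interval_months
  ev <- p$events
  h <- function(f) .monthly_hazard(ev[[f]]$value, ev[[f]]$basis %||% "monthly", ri)
  comp <- list(
    initial = c(shock_continue = h("shock_continue"),
                shock_discontinue = h("shock_discontinue"),
                lead_replacement = h("lead_replacement_initial"),
                lead_dislodgement = h("lead_dislodgement_initial"),
                infection = h("infection_initial")),
    replacement = c(shock_continue = h("shock_continue"),
                    shock_discontinue = h("shock_discontinue"),
                    lead_replacement = h("lead_replacement_replacement"),
                    lead_dislodgement = h("lead_dislodgement_replacement"),
                    infection = h("infection_replacement"))
  )
  mi <- vapply(p$mortality_icd$causes, function(cz) p$mortality_icd[[cz]]$value, 0)
  mn <- vapply(p$mortality_no_icd$causes, function(cz) p$mortality_no_icd[[cz]]$value, 0)
  list(
    ri = ri,
    horizon = p$structural$horizon_months,
    m_icd = mi, m_no = mn,
    comp = comp,
    comp_total = vapply(comp, sum, 0),
    # only shock events carry a discontinuation pathway
    frac_disc = vapply(comp, function(x) {
      if (sum(x) > 0) unname(x[["shock_discontinue"]] / sum(x)) else 0
    }, 0),
    op_death = ev$operative_death_initial$value,
    op_at_replacement = isTRUE(p$structural$apply_operative_death_at_replacement)
  )
}

# Age-indexed background monthly hazard for cycles t (vectorized). "excess"
# subtracts the life-table annual risk at entry age before the monthly
# conversion, so only the increase of general-population mortality with age is
# added on top of the cohort's constant cause-specific hazards.
.bg_hazard_monthly <- function(p, t) {
  mode <- p$structural$background_mortality_mode %||% "off"
  if (mode == "off") return(rep(0, length(t)))
  lt <- p$structural$life_table_data
  entry <- p$structural$entry_age_years
  age <- entry + (t - 1) / 12
  q_age <- stats::approx(lt$age, lt$qx, xout = age, rule = 2)$y
  q <- if (mode == "excess") {
    q0 <- stats::approx(lt$age, lt$qx, xout = entry, rule = 2)$y
    pmax(0, q_age - q0)
  } else {
    q_age
  }
  1 - (1 - q)^(1 / 12)
}

#' One-cycle transition matrix of an arm
#'
#' Builds the row-stochastic single-cycle transition matrix. The two well
#' states always carry their own device phase's complication hazards; the
#' `phase` argument selects where survivors of the one-cycle complication
#' tunnel return to (the well state of the currently active phase) and which
#' entry mix determines the continue/discontinue split. With an age-indexed
#' background-mortality mode the matrix depends on the cycle index.
#'
#' @param p A valid `param_set`.
#' @param arm `"icd"` or `"no_icd"`.
#' @param phase `"initial"` or `"replacement"` device phase.
#' @param cycle Cycle index (1-based) used for background mortality.
#' @return A named square matrix; rows sum to 1.
#' @export
build_transition_matrix <- function(p, arm = c("icd", "no_icd"),
                                    phase = c("initial", "replacement"),
                                    cycle = 1L) {
  arm <- match.arg(arm)
  phase <- match.arg(phase)
  viol <- validate_param_set(p)
  if (nrow(viol)) {
    stop("invalid param_set: ", paste(viol$field, collapse = ", "), call. = FALSE)
  }
  inp <- .engine_inputs(p, arm)
  hb <- .bg_hazard_monthly(p, cycle)
  .transition_matrix(p, arm, phase, inp, hb)
}

# matrix construction without validation; hb is the scalar background hazard
.transition_matrix <- function(p, arm, phase, inp, hb) {
  states <- state_space(p, arm)
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(states, states))
  causes_icd <- paste0("dead_", p$mortality_icd$causes)
  causes_no <- paste0("dead_", p$mortality_no_icd$causes)

  if (arm == "no_icd") {
    M["well", causes_no] <- inp$m_no
    M["well", "dead_background"] <- hb
    stay <- 1 - sum(inp$m_no) - hb
    if (stay < 0) stop("exit probabilities from state 'well' sum above 1", call. = FALSE)
    M["well", "well"] <- stay
  } else {
    for (w in c("well_initial", "well_replacement")) {
      ph <- if (w == "well_initial") "initial" else "replacement"
      ct <- inp$comp_total[[ph]]
      M[w, causes_icd] <- inp$m_icd
      M[w, "dead_background"] <- hb
      M[w, "complication"] <- ct
      stay <- 1 - sum(inp$m_icd) - hb - ct
      if (stay < 0) stop("exit probabilities from state '", w, "' sum above 1",
                         call. = FALSE)
      M[w, w] <- stay
    }
    # complication tunnel: forced exit, mortality applies during the sojourn
    surv <- 1 - sum(inp$m_icd) - hb
    if (surv < 0) stop("exit probabilities from state 'complication' sum above 1",
                       call. = FALSE)
    fd <- inp$frac_disc[[phase]]
    M["complication", causes_icd] <- inp$m_icd
    M["complication", "dead_background"] <- hb
    M["complication", "discontinued"] <- surv * fd
    well_target <- if (phase == "initial") "well_initial" else "well_replacement"
    M["complication", well_target] <- surv * (1 - fd)
    # discontinued therapy reverts to conventional-arm mortality
    M["discontinued", causes_no] <- M["discontinued", causes_no] + inp$m_no
    M["discontinued", "dead_background"] <- hb
    stay <- 1 - sum(inp$m_no) - hb
    if (stay < 0) stop("exit probabilities from state 'discontinued' sum above 1",
                       call. = FALSE)
    M["discontinued", "discontinued"] <- stay
  }
  dead <- grep("^dead_", states, value = TRUE)
  for (d in dead) M[d, d] <- 1
  M
}

#' Run the deterministic cohort trace of one arm
#'
#' Starts the full cohort in the well state (the ICD arm first passes through
#' the decision-tree implant node, where the operative-death fraction moves
#' straight to an absorbing state) and multiplies through the cycle-specific
#' transition matrices over the whole horizon. At every multiple of the device
#' replacement interval the surviving well occupancy switches to the
#' replacement-device phase and a device replacement event is recorded.
#'
#' @param p A valid `param_set`.
#' @param arm `"icd"` or `"no_icd"`.
#' @return A `cohort_trace`: list with the occupancy matrix `trace` (rows
#'   cycle 0..horizon), `arm`, `states`, the expected-event `schedule`, the
#'   `param_set` used, and its fingerprint.
#' @export
run_cohort_trace <- function(p, arm = c("icd", "no_icd")) {
  arm <- match.arg(arm)
  viol <- validate_param_set(p)
  if (nrow(viol)) {
    stop("invalid param_set: ", paste(viol$field, collapse = ", "), call. = FALSE)
  }
  H <- p$structural$horizon_months
  states <- state_space(p, arm)
  inp <- .engine_inputs(p, arm)
  hb <- .bg_hazard_monthly(p, seq_len(H))

  trace <- matrix(0, H + 1L, length(states), dimnames = list(0:H, states))
  sched <- matrix(0, H + 1L, 9L, dimnames = list(0:H, c(
    "initial_implant", "operative_death", "device_replacement",
    "shock_continue", "shock_discontinue", "lead_replacement",
    "lead_dislodgement", "infection", "discontinuation")))

  if (arm == "icd") {
    trace[1L, "well_initial"] <- 1 - inp$op_death
    trace[1L, "dead_operative"] <- inp$op_death
    sched[1L, "initial_implant"] <- 1
    sched[1L, "operative_death"] <- inp$op_death
  } else {
    trace[1L, "well"] <- 1
  }

  occ <- trace[1L, ]
  for (t in seq_len(H)) {
    phase <- if (t <= inp$ri) "initial" else "replacement"
    if (arm == "icd" && t %% inp$ri == 0L) {
      wells <- occ[["well_initial"]] + occ[["well_replacement"]]
      sched[t + 1L, "device_replacement"] <- wells
      if (inp$op_at_replacement && wells > 0) {
        occ[["dead_operative"]] <- occ[["dead_operative"]] + wells * inp$op_death
        wells <- wells * (1 - inp$op_death)
        sched[t + 1L, "operative_death"] <- sched[t + 1L, "operative_death"] +
          sched[t + 1L, "device_replacement"] * inp$op_death
      }
      occ[["well_initial"]] <- 0
      occ[["well_replacement"]] <- wells
      phase <- "replacement"
    }
    M <- .transition_matrix(p, arm, phase, inp, hb[t])
    if (arm == "icd") {
      wi <- occ[["well_initial"]]; wr <- occ[["well_replacement"]]
      ci <- inp$comp$initial; cr <- inp$comp$replacement
      sched[t + 1L, "shock_continue"] <- wi * ci[["shock_continue"]] + wr * cr[["shock_continue"]]
      sched[t + 1L, "shock_discontinue"] <- wi * ci[["shock_discontinue"]] + wr * cr[["shock_discontinue"]]
      sched[t + 1L, "lead_replacement"] <- wi * ci[["lead_replacement"]] + wr * cr[["lead_replacement"]]
      sched[t + 1L, "lead_dislodgement"] <- wi * ci[["lead_dislodgement"]] + wr * cr[["lead_dislodgement"]]
      sched[t + 1L, "infection"] <- wi * ci[["infection"]] + wr * cr[["infection"]]
      sched[t + 1L, "discontinuation"] <- occ[["complication"]] *
        (1 - sum(inp$m_icd) - hb[t]) * inp$frac_disc[[phase]]
    }
    occ <- drop(occ %*% M)
    trace[t + 1L, ] <- occ
  }

  structure(list(trace = trace, arm = arm, states = states,
                 schedule = as.data.frame(cbind(cycle = 0:H, sched)),
                 param_set = p, fingerprint = param_fingerprint(p)),
            class = "cohort_trace")
}

#' Expected per-cycle event counts of a cohort trace
#'
#' Expected counts per entering cohort member of implants, device
#' replacements, shocks (continued / discontinued therapy), lead
#' replacements, lead dislodgements, infections and therapy
#' discontinuations, cycle by cycle.
#'
#' @param trace A `cohort_trace`.
#' @param p The `param_set` the trace was produced from.
#' @return An `event_schedule` data frame, one row per cycle 0..horizon.
#' @export
build_event_schedule <- function(trace, p) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (!identical(trace$fingerprint, param_fingerprint(p))) {
    stop("trace was not produced from this param_set", call. = FALSE)
  }
  structure(trace$schedule, class = c("event_schedule", "data.frame"))
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$trace) - 1L
  alive <- sum(x$trace[H + 1L, !grepl("^dead_", x$states)])
  cat("<cohort_trace>", x$arm, "arm,", x$param_set$population, "population\n")
  cat("  ", H, "monthly cycles,", length(x$states), "states; alive at horizon:",
      signif(alive, 4), "\n")
  invisible(x)
}

#' Export a cohort trace as a long-format CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path (columns cycle, state, occupancy).
#' @return `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  H <- nrow(trace$trace) - 1L
  long <- data.frame(
    cycle = rep(0:H, times = length(trace$states)),
    state = rep(trace$states, each = H + 1L),
    occupancy = as.vector(trace$trace)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
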