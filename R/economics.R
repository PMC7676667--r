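# Cost, life-year and QALY accrual, and paired-arm cost-effectiveness.
#
# Accrual convention: quantities for cycle t (t = 1..horizon) are accrued on
# the end-of-cycle occupancy (trace row t) and discounted with the factor at
# month t; event costs use the expected event counts of cycle t. Cycle-0
# events (the implant procedure, operative death) are undiscounted. An
# optional half-cycle correction averages start- and end-of-cycle occupancy
# for the recurring (monthly) quantities.

#' Discount factor at a given month
#'
#' `(1 + annual_rate)^(-month/12)`: compounds in months and is exact at
#' annual boundaries.
#'
#' @param annual_rate Annual discount rate in `[0, 1)`.
#' @param month Months elapsed since model entry (vectorized, >= 0).
#' @return Discount factor(s) in (0, 1].
#' @examples
#' discount_factor(0.01375, 12) # = 1 / 1.01375
#' @export
discount_factor <- function(annual_rate, month) {
  if (any(month < 0)) stop("month must be >= 0", call. = FALSE)
  if (annual_rate < 0 || annual_rate >= 1) {
    stop("annual_rate must be in [0, 1)", call. = FALSE)
  }
  (1 + annual_rate)^(-month / 12)
}

# alive occupancy per trace row, with optional half-cycle averaging
.alive_by_cycle <- function(trace, half_cycle) {
  alive_states <- !grepl("^dead_", trace$states)
  alive <- rowSums(trace$trace[, alive_states, drop = FALSE])
  H <- length(alive) - 1L
  a <- alive[-1L]                       # end-of-cycle, cycles 1..H
  if (half_cycle) a <- (alive[-(H + 1L)] + alive[-1L]) / 2
  a
}

#' Accrue costs of one arm
#'
#' Per cycle: alive occupancy times the recurring inpatient + outpatient
#' costs, plus expected event counts times their one-off costs. The initial
#' implant procedure is charged at cycle 0 on the whole entering cohort;
#' device replacements at each replacement epoch on the surviving well
#' occupancy; every infection additionally carries the generator-removal
#' cost.
#'
#' @param trace A `cohort_trace`.
#' @param schedule Its `event_schedule` (defaults to the one carried by the
#'   trace).
#' @param p The `param_set` used to produce the trace.
#' @return List with `undiscounted` and `discounted` totals and per-category
#'   breakdowns (`device`, `complications`, `inpatient`, `outpatient`).
#' @export
accrue_costs <- function(trace, schedule = NULL, p = trace$param_set) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (is.null(schedule)) schedule <- build_event_schedule(trace, p)
  H <- nrow(trace$trace) - 1L
  s <- p$structural
  cst <- p$costs
  d <- discount_factor(s$annual_discount_rate, seq_len(H))
  alive <- .alive_by_cycle(trace, isTRUE(s$half_cycle_correction))
  ev <- schedule[-1L, , drop = FALSE]   # cycles 1..H

  inpatient <- alive * cst$monthly_inpatient
  outpatient <- alive * cst$monthly_outpatient
  device <- ev$device_replacement * cst$implant_replacement
  complications <-
    (ev$shock_continue + ev$shock_discontinue) * cst$inappropriate_shock +
    ev$lead_replacement * cst$lead_replacement +
    ev$lead_dislodgement * cst$lead_dislodgement +
    ev$infection * (cst$infection + cst$generator_removal)
  implant0 <- schedule$initial_implant[1L] * cst$implant_initial

  sum_u <- function(x) sum(x)
  sum_d <- function(x) sum(x * d)
  breakdown_u <- c(device = implant0 + sum_u(device),
                   complications = sum_u(complications),
                   inpatient = sum_u(inpatient), outpatient = sum_u(outpatient))
  breakdown_d <- c(device = implant0 + sum_d(device),
                   complications = sum_d(complications),
                   inpatient = sum_d(inpatient), outpatient = sum_d(outpatient))
  list(undiscounted = list(total = sum(breakdown_u), breakdown = breakdown_u),
       discounted = list(total = sum(breakdown_d), breakdown = breakdown_d))
}

#' Accrue life-years and QALYs of one arm
#'
#' Life-years: alive occupancy times 1/12 per cycle. QALYs: well and
#' discontinued occupancy at the annual well utility / 12, the complication
#' tunnel cycle at the complication-state utility / 12, and an absolute
#' short-term decrement per complication event (default 0.096 over 3.5 days)
#' on top.
#'
#' @inheritParams accrue_costs
#' @return List with `undiscounted` and `discounted` `life_years` and
#'   `qalys`.
#' @export
accrue_qalys <- function(trace, p = trace$param_set) {
  stopifnot(inherits(trace, "cohort_trace"))
  schedule <- build_event_schedule(trace, p)
  H <- nrow(trace$trace) - 1L
  s <- p$structural
  u <- p$utilities
  d <- discount_factor(s$annual_discount_rate, seq_len(H))
  half <- isTRUE(s$half_cycle_correction)
  alive <- .alive_by_cycle(trace, half)

  occ <- trace$trace
  avg <- function(col) {
    x <- occ[, col]
    if (half) (x[-(H + 1L)] + x[-1L]) / 2 else x[-1L]
  }
  if (trace$arm == "icd") {
    well <- avg("well_initial") + avg("well_replacement") + avg("discontinued")
    comp <- avg("complication")
  } else {
    well <- avg("well")
    comp <- rep(0, H)
  }
  ev <- schedule[-1L, , drop = FALSE]
  n_events <- ev$shock_continue + ev$shock_discontinue + ev$lead_replacement +
    ev$lead_dislodgement + ev$infection
  decrement <- u$complication_decrement *
    u$complication_decrement_duration_days / 365.25

  q <- well * u$annual_utility_well$value / 12 +
    comp * u$utility_complication_state$value / 12 -
    n_events * decrement
  if (any(q < 0)) {
    warning("negative per-cycle utility clamped at 0", call. = FALSE)
    q <- pmax(q, 0)
  }
  ly <- alive / 12
  list(undiscounted = list(life_years = sum(ly), qalys = sum(q)),
       discounted = list(life_years = sum(ly * d), qalys = sum(q * d)))
}

#' Run one arm end to end
#'
#' Cohort trace, event schedule, cost and effectiveness accrual for one arm.
#'
#' @param p A valid `param_set`.
#' @param arm `"icd"` or `"no_icd"`.
#' @return An `arm_result` with discounted and undiscounted totals and the
#'   cost breakdown.
#' @export
run_arm <- function(p, arm = c("icd", "no_icd")) {
  arm <- match.arg(arm)
  trace <- run_cohort_trace(p, arm)
  costs <- accrue_costs(trace, p = p)
  eff <- accrue_qalys(trace, p = p)
  structure(list(
    arm = arm, population = p$population,
    undiscounted = list(cost = costs$undiscounted$total,
                        cost_breakdown = costs$undiscounted$breakdown,
                        life_years = eff$undiscounted$life_years,
                        qalys = eff$undiscounted$qalys),
    discounted = list(cost = costs$discounted$total,
                      cost_breakdown = costs$discounted$breakdown,
                      life_years = eff$discounted$life_years,
                      qalys = eff$discounted$qalys),
    fingerprint = trace$fingerprint
  ), class = "arm_result")
}

.ce_one <- function(a, b, wtp) {
  dc <- a$cost - b$cost
  dq <- a$qalys - b$qalys
  status <- if (dq > 0 && dc > 0) "tradeoff"
    else if (dq > 0 && dc <= 0) "dominant"
    else if (dq < 0 && dc >= 0) "dominated"
    else if (dq == 0 && dc == 0) "equivalent"
    else "tradeoff_sw"                  # cheaper and less effective
  icer <- if (dq != 0) dc / dq else NA_real_
  if (status %in% c("dominant", "dominated")) icer <- NA_real_
  list(d_cost = dc, d_qaly = dq, icer = icer, status = status,
       nmb = wtp * dq - dc)
}

#' Compare two arms
#'
#' Differential cost and QALYs, the ICER (when both differentials are on the
#' trade-off diagonal), dominance status, and net monetary benefit at the
#' willingness-to-pay threshold — discounted and undiscounted.
#'
#' @param a,b `arm_result`s of the intervention and the comparator, produced
#'   from the same `param_set`.
#' @param wtp Willingness-to-pay threshold (NT$/QALY). The packaged configs
#'   use NT$2,100,000.
#' @return A `ce_result` with `discounted` and `undiscounted` components.
#' @export
compare_arms <- function(a, b, wtp = 2100000) {
  stopifnot(inherits(a, "arm_result"), inherits(b, "arm_result"))
  if (!identical(a$population, b$population)) {
    stop("arms come from different populations", call. = FALSE)
  }
  structure(list(
    population = a$population, wtp = wtp,
    arms = c(a$arm, b$arm),
    discounted = .ce_one(a$discounted, b$discounted, wtp),
    undiscounted = .ce_one(a$undiscounted, b$undiscounted, wtp)
  ), class = "ce_result")
}

#' Run the base case for one population
#'
#' Both arms plus their comparison, the package's core deliverable.
#'
#' @param p A valid `param_set`.
#' @return List with `icd`, `no_icd` (`arm_result`s) and `ce` (`ce_result`).
#' @examples
#' \donttest{
#' bc <- run_base_case(load_param_set(icdcea_config("1.5PP")))
#' bc$ce$discounted$icer
#' }
#' @export
run_base_case <- function(p) {
  icd <- run_arm(p, "icd")
  no <- run_arm(p, "no_icd")
  list(icd = icd, no_icd = no,
       ce = compare_arms(icd, no, wtp = p$structural$wtp_threshold))
}

#' @export
print.arm_result <- function(x, ...) {
  cat("<arm_result>", x$arm, "arm,", x$population, "population\n")
  for (v in c("discounted", "undiscounted")) {
    cat(sprintf("  %-12s cost NT$%s  LY %.2f  QALY %.2f\n", v,
                format(round(x[[v]]$cost), big.mark = ","),
                x[[v]]$life_years, x[[v]]$qalys))
  }
  invisible(x)
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>", x$population, ":", x$arms[1], "vs", x$arms[2], "\n")
  for (v in c("discounted", "undiscounted")) {
    z <- x[[v]]
    icer <- if (is.na(z$icer)) z$status else
      paste0("NT$", format(round(z$icer), big.mark = ","), "/QALY")
    cat(sprintf("  %-12s dCost NT$%s  dQALY %.2f  ICER %s  NMB NT$%s\n", v,
                format(round(z$d_cost), big.mark = ","), z$d_qaly, icer,
                format(round(z$nmb), big.mark = ",")))
  }
  invisible(x)
}
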