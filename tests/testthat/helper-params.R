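# Shared fixtures: a fully synthetic toy parameterization whose numbers are
# easy to reason about by hand, plus loaders for the packaged configurations.

toy_param_set <- function(mortality_icd = c(0.001, 0.002, 0.0005, 0.0015),
                          mortality_no_icd = c(0.004, 0.002, 0.001, 0.001),
                          shock_continue = 0.0034, shock_discontinue = 0.0001,
                          event_probs = TRUE, op_death = 0.0002,
                          utility_well = 0.8, utility_comp = 0.7,
                          costs_on = TRUE, horizon = 420L,
                          discount = 0.01375, repl_interval = 72L) {
  causes <- c("sudden_cardiac", "non_sudden_cardiac", "non_cardiac", "unknown")
  mort <- function(v) {
    blk <- list(causes = causes)
    for (i in seq_along(causes)) blk[[causes[i]]] <- list(value = v[i], se = v[i] / 4)
    blk
  }
  ev <- function(value, basis) list(value = value, se = value / 4, basis = basis)
  k <- if (event_probs) 1 else 0
  structure(list(
    population = "1.5PP",
    mortality_icd = mort(mortality_icd),
    mortality_no_icd = mort(mortality_no_icd),
    events = list(
      operative_death_initial = ev(op_death, "per_implant"),
      shock_continue = ev(shock_continue, "monthly"),
      shock_discontinue = ev(shock_discontinue, "monthly"),
      lead_replacement_initial = ev(0.0004 * k, "monthly"),
      lead_replacement_replacement = ev(0.0008 * k, "monthly"),
      lead_dislodgement_initial = ev(0.018 * k, "annual"),
      lead_dislodgement_replacement = ev(0.005 * k, "annual"),
      infection_initial = ev(0.0244 * k, "phase_lifetime"),
      infection_replacement = ev(0.0432 * k, "phase_lifetime")
    ),
    costs = list(
      implant_initial = 633678 * costs_on, implant_replacement = 315513 * costs_on,
      lead_replacement = 62757 * costs_on, infection = 765213 * costs_on,
      lead_dislodgement = 61566 * costs_on, generator_removal = 64290 * costs_on,
      inappropriate_shock = 670 * costs_on,
      monthly_inpatient = 6828 * costs_on, monthly_outpatient = 858 * costs_on
    ),
    utilities = list(
      annual_utility_well = list(value = utility_well, se = 0.02),
      utility_complication_state = list(value = utility_comp, se = 0.02),
      complication_decrement = 0.096,
      complication_decrement_duration_days = 3.5
    ),
    structural = list(
      horizon_months = as.integer(horizon),
      annual_discount_rate = discount,
      cohort_size = 1000L,
      device_replacement_interval_months = as.integer(repl_interval),
      wtp_threshold = 2100000,
      apply_operative_death_at_replacement = FALSE,
      half_cycle_correction = FALSE,
      background_mortality_mode = "off"
    )
  ), class = "param_set")
}

# a toy set with no mortality, no events and no discounting: pure conservation
inert_param_set <- function(...) {
  toy_param_set(mortality_icd = rep(0, 4), mortality_no_icd = rep(0, 4),
                shock_continue = 0, shock_discontinue = 0, event_probs = FALSE,
                op_death = 0, discount = 0, ...)
}

pp_config <- function() load_param_set(icdcea_config("PP"))
pp15_config <- function() load_param_set(icdcea_config("1.5PP"))

# same parameterization with the uncalibrated constant-hazard reading
constant_hazard <- function(p) {
  p$structural$background_mortality_mode <- "off"
  p
}

# published input table as (config, dotted path, value) triples, used to audit
# that every packaged-config field equals its printed source value
published_inputs <- function() {
  rows <- function(cfg, ...) {
    x <- list(...)
    data.frame(config = cfg,
               path = vapply(x, `[[`, "", 1L),
               value = as.numeric(vapply(x, `[[`, "", 2L)))
  }
  rbind(
    rows("1.5PP",
      c("mortality_icd.sudden_cardiac.value", "0.0007"),
      c("mortality_icd.sudden_cardiac.se", "0.0003"),
      c("mortality_icd.non_sudden_cardiac.value", "0.0014"),
      c("mortality_icd.non_sudden_cardiac.se", "0.0004"),
      c("mortality_icd.non_cardiac.value", "0.0005"),
      c("mortality_icd.non_cardiac.se", "0.0003"),
      c("mortality_icd.unknown.value", "0.0013"),
      c("mortality_icd.unknown.se", "0.0003"),
      c("mortality_no_icd.sudden_cardiac.value", "0.0028"),
      c("mortality_no_icd.sudden_cardiac.se", "0.0005"),
      c("mortality_no_icd.non_sudden_cardiac.value", "0.0021"),
      c("mortality_no_icd.non_sudden_cardiac.se", "0.0004"),
      c("mortality_no_icd.non_cardiac.value", "0.0010"),
      c("mortality_no_icd.non_cardiac.se", "0.0004"),
      c("mortality_no_icd.unknown.value", "0.0014"),
      c("mortality_no_icd.unknown.se", "0.0004"),
      c("utilities.annual_utility_well.value", "0.8683"),
      c("utilities.annual_utility_well.se", "0.0360"),
      c("utilities.utility_complication_state.value", "0.7685"),
      c("utilities.utility_complication_state.se", "0.0360")),
    rows("PP",
      c("mortality_icd.sudden_cardiac.value", "0.0015"),
      c("mortality_icd.sudden_cardiac.se", "0.0001"),
      c("mortality_icd.heart_failure.value", "0.0029"),
      c("mortality_icd.heart_failure.se", "0.0002"),
      c("mortality_icd.other_cardiac.value", "0.0004"),
      c("mortality_icd.other_cardiac.se", "0.00002"),
      c("mortality_icd.non_cardiac.value", "0.0024"),
      c("mortality_icd.non_cardiac.se", "0.0002"),
      c("mortality_no_icd.sudden_cardiac.value", "0.0042"),
      c("mortality_no_icd.sudden_cardiac.se", "0.0004"),
      c("mortality_no_icd.heart_failure.value", "0.0029"),
      c("mortality_no_icd.heart_failure.se", "0.0003"),
      c("mortality_no_icd.other_cardiac.value", "0.0002"),
      c("mortality_no_icd.other_cardiac.se", "0.00002"),
      c("mortality_no_icd.non_cardiac.value", "0.0031"),
      c("mortality_no_icd.non_cardiac.se", "0.0003"),
      c("utilities.annual_utility_well.value", "0.7315"),
      c("utilities.annual_utility_well.se", "0.0126"),
      c("utilities.utility_complication_state.value", "0.6474"),
      c("utilities.utility_complication_state.se", "0.112")),
    rows("both",
      c("events.operative_death_initial.value", "0.0002"),
      c("events.operative_death_initial.se", "0.00002"),
      c("events.shock_continue.value", "0.0034"),
      c("events.shock_continue.se", "0.0002"),
      c("events.shock_discontinue.value", "0.0001"),
      c("events.shock_discontinue.se", "0.00007"),
      c("events.lead_replacement_initial.value", "0.0004"),
      c("events.lead_replacement_initial.se", "0.0005"),
      c("events.lead_replacement_replacement.value", "0.0008"),
      c("events.lead_replacement_replacement.se", "0.0009"),
      c("events.lead_dislodgement_initial.value", "0.018"),
      c("events.lead_dislodgement_initial.se", "0.0012"),
      c("events.lead_dislodgement_replacement.value", "0.005"),
      c("events.lead_dislodgement_replacement.se", "0.0009"),
      c("events.infection_initial.value", "0.0244"),
      c("events.infection_initial.se", "0.0049"),
      c("events.infection_replacement.value", "0.0432"),
      c("events.infection_replacement.se", "0.0064"),
      c("costs.implant_initial", "633678"),
      c("costs.implant_replacement", "315513"),
      c("costs.lead_replacement", "62757"),
      c("costs.infection", "765213"),
      c("costs.lead_dislodgement", "61566"),
      c("costs.generator_removal", "64290"),
      c("costs.inappropriate_shock", "670"),
      c("costs.monthly_inpatient", "6828"),
      c("costs.monthly_outpatient", "858"),
      c("structural.annual_discount_rate", "0.01375"),
      c("utilities.complication_decrement", "0.096"),
      c("utilities.complication_decrement_duration_days", "3.5"),
      c("structural.wtp_threshold", "2100000"),
      c("structural.horizon_months", "420"),
      c("structural.cohort_size", "1000"))
  )
}
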