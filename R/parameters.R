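# Model parameterization: loading, validation, uncertainty distributions.
#
# A param_set holds everything one population's model run needs: cause-specific
# monthly mortality for both treatment arms, ICD-related event probabilities
# (with an explicit time basis per field), one-off and recurring costs in 2017
# NT$, utilities, and structural settings (horizon, discount rate, device
# replacement interval, background-mortality mode, ...).

.EVENT_FIELDS <- c(
  "operative_death_initial",
  "shock_continue", "shock_discontinue",
  "lead_replacement_initial", "lead_replacement_replacement",
  "lead_dislodgement_initial", "lead_dislodgement_replacement",
  "infection_initial", "infection_replacement"
)

.COST_FIELDS <- c(
  "implant_initial", "implant_replacement", "lead_replacement", "infection",
  "lead_dislodgement", "generator_removal", "inappropriate_shock",
  "monthly_inpatient", "monthly_outpatient"
)

.BASIS_LEVELS <- c("monthly", "annual", "phase_lifetime", "per_implant")
.BG_MODES <- c("off", "excess", "additive")

#' Load a model parameter set from a YAML/JSON configuration
#'
#' Reads a structured configuration (YAML; JSON is a YAML subset and parses
#' too) describing one population's complete model parameterization and
#' returns a validated `param_set`. The package ships two configurations,
#' `pp.yaml` (primary prevention) and `pp15.yaml` (1.5 primary prevention);
#' see [icdcea_config()].
#'
#' @param config_source Path to a configuration file, or a single string of
#'   YAML text.
#' @param population Optional population label (`"PP"` or `"1.5PP"`); when
#'   given it must match the config's own label.
#' @return A `param_set` object.
#' @examples
#' p <- load_param_set(icdcea_config("1.5PP"))
#' p$mortality_no_icd$sudden_cardiac$value
#' @export
load_param_set <- function(config_source, population = NULL) {
  if (length(config_source) == 1L && file.exists(config_source)) {
    raw <- yaml::read_yaml(config_source)
    base_dir <- dirname(normalizePath(config_source))
  } else {
    raw <- yaml::yaml.load(config_source)
    base_dir <- getwd()
  }
  required <- c("population", "mortality_icd", "mortality_no_icd", "events",
                "costs", "utilities", "structural")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("config is missing required field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(population) && !identical(raw$population, population)) {
    stop("config population label '", raw$population,
         "' does not match requested '", population, "'", call. = FALSE)
  }
  p <- structure(raw, class = "param_set")
  p$structural$life_table_data <- .resolve_life_table(p$structural$life_table, base_dir)
  viol <- validate_param_set(p)
  if (nrow(viol)) {
    stop("invalid parameter set:\n",
         paste0("  - ", viol$field, " = ", viol$value, ": ", viol$rule,
                collapse = "\n"),
         call. = FALSE)
  }
  p
}

.resolve_life_table <- function(ref, base_dir) {
  if (is.null(ref)) return(NULL)
  path <- ref
  if (!file.exists(path)) path <- file.path(base_dir, ref)
  if (!file.exists(path)) path <- system.file("extdata", ref, package = "icdcea")
  if (!nzchar(path) || !file.exists(path)) {
    stop("life table file not found: ", ref, call. = FALSE)
  }
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns 'age' and 'qx'", call. = FALSE)
  }
  lt[order(lt$age), c("age", "qx")]
}

#' Path to a packaged model configuration
#'
#' @param population `"PP"` or `"1.5PP"`.
#' @return File path of the packaged YAML configuration.
#' @export
icdcea_config <- function(population = c("PP", "1.5PP")) {
  population <- match.arg(population)
  fn <- if (population == "PP") "pp.yaml" else "pp15.yaml"
  system.file("extdata", fn, package = "icdcea", mustWork = TRUE)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameterization. Violations are
#' returned as data, not raised: an empty data frame means the set is valid.
#'
#' @param p A `param_set`.
#' @return A data frame with columns `field`, `value`, `rule`; zero rows when
#'   every invariant holds.
#' @export
validate_param_set <- function(p) {
  v <- list()
  bad <- function(field, value, rule) {
    v[[length(v) + 1L]] <<- data.frame(field = field,
                                       value = as.character(value)[1L],
                                       rule = rule)
  }

  if (!identical(p$population, "PP") && !identical(p$population, "1.5PP")) {
    bad("population", p$population %||% "<missing>", "must be 'PP' or '1.5PP'")
  }

  for (arm in c("mortality_icd", "mortality_no_icd")) {
    blk <- p[[arm]]
    causes <- blk$causes
    if (is.null(causes) || length(causes) != 4L) {
      bad(paste0(arm, ".causes"), length(causes), "exactly four death causes required")
      next
    }
    total <- 0
    for (cz in causes) {
      fld <- blk[[cz]]
      if (is.null(fld$value)) {
        bad(paste(arm, cz, sep = "."), "<missing>", "missing value")
        next
      }
      if (fld$value < 0 || fld$value > 1) {
        bad(paste(arm, cz, sep = "."), fld$value, "probability must be in [0, 1]")
      }
      if (!is.null(fld$se) && fld$se < 0) {
        bad(paste(arm, cz, "se", sep = "."), fld$se, "standard error must be >= 0")
      }
      total <- total + fld$value
    }
    if (total >= 1) {
      bad(arm, total, "cause-specific monthly probabilities must sum to < 1")
    }
  }

  for (ev in .EVENT_FIELDS) {
    fld <- p$events[[ev]]
    if (is.null(fld$value)) {
      bad(paste0("events.", ev), "<missing>", "missing value")
      next
    }
    if (fld$value < 0 || fld$value > 1) {
      bad(paste0("events.", ev), fld$value, "probability must be in [0, 1]")
    }
    if (!is.null(fld$se) && fld$se < 0) {
      bad(paste0("events.", ev, ".se"), fld$se, "standard error must be >= 0")
    }
    if (!is.null(fld$basis) && !fld$basis %in% .BASIS_LEVELS) {
      bad(paste0("events.", ev, ".basis"), fld$basis,
          paste("basis must be one of:", paste(.BASIS_LEVELS, collapse = ", ")))
    }
  }

  for (cst in .COST_FIELDS) {
    val <- p$costs[[cst]]
    if (is.null(val)) {
      bad(paste0("costs.", cst), "<missing>", "missing value")
    } else if (val < 0) {
      bad(paste0("costs.", cst), val, "cost must be >= 0")
    }
  }

  for (ut in c("annual_utility_well", "utility_complication_state")) {
    fld <- p$utilities[[ut]]
    if (is.null(fld$value)) {
      bad(paste0("utilities.", ut), "<missing>", "missing value")
    } else if (fld$value < 0 || fld$value > 1) {
      bad(paste0("utilities.", ut), fld$value, "utility must be in [0, 1]")
    }
  }
  dec <- p$utilities$complication_decrement
  if (is.null(dec) || dec < 0 || dec > 1) {
    bad("utilities.complication_decrement", dec %||% "<missing>",
        "decrement must be in [0, 1]")
  }
  dur <- p$utilities$complication_decrement_duration_days
  if (is.null(dur) || dur <= 0) {
    bad("utilities.complication_decrement_duration_days", dur %||% "<missing>",
        "duration must be > 0")
  }

  s <- p$structural
  if (is.null(s$horizon_months) || s$horizon_months < 1) {
    bad("structural.horizon_months", s$horizon_months %||% "<missing>",
        "horizon must be >= 1 month")
  }
  if (is.null(s$annual_discount_rate) || s$annual_discount_rate < 0 ||
      s$annual_discount_rate >= 1) {
    bad("structural.annual_discount_rate", s$annual_discount_rate %||% "<missing>",
        "annual discount rate must be in [0, 1)")
  }
  if (is.null(s$device_replacement_interval_months) ||
      s$device_replacement_interval_months < 1) {
    bad("structural.device_replacement_interval_months",
        s$device_replacement_interval_months %||% "<missing>",
        "replacement interval must be >= 1 month")
  }
  if (is.null(s$wtp_threshold) || s$wtp_threshold <= 0) {
    bad("structural.wtp_threshold", s$wtp_threshold %||% "<missing>",
        "willingness-to-pay threshold must be > 0")
  }
  if (!is.null(s$background_mortality_mode) &&
      !s$background_mortality_mode %in% .BG_MODES) {
    bad("structural.background_mortality_mode", s$background_mortality_mode,
        paste("mode must be one of:", paste(.BG_MODES, collapse = ", ")))
  }
  if (!identical(s$background_mortality_mode %||% "off", "off")) {
    if (is.null(s$life_table_data)) {
      bad("structural.life_table", "<missing>",
          "background mortality requires a life table")
    }
    if (is.null(s$entry_age_years) || s$entry_age_years <= 0) {
      bad("structural.entry_age_years", s$entry_age_years %||% "<missing>",
          "entry age must be > 0")
    }
  }

  if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), value = character(), rule = character())
}

#' Beta distribution from a reported mean and standard error
#'
#' Method-of-moments parameterization: with nu = mean(1-mean)/se^2 - 1,
#' alpha = mean * nu and beta = (1-mean) * nu, so the analytic mean and SD of
#' the returned distribution equal the inputs exactly.
#'
#' @param mean Mean probability/utility, in (0, 1).
#' @param se Standard error, with 0 < se^2 < mean(1-mean).
#' @return A `beta_spec`: list with elements `alpha` and `beta`.
#' @examples
#' beta_from_moments(0.0007, 0.0003)
#' @export
beta_from_moments <- function(mean, se) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop("mean must lie strictly inside (0, 1), got ", mean, call. = FALSE)
  }
  if (!is.numeric(se) || se <= 0) {
    stop("se must be > 0, got ", se, call. = FALSE)
  }
  if (se^2 >= mean * (1 - mean)) {
    stop("no beta distribution has mean ", mean, " and sd ", se,
         " (se^2 must be < mean*(1-mean))", call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  structure(list(alpha = mean * nu, beta = (1 - mean) * nu), class = "beta_spec")
}

#' Serialize a parameter set back to YAML
#'
#' Writes the primary configuration content (the cached life-table data is a
#' derived object and is dropped), so `load_param_set()` of the written file
#' round-trips field-for-field.
#'
#' @param p A `param_set`.
#' @param path Output file path. When `NULL`, the YAML text is returned.
#' @return `path` invisibly, or the YAML text when `path` is `NULL`.
#' @export
serialize_param_set <- function(p, path = NULL) {
  q <- unclass(p)
  q$structural$life_table_data <- NULL
  txt <- yaml::as.yaml(q, precision = 12L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.param_set <- function(x, ...) {
  s <- x$structural
  cat("<param_set> population:", x$population, "\n")
  cat("  horizon:", s$horizon_months, "months; discount:",
      s$annual_discount_rate * 100, "%/yr; WTP: NT$",
      format(s$wtp_threshold, big.mark = ","), "\n")
  cat("  replacement interval:", s$device_replacement_interval_months,
      "months; background mortality:", s$background_mortality_mode %||% "off", "\n")
  cat("  monthly mortality (ICD arm):",
      paste(x$mortality_icd$causes,
            vapply(x$mortality_icd$causes,
                   function(cz) x$mortality_icd[[cz]]$value, 0),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
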