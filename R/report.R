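# Report generation: base-case table in the published row layout, sensitivity
# reports, and a run manifest tying outputs to their inputs.

.usage_error <- function(...) {
  stop(structure(class = c("icdcea_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.write_manifest <- function(output_dir, command, config, seed = NULL, outputs) {
  manifest <- list(
    command = command,
    config = normalizePath(config),
    config_hash = rlang::hash(paste(readLines(config), collapse = "\n")),
    package_version = as.character(utils::packageVersion("icdcea")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = outputs
  )
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

# Table rows in the published base-case layout, for one population
.base_case_rows <- function(bc) {
  row <- function(variant, label, icd, no = NA_real_) {
    data.frame(variant = variant, quantity = label,
               icd_therapy = icd, no_icd_therapy = no)
  }
  out <- list()
  for (v in c("Undiscounted", "Discounted")) {
    k <- tolower(v)
    icd <- bc$icd[[k]]; no <- bc$no_icd[[k]]; ce <- bc$ce[[k]]
    out[[length(out) + 1L]] <- rbind(
      row(v, "Aggregated costs", icd$cost, no$cost),
      row(v, "Differential cost", ce$d_cost),
      row(v, "Effectiveness (life-years saved)", icd$life_years, no$life_years),
      row(v, "Effectiveness (QALY saved)", icd$qalys, no$qalys),
      row(v, "Differential effectiveness (QALY)", ce$d_qaly),
      row(v, "ICER (costs per QALY saved)", ce$icer)
    )
  }
  do.call(rbind, out)
}

.format_base_case <- function(rows) {
  fmt <- function(q, x) {
    ifelse(is.na(x), "",
           ifelse(grepl("cost|ICER", q),
                  paste0("NT$", format(round(x), big.mark = ",", trim = TRUE)),
                  sprintf("%.2f", x)))
  }
  transform(rows, icd_therapy = fmt(quantity, icd_therapy),
            no_icd_therapy = fmt(quantity, no_icd_therapy))
}

#' Base-case report command
#'
#' Loads and validates a configuration, runs both arms, and writes the
#' base-case results in the published row layout (`base_case.csv`, raw
#' numbers; `base_case.txt`, rendered with NT$ rounded to the nearest dollar
#' and effectiveness to 2 decimals) plus a run manifest.
#'
#' @param config Path to a model configuration file.
#' @param population Optional population label the config must match.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
cmd_base_case <- function(config, population = NULL, output_dir = ".") {
  if (missing(config) || is.null(config)) .usage_error("--config is required")
  p <- load_param_set(config, population)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  bc <- run_base_case(p)
  rows <- .base_case_rows(bc)
  csv <- file.path(output_dir, "base_case.csv")
  utils::write.csv(cbind(population = p$population, rows), csv, row.names = FALSE)
  txt <- file.path(output_dir, "base_case.txt")
  pretty <- .format_base_case(rows)
  writeLines(c(paste0(p$population, " base case scenario results"),
               utils::capture.output(print(pretty, row.names = FALSE))), txt)
  manifest <- .write_manifest(output_dir, "base-case", config,
                              outputs = basename(c(csv, txt)))
  invisible(list(base_case_csv = csv, base_case_txt = txt, manifest = manifest))
}

#' Sensitivity analysis command
#'
#' One-way mode writes the tornado table sorted by decreasing bar width
#' (`tornado.csv`); probabilistic mode writes the per-iteration draws
#' (`psa_draws.csv`), the summary (`psa_summary.csv`: mean, median, 95%
#' credible interval, fractions below the willingness-to-pay threshold and a
#' third of it) and the acceptability curve (`ceac.csv`). A manifest is
#' always written.
#'
#' @param config Path to a model configuration file.
#' @param population Optional population label the config must match.
#' @param mode `"owsa"` or `"psa"`.
#' @param seed Integer seed; required for `"psa"`.
#' @param n_iter PSA iterations (default 1000).
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
cmd_sensitivity <- function(config, population = NULL,
                            mode = c("owsa", "psa"), seed = NULL,
                            n_iter = 1000L, output_dir = ".") {
  if (missing(config) || is.null(config)) .usage_error("--config is required")
  mode <- match.arg(mode)
  p <- load_param_set(config, population)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if (mode == "owsa") {
    tn <- tornado(p)
    out$tornado <- file.path(output_dir, "tornado.csv")
    utils::write.csv(as.data.frame(tn), out$tornado, row.names = FALSE)
  } else {
    if (is.null(seed)) .usage_error("psa mode requires a seed")
    if (is.null(n_iter) || n_iter < 1) .usage_error("n_iter must be >= 1")
    psa <- run_psa(p, n_iter = n_iter, seed = seed)
    out$draws <- file.path(output_dir, "psa_draws.csv")
    utils::write.csv(psa$draws, out$draws, row.names = FALSE)
    s <- psa$summary
    out$summary <- file.path(output_dir, "psa_summary.csv")
    utils::write.csv(data.frame(
      statistic = c("n_iter", "n_ne_quadrant", "n_dominant", "n_dominated",
                    "cost_per_qaly_at_means", "mean_cost_per_qaly",
                    "median_cost_per_qaly", "cri95_lower", "cri95_upper",
                    "fraction_below_wtp", "fraction_below_wtp_third"),
      value = c(s$n_iter, s$n_ne, s$n_dominant, s$n_dominated,
                s$icer_at_means, s$mean, s$median, s$ci95[1], s$ci95[2],
                s$frac_below_wtp, s$frac_below_wtp_third)
    ), out$summary, row.names = FALSE)
    grid <- seq(0, 3 * p$structural$wtp_threshold, length.out = 61L)
    out$ceac <- file.path(output_dir, "ceac.csv")
    utils::write.csv(ceac(psa, grid), out$ceac, row.names = FALSE)
  }
  out$manifest <- .write_manifest(output_dir, paste0("sens-", mode), config,
                                  seed = seed,
                                  outputs = basename(unlist(out)))
  invisible(out)
}
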