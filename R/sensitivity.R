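# One-way (tornado) and probabilistic sensitivity analyses.

#' One-way sensitivity sweep of a single parameter
#'
#' Re-runs the full base-case pipeline at substituted values of one
#' parameter, everything else held at base case, and reports the discounted
#' ICER along the sweep. Parameter paths follow [param_set_path()], including
#' the `@scale` block-multiplier pseudo-paths used for the conventional
#' mortality / quality-of-life / cost axes.
#'
#' @param p A valid `param_set`.
#' @param parameter Dotted parameter path.
#' @param low,high End points of the sweep on the input scale (multipliers
#'   for `@scale` paths); must bracket the base value.
#' @param n_points Number of sweep points (>= 2).
#' @return A `tornado_entry`: the end-point ICERs, the bar width, and the
#'   full sweep series.
#' @export
one_way_sweep <- function(p, parameter, low, high, n_points = 2L) {
  if (low > high) stop("low must be <= high", call. = FALSE)
  base_val <- if (grepl("@scale$", parameter)) 1 else param_get_path(p, parameter)
  if (base_val < low || base_val > high) {
    stop("sweep range [", low, ", ", high, "] does not bracket the base value ",
         base_val, " of ", parameter, call. = FALSE)
  }
  values <- unique(sort(c(seq(low, high, length.out = max(2L, n_points)), base_val)))
  run_at <- function(val) {
    q <- param_set_path(p, parameter, val)
    viol <- validate_param_set(q)
    if (nrow(viol)) {
      stop("substituted value ", val, " for ", parameter,
           " violates: ", paste(viol$rule, collapse = "; "), call. = FALSE)
    }
    bc <- run_base_case(q)
    c(icer = bc$ce$discounted$icer, d_cost = bc$ce$discounted$d_cost,
      d_qaly = bc$ce$discounted$d_qaly)
  }
  series <- t(vapply(values, run_at, c(icer = 0, d_cost = 0, d_qaly = 0)))
  series <- data.frame(value = values, series)
  icer_low <- series$icer[1L]
  icer_high <- series$icer[nrow(series)]
  structure(list(parameter = parameter, base_value = base_val,
                 low = low, high = high,
                 icer_low = icer_low, icer_high = icer_high,
                 width = abs(icer_high - icer_low),
                 series = series),
            class = "tornado_entry")
}

#' Default one-way sensitivity axes
#'
#' The axes swept in the tornado analysis: age at implant, conventional
#' (no-ICD) mortality, device replacement period, quality of life, and event
#' costs, with the ranges stored in the packaged `owsa_axes.yaml`.
#'
#' @return Data frame with columns `label`, `parameter`, `low`, `high`.
#' @export
owsa_axes <- function() {
  path <- system.file("extdata", "owsa_axes.yaml", package = "icdcea",
                      mustWork = TRUE)
  ax <- yaml::read_yaml(path)
  do.call(rbind, lapply(ax$axes, function(a) {
    data.frame(label = a$label, parameter = a$parameter,
               low = a$low, high = a$high)
  }))
}

#' Tornado analysis over a set of one-way axes
#'
#' @param p A valid `param_set`.
#' @param axes Data frame as returned by [owsa_axes()] (the default).
#' @param n_points Sweep points per axis.
#' @return A `tornado` data frame (one row per axis, sorted by decreasing bar
#'   width) with the underlying `tornado_entry`s attached as an attribute.
#' @export
tornado <- function(p, axes = owsa_axes(), n_points = 2L) {
  entries <- lapply(seq_len(nrow(axes)), function(i) {
    one_way_sweep(p, axes$parameter[i], axes$low[i], axes$high[i], n_points)
  })
  out <- data.frame(
    label = axes$label, parameter = axes$parameter,
    low = axes$low, high = axes$high,
    icer_low = vapply(entries, `[[`, 0, "icer_low"),
    icer_high = vapply(entries, `[[`, 0, "icer_high"),
    width = vapply(entries, `[[`, 0, "width")
  )
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  structure(out, entries = entries, class = c("tornado", "data.frame"))
}

# canonical ordered list of PSA-sampled fields: (block, field) pairs
.psa_fields <- function(p) {
  fields <- list()
  for (arm in c("mortality_icd", "mortality_no_icd")) {
    for (cz in p[[arm]]$causes) fields[[length(fields) + 1L]] <- c(arm, cz)
  }
  for (ev in .EVENT_FIELDS) fields[[length(fields) + 1L]] <- c("events", ev)
  for (ut in c("annual_utility_well", "utility_complication_state")) {
    fields[[length(fields) + 1L]] <- c("utilities", ut)
  }
  fields
}

#' Draw one parameter set from its uncertainty distributions
#'
#' Every probability and utility that carries a beta distribution (Table-style
#' `value`/`se` pairs) is drawn from its method-of-moments beta; costs and
#' structural settings stay fixed. Mortality cause probabilities are drawn
#' independently and jointly redrawn in the (practically impossible) case
#' that they sum to 1 or more. Fields whose `se` is zero — or whose reported
#' moments admit no beta distribution — are held at their base value. Uses
#' the current RNG state; seed the caller for reproducibility.
#'
#' @param p A valid `param_set`.
#' @return A new `param_set` with sampled values.
#' @export
sample_param_set <- function(p) {
  draw <- function(fld) {
    if (is.null(fld$se) || fld$se <= 0) return(fld$value)
    if (fld$se^2 >= fld$value * (1 - fld$value)) return(fld$value)
    bs <- beta_from_moments(fld$value, fld$se)
    stats::rbeta(1L, bs$alpha, bs$beta)
  }
  q <- p
  for (f in .psa_fields(p)) {
    q[[f[1L]]][[f[2L]]]$value <- draw(p[[f[1L]]][[f[2L]]])
  }
  # joint rejection: keep cause-specific monthly deaths summing below 1
  for (arm in c("mortality_icd", "mortality_no_icd")) {
    repeat {
      tot <- sum(vapply(q[[arm]]$causes, function(cz) q[[arm]][[cz]]$value, 0))
      if (tot < 1) break
      for (cz in q[[arm]]$causes) q[[arm]][[cz]]$value <- draw(p[[arm]][[cz]])
    }
  }
  q
}

#' Probabilistic sensitivity analysis
#'
#' `n_iter` independent parameter draws, each run through both arms and the
#' discounted comparison. Cost-per-QALY percentile summaries (mean, median,
#' 95% credible interval) are computed over the iterations in the
#' north-east quadrant (both differentials positive), where the ratio is
#' order-meaningful; other quadrants are tallied separately. The summary also
#' carries `icer_at_means`, the cost per QALY at the PSA mean differentials
#' (mean incremental cost over mean incremental QALYs), the headline summary
#' of a probabilistic analysis. The fractions
#' below the willingness-to-pay threshold (and a third of it) count an
#' iteration as cost-effective when its net monetary benefit is positive.
#'
#' @param p A valid `param_set`.
#' @param n_iter Number of iterations (>= 1); 1000 in the base analysis.
#' @param seed Integer seed; mandatory, the analysis is fully reproducible
#'   from it.
#' @return A `psa_result` with the per-iteration draws and the summary.
#' @export
run_psa <- function(p, n_iter = 1000L, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (!is.numeric(n_iter) || n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  n_iter <- as.integer(n_iter)
  set.seed(seed)
  wtp <- p$structural$wtp_threshold
  dc <- dq <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    sp <- sample_param_set(p)
    icd <- run_arm(sp, "icd")
    no <- run_arm(sp, "no_icd")
    dc[i] <- icd$discounted$cost - no$discounted$cost
    dq[i] <- icd$discounted$qalys - no$discounted$qalys
  }
  ratio <- ifelse(dq > 0 & dc > 0, dc / dq, NA_real_)
  nmb <- wtp * dq - dc
  ne <- ratio[!is.na(ratio)]
  draws <- data.frame(iteration = seq_len(n_iter), d_cost = dc, d_qaly = dq,
                      cost_per_qaly = ratio, nmb = nmb)
  summary <- list(
    n_iter = n_iter, n_ne = length(ne),
    n_dominant = sum(dq > 0 & dc <= 0),
    n_dominated = sum(dq < 0 & dc >= 0),
    # cost per QALY at the PSA means: the expectation-based ICER, the stable
    # headline summary (the per-iteration ratio is strongly right-skewed)
    icer_at_means = mean(dc) / mean(dq),
    mean = mean(ne), median = stats::median(ne),
    ci95 = stats::quantile(ne, c(0.025, 0.975), names = FALSE),
    frac_below_wtp = mean(nmb > 0),
    frac_below_wtp_third = mean((wtp / 3) * dq - dc > 0)
  )
  structure(list(draws = draws, summary = summary, seed = seed,
                 n_iter = n_iter, wtp = wtp, population = p$population),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective (positive net monetary
#' benefit) as a function of the willingness-to-pay threshold.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Ascending vector of willingness-to-pay values (NT$/QALY).
#' @return Data frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"))
  if (!length(wtp_grid) || is.unsorted(wtp_grid)) {
    stop("wtp_grid must be non-empty and ascending", call. = FALSE)
  }
  prob <- vapply(wtp_grid, function(w) {
    mean(w * psa$draws$d_qaly - psa$draws$d_cost > 0)
  }, 0)
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat("<psa_result>", x$population, ":", x$n_iter, "iterations, seed", x$seed, "\n")
  cat(sprintf("  cost/QALY mean NT$%s  median NT$%s  95%% CrI [NT$%s, NT$%s]\n",
              format(round(s$mean), big.mark = ","),
              format(round(s$median), big.mark = ","),
              format(round(s$ci95[1]), big.mark = ","),
              format(round(s$ci95[2]), big.mark = ",")))
  cat(sprintf("  below WTP NT$%s: %.1f%%; below WTP/3: %.1f%%\n",
              format(x$wtp, big.mark = ","), 100 * s$frac_below_wtp,
              100 * s$frac_below_wtp_third))
  invisible(x)
}

#' @export
print.tornado_entry <- function(x, ...) {
  cat("<tornado_entry>", x$parameter, "\n")
  cat(sprintf("  range [%g, %g] (base %g): ICER %.0f -> %.0f, width %.0f\n",
              x$low, x$high, x$base_value, x$icer_low, x$icer_high, x$width))
  invisible(x)
}
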