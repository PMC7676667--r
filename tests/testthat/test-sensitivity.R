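# short horizons keep the re-run pipelines cheap; the economics of each test
# are unaffected by the truncation
short <- function(p, h = 180L) {
  p$structural$horizon_months <- h
  p
}

test_that("a degenerate sweep range returns the base-case ICER at both ends", {
  p <- short(pp15_config())
  base <- run_base_case(p)$ce$discounted$icer
  sw <- one_way_sweep(p, "costs.monthly_inpatient", 6828, 6828)
  expect_equal(sw$icer_low, base)
  expect_equal(sw$icer_high, base)
  expect_equal(sw$width, 0)
})

test_that("sweeping conventional sudden-cardiac mortality upward widens the QALY gap", {
  p <- short(pp15_config())
  sw <- one_way_sweep(p, "mortality_no_icd.sudden_cardiac.value",
                      0.0028, 0.006, n_points = 3L)
  expect_true(all(diff(sw$series$d_qaly) > 0))
  expect_true(all(diff(sw$series$icer) < 0))
})

test_that("a sweep outside the validated range is rejected with the bound", {
  p <- short(pp15_config())
  expect_error(one_way_sweep(p, "utilities.annual_utility_well", 0.5, 1.4),
               "\\[0, 1\\]")
  expect_error(one_way_sweep(p, "costs.monthly_inpatient", 100, 200),
               "bracket")
})

test_that("parameters without model influence give zero-width tornado bars", {
  p <- short(pp15_config())
  p$events$infection_initial$value <- 0
  p$events$infection_replacement$value <- 0
  sw <- one_way_sweep(p, "costs.infection", 0, 2e6, n_points = 2L)
  expect_equal(sw$width, 0)
})

test_that("parameter sampling is seed-deterministic and respects zero variance", {
  p <- pp15_config()
  set.seed(5); a <- sample_param_set(p)
  set.seed(5); b <- sample_param_set(p)
  expect_identical(param_fingerprint(a), param_fingerprint(b))
  expect_false(identical(param_fingerprint(a), param_fingerprint(p)))

  frozen <- p
  for (blk in c("mortality_icd", "mortality_no_icd")) {
    for (cz in frozen[[blk]]$causes) frozen[[blk]][[cz]]$se <- 0
  }
  for (ev in names(frozen$events)) frozen$events[[ev]]$se <- 0
  frozen$utilities$annual_utility_well$se <- 0
  frozen$utilities$utility_complication_state$se <- 0
  expect_identical(param_fingerprint(sample_param_set(frozen)),
                   param_fingerprint(frozen))
})

test_that("sampled fields reproduce their reported moments", {
  p <- pp15_config()
  set.seed(31)
  draws <- replicate(4000, sample_param_set(p)$mortality_icd$sudden_cardiac$value)
  m <- 0.0007; s <- 0.0003
  expect_lt(abs(mean(draws) - m), 3 * s / sqrt(4000))
  expect_lt(abs(sd(draws) - s), 3 * s / sqrt(2 * 4000))
})

test_that("fields without an admissible beta distribution stay fixed", {
  p <- pp15_config()
  p$events$shock_continue$se <- 0.9   # se^2 >= mean(1-mean): no valid beta
  set.seed(8)
  s <- sample_param_set(p)
  expect_identical(s$events$shock_continue$value, p$events$shock_continue$value)
  expect_false(identical(s$events$shock_discontinue$value,
                         p$events$shock_discontinue$value))
})

test_that("PSA is reproducible and collapses to the base case without variance", {
  p <- short(pp15_config(), 120L)
  a <- run_psa(p, n_iter = 4L, seed = 77)
  b <- run_psa(p, n_iter = 4L, seed = 77)
  expect_identical(a$draws, b$draws)

  frozen <- p
  for (blk in c("mortality_icd", "mortality_no_icd")) {
    for (cz in frozen[[blk]]$causes) frozen[[blk]][[cz]]$se <- 0
  }
  for (ev in names(frozen$events)) frozen$events[[ev]]$se <- 0
  frozen$utilities$annual_utility_well$se <- 0
  frozen$utilities$utility_complication_state$se <- 0
  one <- run_psa(frozen, n_iter = 2L, seed = 1)
  base <- run_base_case(frozen)$ce$discounted$icer
  expect_equal(one$summary$mean, base)
  expect_equal(one$summary$median, base)
  expect_equal(unname(one$summary$ci95), c(base, base))
  expect_equal(one$summary$icer_at_means, base)

  expect_error(run_psa(p, n_iter = 4L), "seed")
  expect_error(run_psa(p, n_iter = 0L, seed = 3), "n_iter")
})

test_that("the acceptability curve is consistent with the PSA summary", {
  p <- short(pp15_config(), 120L)
  psa <- run_psa(p, n_iter = 30L, seed = 12)
  wtp <- p$structural$wtp_threshold
  curve <- ceac(psa, c(0, wtp / 3, wtp, 5 * wtp))
  expect_equal(curve$prob_cost_effective[1], mean(psa$draws$d_cost < 0))
  expect_equal(curve$prob_cost_effective[3], psa$summary$frac_below_wtp)
  expect_equal(curve$prob_cost_effective[2], psa$summary$frac_below_wtp_third)
  if (all(psa$draws$d_qaly > 0)) {
    expect_true(all(diff(curve$prob_cost_effective) >= 0))
    expect_equal(curve$prob_cost_effective[4], mean(psa$draws$d_qaly > 0))
  }
  expect_error(ceac(psa, numeric(0)), "ascending|non-empty")
})
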