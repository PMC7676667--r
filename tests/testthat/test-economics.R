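test_that("discount factors follow the compound-in-months closed form", {
  expect_equal(discount_factor(0.01375, 0), 1)
  expect_equal(discount_factor(0.01375, 12), 1 / 1.01375)
  expect_equal(discount_factor(0.01375, 18), 1.01375^(-1.5))
  expect_equal(discount_factor(0, 240), 1)
  expect_error(discount_factor(0.01375, -1), "month")
  expect_error(discount_factor(1.2, 10), "annual_rate")
})

test_that("maintenance costs accrue on alive occupancy", {
  # immortal no-ICD cohort, no discounting: exactly 420 months of upkeep
  p <- inert_param_set()
  tr <- run_cohort_trace(p, "no_icd")
  cc <- accrue_costs(tr, p = p)
  expect_equal(cc$undiscounted$total, 420 * (6828 + 858))
  expect_equal(cc$discounted$total, cc$undiscounted$total)

  # zero cost inputs give zero totals whatever the trace
  p0 <- inert_param_set(costs_on = FALSE)
  cc0 <- accrue_costs(run_cohort_trace(p0, "icd"), p = p0)
  expect_equal(cc0$undiscounted$total, 0)
})

test_that("a short trace reproduces a hand accrual", {
  # two cycles, 90% monthly mortality, no events: implant plus upkeep on the
  # explicitly computed survivor fractions
  p <- toy_param_set(mortality_icd = c(0.9, 0, 0, 0), event_probs = FALSE,
                     shock_continue = 0, shock_discontinue = 0,
                     horizon = 2L, discount = 0)
  tr <- run_cohort_trace(p, "icd")
  cc <- accrue_costs(tr, p = p)
  s1 <- (1 - 0.0002) * 0.1
  s2 <- s1 * 0.1
  expect_equal(cc$undiscounted$total, 633678 + (s1 + s2) * 7686)
})

test_that("QALY accrual follows utilities and the alive fraction", {
  p <- inert_param_set(utility_well = 1)
  eff <- accrue_qalys(run_cohort_trace(p, "no_icd"), p)
  expect_equal(eff$undiscounted$qalys, 35)
  expect_equal(eff$undiscounted$life_years, 35)

  p0 <- inert_param_set(utility_well = 0)
  eff0 <- accrue_qalys(run_cohort_trace(p0, "no_icd"), p0)
  expect_equal(eff0$undiscounted$qalys, 0)
  expect_equal(eff0$undiscounted$life_years, 35)
})

test_that("discounted totals never exceed undiscounted and QALYs never exceed LYs", {
  for (p in list(pp_config(), pp15_config())) {
    for (arm in c("icd", "no_icd")) {
      r <- run_arm(p, arm)
      expect_lte(r$discounted$cost, r$undiscounted$cost)
      expect_lte(r$discounted$qalys, r$undiscounted$qalys)
      expect_lte(r$discounted$life_years, r$undiscounted$life_years)
      expect_lte(r$discounted$qalys, r$discounted$life_years)
      expect_lte(r$undiscounted$qalys, r$undiscounted$life_years)
    }
  }
})

test_that("cost breakdown categories sum to the total", {
  for (arm in c("icd", "no_icd")) {
    r <- run_arm(pp15_config(), arm)
    for (v in c("discounted", "undiscounted")) {
      expect_equal(sum(r[[v]]$cost_breakdown), r[[v]]$cost, tolerance = 1e-9)
    }
  }
})

test_that("totals are non-increasing in the discount rate", {
  p <- toy_param_set()
  rates <- c(0, 0.01375, 0.05)
  runs <- lapply(rates, function(r) {
    p$structural$annual_discount_rate <- r
    run_arm(p, "icd")$discounted
  })
  for (q in c("cost", "qalys", "life_years")) {
    vals <- vapply(runs, `[[`, 0, q)
    expect_true(all(diff(vals) < 0))
  }
})

test_that("arm comparison computes ICER, dominance and NMB", {
  mk <- function(cost, qaly) {
    structure(list(arm = "icd", population = "1.5PP",
                   discounted = list(cost = cost, qalys = qaly, life_years = qaly),
                   undiscounted = list(cost = cost, qalys = qaly, life_years = qaly),
                   fingerprint = "x"),
              class = "arm_result")
  }
  ce <- compare_arms(mk(1067172 + 100, 1.51 + 2), mk(100, 2), wtp = 2100000)
  expect_equal(ce$discounted$icer, 1067172 / 1.51, tolerance = 1e-12)
  expect_equal(ce$discounted$nmb, 2100000 * 1.51 - 1067172)

  same <- compare_arms(mk(5, 1), mk(5, 1), wtp = 2100000)
  expect_equal(same$discounted$d_cost, 0)
  expect_equal(same$discounted$d_qaly, 0)
  expect_true(is.na(same$discounted$icer))
  expect_equal(same$discounted$nmb, 0)

  dom <- compare_arms(mk(99, 2), mk(100, 1), wtp = 2100000)
  expect_identical(dom$discounted$status, "dominant")
  expect_true(is.na(dom$discounted$icer))
  dominated <- compare_arms(mk(100, 1), mk(99, 2), wtp = 2100000)
  expect_identical(dominated$discounted$status, "dominated")
})

test_that("NMB sign agrees with the ICER-WTP comparison when dQALY > 0", {
  p <- pp15_config()
  bc <- run_base_case(p)
  ce <- bc$ce$discounted
  expect_gt(ce$d_qaly, 0)
  expect_identical(ce$nmb > 0, ce$icer < p$structural$wtp_threshold)
})

test_that("equalized arms produce an exactly zero differential", {
  p <- toy_param_set(event_probs = FALSE, shock_continue = 0,
                     shock_discontinue = 0, op_death = 0)
  p$mortality_icd <- p$mortality_no_icd
  p$costs$implant_initial <- 0
  p$costs$implant_replacement <- 0
  bc <- run_base_case(p)
  expect_equal(bc$ce$discounted$d_cost, 0)
  expect_equal(bc$ce$discounted$d_qaly, 0)
  expect_equal(bc$ce$discounted$nmb, 0)
})
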