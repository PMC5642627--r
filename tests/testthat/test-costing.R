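test_that("vial counts round up to whole opened vials", {
  expect_identical(vials_needed(250, 1.72, 100), 5L)   # 430 mg
  expect_identical(vials_needed(400, 1.72, 100), 7L)   # 688 mg
  expect_identical(vials_needed(0, 1.72, 100), 0L)
  expect_error(vials_needed(250, 1.72, 0), "vial_size")
})

test_that("PAP calendar pays the lead months then follows the repeat blocks", {
  sch2 <- pap_schedule(cycles_per_month = 2)   # integer mapping
  expect_equal(pap_paid_fraction(0, sch2), 1)  # first cycle is payer-paid
  expect_equal(pap_paid_fraction(0:3, sch2), rep(1, 4))   # months 1-2
  expect_equal(pap_paid_fraction(4:7, sch2), rep(0, 4))   # months 3-4 donated
  # repeating pay-1/donate-3: months 5, 9, ... paid
  expect_equal(pap_paid_fraction(8:15, sch2), c(1, 1, 0, 0, 0, 0, 0, 0))
  # no donated months at all collapses to always-paid
  all_paid <- pap_schedule(lead_free_months = 0, repeat_free_months = 0,
                           cycles_per_month = 2)
  expect_equal(pap_paid_fraction(0:20, all_paid), rep(1, 21))
  # repeat_pay_months = 0: donation continues indefinitely after the lead
  donate <- pap_schedule(repeat_pay_months = 0, cycles_per_month = 2)
  expect_equal(pap_paid_fraction(8:40, donate), rep(0, 33))
})

test_that("fractional month mapping yields partial paid cycles at boundaries", {
  sch <- pap_schedule(cycles_per_month = 26.0893 / 12)
  p <- pap_paid_fraction(0:12, sch)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[1], 1)                     # fully inside paid month 1
  boundary <- p[p > 0 & p < 1]
  expect_gt(length(boundary), 0)            # month edges split a cycle
  # paid month-time over the four lead months totals the two paid months
  lead_cycles <- 0:(floor(4 * sch$cycles_per_month) - 1)
  expect_equal(sum(pap_paid_fraction(lead_cycles, sch)) / sch$cycles_per_month,
               2, tolerance = 1e-6)
})

test_that("cetuximab cycle cost follows the dosing schedule and PAP", {
  d <- dosing_rule(); cb <- cost_book()
  expect_equal(cetuximab_cycle_cost(0, d, cb), 12 * 637.4)  # 7 + 5 vials
  expect_equal(cetuximab_cycle_cost(3, d, cb), 10 * 637.4)
  sch2 <- pap_schedule(cycles_per_month = 2)
  expect_equal(cetuximab_cycle_cost(5, d, cb, pap_enabled = TRUE,
                                    schedule = sch2), 0)    # donated month
  expect_equal(cetuximab_cycle_cost(4, d, cb, basis = "per_cycle_price"),
               637.4)
})

test_that("screening load spreads tests over wild-type patients", {
  expect_equal(screening_cost_per_treated_patient(176.9, 0.41),
               176.9 / 0.59, tolerance = 1e-12)
  expect_equal(round(screening_cost_per_treated_patient(176.9, 0.41), 2),
               299.83)
  expect_equal(screening_cost_per_treated_patient(176.9, 0), 176.9)
  expect_equal(screening_cost_per_treated_patient(100, 0.5), 200)
  expect_error(screening_cost_per_treated_patient(176.9, 1), "prevalence")
})

test_that("strategy constructor enforces arm-specific rules", {
  expect_error(strategy_spec("control", pap_enabled = TRUE), "control")
  expect_error(strategy_spec("cetuximab", sae_probabilities = c(rash = 2)),
               "probabilities")
  s <- strategy_spec("cetuximab", pap_enabled = TRUE)
  expect_true(s$screening_applied)
})

test_that("cost accrual composes components and scales with coverage", {
  cfg <- model_config()
  tr <- build_trace(ctl_pfs(), ctl_os(), cfg)
  cb0 <- cost_book(0, 0, 0, 0, 0, c(vomiting = 0, rash_acne = 0, fatigue = 0,
                                    neutropenia = 0, diarrhea = 0))
  ctl <- strategy_spec("control")
  expect_equal(accrue_costs(tr, ctl, cb0)$total, 0)

  # one 14-day cycle, everyone alive and progression-free, no discounting:
  # exactly one FOLFIRI cycle is charged
  cfg1 <- model_config(horizon_years = 15 / 365.25, discount_rate_annual = 0)
  flat <- weibull_curve(1e-14, 1, "year")
  tr1 <- build_trace(flat, flat, cfg1)
  one <- strategy_spec("control", coverage_fraction = 1,
                       salvage_cycles_cap = 0)
  expect_equal(accrue_costs(tr1, one, cost_book())$total, 2050.5,
               tolerance = 1e-9)

  # coverage scales the total exactly linearly
  full <- strategy_spec("cetuximab", pap_enabled = TRUE, coverage_fraction = 1)
  sixty <- strategy_spec("cetuximab", pap_enabled = TRUE,
                         coverage_fraction = 0.6)
  trx <- build_trace(cet_pfs(), cet_os(), cfg)
  t_full <- accrue_costs(trx, full, cost_book())$total
  expect_equal(accrue_costs(trx, sixty, cost_book())$total, 0.6 * t_full,
               tolerance = 1e-12)
})

test_that("cost totals are monotone in every unit cost", {
  cfg <- model_config()
  trx <- build_trace(cet_pfs(), cet_os(), cfg)
  strat <- strategy_spec("cetuximab",
                         sae_probabilities = c(vomiting = 0.1, diarrhea = 0.05))
  set.seed(7)
  for (rep in 1:3) {
    base_vals <- runif(6, 100, 3000)
    mk_book <- function(v) cost_book(v[1], v[2], v[3], v[4], v[5],
                                     c(vomiting = v[6], rash_acne = 1,
                                       fatigue = 1, neutropenia = 1,
                                       diarrhea = 1))
    t0 <- accrue_costs(trx, strat, mk_book(base_vals))$total
    for (i in seq_along(base_vals)) {
      up <- base_vals; up[i] <- up[i] * 1.5
      expect_gte(accrue_costs(trx, strat, mk_book(up))$total, t0)
    }
  }
})

test_that("the PAP lowers cetuximab spend once treatment outlives the lead", {
  cfg <- model_config()
  trx <- build_trace(cet_pfs(), cet_os(), cfg)
  no_pap <- strategy_spec("cetuximab", pap_enabled = FALSE)
  pap <- strategy_spec("cetuximab", pap_enabled = TRUE)
  cb <- cost_book()
  expect_lt(accrue_costs(trx, pap, cb)$total,
            accrue_costs(trx, no_pap, cb)$total)
})

test_that("the cost ledger accounts for the discounted total", {
  cfg <- model_config()
  trx <- build_trace(cet_pfs(), cet_os(), cfg)
  strat <- strategy_spec("cetuximab", pap_enabled = TRUE)
  acc <- accrue_costs(trx, strat, cost_book())
  expect_named(acc$ledger, c("cycle", "component", "undiscounted",
                             "discounted"))
  expect_setequal(unique(acc$ledger$component),
                  c("folfiri", "cetuximab", "salvage", "terminal",
                    "screening_sae"))
  expect_equal(sum(acc$ledger$discounted) * strat$coverage_fraction,
               acc$total, tolerance = 1e-12)
  # ledger can be skipped without changing the total
  expect_equal(accrue_costs(trx, strat, cost_book(),
                            keep_ledger = FALSE)$total, acc$total)
})
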