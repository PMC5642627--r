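make_legs <- function() {
  ps <- default_paramset()
  run_base_case(ps)
}

test_that("QALYs reduce to life-years at unit utility and vanish at zero", {
  tr <- build_trace(ctl_pfs(), ctl_os(), model_config())
  ones <- utility_book(1, 1, 1)
  expect_equal(qalys(tr, "control", ones), state_years(tr, "overall"),
               tolerance = 1e-12)
  zeros <- utility_book(0, 0, 0)
  expect_equal(qalys(tr, "control", zeros), 0)
  expect_lte(qalys(tr, "control"), state_years(tr, "overall"))
})

test_that("QALYs match the aggregate utility identity within discount drift", {
  tr <- build_trace(ctl_pfs(), ctl_os(), model_config())
  ub <- utility_book()
  q <- qalys(tr, "control", ub)
  pf <- state_years(tr, "pf")
  ly <- state_years(tr, "overall")
  approx <- ub$u_pfs * pf + ub$u_pd_chemo * (ly - pf)
  expect_equal(q, approx, tolerance = 0.02)
})

test_that("the cetuximab arm blends its progressed-disease utility", {
  tr <- build_trace(cet_pfs(), cet_os(), model_config())
  lo <- utility_book(0.85, 0.24, 0.68, 0)
  hi <- utility_book(0.85, 0.24, 0.68, 1)
  mid <- utility_book(0.85, 0.24, 0.68, 0.5)
  q0 <- qalys(tr, "cetuximab", lo); q1 <- qalys(tr, "cetuximab", hi)
  expect_equal(qalys(tr, "cetuximab", mid), (q0 + q1) / 2, tolerance = 1e-12)
  expect_equal(q0, qalys(tr, "control", lo))  # f = 0 is pure chemo utility
})

test_that("ICER arithmetic on the published cells matches the printed ratio", {
  a <- list(cost = 47754, qaly = 1.593, total_ly = 2.796)
  b <- list(cost = 30668, qaly = 0.963, total_ly = 2.066)
  inc <- icer(a, b)
  expect_equal(inc$icer_per_qaly, (47754 - 30668) / (1.593 - 0.963))
  # printed 27,145 was computed from unrounded cells; rounded cells get
  # within 0.1% of it
  expect_equal(inc$icer_per_qaly, 27145, tolerance = 1e-3)
})

test_that("dominance is flagged instead of a ratio", {
  base <- list(cost = 100, qaly = 1, total_ly = 2)
  same <- icer(base, base)
  expect_identical(same$dominance, "none")
  expect_true(is.na(same$icer_per_qaly))
  better_cheaper <- icer(list(cost = 50, qaly = 2, total_ly = 3), base)
  expect_identical(better_cheaper$dominance, "intervention_dominates")
  worse_dearer <- icer(list(cost = 150, qaly = 0.5, total_ly = 1), base)
  expect_identical(worse_dearer$dominance, "comparator_dominates")
})

test_that("net monetary benefit is linear and consistent with the ICER rule", {
  leg <- list(cost = 30668, qaly = 0.963)
  expect_equal(net_monetary_benefit(leg, 0), -30668)
  expect_equal(net_monetary_benefit(leg, 22200), 22200 * 0.963 - 30668)
  expect_equal(round(net_monetary_benefit(leg, 22200), 1), -9289.4)
  # NMB(intervention) > NMB(comparator) <=> ICER < threshold when dq > 0
  set.seed(3)
  for (i in 1:20) {
    b <- list(cost = runif(1, 1e4, 3e4), qaly = runif(1, 0.5, 1.2),
              total_ly = 1.5)
    a <- list(cost = b$cost + runif(1, 1e3, 3e4),
              qaly = b$qaly + runif(1, 0.1, 0.9), total_ly = 2)
    th <- runif(1, 0, 5e4)
    ratio <- icer(a, b)$icer_per_qaly
    expect_identical(net_monetary_benefit(a, th) > net_monetary_benefit(b, th),
                     ratio < th)
  }
})

test_that("rescaling the currency rescales the ICER exactly", {
  bc <- make_legs()
  inc <- bc$inc_no_pap
  scaled_icer <- icer(
    list(cost = 7 * bc$cetux_no_pap$cost, qaly = bc$cetux_no_pap$qaly,
         total_ly = bc$cetux_no_pap$total_ly),
    list(cost = 7 * bc$control$cost, qaly = bc$control$qaly,
         total_ly = bc$control$total_ly))
  expect_equal(scaled_icer$icer_per_qaly, 7 * inc$icer_per_qaly,
               tolerance = 1e-12)
  # a one-off added to both legs cancels out of the increment only when
  # applied to both
  both <- icer(
    list(cost = bc$cetux_no_pap$cost + 500, qaly = bc$cetux_no_pap$qaly,
         total_ly = bc$cetux_no_pap$total_ly),
    list(cost = bc$control$cost + 500, qaly = bc$control$qaly,
         total_ly = bc$control$total_ly))
  expect_equal(both$icer_per_qaly, inc$icer_per_qaly, tolerance = 1e-9)
  one <- icer(
    list(cost = bc$cetux_no_pap$cost + 500, qaly = bc$cetux_no_pap$qaly,
         total_ly = bc$cetux_no_pap$total_ly),
    list(cost = bc$control$cost, qaly = bc$control$qaly,
         total_ly = bc$control$total_ly))
  expect_gt(one$icer_per_qaly, inc$icer_per_qaly)
})
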