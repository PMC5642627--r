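test_that("survival function has the Weibull closed forms and limits", {
  cv <- ctl_pfs()
  expect_identical(survival_at(cv, 0), 1)
  # gamma = 1 collapses to the exponential
  ex <- weibull_curve(0.00267, 1, "cycle_14d")
  expect_equal(survival_at(ex, 14 / 365.25), exp(-0.00267))
  # strictly decreasing while above underflow, [0, 1], vanishing tail
  t <- seq(0, 5, length.out = 200)
  s <- survival_at(cv, t)
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 0 & s <= 1))
  expect_lt(survival_at(cv, 1e3), 1e-12)
  expect_error(survival_at(cv, -1), "must be finite and >= 0")
})

test_that("survival is monotone nonincreasing for random valid curves", {
  set.seed(11)
  for (i in 1:25) {
    cv <- weibull_curve(exp(runif(1, -7, 1)), runif(1, 0.3, 4),
                        sample(c("day", "week", "cycle_14d", "month", "year"), 1))
    s <- survival_at(cv, sort(runif(50, 0, 30)))
    expect_true(all(diff(s) <= 0))
  }
})

test_that("median agrees with a bisection oracle and obeys scaling laws", {
  cv <- ctl_pfs()
  med <- median_time(cv)
  expect_equal(survival_at(cv, med), 0.5, tolerance = 1e-10)
  expect_equal(med, bisect_survival(cv, 0.5), tolerance = 1e-8)
  expect_equal(median_time(weibull_curve(log(2), 1, "year")), 1)
  # doubling the scale halves the exponential median
  expect_equal(median_time(weibull_curve(0.4, 1, "year")),
               2 * median_time(weibull_curve(0.8, 1, "year")))
})

test_that("restricted mean matches exponential and step-sum oracles", {
  ex <- weibull_curve(log(2), 1, "year")
  expect_equal(restricted_mean(ex, 1000, 0), 1 / log(2), tolerance = 1e-6)
  # discounting shrinks the area for any curve
  cv <- ctl_pfs()
  expect_lt(restricted_mean(cv, 10, 0.05), restricted_mean(cv, 10, 0))
  # 14-day trapezoid step-sum oracle
  dt <- 14 / 365.25
  grid <- survival_at(cv, seq(0, 10, by = dt))
  steps <- sum((grid[-1] + grid[-length(grid)]) / 2) * dt
  expect_equal(restricted_mean(cv, 10, 0), steps, tolerance = 5e-3)
  expect_error(restricted_mean(cv, -1), "horizon")
  expect_error(restricted_mean(cv, 10, 1.2), "discount_rate")
})

test_that("long-horizon undiscounted mean recovers the Gamma closed form", {
  for (gam in c(0.5, 1, 1.9, 3, 4)) {
    cv <- weibull_curve(0.35, gam, "year")
    exact <- 0.35^(-1 / gam) * gamma(1 + 1 / gam)
    expect_equal(restricted_mean(cv, 1e4, 0), exact, tolerance = 1e-3)
  }
})

test_that("per-cycle event probabilities behave like the hazard", {
  ex <- weibull_curve(0.00267, 1, "cycle_14d")
  p <- per_cycle_event_prob(ex, 0:9)
  expect_equal(p, rep(1 - exp(-0.00267), 10))   # memoryless
  # increasing hazard for shape > 1
  p2 <- per_cycle_event_prob(ctl_pfs(), 0:9)
  expect_true(all(diff(p2) > 0))
  # product identity: 1 - prod(1 - p_k) = 1 - S(t_K)
  K <- 40
  pk <- per_cycle_event_prob(ctl_pfs(), 0:(K - 1))
  expect_equal(1 - prod(1 - pk),
               1 - survival_at(ctl_pfs(), K * 14 / 365.25), tolerance = 1e-10)
  # underflowed survival gives an absorbing cycle
  expect_message(pu <- per_cycle_event_prob(ctl_pfs(), 5000), "underflow")
  expect_equal(pu, 1)
})

test_that("rescaling to a target median is exact and idempotent", {
  cv <- cet_os()
  same <- rescale_to_median(cv, median_time(cv))
  expect_equal(same$scale, cv$scale, tolerance = 1e-12)
  halved <- rescale_to_median(weibull_curve(0.2, 1, "year"), 2 * log(2) / 0.2)
  expect_equal(halved$scale, 0.1, tolerance = 1e-12)
  for (target in c(0.3, 1.7, 6)) {
    rs <- rescale_to_median(cv, target)
    expect_equal(survival_at(rs, target), 0.5, tolerance = 1e-12)
    expect_equal(rs$shape, cv$shape)
  }
  expect_error(rescale_to_median(cv, -2), "positive")
})

test_that("curve and book constructors validate their inputs", {
  expect_error(weibull_curve(-1, 2), "scale")
  expect_error(weibull_curve(1, 0), "shape")
  expect_error(weibull_curve(1, 1, "fortnight"), "arg")
  expect_error(curve_book(ctl_pfs(), ctl_os(), cet_pfs(), "no"),
               "weibull_curve")
  bk <- curve_book(ctl_pfs(), cet_pfs(), ctl_os(), cet_os())
  expect_named(bk, c("pfs_control", "pfs_cetuximab", "os_control",
                     "os_cetuximab"))
})
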