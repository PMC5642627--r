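test_that("triangular draws stay in range and recover the closed-form mean", {
  set.seed(101)
  x <- rtriangular(1e5, 1083, 2050.5, 3018)
  expect_true(all(x >= 1083 & x <= 3018))
  tri_mean <- (1083 + 2050.5 + 3018) / 3
  tri_sd <- sqrt((1083^2 + 2050.5^2 + 3018^2 - 1083 * 2050.5 -
                    1083 * 3018 - 2050.5 * 3018) / 18)
  expect_lt(abs(mean(x) - tri_mean), 3 * tri_sd / sqrt(1e5))
  # degenerate mode at an endpoint still samples
  y <- rtriangular(1e4, 318.7, 637.4, 637.4)
  expect_true(all(y >= 318.7 & y <= 637.4))
})

test_that("utility betas recover the 25%-of-mean standard deviation", {
  spec <- param_spec("u_pfs", 0.85, 0.68, 1, "beta_se25", "utility")
  set.seed(55)
  x <- sample_param(spec, 1e5)
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(mean(x), 0.85, tolerance = 3 * 0.2125 / sqrt(1e5) / 0.85)
  # empirical sd close to 0.25 * 0.85 = 0.2125 (3 se of the sd estimate)
  se_sd <- 0.2125 / sqrt(2 * (1e5 - 1))
  expect_lt(abs(sd(x) - 0.2125), 10 * se_sd)
})

test_that("infeasible beta moments fall back to a range-fit beta", {
  # sd = 0.25 * 0.98 is infeasible for a mean-0.98 beta on [0, 1]
  spec <- param_spec("u_big", 0.98, 0.9, 1, "beta_se25", "utility")
  set.seed(8)
  expect_message(x <- sample_param(spec, 1e4), "range-fit")
  expect_true(all(x >= 0.9 & x <= 1))
})

test_that("fixed specs return the base value", {
  spec <- param_spec("median_os", 2.5, 1, 3, "fixed", "median")
  expect_identical(sample_param(spec, 5), rep(2.5, 5))
})

test_that("one-way bars are zero-width at degenerate ranges", {
  ps <- default_paramset()
  spec <- param_spec("folfiri_per_cycle", 2050.5, 2050.5, 2050.5,
                     "triangular", "cost")
  row <- one_way(spec, ps)
  expect_equal(row$width, 0)
  expect_equal(row$icer_low, row$icer_base)
})

test_that("ICER rises with the cetuximab price and the tornado ranks sensibly", {
  ps <- default_paramset()
  spec <- param_specs(ps)$cetuximab_per_100mg
  row <- one_way(spec, ps)
  expect_lt(row$icer_low, row$icer_base)
  expect_gte(row$icer_high, row$icer_base)
  tor <- run_tornado(ps)
  expect_true(all(diff(tor$width) <= 0))
  # the cetuximab-arm OS median out-weighs every cost parameter
  cost_names <- names(ps$cost_params)
  expect_gte(tor$width[tor$parameter == "median_os_cetuximab"],
             max(tor$width[tor$parameter %in% cost_names]))
})

test_that("PSA is bit-reproducible and parameter substreams are independent", {
  ps <- default_paramset()
  a <- run_psa(ps, 40, seed = 9)
  b <- run_psa(ps, 40, seed = 9)
  expect_identical(a$draws, b$draws)
  c_ <- run_psa(ps, 40, seed = 10)
  expect_false(identical(a$draws, c_$draws))
  # substream seeds do not depend on parameter position
  expect_identical(substream_seed(9, "u_pfs"), substream_seed(9, "u_pfs"))
  expect_false(substream_seed(9, "u_pfs") == substream_seed(9, "u_pd_chemo"))
  expect_error(run_psa(ps, 0), "positive")
})

test_that("PSA means approach the base case as distributions degenerate", {
  ps <- default_paramset()
  # collapse every range onto its base value
  for (nm in names(ps$cost_params))
    ps$cost_params[[nm]]$low <- ps$cost_params[[nm]]$high <-
      ps$cost_params[[nm]]$base
  for (nm in names(ps$utility_params)) {
    ps$utility_params[[nm]]$low <- ps$utility_params[[nm]]$high <-
      ps$utility_params[[nm]]$base
  }
  ps$proportion_params$ras_prevalence$low <-
    ps$proportion_params$ras_prevalence$high <-
    ps$proportion_params$ras_prevalence$base
  ps$bsa_param$low <- ps$bsa_param$high <- ps$bsa_param$base
  bc <- run_base_case(ps)
  psa <- run_psa(ps, 3, seed = 4)
  expect_equal(mean(psa$draws$cost_cetuximab), bc$cetux_pap$cost,
               tolerance = 1e-9)
  expect_equal(mean(psa$draws$cost_control), bc$control$cost,
               tolerance = 1e-9)
  expect_equal(mean(psa$draws$delta_qaly), bc$inc_pap$delta_qaly,
               tolerance = 1e-9)
})

test_that("CEAC is monotone, complementary, and anchored at its limits", {
  ps <- default_paramset()
  psa <- run_psa(ps, 200, seed = 12)
  grid <- seq(0, 1e5, by = 5000)
  cc <- ceac(psa, grid)
  expect_equal(cc$p_cetuximab + cc$p_control, rep(1, nrow(cc)))
  if (all(psa$draws$delta_qaly > 0)) {
    expect_true(all(diff(cc$p_cetuximab) >= 0))
  }
  expect_equal(cc$p_cetuximab[1], mean(psa$draws$delta_cost <= 0))
  expect_equal(ceac(psa, 1e9)$p_cetuximab,
               mean(psa$draws$delta_qaly > 0) +
                 mean(psa$draws$delta_qaly == 0 & psa$draws$delta_cost <= 0))
  expect_error(ceac(psa, numeric(0)), "empty")
})
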