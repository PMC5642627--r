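# curves of the shipped base case, constructed in code so unit tests do not
# depend on the YAML fixture being loadable
ctl_pfs <- function() weibull_curve(0.00267, 1.89552, "cycle_14d", "PFS control")
ctl_os  <- function() weibull_curve(0.00540, 1.53841, "month", "OS control")
cet_pfs <- function() weibull_curve(0.00195, 1.52888, "week", "PFS cetuximab")
cet_os  <- function() weibull_curve(0.00324, 1.26410, "cycle_14d", "OS cetuximab")

# bisection root of S(t) = p, independent of the closed-form median
bisect_survival <- function(curve, p, lower = 0, upper = 200, tol = 1e-12) {
  f <- function(t) survival_at(curve, t) - p
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) lower <- mid else upper <- mid
    if (upper - lower < tol) break
  }
  (lower + upper) / 2
}

# published base-case cells used by the reproduction checks
published_cells <- function() {
  list(control = list(cost = 30668, pf_ly = 0.795, total_ly = 2.066, qaly = 0.963),
       cetux_no_pap = list(cost = 47754, pf_ly = 0.944, total_ly = 2.796, qaly = 1.593),
       cetux_pap = list(cost = 39511),
       d_cost_no_pap = 17086, d_cost_pap = 8843, d_qaly = 0.63,
       d_pf_ly = 0.149, icer_qaly_pap = 14049, icer_qaly_no_pap = 27145,
       icer_ly_pap = 12107, threshold = 22200)
}
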