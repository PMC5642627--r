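#' Health-state utility book
#'
#' Utility weights applied to state occupancy when computing QALYs.
#' Progressed-disease utility differs by management: chemotherapy/supportive
#' care (0.24) versus targeted therapy (0.68). The published outcome table is
#' only consistent with a progressed-disease utility for the cetuximab arm
#' between the two, so the arm's progressed utility is the blend
#' `(1 - f) * u_pd_chemo + f * u_pd_targeted` with
#' `f = pd_targeted_fraction_cetux_arm`, a calibration constant (frozen at
#' about 0.371 in the shipped config; see [calibrate()]).
#'
#' @param u_pfs Progression-free utility.
#' @param u_pd_chemo Progressed-disease utility under chemotherapy or
#'   supportive care.
#' @param u_pd_targeted Progressed-disease utility under targeted therapy.
#' @param pd_targeted_fraction_cetux_arm Blend fraction `f` in `[0, 1]` for
#'   the cetuximab arm's progressed-disease utility.
#' @return An object of class `utility_book`.
#' @export
utility_book <- function(u_pfs = 0.85, u_pd_chemo = 0.24, u_pd_targeted = 0.68,
                         pd_targeted_fraction_cetux_arm = 0) {
  u <- c(u_pfs, u_pd_chemo, u_pd_targeted)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("utility_book: utilities must lie in [0, 1]", call. = FALSE)
  f <- pd_targeted_fraction_cetux_arm
  if (!is.finite(f) || f < 0 || f > 1)
    stop("utility_book: 'pd_targeted_fraction_cetux_arm' must lie in [0, 1]",
         call. = FALSE)
  structure(
    list(u_pfs = u_pfs, u_pd_chemo = u_pd_chemo, u_pd_targeted = u_pd_targeted,
         pd_targeted_fraction_cetux_arm = f),
    class = "utility_book"
  )
}

# progressed-disease utility for an arm
u_pd_for_arm <- function(utilities, arm) {
  if (arm == "control") return(utilities$u_pd_chemo)
  f <- utilities$pd_targeted_fraction_cetux_arm
  (1 - f) * utilities$u_pd_chemo + f * utilities$u_pd_targeted
}

#' Quality-adjusted life-years from a cohort trace
#'
#' Discounted sum over cycles of occupancy-weighted utilities,
#' \eqn{\sum_k w_k \Delta t\, (pf_k u_{PFS} + pd_k u_{PD})}, with the same
#' cycle weighting (half-cycle or cycle-end) as [state_years()]. The
#' progressed-disease utility depends on the arm (see [utility_book()]).
#'
#' @param trace A [build_trace()] result.
#' @param arm `"control"` or `"cetuximab"`.
#' @param utilities A [utility_book()].
#' @param discounted Apply discounting (default `TRUE`).
#' @return QALYs.
#' @export
qalys <- function(trace, arm = c("control", "cetuximab"),
                  utilities = utility_book(), discounted = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(utilities, "utility_book"))
  arm <- match.arg(arm)
  u_pd <- u_pd_for_arm(utilities, arm)
  x <- trace$pf * utilities$u_pfs + trace$pd * u_pd
  w <- cycle_weights(trace)
  wt <- if (discounted) w$wdisc else 1
  sum(w$occ(x) * wt) * w$dt
}

#' Pairwise incremental cost-effectiveness results
#'
#' Computes cost and effect differences between two completed strategy legs
#' and the corresponding ratios (cost per QALY and cost per life-year).
#' Dominance is flagged instead of a ratio when one strategy is both cheaper
#' and at least as effective.
#'
#' @param intervention,comparator Strategy legs as returned by
#'   [run_strategy()]: lists with `cost`, `pf_ly`, `total_ly`, `qaly`.
#' @return An object of class `cea_increment`: `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer_per_qaly`, `icer_per_ly` (both `NA` under dominance or
#'   zero effect difference) and `dominance` (one of `"none"`,
#'   `"intervention_dominates"`, `"comparator_dominates"`).
#' @export
icer <- function(intervention, comparator) {
  need <- c("cost", "qaly", "total_ly")
  stopifnot(all(need %in% names(intervention)), all(need %in% names(comparator)))
  d_cost <- intervention$cost - comparator$cost
  d_qaly <- intervention$qaly - comparator$qaly
  d_ly <- intervention$total_ly - comparator$total_ly
  dominance <- "none"
  if (d_qaly >= 0 && d_cost <= 0 && !(d_qaly == 0 && d_cost == 0)) {
    dominance <- "intervention_dominates"
  } else if (d_qaly <= 0 && d_cost >= 0 && !(d_qaly == 0 && d_cost == 0)) {
    dominance <- "comparator_dominates"
  }
  ratio_ok <- dominance == "none" && d_qaly > 0
  structure(
    list(delta_cost = d_cost, delta_qaly = d_qaly, delta_ly = d_ly,
         icer_per_qaly = if (ratio_ok) d_cost / d_qaly else NA_real_,
         icer_per_ly = if (dominance == "none" && d_ly > 0) d_cost / d_ly
                       else NA_real_,
         dominance = dominance),
    class = "cea_increment"
  )
}

#' @export
print.cea_increment <- function(x, ...) {
  cat(sprintf("Incremental: cost %+.0f, QALY %+.3f, LY %+.3f | %s\n",
              x$delta_cost, x$delta_qaly, x$delta_ly,
              if (x$dominance == "none")
                sprintf("ICER %s/QALY, %s/LY",
                        format(round(x$icer_per_qaly), big.mark = ","),
                        format(round(x$icer_per_ly), big.mark = ","))
              else x$dominance))
  invisible(x)
}

#' Net monetary benefit of a strategy leg
#'
#' `threshold * QALYs - cost`. At a given willingness-to-pay threshold the
#' strategy with the higher net monetary benefit is preferred; for a positive
#' QALY difference this is equivalent to comparing the ICER against the
#' threshold.
#'
#' @param leg A strategy leg (list with `cost` and `qaly`).
#' @param threshold Willingness to pay per QALY (>= 0).
#' @return Net monetary benefit in dollars.
#' @export
net_monetary_benefit <- function(leg, threshold) {
  stopifnot(is.numeric(threshold), threshold >= 0,
            all(c("cost", "qaly") %in% names(leg)))
  threshold * leg$qaly - leg$cost
}
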