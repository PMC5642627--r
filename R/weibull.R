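#' @keywords internal
"_PACKAGE"

# Calendar constants used everywhere a native curve unit is converted to
# years. One year is 365.25 days; one month is 365.25/12 days.
DAYS_PER_YEAR <- 365.25
UNITS_PER_YEAR <- c(
  day       = 365.25,
  week      = 365.25 / 7,     # 52.1786
  cycle_14d = 365.25 / 14,    # 26.0893
  month     = 12,
  year      = 1
)
TIME_UNITS <- names(UNITS_PER_YEAR)

#' Weibull survival curve for one endpoint and arm
#'
#' Represents the parametric survival law \eqn{S(u) = \exp(-\lambda u^\gamma)}
#' where `u` is time expressed in the curve's native unit. The scale
#' \eqn{\lambda} is tied to that unit (dimension \eqn{\mathrm{unit}^{-\gamma}}),
#' so the unit is part of the object, not an evaluation-time choice: the fitted
#' scale/shape pairs used for model input do not share a single consistent
#' unit, and the calibration stage assigns one per curve (see
#' [calibrate()]).
#'
#' @param scale Positive Weibull scale \eqn{\lambda} per native-unit^shape.
#' @param shape Positive Weibull shape \eqn{\gamma}; values above 1 give a
#'   hazard that increases with time.
#' @param time_unit Native time unit of the curve, one of
#'   `"day"`, `"week"`, `"cycle_14d"` (14-day model cycle), `"month"`,
#'   `"year"`.
#' @param label Free-text label (endpoint and arm) used in printing.
#' @return An object of class `weibull_curve`.
#' @examples
#' pfs <- weibull_curve(0.00267, 1.89552, "cycle_14d", "PFS control")
#' survival_at(pfs, 0.5)
#' median_time(pfs)
#' @export
weibull_curve <- function(scale, shape, time_unit = "cycle_14d", label = "") {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (scale <= 0) stop("weibull_curve: 'scale' must be positive", call. = FALSE)
  if (shape <= 0) stop("weibull_curve: 'shape' must be positive", call. = FALSE)
  time_unit <- match.arg(time_unit, TIME_UNITS)
  structure(
    list(scale = scale, shape = shape, time_unit = time_unit,
         label = as.character(label)),
    class = "weibull_curve"
  )
}

#' @export
print.weibull_curve <- function(x, ...) {
  cat(sprintf("Weibull curve%s: scale = %g, shape = %g per %s (median %.3f y)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$scale, x$shape, x$time_unit, median_time(x)))
  invisible(x)
}

# t (years) -> native units of the curve
to_native <- function(curve, t) t * UNITS_PER_YEAR[[curve$time_unit]]
from_native <- function(curve, u) u / UNITS_PER_YEAR[[curve$time_unit]]

#' Survival probability at a time point
#'
#' Evaluates \eqn{S(t) = \exp(-\lambda u^\gamma)} with `u` the time converted
#' from years into the curve's native unit.
#'
#' @param curve A [weibull_curve()].
#' @param t Time in years (vectorised, all values must be non-negative).
#' @return Survival probabilities in `[0, 1]`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("survival_at: 't' must be finite and >= 0", call. = FALSE)
  exp(-curve$scale * to_native(curve, t)^curve$shape)
}

#' Median survival time of a Weibull curve
#'
#' Closed form \eqn{(\ln 2 / \lambda)^{1/\gamma}}, returned in years.
#'
#' @inheritParams survival_at
#' @return Median time in years; `survival_at(curve, median_time(curve))` is
#'   0.5 to numerical precision.
#' @export
median_time <- function(curve) {
  stopifnot(inherits(curve, "weibull_curve"))
  from_native(curve, (log(2) / curve$scale)^(1 / curve$shape))
}

#' Discounted restricted mean survival time
#'
#' Numeric integral of \eqn{S(t)\,(1+r)^{-t}} over `[0, horizon]` years by
#' composite Simpson quadrature on 2,000 panels. With `discount_rate = 0` and
#' a long horizon this converges to the Weibull mean
#' \eqn{\lambda^{-1/\gamma}\,\Gamma(1 + 1/\gamma)} (in native units).
#' Used as the continuous-time oracle for the cycle-based trace sums of
#' [state_years()].
#'
#' @inheritParams survival_at
#' @param horizon Upper integration limit in years (> 0).
#' @param discount_rate Annual discount rate in `[0, 1)`.
#' @param panels Number of Simpson panels (even; default 2000).
#' @return Restricted (discounted) mean survival in years.
#' @export
restricted_mean <- function(curve, horizon, discount_rate = 0, panels = 2000L) {
  stopifnot(inherits(curve, "weibull_curve"),
            is.numeric(horizon), length(horizon) == 1L, is.finite(horizon),
            is.numeric(discount_rate), length(discount_rate) == 1L,
            is.finite(discount_rate))
  if (horizon <= 0) stop("restricted_mean: 'horizon' must be > 0", call. = FALSE)
  if (discount_rate < 0 || discount_rate >= 1)
    stop("restricted_mean: 'discount_rate' must be in [0, 1)", call. = FALSE)
  m <- 2L * as.integer(ceiling(panels / 2))
  # truncate where S < 1e-16 (the integrand is below double-precision
  # relevance there), and integrate under the substitution t = x^2, which
  # concentrates the fixed panel budget near the origin where heavy-tailed
  # (shape < 1) curves change fastest
  t_tail <- from_native(curve, (log(1e16) / curve$scale)^(1 / curve$shape))
  upper <- min(horizon, t_tail)
  x <- seq(0, sqrt(upper), length.out = m + 1L)
  t <- x^2
  f <- 2 * x * survival_at(curve, t) * (1 + discount_rate)^(-t)
  h <- sqrt(upper) / m
  w <- rep(c(4, 2), length.out = m - 1L)
  h / 3 * (f[1L] + sum(w * f[2L:m]) + f[m + 1L])
}

#' Per-cycle event probability from a survival curve
#'
#' Conditional probability \eqn{1 - S(t_{k+1})/S(t_k)} of the event during
#' cycle `k` (0-based) given event-free survival to its start. For shape > 1
#' the sequence is nondecreasing in `k`. When \eqn{S(t_k)} has underflowed to
#' zero the cycle is treated as absorbing (probability 1) and a single
#' message is emitted.
#'
#' @inheritParams survival_at
#' @param k Cycle index or vector of indices, `k >= 0`.
#' @param cycle_length_days Cycle length in days (default 14).
#' @return Event probabilities in `[0, 1]`.
#' @export
per_cycle_event_prob <- function(curve, k, cycle_length_days = 14) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(k))
  if (any(k < 0) || any(k != floor(k)))
    stop("per_cycle_event_prob: 'k' must be a non-negative integer", call. = FALSE)
  dt <- cycle_length_days / DAYS_PER_YEAR
  s0 <- survival_at(curve, k * dt)
  s1 <- survival_at(curve, (k + 1) * dt)
  p <- ifelse(s0 > 0, 1 - s1 / s0, 1)
  if (any(s0 == 0))
    message("per_cycle_event_prob: survival underflowed to 0; absorbing tail")
  pmin(pmax(p, 0), 1)
}

#' Rescale a Weibull curve to a new median survival time
#'
#' Keeps the shape fixed and sets \eqn{\lambda' = \ln 2 / u_m^\gamma} where
#' \eqn{u_m} is the requested median in native units. This is how median
#' survival times are perturbed in one-way sensitivity analysis.
#'
#' @inheritParams survival_at
#' @param new_median Target median in years (> 0).
#' @return A new [weibull_curve()] whose [median_time()] equals `new_median`.
#' @export
rescale_to_median <- function(curve, new_median) {
  stopifnot(inherits(curve, "weibull_curve"),
            is.numeric(new_median), length(new_median) == 1L)
  if (!is.finite(new_median) || new_median <= 0)
    stop("rescale_to_median: 'new_median' must be positive", call. = FALSE)
  u <- to_native(curve, new_median)
  weibull_curve(log(2) / u^curve$shape, curve$shape, curve$time_unit, curve$label)
}

#' Book of the four model survival curves
#'
#' Bundles the progression-free and overall survival curves of the control
#' (FOLFIRI) and cetuximab arms. The raw fitted curves need not satisfy
#' OS >= PFS at every time; the trace construction clamps any crossing (see
#' [build_trace()]).
#'
#' @param pfs_control,pfs_cetuximab,os_control,os_cetuximab
#'   [weibull_curve()] objects.
#' @return An object of class `curve_book`.
#' @export
curve_book <- function(pfs_control, pfs_cetuximab, os_control, os_cetuximab) {
  curves <- list(pfs_control = pfs_control, pfs_cetuximab = pfs_cetuximab,
                 os_control = os_control, os_cetuximab = os_cetuximab)
  ok <- vapply(curves, inherits, logical(1L), "weibull_curve")
  if (!all(ok))
    stop("curve_book: all four entries must be weibull_curve objects: missing ",
         paste(names(curves)[!ok], collapse = ", "), call. = FALSE)
  structure(curves, class = "curve_book")
}

#' @export
print.curve_book <- function(x, ...) {
  cat("Survival curve book:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s scale %.5g shape %.5g per %-9s median %6.3f y\n",
                nm, x[[nm]]$scale, x[[nm]]$shape, x[[nm]]$time_unit,
                median_time(x[[nm]])))
  }
  invisible(x)
}
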