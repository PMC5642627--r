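#' Simulate pseudo individual-patient survival data from a Weibull curve
#'
#' Event times are drawn by inverse transform,
#' \eqn{t = (-\ln U / \lambda)^{1/\gamma}} in the curve's native unit, then
#' converted to years. Independent exponential censoring at `censor_rate`
#' per year and administrative censoring at `admin_censor_time` are applied;
#' the observed time is the minimum and the event flag records whether the
#' event preceded censoring (ties count as events). This emulates the kind
#' of trial data the model's curves were originally fitted to, so the
#' fitting stage can be tested end-to-end without external data.
#'
#' @param curve A [weibull_curve()].
#' @param n Number of subjects (>= 2).
#' @param censor_rate Exponential censoring hazard per year (0 disables).
#' @param admin_censor_time Administrative censoring time in years
#'   (`Inf` disables).
#' @param seed Optional integer seed for reproducibility.
#' @return A `pseudo_ipd` data frame with columns `time_years` and `event`
#'   (1 = event, 0 = censored); generating parameters and seed are stored as
#'   attributes.
#' @export
simulate_ipd <- function(curve, n, censor_rate = 0, admin_censor_time = Inf,
                         seed = NULL) {
  stopifnot(inherits(curve, "weibull_curve"))
  if (n < 2) stop("simulate_ipd: need n >= 2", call. = FALSE)
  stopifnot(censor_rate >= 0, admin_censor_time > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- stats::runif(n)
  t_event <- from_native(curve, (-log(u) / curve$scale)^(1 / curve$shape))
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, admin_censor_time)
  out <- data.frame(time_years = pmin(t_event, t_cens),
                    event = as.integer(t_event <= t_cens))
  attr(out, "curve") <- curve
  attr(out, "seed") <- seed
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

#' Kaplan-Meier estimate from pseudo individual-patient data
#'
#' Product-limit estimator via [survival::survfit()] (events precede
#' censorings at tied times, the standard convention).
#'
#' @param ipd A [simulate_ipd()] data frame (or any data frame with
#'   `time_years` and `event`).
#' @return A `km_curve` data frame with columns `time`, `survival`,
#'   `n_risk` at each distinct observed time.
#' @export
km_estimate <- function(ipd) {
  stopifnot(is.data.frame(ipd), all(c("time_years", "event") %in% names(ipd)))
  if (!any(ipd$event == 1))
    stop("km_estimate: need at least one event", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time_years, event) ~ 1, data = ipd)
  out <- data.frame(time = fit$time, survival = fit$surv, n_risk = fit$n.risk)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Fit a Weibull survival curve to Kaplan-Meier data
#'
#' Primary fit: least squares on the linearisation
#' \eqn{\ln(-\ln S) = \ln\lambda + \gamma \ln t} over Kaplan-Meier points
#' with `0 < S < 1` (this regression formulation is what produces an
#' adjusted R-squared for the fit). When individual-patient data are
#' supplied, a maximum-likelihood Weibull fit ([survival::survreg()]) is
#' attached as an independent cross-check of the regression estimates.
#'
#' @param x A `km_curve` from [km_estimate()] or a `pseudo_ipd` data frame
#'   (the Kaplan-Meier step is then computed internally and the ML refit is
#'   available).
#' @return An object of class `weibull_fit`: `curve` (the fitted
#'   [weibull_curve()] with time unit `"year"`), `scale`, `shape`, their
#'   standard errors, `r2_adj`, `n_points`, and `ml` (list with
#'   ML `scale`/`shape`, or `NULL` if only curve points were supplied).
#' @export
fit_weibull <- function(x) {
  ipd <- NULL
  if (inherits(x, "pseudo_ipd") ||
      (is.data.frame(x) && all(c("time_years", "event") %in% names(x)))) {
    ipd <- x
    km <- km_estimate(x)
  } else if (inherits(x, "km_curve") ||
             (is.data.frame(x) && all(c("time", "survival") %in% names(x)))) {
    km <- x
  } else {
    stop("fit_weibull: supply a km_curve or pseudo_ipd data frame",
         call. = FALSE)
  }
  keep <- km$survival > 0 & km$survival < 1 & km$time > 0
  km <- km[keep, , drop = FALSE]
  if (sum(!duplicated(km$time)) < 5)
    stop("fit_weibull: need at least 5 distinct usable event times",
         call. = FALSE)
  lx <- log(km$time)
  ly <- log(-log(km$survival))
  fit <- stats::lm(ly ~ lx)
  shape <- unname(stats::coef(fit)[2L])
  scale <- exp(unname(stats::coef(fit)[1L]))
  if (shape <= 0)
    stop("fit_weibull: non-positive shape estimate; data not Weibull-like",
         call. = FALSE)
  se <- sqrt(diag(stats::vcov(fit)))
  ml <- NULL
  if (!is.null(ipd)) {
    sr <- survival::survreg(survival::Surv(time_years, event) ~ 1, data = ipd,
                            dist = "weibull")
    ml_shape <- 1 / sr$scale
    # survreg: S(t) = exp(-(t / exp(intercept))^(1/scale))
    ml <- list(shape = ml_shape,
               scale = exp(-unname(stats::coef(sr)[1L]) * ml_shape))
  }
  structure(
    list(curve = weibull_curve(scale, shape, "year", "fitted"),
         scale = scale, shape = shape,
         se_scale = scale * se[1L], se_shape = unname(se[2L]),
         r2_adj = summary(fit)$adj.r.squared,
         n_points = nrow(km), ml = ml),
    class = "weibull_fit"
  )
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (per year): scale %.5g (SE %.2g), shape %.4g (SE %.2g)\n",
              x$scale, x$se_scale, x$shape, x$se_shape))
  cat(sprintf("  adj. R^2 %.4f on %d KM points%s\n", x$r2_adj, x$n_points,
              if (!is.null(x$ml))
                sprintf(" | ML cross-check: scale %.5g, shape %.4g",
                        x$ml$scale, x$ml$shape) else ""))
  invisible(x)
}
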