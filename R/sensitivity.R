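#' Triangular random deviates
#'
#' Inverse-transform sampling from the triangular distribution with support
#' `[low, high]` and mode `mode`. Degenerate edges (`mode == low` or
#' `mode == high`) are handled; `low == high` returns the point mass.
#'
#' @param n Number of draws.
#' @param low,mode,high Distribution parameters, `low <= mode <= high`.
#' @return Numeric vector of draws.
#' @export
rtriangular <- function(n, low, mode, high) {
  stopifnot(low <= mode, mode <= high)
  if (high == low) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

# method-of-moments beta parameters; NULL if infeasible
beta_moments <- function(mean, sd) {
  v <- sd^2
  if (v <= 0 || v >= mean * (1 - mean)) return(NULL)
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Sampling specification for one uncertain parameter
#'
#' @param name Parameter name (matches a parameter-book entry or a
#'   `median_*` survival target).
#' @param base,low,high Base value and one-way range, `low <= base <= high`.
#' @param dist Probabilistic distribution tag: `"triangular"` (costs and
#'   body surface area), `"beta_se25"` (utilities: beta with SD equal to 25%
#'   of the mean), `"beta_range"` (proportions: beta with SD =
#'   `(high - low) / (2 * 1.96)`), or `"fixed"` (varied one-way only, held at
#'   base in the probabilistic analysis; survival medians default to this).
#' @param target What the parameter feeds:
#'   `"cost"`, `"utility"`, `"proportion"`, `"bsa"`, or `"median"`.
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, base, low, high,
                       dist = c("triangular", "beta_se25", "beta_range", "fixed"),
                       target = c("cost", "utility", "proportion", "bsa", "median")) {
  dist <- match.arg(dist)
  target <- match.arg(target)
  if (!(low <= base && base <= high))
    stop("param_spec: need low <= base <= high for '", name, "'", call. = FALSE)
  if (startsWith(dist, "beta") && (low < 0 || high > 1))
    stop("param_spec: beta distributions require a [0, 1] range ('", name, "')",
         call. = FALSE)
  structure(list(name = name, base = base, low = low, high = high,
                 dist = dist, target = target),
            class = "param_spec")
}

#' Draw values for one parameter
#'
#' Samples from the distribution tagged in `spec`. Beta distributions are
#' parameterised by method of moments from the mean (`base`) and an SD of
#' 25% of the mean for utilities or `(high - low) / 3.92` for proportions.
#' If the implied moments are infeasible for a beta on `[0, 1]`
#' (`sd^2 >= mean (1 - mean)`), a range-fit beta is used instead — a beta on
#' `[low, high]` with the same mean and SD `(high - low) / 3.92` — and a
#' message is emitted once per call. Draws use the current RNG state; seed
#' management (one substream per parameter) is done by [run_psa()].
#'
#' @param spec A [param_spec()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_param <- function(spec, n) {
  stopifnot(inherits(spec, "param_spec"), n >= 1)
  if (spec$high == spec$low) return(rep(spec$base, n))
  switch(spec$dist,
    fixed = rep(spec$base, n),
    triangular = rtriangular(n, spec$low, spec$base, spec$high),
    beta_se25 = ,
    beta_range = {
      sd <- if (spec$dist == "beta_se25") 0.25 * spec$base
            else (spec$high - spec$low) / (2 * 1.96)
      ab <- beta_moments(spec$base, sd)
      if (!is.null(ab)) {
        stats::rbeta(n, ab[1L], ab[2L])
      } else {
        message("sample_param: infeasible beta moments for '", spec$name,
                "'; falling back to a range-fit beta")
        m <- (spec$base - spec$low) / (spec$high - spec$low)
        ab <- beta_moments(m, 1 / 3.92)
        if (is.null(ab)) ab <- c(shape1 = 1, shape2 = 1)
        spec$low + (spec$high - spec$low) * stats::rbeta(n, ab[1L], ab[2L])
      }
    })
}

#' Uncertain-parameter book of a model configuration
#'
#' Expands a parameter set into the list of [param_spec()]s used by the
#' tornado and probabilistic analyses: all unit costs (triangular), the three
#' utilities (beta, SE 25% of mean), RAS prevalence (beta from its range),
#' body surface area (triangular), and the four median survival times
#' (one-way range +-25% of the base median, held fixed in the probabilistic
#' analysis since no sampling distribution is reported for the survival
#' parameters).
#'
#' @param paramset A parameter set from [load_config()] or
#'   [default_paramset()].
#' @return Named list of [param_spec()] objects.
#' @export
param_specs <- function(paramset) {
  stopifnot(inherits(paramset, "cea_paramset"))
  specs <- list()
  for (nm in names(paramset$cost_params)) {
    p <- paramset$cost_params[[nm]]
    specs[[nm]] <- param_spec(nm, p$base, p$low, p$high, "triangular", "cost")
  }
  for (nm in names(paramset$utility_params)) {
    p <- paramset$utility_params[[nm]]
    specs[[nm]] <- param_spec(nm, p$base, p$low, p$high, "beta_se25", "utility")
  }
  pr <- paramset$proportion_params$ras_prevalence
  specs$ras_prevalence <- param_spec("ras_prevalence", pr$base, pr$low, pr$high,
                                     "beta_range", "proportion")
  b <- paramset$bsa_param
  specs$bsa <- param_spec("bsa", b$base, b$low, b$high, "triangular", "bsa")
  for (nm in names(paramset$curves)) {
    med <- median_time(paramset$curves[[nm]])
    specs[[paste0("median_", nm)]] <-
      param_spec(paste0("median_", nm), med, 0.75 * med, 1.25 * med,
                 "fixed", "median")
  }
  specs
}

# apply one parameter value to a copy of the paramset
apply_param <- function(paramset, name, value) {
  ps <- paramset
  if (name %in% names(ps$cost_params)) {
    ps$cost_params[[name]]$base <- value
    ps$costs <- rebuild_cost_book(ps)
  } else if (name %in% names(ps$utility_params)) {
    ps$utility_params[[name]]$base <- value
    ps$utilities[[name]] <- value
  } else if (name == "ras_prevalence") {
    ps$proportion_params$ras_prevalence$base <- value
  } else if (name == "bsa") {
    ps$bsa_param$base <- value
    ps$dosing$bsa <- value
  } else if (startsWith(name, "median_")) {
    curve <- sub("^median_", "", name)
    if (!curve %in% names(ps$curves))
      stop("apply_param: unknown curve '", curve, "'", call. = FALSE)
    ps$curves[[curve]] <- rescale_to_median(ps$curves[[curve]], value)
  } else {
    stop("apply_param: parameter '", name, "' is not re-runnable", call. = FALSE)
  }
  ps
}

#' One-way sensitivity of the ICER to a single parameter
#'
#' Reruns the full deterministic model with the parameter at its low and
#' high range end, all other inputs at base. Median survival parameters
#' perturb their curve through [rescale_to_median()].
#'
#' @param spec A [param_spec()].
#' @param paramset Parameter set defining the base case.
#' @param pap_enabled Whether the cetuximab strategy uses the PAP.
#' @return A one-row data frame: parameter, ICER at low, base and high, and
#'   the tornado bar width `abs(high - low)`.
#' @export
one_way <- function(spec, paramset, pap_enabled = TRUE) {
  stopifnot(inherits(spec, "param_spec"))
  icer_at <- function(value) {
    ps <- apply_param(paramset, spec$name, value)
    bc <- run_base_case(ps)
    inc <- if (pap_enabled) bc$inc_pap else bc$inc_no_pap
    inc$icer_per_qaly
  }
  base <- run_base_case(paramset)
  icer_base <- (if (pap_enabled) base$inc_pap else base$inc_no_pap)$icer_per_qaly
  lo <- if (spec$low == spec$base) icer_base else icer_at(spec$low)
  hi <- if (spec$high == spec$base) icer_base else icer_at(spec$high)
  data.frame(parameter = spec$name, icer_low = lo, icer_base = icer_base,
             icer_high = hi, width = abs(hi - lo))
}

#' Tornado analysis over every uncertain parameter
#'
#' @inheritParams one_way
#' @return Data frame of [one_way()] rows sorted by decreasing bar width,
#'   class `cea_tornado`.
#' @export
run_tornado <- function(paramset, pap_enabled = TRUE) {
  specs <- param_specs(paramset)
  out <- do.call(rbind, lapply(specs, one_way, paramset = paramset,
                               pap_enabled = pap_enabled))
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  class(out) <- c("cea_tornado", "data.frame")
  out
}

# deterministic per-parameter RNG substream seed (kept < 2^31); adding or
# reordering parameters never perturbs another parameter's draws because the
# substream is indexed by parameter name hash, not position
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 40000L
  (as.integer(seed) %% 44487L) * 48000L + h
}

#' Probabilistic sensitivity analysis
#'
#' Jointly samples all uncertain parameters `n` times (one independent,
#' seeded RNG substream per parameter, so draws for one parameter do not
#' depend on which others are present) and reruns the deterministic model
#' per draw. Survival curves stay at base (their specs are tagged
#' `"fixed"`), so the cohort traces are computed once and reused.
#'
#' @param paramset Parameter set defining the model.
#' @param n Number of draws (default 1000).
#' @param seed Integer seed controlling every substream.
#' @param pap_enabled Whether the cetuximab strategy uses the PAP.
#' @return An object of class `cea_psa`: draws data frame with per-strategy
#'   cost and QALYs plus `delta_cost`, `delta_qaly` (cetuximab - control),
#'   the sampled parameter matrix, `n`, `seed`, `pap_enabled`.
#' @export
run_psa <- function(paramset, n = 1000, seed = 1, pap_enabled = TRUE) {
  stopifnot(inherits(paramset, "cea_paramset"))
  if (n <= 0) stop("run_psa: 'n' must be positive", call. = FALSE)
  specs <- param_specs(paramset)
  draws <- matrix(NA_real_, nrow = n, ncol = length(specs),
                  dimnames = list(NULL, names(specs)))
  for (nm in names(specs)) {
    set.seed(substream_seed(seed, nm))
    draws[, nm] <- sample_param(specs[[nm]], n)
  }
  base_traces <- build_arm_traces(paramset)
  res <- matrix(NA_real_, nrow = n, ncol = 4,
                dimnames = list(NULL, c("cost_control", "qaly_control",
                                        "cost_cetuximab", "qaly_cetuximab")))
  for (i in seq_len(n)) {
    ps <- paramset
    for (nm in colnames(draws)) {
      if (specs[[nm]]$dist != "fixed") ps <- apply_param(ps, nm, draws[i, nm])
    }
    legs <- evaluate_strategies(ps, pap_enabled, traces = base_traces)
    res[i, ] <- c(legs$control$cost, legs$control$qaly,
                  legs$cetuximab$cost, legs$cetuximab$qaly)
  }
  out <- as.data.frame(res)
  out$delta_cost <- out$cost_cetuximab - out$cost_control
  out$delta_qaly <- out$qaly_cetuximab - out$qaly_control
  structure(list(draws = out, params = draws, n = n, seed = seed,
                 pap_enabled = pap_enabled),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %s, PAP %s)\n", x$n, x$seed,
              if (x$pap_enabled) "on" else "off"))
  cat(sprintf("  mean incremental cost %8.0f  mean incremental QALY %.3f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws in which
#' each strategy has the higher net monetary benefit. Ties are credited to
#' the cetuximab (intervention) strategy. With two comparators the two
#' probabilities sum to one.
#'
#' @param psa A [run_psa()] result.
#' @param thresholds Numeric vector of thresholds (dollars per QALY).
#' @return Data frame with columns `threshold`, `p_cetuximab`, `p_control`.
#' @export
ceac <- function(psa, thresholds = seq(0, 60000, by = 2000)) {
  stopifnot(inherits(psa, "cea_psa"))
  if (!length(thresholds)) stop("ceac: empty threshold grid", call. = FALSE)
  p <- vapply(thresholds, function(th) {
    mean(th * psa$draws$delta_qaly - psa$draws$delta_cost >= 0)
  }, numeric(1L))
  data.frame(threshold = thresholds, p_cetuximab = p, p_control = 1 - p)
}

#' Plot a tornado diagram
#'
#' @param x A [run_tornado()] result.
#' @param top Number of widest bars to show.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.cea_tornado <- function(x, top = 10, ...) {
  x <- utils::head(x, top)
  rng <- rbind(x$icer_low, x$icer_high) - x$icer_base[1L]
  graphics::barplot(rng[2L, rev(seq_len(nrow(x)))],
                    horiz = TRUE, names.arg = rev(x$parameter), las = 1,
                    xlab = "ICER shift from base ($/QALY)", ...)
  graphics::barplot(rng[1L, rev(seq_len(nrow(x)))], horiz = TRUE, add = TRUE,
                    names.arg = NULL, col = "grey60")
  invisible(x)
}
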