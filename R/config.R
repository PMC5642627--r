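CONFIG_SECTIONS <- c("seed", "threshold_per_qaly", "model", "curves", "costs",
                     "utilities", "proportions", "dosing", "pap",
                     "conventions", "calibration_targets")

range_entry <- function(x, name, lo_bound = -Inf, hi_bound = Inf) {
  need <- c("base", "low", "high")
  if (!is.list(x) || !all(need %in% names(x)))
    stop("config: '", name, "' must have base/low/high", call. = FALSE)
  v <- unlist(x[need])
  if (any(!is.finite(v)))
    stop("config: '", name, "' has non-finite values", call. = FALSE)
  if (!(x$low <= x$base && x$base <= x$high))
    stop("config: '", name, "' violates low <= base <= high", call. = FALSE)
  if (x$low < lo_bound || x$high > hi_bound)
    stop("config: '", name, "' outside its admissible bounds [",
         lo_bound, ", ", hi_bound, "]", call. = FALSE)
  x[need]
}

#' Load and validate a model configuration
#'
#' Reads the structured YAML parameter book — survival curves, unit costs
#' with one-way ranges, utilities, RAS prevalence, dosing, PAP calendar,
#' model settings and the frozen calibration conventions — validates every
#' entry (unknown keys are rejected; range entries must satisfy
#' `low <= base <= high`; utilities and proportions must lie in `[0, 1]`)
#' and assembles the parameter set consumed by every analysis function.
#'
#' @param path Path to a YAML config; the default is the shipped base-case
#'   fixture (the published parameter book plus frozen calibration).
#' @return An object of class `cea_paramset`.
#' @export
load_config <- function(path = system.file("extdata", "default_params.yaml",
                                           package = "cetuxcea")) {
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!length(raw)) {
    stop("load_config: empty config; required sections: ",
         paste(CONFIG_SECTIONS, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), CONFIG_SECTIONS)
  if (length(unknown))
    stop("load_config: unknown top-level keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(CONFIG_SECTIONS, names(raw))
  if (length(missing))
    stop("load_config: missing required sections: ",
         paste(missing, collapse = ", "), call. = FALSE)

  curves <- lapply(names(raw$curves), function(nm) {
    cv <- raw$curves[[nm]]
    weibull_curve(cv$scale, cv$shape, cv$time_unit,
                  if (is.null(cv$label)) nm else cv$label)
  })
  names(curves) <- names(raw$curves)
  curves <- do.call(curve_book, curves[c("pfs_control", "pfs_cetuximab",
                                         "os_control", "os_cetuximab")])

  cost_params <- lapply(names(raw$costs), function(nm)
    range_entry(raw$costs[[nm]], nm, lo_bound = 0))
  names(cost_params) <- names(raw$costs)
  needed_costs <- c("folfiri_per_cycle", "cetuximab_per_100mg",
                    "salvage_per_cycle", "ras_test_per_unit", "terminal_care",
                    "sae_vomiting", "sae_rash_acne", "sae_fatigue",
                    "sae_neutropenia", "sae_diarrhea")
  miss <- setdiff(needed_costs, names(cost_params))
  if (length(miss))
    stop("load_config: missing cost entries: ", paste(miss, collapse = ", "),
         call. = FALSE)

  utility_params <- lapply(names(raw$utilities), function(nm)
    range_entry(raw$utilities[[nm]], nm, 0, 1))
  names(utility_params) <- names(raw$utilities)
  miss <- setdiff(c("u_pfs", "u_pd_chemo", "u_pd_targeted"),
                  names(utility_params))
  if (length(miss))
    stop("load_config: missing utility entries: ",
         paste(miss, collapse = ", "), call. = FALSE)

  proportion_params <- list(
    ras_prevalence = range_entry(raw$proportions$ras_prevalence,
                                 "ras_prevalence", 0, 1))

  bsa_param <- range_entry(raw$dosing$bsa, "bsa", lo_bound = 0)
  dosing <- dosing_rule(raw$dosing$loading_dose, raw$dosing$maintenance_dose,
                        raw$dosing$infusions_per_cycle, raw$dosing$vial_size,
                        bsa_param$base)

  pap <- pap_schedule(raw$pap$lead_pay_months, raw$pap$lead_free_months,
                      raw$pap$repeat_pay_months, raw$pap$repeat_free_months,
                      raw$pap$cycles_per_month)

  model <- model_config(raw$model$cycle_length_days, raw$model$horizon_years,
                        raw$model$discount_rate_annual,
                        raw$model$half_cycle_correction)

  conv <- raw$conventions
  conv$cetuximab_costing <- match.arg(conv$cetuximab_costing,
                                      c("vial_dosing", "per_cycle_price"))
  conv$terminal_care_mode <- match.arg(conv$terminal_care_mode,
                                       c("once_at_death", "per_cycle"))
  stopifnot(conv$coverage_fraction >= 0, conv$coverage_fraction <= 1,
            conv$salvage_cycles_cap >= 0)
  f <- conv$pd_targeted_fraction_cetux_arm
  if (is.null(f) || !is.finite(f) || f < 0 || f > 1)
    stop("load_config: conventions$pd_targeted_fraction_cetux_arm must lie in [0, 1]",
         call. = FALSE)
  sae_probs <- conv$sae_probabilities
  sae_probs <- if (is.null(sae_probs)) numeric(0) else unlist(sae_probs)

  utilities <- utility_book(utility_params$u_pfs$base,
                            utility_params$u_pd_chemo$base,
                            utility_params$u_pd_targeted$base,
                            f)
  ps <- structure(
    list(seed = raw$seed, threshold_per_qaly = raw$threshold_per_qaly,
         model = model, curves = curves,
         cost_params = cost_params,
         utility_params = utility_params,
         proportion_params = proportion_params,
         bsa_param = bsa_param,
         utilities = utilities, dosing = dosing, pap = pap,
         conventions = conv, sae_probabilities = sae_probs,
         calibration_targets = raw$calibration_targets,
         source = path),
    class = "cea_paramset")
  ps$costs <- rebuild_cost_book(ps)
  ps
}

#' Shipped base-case parameter set
#'
#' Convenience wrapper for [load_config()] on the packaged fixture.
#' @return A `cea_paramset`.
#' @export
default_paramset <- function() load_config()

# cost_book from the current cost_params bases
rebuild_cost_book <- function(ps) {
  cp <- ps$cost_params
  cost_book(cp$folfiri_per_cycle$base, cp$cetuximab_per_100mg$base,
            cp$salvage_per_cycle$base, cp$ras_test_per_unit$base,
            cp$terminal_care$base,
            c(vomiting = cp$sae_vomiting$base, rash_acne = cp$sae_rash_acne$base,
              fatigue = cp$sae_fatigue$base, neutropenia = cp$sae_neutropenia$base,
              diarrhea = cp$sae_diarrhea$base))
}

#' @export
print.cea_paramset <- function(x, ...) {
  cat("CEA parameter set (", basename(x$source), ")\n", sep = "")
  print(x$curves)
  cat(sprintf("  coverage %.0f%% | salvage cap %s cycles | cetuximab basis %s | f(PD targeted) %.3f\n",
              100 * x$conventions$coverage_fraction,
              format(x$conventions$salvage_cycles_cap),
              x$conventions$cetuximab_costing,
              x$utilities$pd_targeted_fraction_cetux_arm))
  invisible(x)
}

# traces for both arms under the paramset's model settings
build_arm_traces <- function(ps) {
  list(control = build_trace(ps$curves$pfs_control, ps$curves$os_control,
                             ps$model),
       cetuximab = build_trace(ps$curves$pfs_cetuximab, ps$curves$os_cetuximab,
                               ps$model))
}

strategy_from_paramset <- function(ps, name, pap_enabled) {
  strategy_spec(name,
                pap_enabled = (name == "cetuximab") && pap_enabled,
                screening_applied = name == "cetuximab",
                ras_prevalence = ps$proportion_params$ras_prevalence$base,
                coverage_fraction = ps$conventions$coverage_fraction,
                salvage_cycles_cap = ps$conventions$salvage_cycles_cap,
                sae_probabilities = ps$sae_probabilities)
}

#' Evaluate one strategy arm
#'
#' Builds (or reuses) the arm's cohort trace, accrues discounted costs under
#' the parameter set's conventions and computes the outcome quantities.
#'
#' @param paramset A `cea_paramset`.
#' @param name `"control"` or `"cetuximab"`.
#' @param pap_enabled PAP calendar active (cetuximab arm only).
#' @param trace Optional precomputed [build_trace()] result for the arm.
#' @param keep_ledger Attach the per-cycle cost ledger.
#' @return A strategy leg: list with `strategy`, `cost`, `pf_ly`, `total_ly`,
#'   `qaly` (and `ledger` if requested).
#' @export
run_strategy <- function(paramset, name = c("control", "cetuximab"),
                         pap_enabled = FALSE, trace = NULL,
                         keep_ledger = FALSE) {
  name <- match.arg(name)
  if (is.null(trace)) trace <- build_arm_traces(paramset)[[name]]
  strat <- strategy_from_paramset(paramset, name, pap_enabled)
  acc <- accrue_costs(trace, strat, paramset$costs, paramset$dosing,
                      paramset$pap,
                      cetuximab_costing = paramset$conventions$cetuximab_costing,
                      terminal_care_mode = paramset$conventions$terminal_care_mode,
                      keep_ledger = keep_ledger)
  leg <- list(strategy = name, pap_enabled = strat$pap_enabled,
              cost = acc$total,
              pf_ly = state_years(trace, "pf"),
              total_ly = state_years(trace, "overall"),
              qaly = qalys(trace, name, paramset$utilities))
  if (keep_ledger) leg$ledger <- acc$ledger
  leg
}

# both strategies, minimal allocations (used by the PSA inner loop)
evaluate_strategies <- function(ps, pap_enabled, traces = NULL) {
  if (is.null(traces)) traces <- build_arm_traces(ps)
  list(control = run_strategy(ps, "control", FALSE, traces$control),
       cetuximab = run_strategy(ps, "cetuximab", pap_enabled,
                                traces$cetuximab))
}

#' Deterministic base-case analysis
#'
#' Runs the control strategy and the cetuximab strategy both with and
#' without the patient assistance program, and computes pairwise incremental
#' results against control.
#'
#' @param paramset A `cea_paramset`.
#' @return An object of class `cea_base_case`: legs `control`, `cetux_pap`,
#'   `cetux_no_pap`, increments `inc_pap`, `inc_no_pap`, and the threshold.
#' @export
run_base_case <- function(paramset) {
  stopifnot(inherits(paramset, "cea_paramset"))
  traces <- build_arm_traces(paramset)
  control <- run_strategy(paramset, "control", FALSE, traces$control)
  cetux_pap <- run_strategy(paramset, "cetuximab", TRUE, traces$cetuximab)
  cetux_no_pap <- run_strategy(paramset, "cetuximab", FALSE, traces$cetuximab)
  structure(
    list(control = control, cetux_pap = cetux_pap, cetux_no_pap = cetux_no_pap,
         inc_pap = icer(cetux_pap, control),
         inc_no_pap = icer(cetux_no_pap, control),
         threshold = paramset$threshold_per_qaly),
    class = "cea_base_case")
}

#' @export
as.data.frame.cea_base_case <- function(x, ...) {
  leg_row <- function(leg, inc) {
    data.frame(strategy = paste0(leg$strategy,
                                 if (leg$strategy == "cetuximab")
                                   if (leg$pap_enabled) "_pap" else "_no_pap"
                                 else ""),
               cost = leg$cost, pf_ly = leg$pf_ly, total_ly = leg$total_ly,
               qaly = leg$qaly,
               icer_per_qaly = if (is.null(inc)) NA_real_ else inc$icer_per_qaly,
               icer_per_ly = if (is.null(inc)) NA_real_ else inc$icer_per_ly)
  }
  rbind(leg_row(x$control, NULL),
        leg_row(x$cetux_pap, x$inc_pap),
        leg_row(x$cetux_no_pap, x$inc_no_pap))
}

#' @export
print.cea_base_case <- function(x, ...) {
  df <- as.data.frame(x)
  df$cost <- round(df$cost)
  df$icer_per_qaly <- round(df$icer_per_qaly)
  df$icer_per_ly <- round(df$icer_per_ly)
  for (col in c("pf_ly", "total_ly", "qaly")) df[[col]] <- round(df[[col]], 3)
  cat("Base-case cost and outcome results (vs control):\n")
  print(df, row.names = FALSE)
  cat(sprintf("NMB at $%s/QALY: control %.0f | cetuximab+PAP %.0f | cetuximab %.0f\n",
              format(x$threshold, big.mark = ","),
              net_monetary_benefit(x$control, x$threshold),
              net_monetary_benefit(x$cetux_pap, x$threshold),
              net_monetary_benefit(x$cetux_no_pap, x$threshold)))
  invisible(x)
}
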