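#' Unit-cost book (2016 US dollars)
#'
#' Per-cycle and per-event unit costs of the model. Defaults are the base
#' values of the parameter book; every value must be non-negative.
#'
#' @param folfiri_per_cycle FOLFIRI chemotherapy cost per 14-day cycle.
#' @param cetuximab_per_100mg Cetuximab list price per 100 mg vial.
#' @param salvage_per_cycle Second-line (salvage) therapy cost per cycle.
#' @param ras_test_per_unit RAS mutation screening cost per test.
#' @param terminal_care Terminal-care cost (charged once at death entry under
#'   the default convention).
#' @param sae_unit_costs Named numeric vector of severe adverse event
#'   management costs per event (vomiting, rash_acne, fatigue, neutropenia,
#'   diarrhea).
#' @return An object of class `cost_book`.
#' @export
cost_book <- function(folfiri_per_cycle = 2050.5,
                      cetuximab_per_100mg = 637.4,
                      salvage_per_cycle = 2411.8,
                      ras_test_per_unit = 176.9,
                      terminal_care = 1980.1,
                      sae_unit_costs = c(vomiting = 175.7, rash_acne = 11.1,
                                         fatigue = 1524.6, neutropenia = 2694.6,
                                         diarrhea = 891.5)) {
  vals <- c(folfiri_per_cycle, cetuximab_per_100mg, salvage_per_cycle,
            ras_test_per_unit, terminal_care, sae_unit_costs)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("cost_book: all unit costs must be finite and non-negative",
         call. = FALSE)
  structure(
    list(folfiri_per_cycle = folfiri_per_cycle,
         cetuximab_per_100mg = cetuximab_per_100mg,
         salvage_per_cycle = salvage_per_cycle,
         ras_test_per_unit = ras_test_per_unit,
         terminal_care = terminal_care,
         sae_unit_costs = sae_unit_costs),
    class = "cost_book"
  )
}

#' Cetuximab dosing rule
#'
#' Weekly cetuximab dosing within the 14-day cycle: a 400 mg/m2 loading
#' infusion at treatment start, 250 mg/m2 maintenance infusions weekly
#' thereafter (two infusions per cycle), 100 mg vials with wastage (opened
#' vials are discarded), for a typical body surface area of 1.72 m2.
#'
#' @param loading_dose,maintenance_dose Doses in mg per m2.
#' @param infusions_per_cycle Infusions per 14-day cycle (default 2).
#' @param vial_size Vial content in mg (default 100).
#' @param bsa Body surface area in m2 (default 1.72).
#' @return An object of class `dosing_rule`.
#' @export
dosing_rule <- function(loading_dose = 400, maintenance_dose = 250,
                        infusions_per_cycle = 2, vial_size = 100, bsa = 1.72) {
  stopifnot(loading_dose > 0, maintenance_dose > 0, infusions_per_cycle >= 1,
            vial_size > 0, bsa > 0)
  structure(
    list(loading_dose = loading_dose, maintenance_dose = maintenance_dose,
         infusions_per_cycle = as.integer(infusions_per_cycle),
         vial_size = vial_size, bsa = bsa),
    class = "dosing_rule"
  )
}

#' Patient assistance program (PAP) calendar
#'
#' The pay/donate supply calendar for cetuximab: the payer pays for the first
#' `lead_pay_months` months, the producer donates the next
#' `lead_free_months`, and thereafter blocks of `repeat_pay_months` paid plus
#' `repeat_free_months` donated months repeat while the patient remains on
#' treatment. Months are mapped onto 14-day cycles through
#' `cycles_per_month`; the exact calendar value (26.0893/12, about 2.174) is
#' the calibrated default and yields fractional paid cycles at month
#' boundaries. Setting `repeat_pay_months = 0` makes the donation phase
#' permanent after the lead months.
#'
#' @param lead_pay_months,lead_free_months,repeat_pay_months,repeat_free_months
#'   Non-negative month counts.
#' @param cycles_per_month Cycles per calendar month used to map the monthly
#'   calendar onto the cycle grid.
#' @return An object of class `pap_schedule`.
#' @export
pap_schedule <- function(lead_pay_months = 2, lead_free_months = 2,
                         repeat_pay_months = 1, repeat_free_months = 3,
                         cycles_per_month = UNITS_PER_YEAR[["cycle_14d"]] / 12) {
  m <- c(lead_pay_months, lead_free_months, repeat_pay_months,
         repeat_free_months)
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m)))
    stop("pap_schedule: month counts must be non-negative integers",
         call. = FALSE)
  stopifnot(cycles_per_month > 0)
  structure(
    list(lead_pay_months = lead_pay_months, lead_free_months = lead_free_months,
         repeat_pay_months = repeat_pay_months,
         repeat_free_months = repeat_free_months,
         cycles_per_month = cycles_per_month),
    class = "pap_schedule"
  )
}

# paid indicator for integer month index m (0-based)
month_is_paid <- function(m, schedule) {
  lp <- schedule$lead_pay_months
  lf <- schedule$lead_free_months
  rp <- schedule$repeat_pay_months
  rf <- schedule$repeat_free_months
  blk <- rp + rf
  ifelse(m < lp, TRUE,
         ifelse(m < lp + lf, FALSE,
                if (blk == 0) TRUE else ((m - lp - lf) %% blk) < rp))
}

#' Fraction of a cycle's cetuximab supply paid by the payer under the PAP
#'
#' Maps cycle `k` (0-based) to its span on the monthly PAP calendar and
#' returns the paid fraction of that span (0 for fully donated cycles, 1 for
#' fully paid ones, fractional where a month boundary falls inside the
#' cycle). Without a PAP every cycle is fully paid.
#'
#' @param k Cycle index or vector of indices (0-based).
#' @param schedule A [pap_schedule()].
#' @return Paid fractions in `[0, 1]`.
#' @examples
#' pap_paid_fraction(0, pap_schedule())          # first cycle: payer pays
#' pap_paid_fraction(0:11, pap_schedule(cycles_per_month = 2))
#' @export
pap_paid_fraction <- function(k, schedule = pap_schedule()) {
  stopifnot(inherits(schedule, "pap_schedule"), is.numeric(k))
  if (any(k < 0) || any(k != floor(k)))
    stop("pap_paid_fraction: 'k' must be a non-negative integer", call. = FALSE)
  cpm <- schedule$cycles_per_month
  vapply(k, function(kk) {
    a <- kk / cpm            # cycle span in month-time
    b <- (kk + 1) / cpm
    ms <- seq.int(floor(a), ceiling(b) - 1)
    overlap <- pmin(b, ms + 1) - pmax(a, ms)
    sum(overlap * month_is_paid(ms, schedule)) / (b - a)
  }, numeric(1L))
}

#' Whole vials needed for one infusion
#'
#' `ceiling(dose * bsa / vial_size)`: opened vials are discarded, so partial
#' vials are charged in full. A zero dose needs no vial.
#'
#' @param dose_mg_per_m2 Dose in mg per m2 (>= 0).
#' @param bsa Body surface area in m2.
#' @param vial_size Vial content in mg (> 0).
#' @return Integer vial count.
#' @examples
#' vials_needed(250, 1.72, 100)  # 430 mg -> 5 vials
#' vials_needed(400, 1.72, 100)  # 688 mg -> 7 vials
#' @export
vials_needed <- function(dose_mg_per_m2, bsa, vial_size) {
  stopifnot(is.numeric(dose_mg_per_m2), is.numeric(bsa), is.numeric(vial_size))
  if (vial_size <= 0) stop("vials_needed: 'vial_size' must be > 0", call. = FALSE)
  if (any(dose_mg_per_m2 < 0) || bsa <= 0)
    stop("vials_needed: dose must be >= 0 and bsa > 0", call. = FALSE)
  as.integer(ceiling(dose_mg_per_m2 * bsa / vial_size))
}

#' Cetuximab acquisition cost for one cycle
#'
#' Two costing bases are supported. `"vial_dosing"` prices the mechanistic
#' schedule: at cycle 0 one loading plus one maintenance infusion, from cycle
#' 1 two maintenance infusions, each rounded up to whole vials and priced per
#' vial. `"per_cycle_price"` charges the parameter book's per-100 mg price
#' once per progression-free cycle; this is the calibrated reproduction
#' convention (see the methods vignette) under which the published cost
#' totals are recovered. Under an active PAP the cycle cost is scaled by the
#' paid fraction of the cycle.
#'
#' @param k Cycle index (0-based, vectorised).
#' @param dosing A [dosing_rule()].
#' @param costbook A [cost_book()].
#' @param pap_enabled Logical; apply the PAP calendar.
#' @param schedule A [pap_schedule()] (used when `pap_enabled`).
#' @param basis `"vial_dosing"` or `"per_cycle_price"`.
#' @return Cost in dollars for each requested cycle.
#' @examples
#' cetuximab_cycle_cost(0, dosing_rule(), cost_book())  # (7 + 5) vials
#' cetuximab_cycle_cost(3, dosing_rule(), cost_book())  # 10 vials
#' @export
cetuximab_cycle_cost <- function(k, dosing, costbook, pap_enabled = FALSE,
                                 schedule = pap_schedule(),
                                 basis = c("vial_dosing", "per_cycle_price")) {
  stopifnot(inherits(dosing, "dosing_rule"), inherits(costbook, "cost_book"))
  basis <- match.arg(basis)
  if (any(k < 0)) stop("cetuximab_cycle_cost: 'k' must be >= 0", call. = FALSE)
  price <- costbook$cetuximab_per_100mg
  if (basis == "vial_dosing") {
    v_load <- vials_needed(dosing$loading_dose, dosing$bsa, dosing$vial_size)
    v_main <- vials_needed(dosing$maintenance_dose, dosing$bsa, dosing$vial_size)
    vials <- ifelse(k == 0,
                    v_load + (dosing$infusions_per_cycle - 1L) * v_main,
                    dosing$infusions_per_cycle * v_main)
    base <- vials * price
  } else {
    base <- rep(price, length(k))
  }
  paid <- if (pap_enabled) pap_paid_fraction(k, schedule) else 1
  base * paid
}

#' One-off RAS screening cost loaded onto each treated patient
#'
#' Screening every candidate and treating only RAS wild-type patients means
#' `1 / (1 - prevalence)` tests are consumed per treated patient; the cost of
#' tests spent on mutant (untreated) patients is loaded onto the treated
#' cohort at model entry.
#'
#' @param test_cost Cost per test.
#' @param prevalence RAS mutation prevalence in `[0, 1)`.
#' @return Screening cost per treated patient.
#' @examples
#' screening_cost_per_treated_patient(176.9, 0.41)  # 299.83
#' @export
screening_cost_per_treated_patient <- function(test_cost, prevalence) {
  stopifnot(is.numeric(test_cost), is.numeric(prevalence))
  if (prevalence >= 1 || prevalence < 0)
    stop("screening_cost_per_treated_patient: 'prevalence' must be in [0, 1)",
         call. = FALSE)
  test_cost / (1 - prevalence)
}

#' Strategy specification
#'
#' One arm's treatment and costing rules: the control arm receives FOLFIRI
#' alone with no screening and no PAP; the cetuximab arm adds RAS screening,
#' cetuximab acquisition and optionally the PAP calendar.
#'
#' @param name `"control"` or `"cetuximab"`.
#' @param pap_enabled Logical; PAP calendar active (cetuximab arm only).
#' @param screening_applied Logical; load RAS screening cost at entry.
#' @param ras_prevalence RAS mutation prevalence in `[0, 1)`.
#' @param coverage_fraction Fraction of total expenditure borne by the payer;
#'   the calibrated base case uses the 60% catastrophic-insurance coverage.
#' @param salvage_cycles_cap Salvage-therapy cycles charged per progressing
#'   patient (finite cap charged once at progression entry) or `Inf` to
#'   charge salvage for all progressed-state time.
#' @param sae_probabilities Named per-patient probabilities of severe adverse
#'   events priced in the cost book; default all zero (the parameter book
#'   prices SAEs but event probabilities must come from the config).
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name = c("control", "cetuximab"),
                          pap_enabled = FALSE,
                          screening_applied = (name == "cetuximab"),
                          ras_prevalence = 0.41,
                          coverage_fraction = 0.6,
                          salvage_cycles_cap = 3,
                          sae_probabilities = numeric(0)) {
  name <- match.arg(name)
  if (name == "control" && (isTRUE(pap_enabled) || isTRUE(screening_applied)))
    stop("strategy_spec: the control arm has no PAP and no screening",
         call. = FALSE)
  stopifnot(ras_prevalence >= 0, ras_prevalence < 1,
            coverage_fraction >= 0, coverage_fraction <= 1,
            salvage_cycles_cap >= 0)
  if (length(sae_probabilities) &&
      (any(sae_probabilities < 0) || any(sae_probabilities > 1)))
    stop("strategy_spec: SAE probabilities must lie in [0, 1]", call. = FALSE)
  structure(
    list(name = name, pap_enabled = isTRUE(pap_enabled),
         screening_applied = isTRUE(screening_applied),
         ras_prevalence = ras_prevalence,
         coverage_fraction = coverage_fraction,
         salvage_cycles_cap = salvage_cycles_cap,
         sae_probabilities = sae_probabilities),
    class = "strategy_spec"
  )
}

#' Accrue discounted costs over a cohort trace
#'
#' Sums, cycle by cycle, treatment costs over progression-free occupancy
#' (FOLFIRI for both arms, cetuximab for the cetuximab arm — treatment
#' continues until progression), salvage therapy at progression (a capped
#' number of salvage cycles charged to each newly progressing patient, or
#' uncapped per-cycle accrual over progressed occupancy), terminal care once
#' at death entry (or per dead-state cycle if configured), the one-off
#' screening load and the expected SAE management cost at entry. The payer's
#' coverage fraction scales the total linearly.
#'
#' New progression events are approximated by the decline of progression-free
#' occupancy between grid points; the trace records no pre-progression death
#' split, and treating all progression-free exits as progressions is the
#' convention consistent with salvage being charged at progression.
#'
#' @param trace A [build_trace()] result for the strategy's arm.
#' @param strategy A [strategy_spec()].
#' @param costbook A [cost_book()].
#' @param dosing A [dosing_rule()].
#' @param schedule A [pap_schedule()].
#' @param cetuximab_costing Costing basis passed to [cetuximab_cycle_cost()].
#' @param terminal_care_mode `"once_at_death"` (default) or `"per_cycle"`.
#' @param keep_ledger Build the per-cycle ledger data frame (default
#'   `TRUE`; the probabilistic and calibration loops turn it off).
#' @return A list with `total` (discounted, coverage-scaled dollars) and
#'   `ledger`, a per-cycle data frame with columns `cycle`, `component`,
#'   `undiscounted`, `discounted` (before coverage scaling), or `NULL` when
#'   `keep_ledger` is off.
#' @export
accrue_costs <- function(trace, strategy, costbook, dosing = dosing_rule(),
                         schedule = pap_schedule(),
                         cetuximab_costing = c("vial_dosing", "per_cycle_price"),
                         terminal_care_mode = c("once_at_death", "per_cycle"),
                         keep_ledger = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(strategy, "strategy_spec"),
            inherits(costbook, "cost_book"))
  cetuximab_costing <- match.arg(cetuximab_costing)
  terminal_care_mode <- match.arg(terminal_care_mode)
  n <- trace$config$n_cycles
  w <- cycle_weights(trace)
  k <- 0:(n - 1L)

  pf_occ <- w$occ(trace$pf)
  pd_occ <- w$occ(trace$pd)
  dead_occ <- w$occ(trace$dead)
  entrants <- pmax(0, trace$pf[-(n + 1L)] - trace$pf[-1L])
  deaths <- trace$dead[-1L] - trace$dead[-(n + 1L)]

  per_cycle <- list()
  per_cycle$folfiri <- pf_occ * costbook$folfiri_per_cycle
  if (strategy$name == "cetuximab") {
    per_cycle$cetuximab <- pf_occ *
      cetuximab_cycle_cost(k, dosing, costbook, strategy$pap_enabled,
                           schedule, cetuximab_costing)
  }
  per_cycle$salvage <- if (is.finite(strategy$salvage_cycles_cap)) {
    entrants * strategy$salvage_cycles_cap * costbook$salvage_per_cycle
  } else {
    pd_occ * costbook$salvage_per_cycle
  }
  per_cycle$terminal <- if (terminal_care_mode == "once_at_death") {
    deaths * costbook$terminal_care
  } else {
    dead_occ * costbook$terminal_care
  }
  oneoff <- 0
  if (strategy$screening_applied)
    oneoff <- oneoff + screening_cost_per_treated_patient(
      costbook$ras_test_per_unit, strategy$ras_prevalence)
  if (length(strategy$sae_probabilities)) {
    idx <- names(strategy$sae_probabilities)
    bad <- setdiff(idx, names(costbook$sae_unit_costs))
    if (length(bad))
      stop("accrue_costs: SAE events not priced in the cost book: ",
           paste(bad, collapse = ", "), call. = FALSE)
    oneoff <- oneoff + sum(strategy$sae_probabilities *
                             costbook$sae_unit_costs[idx])
  }
  per_cycle$screening_sae <- c(oneoff, rep(0, n - 1L))

  # entry one-offs fall due at t = 0 and are not discounted
  weight_for <- function(comp)
    if (comp == "screening_sae") c(1, w$wdisc[-1L]) else w$wdisc
  disc_total <- sum(vapply(names(per_cycle), function(comp)
    sum(per_cycle[[comp]] * weight_for(comp)), numeric(1L)))
  ledger <- NULL
  if (keep_ledger) {
    ledger <- do.call(rbind, lapply(names(per_cycle), function(comp) {
      data.frame(cycle = k, component = comp,
                 undiscounted = per_cycle[[comp]],
                 discounted = per_cycle[[comp]] * weight_for(comp))
    }))
  }
  list(total = strategy$coverage_fraction * disc_total, ledger = ledger)
}
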