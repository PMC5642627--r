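# Base-case parameter book: published model inputs plus the frozen
# calibration conventions (see the methods vignette and calibrate()).
seed: 20160326
threshold_per_qaly: 22200

model:
  cycle_length_days: 14
  horizon_years: 10
  discount_rate_annual: 0.05
  half_cycle_correction: false      # frozen by calibration

# Weibull scale/shape as fitted to the trial Kaplan-Meier data; the native
# time unit of each curve is a frozen calibration convention (no single unit
# reproduces the published life-year cells for all four curves).
curves:
  pfs_control:
    scale: 0.00267
    shape: 1.89552
    time_unit: cycle_14d
    label: "PFS, FOLFIRI control"
  pfs_cetuximab:
    scale: 0.00195
    shape: 1.52888
    time_unit: week
    label: "PFS, cetuximab + FOLFIRI"
  os_control:
    scale: 0.00540
    shape: 1.53841
    time_unit: month
    label: "OS, FOLFIRI control"
  os_cetuximab:
    scale: 0.00324
    shape: 1.26410
    time_unit: cycle_14d
    label: "OS, cetuximab + FOLFIRI"

# 2016 US dollars; ranges are the one-way bounds and triangular min/max.
costs:
  folfiri_per_cycle:   {base: 2050.5, low: 1083,   high: 3018}
  cetuximab_per_100mg: {base: 637.4,  low: 318.7,  high: 637.4}
  salvage_per_cycle:   {base: 2411.8, low: 1891,   high: 2739.1}
  ras_test_per_unit:   {base: 176.9,  low: 132.7,  high: 221.2}
  terminal_care:       {base: 1980.1, low: 769.2,  high: 5288.3}
  sae_vomiting:        {base: 175.7,  low: 134,    high: 223}
  sae_rash_acne:       {base: 11.1,   low: 6.2,    high: 16}
  sae_fatigue:         {base: 1524.6, low: 421.9,  high: 3322.6}
  sae_neutropenia:     {base: 2694.6, low: 2154.7, high: 3294}
  sae_diarrhea:        {base: 891.5,  low: 158.6,  high: 1104.6}

utilities:
  u_pfs:         {base: 0.85, low: 0.68, high: 1}
  u_pd_chemo:    {base: 0.24, low: 0.2,  high: 0.28}
  u_pd_targeted: {base: 0.68, low: 0.52, high: 0.78}

proportions:
  ras_prevalence: {base: 0.41, low: 0.366, high: 0.454}

dosing:
  loading_dose: 400          # mg/m2, first infusion only
  maintenance_dose: 250      # mg/m2, weekly
  infusions_per_cycle: 2
  vial_size: 100             # mg; opened vials are discarded
  bsa: {base: 1.72, low: 1.5, high: 1.9}

# Pay/donate supply calendar. cycles_per_month is the exact calendar value
# 26.0893/12; repeat_pay_months = 0 is a frozen calibration convention
# (donation continues after the two paid + two donated lead months).
pap:
  lead_pay_months: 2
  lead_free_months: 2
  repeat_pay_months: 0
  repeat_free_months: 3
  cycles_per_month: 2.174107142857143

conventions:
  coverage_fraction: 0.6            # catastrophic-insurance payer share
  salvage_cycles_cap: 3             # salvage cycles charged per progressor
  terminal_care_mode: once_at_death
  cetuximab_costing: per_cycle_price
  pd_targeted_fraction_cetux_arm: 0.3713568328
  sae_probabilities: {}             # per-event probabilities; none published

# Published base-case cell values: inputs to calibrate(), which reproduces
# the frozen conventions above from them.
calibration_targets:
  control:
    cost: 30668
    pf_ly: 0.795
    total_ly: 2.066
    qaly: 0.963
  cetuximab_no_pap:
    cost: 47754
    pf_ly: 0.944
    total_ly: 2.796
    qaly: 1.593
  cetuximab_pap:
    cost: 39511
  increments:
    cost_no_pap: 17086
    cost_pap: 8843
    qaly: 0.63
    pf_ly: 0.149
    icer_qaly_pap: 14049
    icer_qaly_no_pap: 27145
    icer_ly_pap: 12107
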