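#!/usr/bin/env Rscript
# Command-line front end over the cetuxcea package.
#
# Usage:
#   Rscript scripts/cea.R <subcommand> [--config FILE] [--seed INT]
#                         [--out-dir DIR] [--threshold DOLLARS]
#
# Subcommands: base-case | tornado | psa | ceac | calibrate | simulate-km

suppressPackageStartupMessages({
  library(optparse)
  library(cetuxcea)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1] else ""
parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML parameter file [default: shipped fixture]"),
  make_option("--seed", type = "integer", default = NULL,
              help = "RNG seed [default: config seed]"),
  make_option("--out-dir", dest = "out_dir", type = "character",
              default = "results", help = "output directory"),
  make_option("--threshold", type = "double", default = NULL,
              help = "willingness to pay per QALY [default: config value]"),
  make_option("--draws", type = "integer", default = 1000L,
              help = "PSA draws"),
  make_option("--no-pap", dest = "no_pap", action = "store_true",
              default = FALSE, help = "disable the PAP for cetuximab")
))
opts <- parse_args(parser, args = args[-1])

ps <- if (is.null(opts$config)) default_paramset() else load_config(opts$config)
seed <- if (is.null(opts$seed)) ps$seed else opts$seed
threshold <- if (is.null(opts$threshold)) ps$threshold_per_qaly else opts$threshold
pap <- !opts$no_pap
dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
out_file <- function(name) file.path(opts$out_dir, name)
log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ..., "\n")

if (cmd == "base-case") {
  bc <- run_base_case(ps)
  print(bc)
  df <- as.data.frame(bc)
  utils::write.csv(df, out_file("base_case.csv"), row.names = FALSE)
  jsonlite::write_json(df, out_file("base_case.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  log_line("base-case written to", opts$out_dir, "| config", ps$source)
} else if (cmd == "tornado") {
  tor <- run_tornado(ps, pap_enabled = pap)
  utils::write.csv(tor, out_file("tornado.csv"), row.names = FALSE)
  print(utils::head(as.data.frame(tor), 10))
  log_line("tornado written | PAP", pap)
} else if (cmd %in% c("psa", "ceac")) {
  psa <- run_psa(ps, opts$draws, seed = seed, pap_enabled = pap)
  print(psa)
  utils::write.csv(psa$draws, out_file("psa_draws.csv"), row.names = FALSE)
  grid <- seq(0, 60000, by = 1000)
  cc <- ceac(psa, sort(unique(c(grid, threshold, 22000))))
  utils::write.csv(cc, out_file("ceac.csv"), row.names = FALSE)
  at <- cc[cc$threshold == threshold, ]
  cat(sprintf("P(cetuximab cost-effective at $%s/QALY) = %.3f\n",
              format(threshold, big.mark = ","), at$p_cetuximab))
  log_line("psa/ceac written | seed", seed, "| draws", opts$draws,
           "| PAP", pap)
} else if (cmd == "calibrate") {
  cal <- calibrate(ps)
  print(cal)
  utils::write.csv(cal$residuals, out_file("calibration_residuals.csv"),
                   row.names = FALSE)
  log_line("calibration residuals written")
} else if (cmd == "simulate-km") {
  set.seed(seed)
  for (nm in names(ps$curves)) {
    ipd <- simulate_ipd(ps$curves[[nm]], n = 600, censor_rate = 0.2)
    km <- km_estimate(ipd)
    utils::write.csv(ipd, out_file(paste0("ipd_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(km, out_file(paste0("km_", nm, ".csv")),
                     row.names = FALSE)
    fit <- fit_weibull(ipd)
    cat(nm, ": ")
    print(fit)
  }
  log_line("synthetic KM data written | seed", seed)
} else {
  optparse::print_help(parser)
  cat("Subcommands: base-case tornado psa ceac calibrate simulate-km\n")
  if (!cmd %in% c("", "-h", "--help")) quit(status = 1)
}
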