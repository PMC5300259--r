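# Step 5 — assemble the summary tables.
#
# Aggregates the per-cell fit tables from steps 2-4 into pharmacology
# (table2.csv), time-course (table3.csv) and open-probability (table4.csv)
# summaries with a provenance block, mirroring the layout the per-cell
# estimates are conventionally reported in.

source(file.path("analysis", "00_common.R"))

cr <- utils::read.csv(file.path(RESULTS, "dose_response_fits.csv"))
deact <- utils::read.csv(file.path(RESULTS, "deactivation_fits.csv"))
popen <- utils::read.csv(file.path(RESULTS, "popen_estimates.csv"))

pharm <- data.frame(composition = cr$composition,
                    parameter = "glutamate_ec50_uM", value = cr$ec50)
tc_cols <- c("peak_density", "ss_density", "i_ss_over_i_peak", "rise_10_90",
             "tau_fast", "tau_slow", "percent_fast", "tau_w",
             "charge_transfer")
tables <- build_report(pharmacology = pharm,
                       time_course = deact[, c("composition", tc_cols)],
                       open_probability = popen,
                       out_dir = RESULTS, seed = SEED)

for (nm in names(tables)) {
  cat("\n==", nm, "==\n")
  df <- tables[[nm]]
  df$formatted <- vapply(seq_len(nrow(df)), function(i)
    format_summary(df[i, ], 3), character(1))
  print(df[, c("composition", "parameter", "formatted")], row.names = FALSE)
}
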