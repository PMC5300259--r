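# Step 1 — generate and inspect example synthetic recordings.
#
# Writes one representative trace per experiment type (wild-type
# concentration-response, wild-type and mutant glutamate pulses, wild-type
# MK-801 block onset) to results/traces/ in the CSV + JSON-sidecar
# interchange format, and verifies the round trip. Finding: the wild-type
# pulse shows the expected strongly desensitizing, slowly deactivating
# response; the mutant pulse is small, barely desensitizing and fast.

source(file.path("analysis", "00_common.R"))

out <- file.path(RESULTS, "traces")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

wt <- MODELS$WT2A
mu <- MODELS$`2A-D731N`

examples <- list(
  wt_cr = simulate_current(wt, protocol_activation("glutamate", CR_CONCS$WT2A),
                           oocyte_of("WT2A"), noise_sd = 20, seed = SEED,
                           sample_interval = 50),
  wt_pulse = simulate_current(wt, protocol_pulse(), hek_of("WT2A"),
                              noise_sd = 5, seed = SEED + 1,
                              sample_interval = 0.2),
  mut_pulse = simulate_current(mu, protocol_pulse(), hek_of("2A-D731N"),
                               noise_sd = 0.5, seed = SEED + 2,
                               sample_interval = 0.2),
  wt_mk801 = simulate_current(wt, protocol_mk801(glutamate = EC50_GLU["WT2A"]),
                              oocyte_of("WT2A"), noise_sd = 10, seed = SEED + 3,
                              sample_interval = 25)
)

for (nm in names(examples)) {
  path <- file.path(out, paste0(nm, ".csv"))
  write_trace(examples[[nm]], path)
  rt <- read_trace(path)
  stopifnot(max(abs(rt$current - examples[[nm]]$current)) < 1e-6)
}

wt_b <- baseline_correct(examples$wt_pulse, c(0, 90))
mu_b <- baseline_correct(examples$mut_pulse, c(0, 90))
cat(sprintf("WT pulse:     peak %8.1f pA  (%.0f pA/pF),  Iss/Ipeak %.2f\n",
            epoch_response(wt_b, 2, "peak"),
            abs(epoch_response(wt_b, 2, "peak")) / 20,
            epoch_response(wt_b, 2, "steady") / epoch_response(wt_b, 2, "peak")))
cat(sprintf("mutant pulse: peak %8.1f pA  (%.1f pA/pF),  Iss/Ipeak %.2f\n",
            epoch_response(mu_b, 2, "peak"),
            abs(epoch_response(mu_b, 2, "peak")) / 20,
            epoch_response(mu_b, 2, "steady") / epoch_response(mu_b, 2, "peak")))
cat("wrote", length(examples), "example traces to", out, "\n")
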