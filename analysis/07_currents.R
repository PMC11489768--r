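#!/usr/bin/env Rscript
# Patch-clamp current analysis of the simulated sweeps: bi-exponential
# decay fit with weighted tau, charge transfer, paired-pulse ratio, and
# sEPSC detection, each against its planted truth.

library(nicocircuit)

data_dir <- "results/data"

sw <- read_sweep(file.path(data_dir, "puff_decay.csv"))
attr(sw, "onset_s") <- 0.05
f <- fit_decay(sw)
q <- charge_transfer(sw, 0.05, max(sw$time_s))
cat(sprintf(
  "puff decay: %d-term fit; AF %.0f pA tau_f %.1f ms, AS %.0f pA tau_s %.1f ms\n  tau_w %.1f ms (planted 27.5 ms); charge %.1f pC\n",
  f$n_terms, f$AF, f$tau_f_ms, f$AS, f$tau_s_ms, f$tau_w_ms, q
))

ep <- read_sweep(file.path(data_dir, "evoked_pair.csv"))
ppr <- evoked_ratios(ep, "ppr", stim_times = c(0.05, 0.10))
cat(sprintf("paired pulses: PPR %.2f (planted 150/120 = 1.25)\n", ppr))

se <- read_sweep(file.path(data_dir, "sepsc.csv"))
truth <- utils::read.csv(file.path(data_dir, "sepsc_truth.csv"))
dv <- detect_sepscs(se)
cat(sprintf(
  "sEPSCs: %d detected vs %d planted in 30 s (%.2f Hz); mean amplitude %.1f pA (planted %.0f)\n",
  dv$n_events, truth$n_events, dv$frequency_hz, mean(dv$amplitudes_pA),
  truth$amp_mean_pA
))

utils::write.csv(
  data.frame(measure = c("n_terms", "AF_pA", "tau_f_ms", "AS_pA",
                         "tau_s_ms", "tau_w_ms", "charge_pC", "ppr",
                         "sepsc_hz", "sepsc_amp_pA"),
             value = c(f$n_terms, f$AF, f$tau_f_ms, f$AS, f$tau_s_ms,
                       f$tau_w_ms, q, ppr, dv$frequency_hz,
                       mean(dv$amplitudes_pA))),
  "results/current_summary.csv", row.names = FALSE
)
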