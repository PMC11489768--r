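#!/usr/bin/env Rscript
# Generate one seeded synthetic dataset per modality and write it in the
# CSV/TIFF dialects the downstream analysis scripts read. Every dataset
# carries known ground truth, so each later stage can be checked against
# what was planted.

library(nicocircuit)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# Two-bottle choice: one cohort of 8 animals, 8 nicotine sessions each,
# preferences spanning the range seen across doses, sparse artifacts.
prefs <- round(seq(0.45, 0.8, length.out = 8), 2)
for (i in seq_along(prefs)) {
  s <- gen_drink_series(8, prefs[i], artifact_rate = 2e-4, seed = 100 + i,
                        animal = sprintf("m%02d", i))
  write_bottle_series(
    s,
    file.path(out, sprintf("drink_m%02d_volumes.csv", i)),
    file.path(out, sprintf("drink_m%02d_labels.csv", i)),
    file.path(out, sprintf("drink_m%02d_weights.csv", i))
  )
}
writeLines(paste(sprintf("m%02d", seq_along(prefs)), prefs, sep = ","),
           file.path(out, "drink_truth.csv"))

# EOM zone traces: saline-like flat bias vs nicotine-like late suppression.
set.seed(199)
jit <- function(m, n = 8) pmin(pmax(rnorm(n, m, 0.05), 0.02), 0.95)
eom_design <- rbind(
  data.frame(animal = sprintf("sal%02d", 1:8), b1 = jit(0.30),
             b2 = jit(0.28), b3 = jit(0.27), group = "saline"),
  data.frame(animal = sprintf("nic%02d", 1:8), b1 = jit(0.30),
             b2 = jit(0.22), b3 = jit(0.12), group = "nicotine")
)
for (i in seq_len(nrow(eom_design))) {
  tr <- gen_behavior_session(
    "eom", list(bias = unlist(eom_design[i, c("b1", "b2", "b3")])),
    fps = 30, seed = 200 + i
  )
  utils::write.csv(tr, file.path(out, paste0("eom_", eom_design$animal[i],
                                             ".csv")),
                   row.names = FALSE)
}
utils::write.csv(eom_design, file.path(out, "eom_design.csv"),
                 row.names = FALSE)

# Spike trains: a population with activated, inhibited and flat responders.
kinds <- rep(c("activated", "inhibited", "flat"), times = c(10, 6, 4))
mags <- ifelse(kinds == "activated", 0.8, ifelse(kinds == "inhibited",
                                                 0.7, 0))
sp_rows <- list(); ev_rows <- list()
for (k in seq_along(kinds)) {
  tr <- gen_spike_train(600, 4, kinds[k], mags[k], 300, seed = 300 + k)
  unit <- sprintf("u%02d", k)
  sp_rows[[k]] <- data.frame(unit = unit, spike_time_s = tr$spikes)
  ev_rows[[k]] <- data.frame(unit = unit, event_time_s = 300,
                             event_type = "nicotine")
}
utils::write.csv(do.call(rbind, sp_rows), file.path(out, "spikes.csv"),
                 row.names = FALSE)
utils::write.csv(do.call(rbind, ev_rows), file.path(out, "spike_events.csv"),
                 row.names = FALSE)
utils::write.csv(data.frame(unit = sprintf("u%02d", seq_along(kinds)),
                            kind = kinds, magnitude = mags),
                 file.path(out, "spike_truth.csv"), row.names = FALSE)

# Region counts: strong 2-module coactivation in controls, restructured
# (merged) coactivation in the treated group, plus mean increases in the
# regions of interest.
regs <- c("NAc", "VTA", "PrL", "BLA", "BMA", "MeA", "CeA", "PVT", "LHb",
          "DRN", "VP", "LS")
mods <- list(c("NAc", "VTA", "PrL", "VP", "LS", "PVT"),
             c("BLA", "BMA", "MeA", "CeA", "LHb", "DRN"))
shift <- stats::setNames(rep(1, length(regs)), regs)
shift[c("NAc", "VTA", "PrL", "VP")] <- 1.5
rc_a <- gen_region_counts(12, regs, mods, 0.75, seed = 400)
rc_b <- gen_region_counts(12, regs, list(regs), 0.5,
                          group_mean_shift = shift, seed = 401)
rc_a$counts[rc_a$group == "NIC", ] <- rc_b$counts[rc_b$group == "NIC", ]
write_region_counts(rc_a, file.path(out, "region_counts.csv"))

# Bouton stacks: three stacks at SNR 10 with planted spot tables.
for (k in 1:3) {
  sp <- local({
    set.seed(500 + k)
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < 20) {
      p <- runif(3, 0.8, 8 - 0.8)
      if (nrow(pts) == 0 || min(sqrt(colSums((t(pts) - p)^2))) > 1.3) {
        pts <- rbind(pts, p)
      }
    }
    data.frame(y_um = pts[, 1], x_um = pts[, 2], z_um = pts[, 3],
               amplitude = 100, sigma_y_um = 0.15, sigma_x_um = 0.15,
               sigma_z_um = 0.3)
  })
  st <- gen_bouton_stack(c(160, 160, 40), c(0.05, 0.05, 0.2), sp,
                         background = 10, noise_sd = 10, seed = 510 + k)
  write_stack_tiff(st, file.path(out, sprintf("boutons_%d.tif", k)))
  utils::write.csv(sp, file.path(out, sprintf("boutons_%d_truth.csv", k)),
                   row.names = FALSE)
}

# Patch-clamp sweeps: nicotinic puff decays, evoked pairs, sEPSC epochs.
sw <- gen_current_trace("puff_decay",
                        list(AF = 300, AS = 100, tau_f_ms = 10,
                             tau_s_ms = 80, onset_s = 0.05,
                             duration_s = 0.7),
                        noise_sd = 5, seed = 600)
utils::write.csv(as.data.frame(sw), file.path(out, "puff_decay.csv"),
                 row.names = FALSE)
ep <- gen_current_trace("evoked_pair", list(amp1 = 120, amp2 = 150),
                        noise_sd = 2, seed = 601)
utils::write.csv(as.data.frame(ep), file.path(out, "evoked_pair.csv"),
                 row.names = FALSE)
se <- gen_current_trace("sepsc_train",
                        list(rate_hz = 2, amp_mean_pA = 30,
                             duration_s = 30),
                        noise_sd = 30 / 8, seed = 602)
utils::write.csv(as.data.frame(se), file.path(out, "sepsc.csv"),
                 row.names = FALSE)
utils::write.csv(
  data.frame(n_events = length(attr(se, "event_times_s")),
             amp_mean_pA = 30),
  file.path(out, "sepsc_truth.csv"), row.names = FALSE
)

cat("simulated inputs written under", out, "\n")
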