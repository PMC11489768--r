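test_that("generators are deterministic given a seed", {
  a <- gen_drink_series(2, 0.6, seed = 11)
  b <- gen_drink_series(2, 0.6, seed = 11)
  expect_identical(a$volumes, b$volumes)
  expect_identical(ground_truth(a)$seed, 11)

  s1 <- gen_spike_train(400, 4, "activated", 0.5, 200, seed = 3)
  s2 <- gen_spike_train(400, 4, "activated", 0.5, 200, seed = 3)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- gen_spike_train(400, 4, "activated", 0.5, 200, seed = 4)
  expect_false(identical(s1$spikes, s3$spikes))

  r1 <- gen_region_counts(5, paste0("R", 1:6),
                          list(paste0("R", 1:3), paste0("R", 4:6)),
                          0.5, seed = 7)
  r2 <- gen_region_counts(5, paste0("R", 1:6),
                          list(paste0("R", 1:3), paste0("R", 4:6)),
                          0.5, seed = 7)
  expect_identical(r1$counts, r2$counts)
})

test_that("generated values respect physical domains", {
  s <- gen_drink_series(3, 0.5, artifact_rate = 0.001, seed = 2)
  expect_true(all(s$volumes$left >= 0) && all(s$volumes$right >= 0))
  tr <- gen_spike_train(400, 4, "flat", 0, 200, seed = 1)
  expect_true(all(diff(tr$spikes) > 0))
  rc <- gen_region_counts(4, paste0("R", 1:4), list(paste0("R", 1:4)),
                          0.3, seed = 1)
  expect_true(all(rc$counts >= 0))
  expect_true(all(rc$counts == round(rc$counts)))
})

test_that("generator parameter validation rejects bad inputs", {
  expect_error(gen_region_counts(5, paste0("R", 1:4),
                                 list(paste0("R", 1:4)), 1.0),
               "within_module_rho")
  expect_error(gen_region_counts(5, paste0("R", 1:4),
                                 list(paste0("R", 1:3)), 0.5),
               "partition")
  expect_error(gen_region_counts(5, paste0("R", 1:4),
                                 list(paste0("R", 1:4), character(0)), 0.5),
               "empty|partition")
  expect_error(gen_spike_train(400, 4, "inhibited", 1.5, 200),
               "magnitude")
  expect_error(gen_spike_train(100, 4, "flat", 0, 50), "duration")
  expect_error(gen_behavior_session("eom", list(bias = c(0.5, 1.2, 0))),
               "bias")
  expect_error(gen_current_trace("puff_decay",
                                 list(AF = 1, tau_f_ms = -2)),
               "positive")
})

test_that("region-count generator plants correlation blocks and mean shifts", {
  regs <- paste0("R", 1:10)
  mods <- list(regs[1:5], regs[6:10])

  # independence: rho = 0 (n large enough that sampling error sits well
  # inside the band)
  rc0 <- gen_region_counts(500, regs, mods, 0, seed = 21)
  r0 <- cor(rc0$counts[rc0$group == "SAC", ])
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.15)

  # rho = 0.8 blocks: within > between
  rc <- gen_region_counts(100, regs, mods, 0.8, seed = 22)
  r <- cor(rc$counts[rc$group == "SAC", ])
  same <- outer(rep(1:2, each = 5), rep(1:2, each = 5), `==`)
  within_r <- mean(r[same & upper.tri(r)])
  between_r <- mean(r[!same & upper.tri(r)])
  expect_gt(within_r, between_r)
  expect_gt(within_r, 0.6)

  # mean shift recovery
  sh <- setNames(rep(1, 10), regs); sh["R3"] <- 2
  rc2 <- gen_region_counts(100, regs, mods, 0.3, group_mean_shift = sh,
                           seed = 23)
  ratio <- mean(rc2$counts[rc2$group == "NIC", "R3"]) /
    mean(rc2$counts[rc2$group == "SAC", "R3"])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("spike generator rates and burst contract hold", {
  flat <- gen_spike_train(600, 4, "flat", 0, 300, seed = 31)
  expect_lt(abs(length(flat$spikes) / 600 - 4) / 4, 0.1)

  act <- gen_spike_train(600, 4, "activated", 0.8, 300, seed = 32,
                         response_duration_s = 180)
  pre <- sum(act$spikes < 300) / 300
  post <- sum(act$spikes >= 300 & act$spikes < 480) / 180
  expect_lt(abs(post / pre - 1.8), 0.25)

  # burst_fraction 0: no two consecutive ISIs below 80 ms, by construction
  for (sd in 1:5) {
    tr <- gen_spike_train(400, 6, "flat", 0, 200, burst_fraction = 0,
                          seed = sd)
    isi <- diff(tr$spikes)
    expect_false(any(isi[-1] < 0.08 & isi[-length(isi)] < 0.08))
  }
})

test_that("drinking generator plants preference and artifact structure", {
  # artifact_rate 0: nothing above the cleaning threshold
  s0 <- gen_drink_series(4, 0.5, artifact_rate = 0, seed = 41)
  expect_true(all(c(s0$volumes$left, s0$volumes$right) <= 0.1))

  # symmetric preference: near-equal totals over a cohort of 8-day animals
  # (pooling animals keeps the sampling error of the share well inside 5%)
  tot_l <- tot_r <- 0
  for (sd_a in 1:8) {
    s5 <- gen_drink_series(8, 0.5, seed = 42 + sd_a)
    tot_l <- tot_l + sum(s5$volumes$left)
    tot_r <- tot_r + sum(s5$volumes$right)
  }
  expect_lt(abs(tot_l - tot_r) / (tot_l + tot_r), 0.05)

  # drinking concentrated after dark onset
  s <- gen_drink_series(6, 0.5, dark_onset_hour = 20, seed = 43)
  hrs <- as.POSIXlt(s$volumes$timestamp, tz = "UTC")$hour
  dark <- hrs >= 20 | hrs < 8
  vol <- s$volumes$left + s$volumes$right
  expect_gt(sum(vol[dark]), 1.5 * sum(vol[!dark]))
  # peak hour falls shortly after dark onset
  peak_hr <- as.integer(names(which.max(tapply(vol, hrs, sum))))
  expect_true(peak_hr %in% c(20, 21, 22, 23))
})

test_that("behavior session generator respects programmed bias", {
  tr <- gen_behavior_session("eom", list(bias = c(0.3, 0.3, 0.1)), seed = 51)
  bt <- eom_block_times(tr)
  expect_lt(bt$open_pct[3], bt$open_pct[1])

  tr0 <- gen_behavior_session("eom", list(bias = c(0, 0, 0)), seed = 52)
  expect_true(all(tr0$zone == "closed"))

  cp <- gen_behavior_session("cpp", list(shift = 100), seed = 53)
  expect_equal(sum(cp["pretest", ]), 900, tolerance = 1e-9)
  expect_equal(sum(cp["test", ]), 900, tolerance = 1e-9)
})

test_that("bouton stack generator places spots where it says", {
  sp <- data.frame(y_um = 2, x_um = 3, z_um = 4, amplitude = 50,
                   sigma_um = 0.3)
  st <- gen_bouton_stack(c(40, 60, 40), c(0.1, 0.1, 0.2), sp,
                         background = 5, noise_sd = 0)
  pk <- arrayInd(which.max(st$data), dim(st$data))
  expect_equal(as.numeric((pk - 0.5) * st$voxel_size_um), c(2, 3, 4),
               tolerance = 0.21)

  st0 <- gen_bouton_stack(c(10, 10, 5), c(0.1, 0.1, 0.2),
                          sp[0, , drop = FALSE], background = 7,
                          noise_sd = 0)
  expect_true(all(st0$data == 7))

  expect_error(
    gen_bouton_stack(c(10, 10, 5), c(0.1, 0.1, 0.2),
                     data.frame(y_um = 99, x_um = 1, z_um = 1,
                                amplitude = 1, sigma_um = 0.1)),
    "inside"
  )
  sp_small <- data.frame(y_um = 0.5, x_um = 0.5, z_um = 0.5,
                         amplitude = 10, sigma_um = 0.1)
  expect_error(
    gen_bouton_stack(c(10, 10, 5), c(0.1, 0.1, 0.2),
                     rbind(sp_small, sp_small)),
    "[Dd]uplicate"
  )
})

test_that("current trace generator matches its closed forms", {
  # mono-exponential: I(tau)/I(0) = 1/e
  sw <- gen_current_trace("puff_decay",
                          list(AF = 300, tau_f_ms = 10, onset_s = 0))
  i0 <- abs(sw$current_pA[sw$time_s == 0])
  itau <- abs(sw$current_pA[which.min(abs(sw$time_s - 0.010))])
  expect_equal(itau / i0, exp(-1), tolerance = 0.02)

  # sEPSC planted count near rate * duration
  se <- gen_current_trace("sepsc_train",
                          list(rate_hz = 2, amp_mean_pA = 30,
                               duration_s = 30), seed = 61)
  n_pl <- length(attr(se, "event_times_s"))
  expect_lt(abs(n_pl - 60), 4 * sqrt(60))

  # evoked pair peaks at the requested amplitudes
  ep <- gen_current_trace("evoked_pair", list(amp1 = 50, amp2 = 75))
  expect_equal(max(abs(ep$current_pA[ep$time_s < 0.0999])), 50,
               tolerance = 0.01)
})

test_that("generated data round-trips through the CSV dialects", {
  tmp <- withr::local_tempdir()
  s <- gen_drink_series(2, 0.6, seed = 71)
  write_bottle_series(s, file.path(tmp, "v.csv"), file.path(tmp, "l.csv"),
                      file.path(tmp, "w.csv"))
  s2 <- read_bottle_series(file.path(tmp, "v.csv"), file.path(tmp, "l.csv"),
                           file.path(tmp, "w.csv"))
  expect_equal(sum(s2$volumes$left), sum(s$volumes$left))
  expect_equal(nrow(s2$labels), nrow(s$labels))

  rc <- gen_region_counts(4, paste0("R", 1:5), list(paste0("R", 1:5)),
                          0.2, seed = 72)
  write_region_counts(rc, file.path(tmp, "rc.csv"))
  rc2 <- read_region_counts(file.path(tmp, "rc.csv"))
  expect_equal(rc2$counts[rownames(rc$counts), rc$regions], rc$counts)

  st <- gen_bouton_stack(c(16, 16, 4), c(0.1, 0.1, 0.2),
                         data.frame(y_um = 0.8, x_um = 0.8, z_um = 0.4,
                                    amplitude = 100, sigma_um = 0.2),
                         background = 10, noise_sd = 0)
  write_stack_tiff(st, file.path(tmp, "s.tif"))
  st2 <- read_stack_tiff(file.path(tmp, "s.tif"), c(0.1, 0.1, 0.2))
  # 16-bit quantization bounds the round-trip error by one grey level
  expect_lt(max(abs(st2$data - st$data)), 1.01)
})
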