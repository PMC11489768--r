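test_that("weighted tau obeys its formula, limits, and invariances", {
  expect_equal(weighted_tau(1, 0, 2, 4), 2)    # AS = 0: tau_w = tau_f
  expect_equal(weighted_tau(1, 1, 2, 4), 3)    # equal weights: midpoint
  # convex combination and rescaling invariance
  set.seed(1)
  for (k in 1:20) {
    af <- runif(1, 0.1, 5); as_ <- runif(1, 0.1, 5)
    tf <- runif(1, 1, 10); ts_ <- tf + runif(1, 1, 50)
    tw <- weighted_tau(af, as_, tf, ts_)
    expect_gte(tw, tf); expect_lte(tw, ts_)
    expect_equal(weighted_tau(3 * af, 3 * as_, tf, ts_), tw)
  }
  expect_error(weighted_tau(-1, 1, 2, 4), "nonnegative")
})

test_that("decay fitting recovers parameters and selects model order", {
  sw <- gen_current_trace("puff_decay",
                          list(AF = 300, AS = 100, tau_f_ms = 10,
                               tau_s_ms = 80, onset_s = 0.05,
                               duration_s = 0.7),
                          noise_sd = 5, seed = 2)
  f <- fit_decay(sw)
  expect_true(f$converged)
  expect_equal(f$n_terms, 2L)
  expect_lt(abs(f$AF / 300 - 1), 0.05)
  expect_lt(abs(f$AS / 100 - 1), 0.05)
  expect_lt(abs(f$tau_f_ms / 10 - 1), 0.05)
  expect_lt(abs(f$tau_s_ms / 80 - 1), 0.05)
  expect_lt(abs(f$tau_w_ms - 27.5), 1.5)
  expect_true(f$tau_f_ms < f$tau_s_ms)

  # noiseless mono-exponential: 1 term chosen, tau exact
  sw1 <- gen_current_trace("puff_decay", list(AF = 300, tau_f_ms = 10))
  f1 <- fit_decay(sw1)
  expect_equal(f1$n_terms, 1L)
  expect_equal(f1$tau_f_ms, 10, tolerance = 1e-3)
  expect_equal(f1$tau_w_ms, f1$tau_f_ms)
})

test_that("model selection finds the second component when it matters", {
  # amplitude share of the slow component >= 20% at SNR ~20
  hits <- vapply(1:20, function(k) {
    sw <- gen_current_trace("puff_decay",
                            list(AF = 240, AS = 60, tau_f_ms = 8,
                                 tau_s_ms = 60, onset_s = 0.02,
                                 duration_s = 0.5),
                            noise_sd = 15, seed = 200 + k)
    fit_decay(sw)$n_terms == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("charge transfer matches closed forms and is additive", {
  tt <- seq(0, 0.5, by = 1e-4)
  rect <- structure(
    data.frame(time_s = tt,
               current_pA = ifelse(tt >= 0.1 & tt <= 0.2, -10, 0)),
    class = c("sweep", "data.frame")
  )
  expect_equal(charge_transfer(rect, 0.1, 0.2, baseline = 0), 1,
               tolerance = 1e-3)
  zero <- rect; zero$current_pA <- 0
  expect_equal(charge_transfer(zero, 0, 0.5, baseline = 0), 0)

  # exponential: integral ~ A * tau
  ex <- structure(
    data.frame(time_s = tt, current_pA = -50 * exp(-tt / 0.02)),
    class = c("sweep", "data.frame")
  )
  expect_equal(charge_transfer(ex, 0, 0.5, baseline = 0), 50 * 0.02,
               tolerance = 0.01)

  # additivity over adjacent windows
  q_all <- charge_transfer(ex, 0, 0.4, baseline = 0)
  q_sum <- charge_transfer(ex, 0, 0.2, baseline = 0) +
    charge_transfer(ex, 0.2, 0.4, baseline = 0)
  expect_equal(q_all, q_sum, tolerance = 1e-9)

  expect_error(charge_transfer(ex, 0.3, 0.2), "precede")
  expect_error(charge_transfer(ex, 0.3, 0.9), "outside")
})

test_that("evoked ratios compute PPR and AMPA/NMDA decomposition", {
  ep <- gen_current_trace("evoked_pair", list(amp1 = 50, amp2 = 75))
  expect_equal(evoked_ratios(ep, "ppr"), 1.5, tolerance = 0.02)

  nmda <- gen_current_trace("puff_decay",
                            list(AF = 100, tau_f_ms = 40, onset_s = 0.05,
                                 duration_s = 0.6))
  comp <- nmda
  comp$current_pA <- comp$current_pA +
    gen_current_trace("puff_decay",
                      list(AF = 200, tau_f_ms = 5, onset_s = 0.05,
                           duration_s = 0.6))$current_pA
  attr(comp, "onset_s") <- 0.05
  expect_equal(evoked_ratios(comp, "ampa_nmda", sweep2 = nmda), 2,
               tolerance = 0.05)
  # identical sweeps: no AMPA component
  expect_equal(evoked_ratios(nmda, "ampa_nmda", sweep2 = nmda), 0)
})

test_that("pharmacology percent change recovers planted reductions", {
  b <- gen_current_trace("puff_decay",
                         list(AF = 100, tau_f_ms = 40, onset_s = 0.05,
                              duration_s = 0.6))
  d <- b; d$current_pA <- 0.6 * d$current_pA
  expect_equal(pharmacology_change(list(b), list(d)), -40,
               tolerance = 1e-6)
  expect_equal(pharmacology_change(list(b), list(b)), 0, tolerance = 1e-9)

  # planted 30% reduction with noise, averaged over sweeps
  bs <- lapply(1:6, function(k) {
    gen_current_trace("puff_decay",
                      list(AF = 100, tau_f_ms = 40, onset_s = 0.05,
                           duration_s = 0.6), noise_sd = 2, seed = k)
  })
  ds <- lapply(7:12, function(k) {
    sw <- gen_current_trace("puff_decay",
                            list(AF = 70, tau_f_ms = 40, onset_s = 0.05,
                                 duration_s = 0.6), noise_sd = 2, seed = k)
    sw
  })
  expect_lt(abs(pharmacology_change(bs, ds) - (-30)), 3)
})

test_that("sEPSC detection recovers planted rate and amplitude", {
  flat <- structure(
    data.frame(time_s = seq(0, 31, 1e-3), current_pA = 0),
    class = c("sweep", "data.frame")
  )
  expect_equal(detect_sepscs(flat)$n_events, 0L)

  found <- t(vapply(1:6, function(k) {
    se <- gen_current_trace("sepsc_train",
                            list(rate_hz = 2, amp_mean_pA = 30,
                                 duration_s = 30),
                            noise_sd = 30 / 8, seed = 300 + k)
    dv <- detect_sepscs(se)
    c(n_true = length(attr(se, "event_times_s")), n_found = dv$n_events,
      amp = mean(dv$amplitudes_pA))
  }, numeric(3)))
  expect_lt(abs(sum(found[, "n_found"]) / sum(found[, "n_true"]) - 1), 0.1)
  expect_lt(abs(mean(found[, "amp"]) - 30), 3)

  short <- structure(
    data.frame(time_s = seq(0, 10, 1e-3), current_pA = 0),
    class = c("sweep", "data.frame")
  )
  expect_warning(detect_sepscs(short), "30 s")
})
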