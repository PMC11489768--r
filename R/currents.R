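# Baseline (holding current) estimate from the pre-onset segment, or the
# first 10% of samples when no onset is known.
sweep_baseline <- function(sweep, onset = NULL) {
  if (!is.null(onset) && any(sweep$time_s < onset)) {
    mean(sweep$current_pA[sweep$time_s < onset])
  } else {
    mean(sweep$current_pA[seq_len(max(2, floor(nrow(sweep) * 0.1)))])
  }
}

#' Fit mono- or bi-exponential decay to a current transient
#'
#' Locates the response peak after `onset`, fits both a one- and a
#' two-exponential model to the baseline-subtracted decay by nonlinear
#' least squares, selects between them with the small-sample-corrected
#' Akaike criterion (AICc), and reports the amplitude-weighted time
#' constant tau_w = (AF tau_f + AS tau_s) / (AF + AS) (equal to tau for a
#' one-term fit). Amplitudes are reported as magnitudes regardless of the
#' stored sign convention.
#'
#' @param sweep A `sweep` (data frame `time_s`, `current_pA`).
#' @param onset Response onset time (s); defaults to the sweep's `onset_s`
#'   attribute or 0.
#' @return A `decay_fit` list: `n_terms`, `AF`, `AS` (pA), `tau_f_ms`,
#'   `tau_s_ms`, `tau_w_ms`, `peak_pA`, `rss`, `aicc_1`, `aicc_2`,
#'   `converged`. Non-convergence of both models is flagged
#'   (`converged = FALSE`), never silently replaced.
#' @export
fit_decay <- function(sweep, onset = NULL) {
  if (is.null(onset)) onset <- attr(sweep, "onset_s", exact = TRUE) %||% 0
  bl <- sweep_baseline(sweep, onset)
  post <- sweep[sweep$time_s >= onset, , drop = FALSE]
  dev <- post$current_pA - bl
  pk <- which.max(abs(dev))
  sgn <- sign(dev[pk])
  # orient the response positive; keep signed noise (rectifying would bias
  # the slow tail upward)
  y_full <- sgn * dev
  y <- y_full[pk:length(y_full)]
  t <- post$time_s[pk:length(y_full)] - post$time_s[pk]
  if (length(y) < 10) stop("too few post-peak samples to fit", call. = FALSE)

  n <- length(y)
  aicc <- function(rss, k) {
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(1, n - k - 1)
  }

  # starting value for tau from the 1/e crossing of the lightly smoothed
  # decay (robust to tail noise, unlike a log-linear slope)
  a0 <- max(y)
  w_sm <- min(21L, max(1L, 2L * (n %/% 40) + 1L))
  y_sm <- as.numeric(stats::filter(y, rep(1 / w_sm, w_sm), sides = 2))
  y_sm[is.na(y_sm)] <- y[is.na(y_sm)]
  cross <- which(y_sm < a0 / exp(1))
  tau0 <- if (length(cross) > 0) max(t[cross[1]], 10 * (t[2] - t[1])) else
    max(t) / 3
  tau0 <- min(tau0, max(t) / 2)

  fit1 <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                      start = list(A = a0, tau = tau0),
                      lower = c(0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  fit2 <- tryCatch(
    minpack.lm::nlsLM(y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
                      start = list(A1 = a0 * 0.7, tau1 = tau0 / 3,
                                   A2 = a0 * 0.3, tau2 = tau0 * 3),
                      lower = c(0, 1e-6, 0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL
  )
  if (is.null(fit1) && is.null(fit2)) {
    return(structure(list(converged = FALSE), class = "decay_fit"))
  }
  rss1 <- if (!is.null(fit1)) sum(stats::residuals(fit1)^2) else Inf
  rss2 <- if (!is.null(fit2)) sum(stats::residuals(fit2)^2) else Inf
  a1 <- aicc(max(rss1, 1e-12), 3)  # A, tau, sigma
  a2 <- aicc(max(rss2, 1e-12), 5)

  if (!is.null(fit2) && a2 < a1) {
    cf <- stats::coef(fit2)
    taus <- c(cf[["tau1"]], cf[["tau2"]])
    amps <- c(cf[["A1"]], cf[["A2"]])
    ord <- order(taus)
    taus <- taus[ord]; amps <- amps[ord]
    tau_w <- sum(amps * taus) / sum(amps)
    out <- list(n_terms = 2L, AF = amps[1], AS = amps[2],
                tau_f_ms = taus[1] * 1000, tau_s_ms = taus[2] * 1000,
                tau_w_ms = tau_w * 1000, peak_pA = max(y_full),
                rss = rss2, aicc_1 = a1, aicc_2 = a2, converged = TRUE)
  } else {
    cf <- stats::coef(fit1)
    out <- list(n_terms = 1L, AF = cf[["A"]], AS = 0,
                tau_f_ms = cf[["tau"]] * 1000, tau_s_ms = NA_real_,
                tau_w_ms = cf[["tau"]] * 1000, peak_pA = max(y_full),
                rss = rss1, aicc_1 = a1, aicc_2 = a2, converged = TRUE)
  }
  structure(out, class = "decay_fit")
}

#' Weighted decay time constant
#'
#' tau_w = (AF tau_f + AS tau_s) / (AF + AS): the amplitude-weighted
#' average of the fast and slow decay constants, a convex combination of
#' the two and invariant to joint rescaling of the amplitudes.
#'
#' @param AF,AS Component amplitudes (>= 0, not both zero).
#' @param tau_f,tau_s Component time constants (any consistent unit).
#' @return tau_w in the units of `tau_f`/`tau_s`.
#' @export
weighted_tau <- function(AF, AS, tau_f, tau_s) {
  if (AF < 0 || AS < 0 || AF + AS == 0) {
    stop("amplitudes must be nonnegative and not both zero", call. = FALSE)
  }
  (AF * tau_f + AS * tau_s) / (AF + AS)
}

#' Charge transfer (area under the current)
#'
#' Trapezoidal integral of the baseline-subtracted current magnitude over
#' \[onset, end\], in pC (pA x s).
#'
#' @param sweep A `sweep`.
#' @param onset,end Integration window (s), inside the sweep.
#' @param baseline Baseline current (pA); default estimated from the
#'   pre-onset segment.
#' @return Charge in pC.
#' @export
charge_transfer <- function(sweep, onset, end, baseline = NULL) {
  if (onset >= end) stop("onset must precede end", call. = FALSE)
  if (onset < min(sweep$time_s) || end > max(sweep$time_s) + 1e-12) {
    stop("integration window outside the sweep", call. = FALSE)
  }
  if (is.null(baseline)) baseline <- sweep_baseline(sweep, onset)
  idx <- sweep$time_s >= onset & sweep$time_s <= end
  pracma::trapz(sweep$time_s[idx], abs(sweep$current_pA[idx] - baseline))
}

# Peak magnitude relative to a local baseline taken just before `from`.
local_peak <- function(sweep, from, to, pre_s = 0.01) {
  pre <- sweep$time_s >= from - pre_s & sweep$time_s < from
  bl <- if (any(pre)) mean(sweep$current_pA[pre]) else sweep_baseline(sweep)
  win <- sweep$time_s >= from & sweep$time_s <= to
  if (!any(win)) stop("empty peak window", call. = FALSE)
  max(abs(sweep$current_pA[win] - bl))
}

#' Evoked-response ratios: paired-pulse and AMPA/NMDA
#'
#' `mode = "ppr"`: ratio of the second to the first evoked peak of a
#' paired-pulse sweep (two stimuli 50 ms apart; times from the sweep's
#' `stim_times_s` attribute or `stim_times`). `mode = "ampa_nmda"`: ratio
#' of the AMPA component peak (composite minus the DNQX-resistant NMDA
#' sweep, point-wise) to the NMDA sweep peak, both baseline-subtracted. The
#' component peaks (not fixed-latency samples) are used.
#'
#' @param sweep Composite (or paired-pulse) `sweep`.
#' @param mode `"ppr"` or `"ampa_nmda"`.
#' @param sweep2 For `"ampa_nmda"`: the DNQX (NMDA-only) sweep on the same
#'   time base.
#' @param stim_times For `"ppr"`: the two stimulus times (s).
#' @return The requested ratio (numeric scalar).
#' @export
evoked_ratios <- function(sweep, mode = c("ppr", "ampa_nmda"),
                          sweep2 = NULL, stim_times = NULL) {
  mode <- match.arg(mode)
  if (mode == "ppr") {
    st <- stim_times %||% attr(sweep, "stim_times_s", exact = TRUE)
    if (is.null(st) || length(st) != 2) {
      stop("need two stimulus times for PPR", call. = FALSE)
    }
    gap <- st[2] - st[1]
    p1 <- local_peak(sweep, st[1], st[1] + gap * 0.9)
    p2 <- local_peak(sweep, st[2], st[2] + gap * 0.9)
    if (p1 <= 0) stop("undetectable first pulse", call. = FALSE)
    p2 / p1
  } else {
    if (is.null(sweep2)) stop("ampa_nmda mode needs the DNQX sweep",
                              call. = FALSE)
    if (nrow(sweep) != nrow(sweep2)) {
      stop("sweeps must share a time base", call. = FALSE)
    }
    bl1 <- sweep_baseline(sweep, attr(sweep, "onset_s", exact = TRUE))
    bl2 <- sweep_baseline(sweep2, attr(sweep2, "onset_s", exact = TRUE))
    nmda <- abs(sweep2$current_pA - bl2)
    ampa <- abs((sweep$current_pA - bl1) - (sweep2$current_pA - bl2))
    if (max(nmda) <= 0) stop("no NMDA component", call. = FALSE)
    max(ampa) / max(nmda)
  }
}

#' Percentage change of response under a drug
#'
#' Averages the baseline sweeps and the drug sweeps, computes the charge
#' (AUC, per [charge_transfer()]) of each average over the same window, and
#' reports 100 x (AUC_drug - AUC_baseline) / AUC_baseline — e.g. the
#' percent change of NMDA currents under ifenprodil relative to the stable
#' pre-drug baseline.
#'
#' @param baseline_sweeps,drug_sweeps Lists of `sweep`s on a common time
#'   base.
#' @param onset,end Integration window (s); defaults to the first baseline
#'   sweep's onset attribute and the end of the sweep.
#' @return Percent change (numeric scalar).
#' @export
pharmacology_change <- function(baseline_sweeps, drug_sweeps,
                                onset = NULL, end = NULL) {
  avg <- function(sweeps) {
    cur <- rowMeans(vapply(sweeps, function(s) s$current_pA,
                           numeric(nrow(sweeps[[1]]))))
    out <- sweeps[[1]]
    out$current_pA <- cur
    out
  }
  b <- avg(baseline_sweeps)
  d <- avg(drug_sweeps)
  if (is.null(onset)) {
    onset <- attr(baseline_sweeps[[1]], "onset_s", exact = TRUE) %||%
      min(b$time_s)
  }
  if (is.null(end)) end <- max(b$time_s)
  auc_b <- charge_transfer(b, onset, end)
  auc_d <- charge_transfer(d, onset, end)
  if (auc_b == 0) stop("zero baseline AUC", call. = FALSE)
  100 * (auc_d - auc_b) / auc_b
}

#' Detect spontaneous EPSCs by threshold crossing
#'
#' The trace is first smoothed with a 1 ms boxcar to suppress sample-wise
#' noise; events are then downward (inward) excursions of the smoothed
#' trace crossing baseline minus `detection_sd_mult` times the raw noise SD
#' (estimated robustly by the MAD of the trace), with a 5 ms refractory
#' between events. Event amplitude is the smoothed peak magnitude within
#' 10 ms of the crossing, relative to baseline.
#'
#' @param sweep A `sweep`.
#' @param epoch Length-2 numeric analysis window (s); default the whole
#'   sweep. Epochs shorter than 30 s trigger a warning.
#' @param detection_sd_mult Threshold multiplier k (default 3).
#' @param refractory_s Minimum separation between events (default 0.005).
#' @return List: `times_s`, `amplitudes_pA`, `n_events`, `frequency_hz`.
#' @export
detect_sepscs <- function(sweep, epoch = NULL, detection_sd_mult = 3,
                          refractory_s = 0.005) {
  if (is.null(epoch)) epoch <- range(sweep$time_s)
  if (diff(epoch) < 30) warning("epoch shorter than 30 s")
  idx <- sweep$time_s >= epoch[1] & sweep$time_s <= epoch[2]
  t <- sweep$time_s[idx]
  i_raw <- sweep$current_pA[idx]
  dt0 <- attr(sweep, "dt", exact = TRUE) %||% stats::median(diff(t))
  w_sm <- max(1L, round(0.001 / dt0))
  i <- as.numeric(stats::filter(i_raw, rep(1 / w_sm, w_sm), sides = 2))
  i[is.na(i)] <- i_raw[is.na(i)]
  bl <- stats::median(i)
  noise <- stats::mad(i_raw)
  thr <- bl - detection_sd_mult * noise
  rearm_thr <- bl - 1.5 * noise
  below <- i < thr
  onsets <- which(below & !c(FALSE, below[-length(below)]))
  above <- i > rearm_thr
  rearms <- which(above & !c(FALSE, above[-length(above)]))
  # Schmitt trigger: once an event fires, a new one needs the trace to
  # first recover above the re-arm level near baseline
  times <- numeric(0)
  amps <- numeric(0)
  last <- -Inf
  armed_until <- 0L
  for (k in onsets) {
    if (k <= armed_until) next
    if (t[k] - last < refractory_s) next
    nxt <- rearms[rearms > k]
    armed_until <- if (length(nxt)) nxt[1] else length(i)
    last <- t[k]
    w <- which(t >= t[k] & t <= t[k] + 0.01)
    times <- c(times, t[k])
    amps <- c(amps, max(abs(i[w] - bl)))
  }
  list(times_s = times, amplitudes_pA = amps, n_events = length(times),
       frequency_hz = length(times) / diff(epoch))
}
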