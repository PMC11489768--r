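# Stereotyped synaptic event template: difference-of-exponentials with
# unit peak, rise tau_r and decay tau_d (seconds).
event_template <- function(t, tau_r = 0.001, tau_d = 0.008) {
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  peak <- exp(-tp / tau_d) - exp(-tp / tau_r)
  out <- (exp(-t / tau_d) - exp(-t / tau_r)) / peak
  out[t < 0] <- 0
  out
}

#' Simulate a patch-clamp current sweep
#'
#' Three kinds of sweep are generated (inward currents stored negative):
#' \describe{
#'   \item{`puff_decay`}{A current step at `onset_s` decaying as
#'     AF exp(-t/tau_f) + AS exp(-t/tau_s); params `AF`, `AS` (pA),
#'     `tau_f_ms`, `tau_s_ms` (requires tau_f < tau_s when both present).}
#'   \item{`evoked_pair`}{Two stereotyped evoked transients 50 ms apart;
#'     params `amp1`, `amp2` (pA), optional `tau_rise_ms`, `tau_decay_ms`.}
#'   \item{`sepsc_train`}{Poisson spontaneous events with template shape;
#'     params `rate_hz`, `amp_mean_pA`, optional `amp_sd_pA`,
#'     `duration_s` (default 30).}
#' }
#'
#' @param kind One of `"puff_decay"`, `"evoked_pair"`, `"sepsc_train"`.
#' @param params Named list of kind-specific parameters (above).
#' @param dt Sampling interval in seconds (default 1e-4, i.e. 10 kHz).
#' @param noise_sd Gaussian noise SD in pA (default 0).
#' @param seed RNG seed.
#' @return A `sweep`: data frame `time_s`, `current_pA`, with attributes
#'   `dt`, `onset_s`/`stim_times_s`/`event_times_s` as appropriate, and
#'   [ground_truth()].
#' @export
gen_current_trace <- function(kind = c("puff_decay", "evoked_pair",
                                       "sepsc_train"),
                              params, dt = 1e-4, noise_sd = 0, seed = 1) {
  kind <- match.arg(kind)
  stopifnot_scalar(dt, "dt", lower = 0, strict_lower = TRUE)

  extra <- list()
  if (kind == "puff_decay") {
    AF <- params$AF; AS <- params$AS %||% 0
    tau_f <- params$tau_f_ms / 1000
    tau_s <- if (!is.null(params$tau_s_ms)) params$tau_s_ms / 1000 else Inf
    if (tau_f <= 0 || (is.finite(tau_s) && tau_s <= 0)) {
      stop("decay time constants must be positive", call. = FALSE)
    }
    if (AS > 0 && is.finite(tau_s) && tau_f >= tau_s) {
      stop("tau_f must be smaller than tau_s", call. = FALSE)
    }
    onset <- params$onset_s %||% 0.05
    dur <- params$duration_s %||%
      (onset + 6 * max(tau_f, if (AS > 0) tau_s else tau_f))
    t <- seq(0, dur, by = dt)
    td <- t - onset
    i <- ifelse(td < 0, 0,
                AF * exp(-td / tau_f) +
                  (if (AS > 0) AS * exp(-td / tau_s) else 0))
    current <- -i
    extra$onset_s <- onset
  } else if (kind == "evoked_pair") {
    tau_r <- (params$tau_rise_ms %||% 1) / 1000
    tau_d <- (params$tau_decay_ms %||% 8) / 1000
    stim <- c(0.05, 0.10)  # two pulses 50 ms apart
    dur <- params$duration_s %||% 0.25
    t <- seq(0, dur, by = dt)
    current <- -(params$amp1 * event_template(t - stim[1], tau_r, tau_d) +
                   params$amp2 * event_template(t - stim[2], tau_r, tau_d))
    extra$stim_times_s <- stim
  } else {
    dur <- params$duration_s %||% 30
    rate <- params$rate_hz
    amp_mean <- params$amp_mean_pA
    amp_sd <- params$amp_sd_pA %||% (0.1 * amp_mean)
    tau_r <- (params$tau_rise_ms %||% 1) / 1000
    tau_d <- (params$tau_decay_ms %||% 5) / 1000
    t <- seq(0, dur, by = dt)
    ev <- with_seed(seed, {
      n <- stats::rpois(1, rate * dur)
      times <- sort(stats::runif(n, 0, dur - 0.05))
      amps <- pmax(stats::rnorm(n, amp_mean, amp_sd), 0.2 * amp_mean)
      list(times = times, amps = amps)
    })
    current <- numeric(length(t))
    for (j in seq_along(ev$times)) {
      k0 <- floor(ev$times[j] / dt) + 1
      k1 <- min(length(t), k0 + ceiling(8 * tau_d / dt))
      idx <- k0:k1
      current[idx] <- current[idx] -
        ev$amps[j] * event_template(t[idx] - ev$times[j], tau_r, tau_d)
    }
    extra$event_times_s <- ev$times
    extra$event_amps_pA <- ev$amps
  }

  if (noise_sd > 0) {
    current <- current +
      with_seed(seed + 7L, stats::rnorm(length(current), sd = noise_sd))
  }
  sw <- data.frame(time_s = t, current_pA = current)
  class(sw) <- c("sweep", "data.frame")
  attr(sw, "dt") <- dt
  for (nm in names(extra)) attr(sw, nm) <- extra[[nm]]
  attr(sw, "ground_truth") <- new_ground_truth(
    paste0("current_", kind), c(params, list(noise_sd = noise_sd)), seed
  )
  sw
}
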