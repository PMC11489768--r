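#' Simulate a dopamine-like spike train with an injection response
#'
#' Spikes are drawn from a piecewise-constant-rate renewal process with a
#' 2 ms refractory period: baseline rate before the injection, rate scaled
#' by (1 + magnitude) (activated) or (1 - magnitude) (inhibited) for
#' `response_duration_s` after the injection, baseline again afterwards.
#' Optional bursting appends short-ISI followers (30-70 ms) to a fraction of
#' spikes. When `burst_fraction = 0`, the generator guarantees by
#' construction that no two consecutive inter-spike intervals are both
#' below 80 ms (so burst detection finds nothing).
#'
#' @param duration_s Recording duration (s); must exceed
#'   `injection_time_s + 180`.
#' @param baseline_rate_hz Baseline firing rate in (0.1, 15\] Hz.
#' @param response_kind `"activated"`, `"inhibited"`, or `"flat"`.
#' @param response_magnitude Fractional rate change; for `"inhibited"` it
#'   must lie in \[0, 1\].
#' @param injection_time_s Injection event time (s).
#' @param burst_fraction Fraction of spikes seeding a burst (default 0).
#' @param seed RNG seed.
#' @param response_duration_s Duration of the rate step after injection
#'   (default 180 s).
#' @param event_type Label for the injection event (default `"nicotine"`).
#' @return A `spike_train`: list with `spikes` (sorted timestamps, s),
#'   `events` (data frame `time`, `type`), `duration`. Ground truth records
#'   the planted parameters and, when bursting, the planted within-burst
#'   spike fraction.
#' @export
gen_spike_train <- function(duration_s, baseline_rate_hz,
                            response_kind = c("activated", "inhibited", "flat"),
                            response_magnitude = 0,
                            injection_time_s = duration_s / 2,
                            burst_fraction = 0, seed = 1,
                            response_duration_s = 180,
                            event_type = "nicotine") {
  response_kind <- match.arg(response_kind)
  stopifnot_scalar(baseline_rate_hz, "baseline_rate_hz",
                   lower = 0.1, upper = 15, strict_lower = TRUE)
  if (duration_s < injection_time_s + 180) {
    stop("duration must be at least injection_time_s + 180 s", call. = FALSE)
  }
  if (response_kind == "inhibited" &&
      (response_magnitude < 0 || response_magnitude > 1)) {
    stop("inhibited response magnitude must be in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar(burst_fraction, "burst_fraction", lower = 0, upper = 1)

  mult <- switch(response_kind,
                 activated = 1 + response_magnitude,
                 inhibited = 1 - response_magnitude,
                 flat = 1)
  refr <- 0.002
  seg <- data.frame(
    start = c(0, injection_time_s,
              min(injection_time_s + response_duration_s, duration_s)),
    end = c(injection_time_s,
            min(injection_time_s + response_duration_s, duration_s),
            duration_s),
    rate = c(baseline_rate_hz, baseline_rate_hz * mult, baseline_rate_hz)
  )
  seg <- seg[seg$end > seg$start, , drop = FALSE]

  out <- with_seed(seed, {
    if (burst_fraction > 0) {
      # Poisson-like renewal with a short dead time; bursts appended below
      spikes <- unlist(lapply(seq_len(nrow(seg)), function(i) {
        r <- seg$rate[i]
        if (r <= 0) return(numeric(0))
        r_eff <- r / max(1e-9, 1 - r * refr)
        len <- seg$end[i] - seg$start[i]
        n_guess <- stats::qpois(0.9999, len * r) + 20
        isi <- refr + stats::rexp(n_guess, r_eff)
        t <- seg$start[i] + cumsum(isi)
        t[t < seg$end[i]]
      }))
      spikes <- sort(spikes)
      in_burst <- logical(length(spikes))
      if (length(spikes) > 1) {
        seeds_b <- which(stats::runif(length(spikes)) < burst_fraction)
        extra <- lapply(seeds_b, function(i) {
          k <- 1L + stats::rpois(1, 1)
          spikes[i] + cumsum(stats::runif(k, 0.03, 0.07))
        })
        burst_members <- c(spikes[seeds_b], unlist(extra))
        spikes <- sort(unique(c(spikes, unlist(extra))))
        in_burst <- spikes %in% burst_members
      }
    } else {
      # Markov renewal honouring the no-two-consecutive-short-ISIs
      # contract natively: an ISI following a short one (< 80 ms) carries
      # an 80 ms dead time, and the exponential rate lambda is solved so
      # the stationary mean ISI is exactly 1/rate — no post-hoc thinning,
      # so segment rates are unbiased.
      gap <- 0.08
      lambda_for <- function(r) {
        f <- function(lam) {
          p <- 1 - exp(-gap * lam)       # P(short ISI | no dead time)
          1 / lam + gap * p / (1 + p) - 1 / r
        }
        stats::uniroot(f, c(r, 5000))$root
      }
      lam <- vapply(seg$rate, lambda_for, numeric(1))
      n_max <- ceiling(duration_s * max(seg$rate) * 1.5) + 100L
      spikes <- numeric(n_max)
      n_sp <- 0L
      t <- 0
      prev_short <- FALSE
      repeat {
        i <- which(t >= seg$start & t < seg$end)
        if (length(i) == 0) break
        isi <- stats::rexp(1, lam[i]) + if (prev_short) gap else 0
        prev_short <- isi < gap
        t <- t + max(isi, refr)
        if (t >= duration_s) break
        n_sp <- n_sp + 1L
        spikes[n_sp] <- t
      }
      spikes <- spikes[seq_len(n_sp)]
      in_burst <- logical(length(spikes))
    }
    list(spikes = spikes, in_burst = in_burst)
  })

  train <- structure(
    list(
      spikes = out$spikes,
      events = data.frame(time = injection_time_s, type = event_type,
                          stringsAsFactors = FALSE),
      duration = duration_s
    ),
    class = "spike_train"
  )
  planted_swb <- if (length(out$spikes) > 0) {
    100 * sum(out$in_burst[seq_along(out$spikes)]) / length(out$spikes)
  } else NA_real_
  attr(train, "ground_truth") <- new_ground_truth(
    "spike_train",
    list(duration_s = duration_s, baseline_rate_hz = baseline_rate_hz,
         response_kind = response_kind,
         response_magnitude = response_magnitude,
         injection_time_s = injection_time_s,
         response_duration_s = response_duration_s,
         burst_fraction = burst_fraction, planted_swb_pct = planted_swb),
    seed
  )
  train
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf(
    "<spike_train> %d spikes over %.0f s (%.2f Hz), %d event(s)\n",
    length(x$spikes), x$duration, length(x$spikes) / x$duration,
    nrow(x$events)
  ))
  invisible(x)
}
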