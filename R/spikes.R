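#' Sliding-window firing rate
#'
#' Firing frequency quantified on overlapping windows (default 60 s wide,
#' shifted by 15 s steps). Only windows lying fully inside the recording are
#' emitted; partial edge windows are dropped, never renormalized. Window
#' counts use the half-open convention \[center - w/2, center + w/2).
#'
#' @param train A `spike_train`.
#' @param window_s Window width in seconds (default 60).
#' @param step_s Step between window centers (default 15).
#' @return A `firing_timecourse`: data frame `center` (s), `rate` (Hz), with
#'   attributes `window_s`, `step_s`, and the train's events.
#' @export
sliding_rate <- function(train, window_s = 60, step_s = 15) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration < window_s) {
    stop("recording shorter than one window", call. = FALSE)
  }
  centers <- seq(window_s / 2, train$duration - window_s / 2, by = step_s)
  sp <- train$spikes
  rate <- vapply(centers, function(ct) {
    sum(sp >= ct - window_s / 2 & sp < ct + window_s / 2) / window_s
  }, numeric(1))
  tc <- data.frame(center = centers, rate = rate)
  class(tc) <- c("firing_timecourse", "data.frame")
  attr(tc, "window_s") <- window_s
  attr(tc, "step_s") <- step_s
  attr(tc, "events") <- train$events
  tc
}

#' Rescale a firing timecourse as percentage of baseline
#'
#' The baseline is the mean rate over windows lying fully inside the 3
#' minutes before the injection (\[injection - 180 s, injection)); each
#' window's rate is then expressed as 100 x rate / baseline. Units with zero
#' baseline cannot be normalized and raise an error (callers exclude them
#' with the reason recorded).
#'
#' @param tc A `firing_timecourse` from [sliding_rate()].
#' @param injection_time Injection time (s); defaults to the first event
#'   carried by the timecourse.
#' @param baseline_s Baseline duration before injection (default 180 s).
#' @return The timecourse with an added `normalized` column (percent of
#'   baseline) and attributes `baseline_hz` and `injection_time`.
#' @export
normalize_to_baseline <- function(tc, injection_time = NULL,
                                  baseline_s = 180) {
  stopifnot(inherits(tc, "firing_timecourse"))
  if (is.null(injection_time)) {
    ev <- attr(tc, "events", exact = TRUE)
    if (is.null(ev) || nrow(ev) == 0) {
      stop("no injection time available", call. = FALSE)
    }
    injection_time <- ev$time[1]
  }
  w <- attr(tc, "window_s", exact = TRUE)
  in_base <- tc$center - w / 2 >= injection_time - baseline_s &
    tc$center + w / 2 <= injection_time
  if (!any(in_base)) {
    stop("no window fully inside the baseline period", call. = FALSE)
  }
  baseline <- mean(tc$rate[in_base])
  if (baseline == 0) {
    stop("zero baseline rate: unit cannot be normalized", call. = FALSE)
  }
  tc$normalized <- 100 * tc$rate / baseline
  attr(tc, "baseline_hz") <- baseline
  attr(tc, "injection_time") <- injection_time
  tc
}

max_variation <- function(tc, injection_time, response_window_s) {
  post <- tc$center > injection_time &
    tc$center <= injection_time + response_window_s
  if (!any(post)) stop("no post-injection windows", call. = FALSE)
  v <- tc$normalized[post]
  list(max = max(v), min = min(v))
}

#' Summarize a unit's response to injection
#'
#' From baseline-normalized timecourses, measures the maximal (activation)
#' and minimal (inhibition) normalized firing within the response period
#' (windows whose center lies in (injection, injection + 180 s\]), classifies
#' the unit, and, when a saline timecourse is supplied, reports the
#' difference of maximum variation after nicotine versus saline.
#'
#' Classification: a unit is `"flat"` when both |max - 100| and |100 - min|
#' are below `flat_band` (default 20 points, configurable); otherwise
#' `"activated"` if the excursion above 100 dominates, else `"inhibited"`.
#'
#' @param nic_tc Normalized timecourse for the nicotine injection (from
#'   [normalize_to_baseline()]).
#' @param sal_tc Optional normalized timecourse for the saline injection.
#' @param response_window_s Response period after injection (default 180 s).
#' @param flat_band Half-width of the flat classification band, in percent
#'   points (default 20).
#' @return A `response_summary` list: `max_activation_pct`,
#'   `max_inhibition_pct`, `class`, and `delta_vs_saline` (signed maximum
#'   variation after nicotine minus after saline; `NA` without a saline
#'   trace).
#' @export
response_summary <- function(nic_tc, sal_tc = NULL, response_window_s = 180,
                             flat_band = 20) {
  inj <- attr(nic_tc, "injection_time", exact = TRUE)
  if (is.null(inj) || is.null(nic_tc$normalized)) {
    stop("timecourse must be baseline-normalized first", call. = FALSE)
  }
  v <- max_variation(nic_tc, inj, response_window_s)
  up <- v$max - 100
  down <- 100 - v$min
  cls <- if (abs(up) < flat_band && abs(down) < flat_band) {
    "flat"
  } else if (up >= down) "activated" else "inhibited"
  signed_var <- function(vv) if ((vv$max - 100) >= (100 - vv$min)) {
    vv$max - 100
  } else -(100 - vv$min)

  delta <- NA_real_
  if (!is.null(sal_tc)) {
    inj_s <- attr(sal_tc, "injection_time", exact = TRUE)
    if (is.null(inj_s) || is.null(sal_tc$normalized)) {
      stop("saline timecourse must be baseline-normalized", call. = FALSE)
    }
    vs <- max_variation(sal_tc, inj_s, response_window_s)
    delta <- signed_var(v) - signed_var(vs)
  }
  structure(
    list(max_activation_pct = v$max, max_inhibition_pct = v$min,
         class = cls, delta_vs_saline = delta),
    class = "response_summary"
  )
}

#' Percentage of spikes within bursts
#'
#' Bursts are detected with the classic dopamine-neuron interspike-interval
#' criterion: a burst starts when an ISI falls below `onset_isi_s` (80 ms)
#' and continues while ISIs stay at or below `offset_isi_s` (160 ms); it
#' ends at the first ISI exceeding the offset. %SWB is 100 x (spikes inside
#' bursts) / (total spikes in the window).
#'
#' @param train A `spike_train`.
#' @param window Length-2 numeric window \[t0, t1\] in seconds; default the
#'   whole recording.
#' @param onset_isi_s Burst onset ISI threshold (default 0.08 s).
#' @param offset_isi_s Burst offset ISI threshold (default 0.16 s).
#' @return List: `pct_swb`, `n_spikes`, `n_bursts`, `in_burst` (logical per
#'   spike in the window). Empty windows raise an error.
#' @export
burst_metrics <- function(train, window = NULL, onset_isi_s = 0.08,
                          offset_isi_s = 0.16) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(window)) window <- c(0, train$duration)
  sp <- train$spikes[train$spikes >= window[1] & train$spikes <= window[2]]
  if (length(sp) == 0) {
    stop("no spikes in window: %SWB undefined", call. = FALSE)
  }
  n <- length(sp)
  in_burst <- logical(n)
  n_bursts <- 0L
  if (n >= 2) {
    isi <- diff(sp)
    i <- 1L
    while (i <= n - 1L) {
      if (isi[i] < onset_isi_s) {
        j <- i + 1L
        while (j <= n - 1L && isi[j] <= offset_isi_s) j <- j + 1L
        in_burst[i:j] <- TRUE
        n_bursts <- n_bursts + 1L
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  list(pct_swb = 100 * sum(in_burst) / n, n_spikes = n,
       n_bursts = n_bursts, in_burst = in_burst)
}
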