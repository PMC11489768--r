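#' Remove artifact minutes from a bottle series
#'
#' Per-minute readings strictly greater than `threshold_ml` (default 0.1 ml)
#' are treated as erroneous measurements (leaking bottle, sensor glitch) and
#' set to missing; they are excluded from all downstream sums, not
#' interpolated. Values exactly at the threshold are retained. The number of
#' removed minutes is recorded in the `n_removed` attribute.
#'
#' @param series A `bottle_series` (see [gen_drink_series()] or
#'   [read_bottle_series()]).
#' @param threshold_ml Artifact threshold in ml/min; readings strictly above
#'   it are removed. Default 0.1.
#' @return The cleaned `bottle_series`, with attribute `n_removed`.
#' @export
clean_minutes <- function(series, threshold_ml = 0.1) {
  stopifnot(inherits(series, "bottle_series"))
  stopifnot_scalar(threshold_ml, "threshold_ml", lower = 0, strict_lower = TRUE)
  ts <- series$volumes$timestamp
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  bad_l <- !is.na(series$volumes$left) & series$volumes$left > threshold_ml
  bad_r <- !is.na(series$volumes$right) & series$volumes$right > threshold_ml
  series$volumes$left[bad_l] <- NA_real_
  series$volumes$right[bad_r] <- NA_real_
  attr(series, "n_removed") <- sum(bad_l) + sum(bad_r)
  series
}

#' Split a bottle series into overnight sessions
#'
#' Sessions run from `start_hour` on each day to `end_hour` the next day
#' (default 20:00 to 14:00, an 18 h window covering the active drinking
#' period); minutes in the off window (`end_hour` to `start_hour`, when
#' bottles are swapped and refilled) belong to no session. Intervals are
#' half-open: a minute stamped exactly at `start_hour` opens that evening's
#' session, and one stamped at `end_hour` is already outside.
#'
#' @param series A `bottle_series`.
#' @param start_hour Session start clock hour (default 20).
#' @param end_hour Session end clock hour on the next day (default 14).
#' @return A named list of `bottle_series` slices, one per session, named by
#'   the session's start date. Sessions with no retained minutes carry the
#'   attribute `empty = TRUE`.
#' @export
session_windows <- function(series, start_hour = 20, end_hour = 14) {
  stopifnot(inherits(series, "bottle_series"))
  if (end_hour >= start_hour) {
    stop("expected an overnight window with `end_hour` < `start_hour`",
         call. = FALSE)
  }
  ts <- series$volumes$timestamp
  lt <- as.POSIXlt(ts, tz = "UTC")
  hour_frac <- lt$hour + lt$min / 60 + lt$sec / 3600
  date <- as.Date(ts, tz = "UTC")

  in_evening <- hour_frac >= start_hour
  in_morning <- hour_frac < end_hour
  session_date <- as.Date(rep(NA, length(ts)))
  session_date[in_evening] <- date[in_evening]
  session_date[in_morning] <- date[in_morning] - 1L

  keep_dates <- sort(unique(stats::na.omit(session_date)))
  sessions <- lapply(keep_dates, function(d) {
    idx <- !is.na(session_date) & session_date == d
    slice <- series
    slice$volumes <- series$volumes[idx, , drop = FALSE]
    slice$labels <- series$labels[series$labels$date == d, , drop = FALSE]
    attr(slice, "session_date") <- d
    tot <- sum(slice$volumes$left, slice$volumes$right, na.rm = TRUE)
    if (nrow(slice$volumes) == 0L || tot == 0) attr(slice, "empty") <- TRUE
    slice
  })
  names(sessions) <- as.character(keep_dates)
  sessions
}

#' Preference and intake for one session
#'
#' Resolves which bottle held the test solution on the session's start date
#' (side swaps are carried by the series' `labels` table) and computes the
#' test-solution preference as a percentage of total liquid.
#'
#' @param session A single session slice from [session_windows()].
#' @param test_label Content label of the test solution (must appear in the
#'   session's labels).
#' @return A one-row data frame: `date`, `test_ml`, `control_ml`, `total_ml`,
#'   `preference_pct` (100 * test / total; `NA` with `undefined = TRUE`
#'   attribute when total is zero).
#' @export
session_preference <- function(session, test_label) {
  stopifnot(inherits(session, "bottle_series"))
  lab <- session$labels
  if (nrow(lab) != 1L) {
    stop("session must carry exactly one day of bottle labels", call. = FALSE)
  }
  if (lab$left_content == test_label) {
    test_col <- "left"; ctrl_col <- "right"
  } else if (lab$right_content == test_label) {
    test_col <- "right"; ctrl_col <- "left"
  } else {
    stop(sprintf("test label '%s' not present on %s", test_label, lab$date),
         call. = FALSE)
  }
  test_ml <- sum(session$volumes[[test_col]], na.rm = TRUE)
  ctrl_ml <- sum(session$volumes[[ctrl_col]], na.rm = TRUE)
  total <- test_ml + ctrl_ml
  pref <- if (total > 0) 100 * test_ml / total else NA_real_
  res <- data.frame(
    date = attr(session, "session_date") %||% lab$date,
    test_ml = test_ml, control_ml = ctrl_ml, total_ml = total,
    preference_pct = pref
  )
  if (total == 0) attr(res, "undefined") <- TRUE
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Daily nicotine dose in mg/kg/day
#'
#' dose = concentration (ug/ml) x test volume (ml) / 1000 / (weight (g)/1000),
#' i.e. mg of free base per kg body weight per session-day. Body weights
#' measured every other day are linearly interpolated to the session date;
#' dates outside the measured range fall back to the nearest measurement
#' (flagged via the `extrapolated` attribute).
#'
#' @param result A session result row from [session_preference()].
#' @param concentration_ug_per_ml Test-solution concentration (ug/ml, > 0).
#' @param weights Data frame `date`, `grams` of body-weight measurements.
#' @return Dose in mg/kg/day (numeric scalar).
#' @export
daily_dose <- function(result, concentration_ug_per_ml, weights) {
  stopifnot_scalar(concentration_ug_per_ml, "concentration_ug_per_ml",
                   lower = 0, strict_lower = TRUE)
  if (nrow(weights) == 0L || any(weights$grams <= 0)) {
    stop("weights must be non-empty and positive", call. = FALSE)
  }
  d <- as.numeric(as.Date(result$date))
  wd <- as.numeric(as.Date(weights$date))
  extrapolated <- d < min(wd) || d > max(wd)
  w_g <- if (nrow(weights) == 1L) {
    weights$grams
  } else {
    stats::approx(wd, weights$grams, xout = d, rule = 2, ties = mean)$y
  }
  dose <- concentration_ug_per_ml * result$test_ml / 1000 / (w_g / 1000)
  if (extrapolated) attr(dose, "extrapolated") <- TRUE
  dose
}

#' Side-bias exclusion from habituation data
#'
#' During the water-vs-water habituation period, animals drinking
#' predominantly from one physical side cannot be scored for solution
#' preference. The animal is excluded iff its left-side share of total
#' habituation volume is strictly below `low` or strictly above `high`
#' (default < 20% or > 80%); boundary values are retained.
#'
#' @param habituation_sessions List of habituation session slices (from
#'   [session_windows()] on water-vs-water days).
#' @param low,high Exclusion bounds as fractions (defaults 0.2 and 0.8).
#' @return A list: `keep` (logical), `left_share` (fraction), `reason`.
#' @export
side_bias_filter <- function(habituation_sessions, low = 0.2, high = 0.8) {
  if (length(habituation_sessions) == 0L) {
    return(list(keep = NA, left_share = NA_real_,
                reason = "no habituation data"))
  }
  left <- sum(vapply(habituation_sessions, function(s)
    sum(s$volumes$left, na.rm = TRUE), numeric(1)))
  right <- sum(vapply(habituation_sessions, function(s)
    sum(s$volumes$right, na.rm = TRUE), numeric(1)))
  total <- left + right
  if (total == 0) {
    return(list(keep = NA, left_share = NA_real_,
                reason = "no habituation drinking"))
  }
  share <- left / total
  # strict bounds, with a float guard so exact-boundary shares are retained
  excluded <- share < low - 1e-9 || share > high + 1e-9
  list(
    keep = !excluded, left_share = share,
    reason = if (excluded) sprintf("side bias: left share %.1f%%", 100 * share)
             else "ok"
  )
}

#' Full per-animal two-bottle-choice analysis
#'
#' Convenience wrapper chaining [clean_minutes()], [session_windows()],
#' [session_preference()] and [daily_dose()] over all sessions of a series.
#'
#' @param series A `bottle_series`.
#' @param test_label Content label of the test solution.
#' @param concentration_ug_per_ml Nicotine concentration for dose computation,
#'   or `NULL` (e.g. sucrose sessions) to skip doses.
#' @param threshold_ml Artifact threshold passed to [clean_minutes()].
#' @return Data frame with one row per session: volumes, preference, and
#'   (when a concentration is given) `dose_mg_per_kg`.
#' @export
choice_analysis <- function(series, test_label,
                            concentration_ug_per_ml = NULL,
                            threshold_ml = 0.1) {
  cleaned <- clean_minutes(series, threshold_ml)
  sessions <- session_windows(cleaned)
  # the first recorded morning belongs to a session that started before the
  # recording (no labels for it): drop such incomplete sessions
  sessions <- Filter(function(s) nrow(s$labels) == 1L, sessions)
  rows <- lapply(sessions, function(s) {
    res <- session_preference(s, test_label)
    if (!is.null(concentration_ug_per_ml)) {
      res$dose_mg_per_kg <- as.numeric(
        daily_dose(res, concentration_ug_per_ml, cleaned$weights)
      )
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_removed") <- attr(cleaned, "n_removed")
  out
}
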