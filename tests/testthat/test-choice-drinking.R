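make_series <- function(ts, left, right, labels = NULL, weights = NULL) {
  if (is.null(labels)) {
    labels <- data.frame(date = unique(as.Date(ts, tz = "UTC")),
                         left_content = "nicotine_100",
                         right_content = "water")
  }
  structure(
    list(animal = "m1",
         volumes = data.frame(timestamp = ts, left = left, right = right),
         labels = labels,
         weights = weights %||% data.frame(date = as.Date(ts[1]), grams = 25)),
    class = "bottle_series"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cleaning removes strictly-above-threshold minutes only", {
  ts <- as.POSIXct("2024-01-01 20:00:00", tz = "UTC") + 60 * (0:4)
  s <- make_series(ts, left = c(0.15, 0.10, 0.05, 0.2, 0),
                   right = c(0, 0.1, 0.1, 0.1, 0.1))
  cl <- clean_minutes(s)
  expect_true(is.na(cl$volumes$left[1]))   # 0.15 removed
  expect_equal(cl$volumes$left[2], 0.10)   # boundary retained
  expect_true(is.na(cl$volumes$left[4]))
  expect_equal(attr(cl, "n_removed"), 2L)

  # all at or below threshold: identity
  s2 <- make_series(ts, left = rep(0.1, 5), right = rep(0.02, 5))
  cl2 <- clean_minutes(s2)
  expect_equal(cl2$volumes, s2$volumes)
  expect_equal(attr(cl2, "n_removed"), 0L)

  # non-monotone timestamps rejected
  s3 <- make_series(ts[c(1, 3, 2, 4, 5)], left = rep(0, 5), right = rep(0, 5))
  expect_error(clean_minutes(s3), "increasing")
})

test_that("session windows are half-open 20:00 to 14:00 slices", {
  s <- gen_drink_series(2, 0.5, seed = 1)
  sess <- session_windows(s)
  # sessions labeled by start date; each full session spans 18 h
  full <- sess[["2024-01-01"]]
  expect_equal(nrow(full$volumes), 18 * 60)
  hrs <- as.POSIXlt(full$volumes$timestamp, tz = "UTC")$hour
  expect_true(all(hrs >= 20 | hrs < 14))

  # a minute at 15:30 belongs to no session
  ts <- as.POSIXct(c("2024-01-01 15:30:00", "2024-01-01 20:00:00"),
                   tz = "UTC")
  s2 <- make_series(ts, left = c(0.05, 0.05), right = c(0, 0))
  sess2 <- session_windows(s2)
  expect_equal(length(sess2), 1L)
  expect_equal(nrow(sess2[[1]]$volumes), 1L)  # only the 20:00 minute
  expect_equal(names(sess2), "2024-01-01")
})

test_that("session preference handles side swaps and edge cases", {
  ts <- as.POSIXct("2024-01-01 20:00:00", tz = "UTC") + 60 * (0:9)
  s <- make_series(ts, left = rep(0.02, 10), right = rep(0.08, 10))
  sess <- session_windows(s)[[1]]
  res <- session_preference(sess, "nicotine_100")
  expect_equal(res$preference_pct, 20)  # 0.2 of 1.0 ml

  # swap sides via labels: preference invariant to physical side
  s_sw <- make_series(ts, left = rep(0.08, 10), right = rep(0.02, 10),
                      labels = data.frame(date = as.Date("2024-01-01"),
                                          left_content = "water",
                                          right_content = "nicotine_100"))
  res_sw <- session_preference(session_windows(s_sw)[[1]], "nicotine_100")
  expect_equal(res_sw$preference_pct, 20)

  # equal volumes: 50%
  s_eq <- make_series(ts, left = rep(0.05, 10), right = rep(0.05, 10))
  expect_equal(
    session_preference(session_windows(s_eq)[[1]], "nicotine_100")$preference_pct,
    50
  )

  # zero total flagged undefined
  s_0 <- make_series(ts, left = rep(0, 10), right = rep(0, 10))
  r0 <- session_preference(session_windows(s_0)[[1]], "nicotine_100")
  expect_true(is.na(r0$preference_pct))

  expect_error(session_preference(sess, "sucrose_1pct"), "not present")
})

test_that("dose arithmetic and weight interpolation are correct", {
  res <- data.frame(date = as.Date("2024-01-03"), test_ml = 3)
  w <- data.frame(date = as.Date(c("2024-01-02", "2024-01-04")),
                  grams = c(25, 25))
  expect_equal(as.numeric(daily_dose(res, 100, w)), 12)
  res$test_ml <- 0
  expect_equal(as.numeric(daily_dose(res, 100, w)), 0)
  res$test_ml <- 2
  expect_equal(as.numeric(daily_dose(res, 50,
                                     data.frame(date = res$date, grams = 20))),
               5)
  # interpolation between bracketing weights
  w2 <- data.frame(date = as.Date(c("2024-01-02", "2024-01-04")),
                   grams = c(20, 30))
  res$test_ml <- 5
  expect_equal(as.numeric(daily_dose(res, 100, w2)), 100 * 5 / 1000 / 0.025)
  # outside range: nearest value, flagged
  res2 <- data.frame(date = as.Date("2024-01-10"), test_ml = 1)
  d <- daily_dose(res2, 100, w2)
  expect_true(isTRUE(attr(d, "extrapolated")))
  expect_equal(as.numeric(d), 100 * 1 / 1000 / 0.030)
  # dose scales linearly in concentration and volume, inversely in weight
  base <- as.numeric(daily_dose(res, 100, w2))
  expect_equal(as.numeric(daily_dose(res, 200, w2)), 2 * base)
})

test_that("side-bias exclusion uses strict 20/80 bounds", {
  ts <- as.POSIXct("2024-01-01 20:00:00", tz = "UTC") + 60 * (0:9)
  mk <- function(left_share) {
    s <- make_series(ts, left = rep(left_share * 0.1, 10),
                     right = rep((1 - left_share) * 0.1, 10),
                     labels = data.frame(date = as.Date("2024-01-01"),
                                         left_content = "water",
                                         right_content = "water"))
    session_windows(s)
  }
  expect_false(side_bias_filter(mk(0.85))$keep)
  expect_true(side_bias_filter(mk(0.50))$keep)
  expect_true(side_bias_filter(mk(0.80))$keep)  # boundary retained
  expect_true(side_bias_filter(mk(0.20))$keep)
  expect_false(side_bias_filter(mk(0.15))$keep)
  expect_true(is.na(side_bias_filter(list())$keep))
})

test_that("volume is conserved from cleaned minutes into sessions", {
  s <- clean_minutes(gen_drink_series(5, 0.6, artifact_rate = 0.002,
                                      seed = 9))
  sess <- session_windows(s)
  total_sessions <- sum(vapply(sess, function(x)
    sum(x$volumes$left, x$volumes$right, na.rm = TRUE), numeric(1)))
  lt <- as.POSIXlt(s$volumes$timestamp, tz = "UTC")
  in_window <- lt$hour >= 20 | lt$hour < 14
  total_direct <- sum(s$volumes$left[in_window], s$volumes$right[in_window],
                      na.rm = TRUE)
  expect_equal(total_sessions, total_direct)
})

test_that("generator preference is recovered within 3 points", {
  for (p in c(0.3, 0.5, 0.8)) {
    s <- gen_drink_series(8, p, seed = 100 + round(100 * p))
    res <- choice_analysis(s, "nicotine_100")
    expect_lt(abs(mean(res$preference_pct) - 100 * p), 3)
  }
})
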