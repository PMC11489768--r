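#' Simulate elevated O-maze or place-preference session data
#'
#' For `kind = "eom"`, generates a 9-minute frame-by-frame zone-label trace
#' (three 3-minute blocks) in which each frame is in the open arms with the
#' per-block probability given in `params$bias`. For `kind = "cpp"`,
#' generates pretest and test chamber times (900 s sessions, two pairing
#' chambers plus a neutral zone) where conditioning shifts time in the
#' drug-paired chamber by `params$shift` seconds (plus Gaussian noise of
#' `params$noise_sd`, default 10 s), balanced against the unpaired chamber.
#'
#' @param kind `"eom"` or `"cpp"`.
#' @param params For `"eom"`: list with `bias`, a length-3 vector of
#'   per-block open-arm probabilities in \[0, 1\]. For `"cpp"`: list with
#'   `shift` (s) and optionally `noise_sd` (s, default 10).
#' @param fps Frame rate for EOM traces (default 30).
#' @param seed RNG seed.
#' @return For `"eom"`, a `zone_trace`: data frame `frame`, `zone`
#'   (`"open"`/`"closed"`) with an `fps` attribute. For `"cpp"`, a
#'   `cpp_times`: data frame with rows `pretest`/`test` and columns
#'   `paired`, `unpaired`, `neutral` (seconds summing to 900 per session),
#'   with a `paired_chamber` attribute. Both carry [ground_truth()].
#' @export
gen_behavior_session <- function(kind = c("eom", "cpp"), params, fps = 30,
                                 seed = 1) {
  kind <- match.arg(kind)
  if (kind == "eom") {
    bias <- params$bias
    if (length(bias) != 3L || any(bias < 0) || any(bias > 1)) {
      stop("`params$bias` must be three open-arm probabilities in [0, 1]",
           call. = FALSE)
    }
    n_block <- as.integer(round(180 * fps))
    zones <- with_seed(seed, {
      unlist(lapply(bias, function(b) {
        ifelse(stats::runif(n_block) < b, "open", "closed")
      }))
    })
    trace <- data.frame(frame = seq_along(zones) - 1L, zone = zones,
                        stringsAsFactors = FALSE)
    attr(trace, "fps") <- fps
    class(trace) <- c("zone_trace", "data.frame")
    attr(trace, "ground_truth") <- new_ground_truth(
      "eom", list(bias = bias, fps = fps), seed
    )
    trace
  } else {
    shift <- params$shift
    noise_sd <- params$noise_sd %||% 10
    stopifnot_scalar(shift, "params$shift", lower = -900, upper = 900)
    times <- with_seed(seed, {
      p0 <- 350 + stats::rnorm(1, sd = 30)
      u0 <- 350 + stats::rnorm(1, sd = 30)
      n0 <- 900 - p0 - u0
      e <- stats::rnorm(1, sd = noise_sd)
      p1 <- p0 + shift + e
      u1 <- 900 - n0 - p1
      rbind(pretest = c(p0, u0, n0), test = c(p1, u1, n0))
    })
    colnames(times) <- c("paired", "unpaired", "neutral")
    res <- as.data.frame(times)
    class(res) <- c("cpp_times", "data.frame")
    attr(res, "paired_chamber") <- "paired"
    attr(res, "ground_truth") <- new_ground_truth(
      "cpp", list(shift = shift, noise_sd = noise_sd), seed
    )
    res
  }
}
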