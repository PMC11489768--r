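#' Open-arm time by 3-minute block
#'
#' Splits a 9-minute elevated O-maze zone trace into three 3-minute blocks
#' (0-3, 3-6, 6-9 min from maze placement; the injection minute precedes the
#' trace) and returns the percentage of frames labeled open in each block.
#' Frames are attributed to blocks by half-open intervals on their
#' timestamps (frame i covers \[i/fps, (i+1)/fps)).
#'
#' @param trace A `zone_trace` (data frame `frame`, `zone`, attribute `fps`).
#' @return Data frame `block` (`"0-3"`, `"3-6"`, `"6-9"`), `open_pct`,
#'   `n_frames`. If the trace is shorter than 9 minutes the final block is
#'   partial and flagged via the `partial` attribute (never silently
#'   rescaled).
#' @export
eom_block_times <- function(trace) {
  fps <- attr(trace, "fps", exact = TRUE)
  if (is.null(fps)) stop("trace must carry an `fps` attribute", call. = FALSE)
  if (!all(trace$zone %in% c("open", "closed"))) {
    stop("zone labels must be 'open' or 'closed'", call. = FALSE)
  }
  t_frame <- trace$frame / fps
  block <- findInterval(t_frame, c(0, 180, 360, 540), rightmost.closed = FALSE)
  keep <- block >= 1 & block <= 3
  block <- factor(block[keep], levels = 1:3, labels = c("0-3", "3-6", "6-9"))
  open <- trace$zone[keep] == "open"
  n <- as.integer(table(block))
  open_n <- as.integer(tapply(open, block, sum, default = 0L))
  out <- data.frame(
    block = levels(block),
    open_pct = ifelse(n > 0, 100 * open_n / n, NA_real_),
    n_frames = n
  )
  expected <- as.integer(round(180 * fps))
  if (any(n < expected)) attr(out, "partial") <- TRUE
  out
}

#' Conditioned place preference score
#'
#' score = time in the drug-paired chamber at test minus time in the same
#' chamber at pretest, in seconds. Positive scores indicate acquired
#' preference for the paired chamber.
#'
#' @param times A `cpp_times` object (rows `pretest`, `test`; attribute
#'   `paired_chamber` naming the paired-chamber column).
#' @return Numeric scalar (seconds).
#' @export
cpp_score <- function(times) {
  paired <- attr(times, "paired_chamber", exact = TRUE)
  if (is.null(paired) || !paired %in% colnames(times)) {
    stop("paired-chamber identity unknown", call. = FALSE)
  }
  if (!all(c("pretest", "test") %in% rownames(times))) {
    stop("missing pretest or test session", call. = FALSE)
  }
  times["test", paired] - times["pretest", paired]
}

#' Unbiased group assignment from pretest biases
#'
#' Partitions animals into `n_groups` groups of (near-)equal size so that
#' the group means of the pretest preference scores are as close to equal
#' (and, when the population mean is near zero, as close to zero) as
#' possible. Deterministic: a greedy pass over animals sorted by decreasing
#' absolute bias (each placed in the non-full group whose running sum it
#' best balances) is followed by pairwise-swap hill climbing on the spread
#' of group means; additional seeded restarts from shuffled insertion
#' orders guard against local optima, and the best split found is
#' returned. Only labels are assigned; no animal's data changes.
#'
#' @param biases Named (or unnamed) numeric vector of per-animal pretest
#'   bias scores, in seconds.
#' @param n_groups Number of groups (default 2); each must receive at least
#'   2 animals.
#' @param restarts Number of shuffled-order restarts beyond the sorted
#'   greedy pass (default 50; deterministic, internally seeded).
#' @return Integer vector of group labels (1..n_groups) aligned with
#'   `biases`, with attribute `group_means`. If group sizes cannot be made
#'   equal (n not divisible by n_groups) the best-effort split is returned
#'   with attribute `unbalanced = TRUE`.
#' @export
cpp_assign_unbiased <- function(biases, n_groups = 2, restarts = 50) {
  n <- length(biases)
  if (n < 2 * n_groups) {
    stop("need at least 2 animals per group", call. = FALSE)
  }
  cap <- ceiling(n / n_groups)

  spread <- function(g) {
    m <- tapply(biases, factor(g, levels = seq_len(n_groups)), mean)
    m[is.na(m)] <- 0
    max(m) - min(m)
  }
  greedy <- function(ord) {
    grp <- integer(n)
    sums <- numeric(n_groups)
    sizes <- integer(n_groups)
    for (i in ord) {
      open_g <- which(sizes < cap)
      # place where the running sum moves closest to zero (ties: first)
      g <- open_g[which.min(abs(sums[open_g] + biases[i]))]
      grp[i] <- g
      sums[g] <- sums[g] + biases[i]
      sizes[g] <- sizes[g] + 1L
    }
    grp
  }
  polish <- function(grp) {
    # pairwise-swap hill climbing on the spread of group means
    improved <- TRUE
    cur <- spread(grp)
    while (improved) {
      improved <- FALSE
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          if (grp[i] == grp[j]) next
          g2 <- grp
          g2[c(i, j)] <- g2[c(j, i)]
          s2 <- spread(g2)
          if (s2 < cur - 1e-12) {
            grp <- g2
            cur <- s2
            improved <- TRUE
          }
        }
      }
    }
    grp
  }

  orders <- c(
    list(order(abs(biases), decreasing = TRUE)),
    with_seed(20240101, lapply(seq_len(restarts), function(i) sample(n)))
  )
  best <- NULL
  for (ord in orders) {
    cand <- polish(greedy(ord))
    if (is.null(best) || spread(cand) < spread(best) - 1e-15) best <- cand
  }
  grp <- best
  means <- tapply(biases, factor(grp, levels = seq_len(n_groups)), mean)
  out <- grp
  attr(out, "group_means") <- as.numeric(means)
  if (n %% n_groups != 0L) attr(out, "unbalanced") <- TRUE
  out
}
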