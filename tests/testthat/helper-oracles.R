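# Independent oracles used across test files. These deliberately take
# different computational routes than the package implementations.

# Exact two-sided rank-sum p-value by full enumeration of all C(n1+n2, n1)
# group-label assignments (tie-free samples only).
enumerate_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  rs <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  lower <- mean(rs <= r_obs)
  upper <- mean(rs >= r_obs)
  min(1, 2 * min(lower, upper))
}

# Holm step-down applied from its definition.
holm_by_hand <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running <- 0
  for (k in seq_len(n)) {
    running <- max(running, (n - k + 1) * p[ord[k]])
    adj[ord[k]] <- min(1, running)
  }
  adj
}

# Benjamini-Hochberg step-up applied from its definition.
bh_by_hand <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (k in rev(seq_len(n))) {
    running <- min(running, n * p[ord[k]] / k)
    adj[ord[k]] <- min(1, running)
  }
  adj
}

# Brute-force %SWB: split the train at ISIs > offset; inside each segment a
# burst starts at the first ISI < onset and runs to the segment end.
swb_by_segments <- function(spikes, onset = 0.08, offset = 0.16) {
  n <- length(spikes)
  if (n < 2) return(0)
  isi <- diff(spikes)
  seg_id <- cumsum(c(0, isi > offset))
  in_burst <- logical(n)
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (length(idx) < 2) next
    seg_isi <- diff(spikes[idx])
    k <- which(seg_isi < onset)
    if (length(k) > 0) in_burst[idx[k[1]]:idx[length(idx)]] <- TRUE
  }
  100 * sum(in_burst) / n
}

# Poisson-disk style spot placement for synthetic bouton stacks.
place_spots <- function(n, ext_um, min_d = 1.3, margin = 0.8, seed = 1,
                        amplitude = 100, sigma_lat = 0.15, sigma_ax = 0.3) {
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    p <- runif(3, margin, ext_um - margin)
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - p)^2))) > min_d) {
      pts <- rbind(pts, p)
    }
  }
  data.frame(y_um = pts[, 1], x_um = pts[, 2], z_um = pts[, 3],
             amplitude = amplitude, sigma_y_um = sigma_lat,
             sigma_x_um = sigma_lat, sigma_z_um = sigma_ax)
}

# Random symmetric nonnegative weight matrix for Louvain oracle checks.
random_weight_matrix <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1)
  }
  rownames(w) <- colnames(w) <- paste0("n", seq_len(n))
  w
}
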