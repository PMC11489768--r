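#' Per-region volcano statistics
#'
#' For each region, compares cFos counts between two groups with Welch's
#' two-sample t test (unequal variances), converts p-values to q-values by
#' Benjamini-Hochberg, and computes a log2 fold change with a pseudo-count
#' of 1 to tolerate zero-count regions. A region passes the volcano rule iff
#' its fold change is positive and -log10(p) exceeds 1.3 (the p < 0.05
#' line).
#'
#' @param rc A `region_counts` object.
#' @param group_a,group_b Group labels; fold change is
#'   log2((mean_b + 1) / (mean_a + 1)).
#' @return Data frame: `region`, `mean_a`, `mean_b`, `log2_fc`, `t`, `p`,
#'   `q`, `pass`, `flagged` (TRUE when both groups are constant and the test
#'   is undefined; `p` is then `NA` and the region never passes).
#' @export
region_volcano <- function(rc, group_a = levels(rc$group)[1],
                           group_b = levels(rc$group)[2]) {
  stopifnot(inherits(rc, "region_counts"))
  a <- rc$counts[rc$group == group_a, , drop = FALSE]
  b <- rc$counts[rc$group == group_b, , drop = FALSE]
  if (nrow(a) < 3 || nrow(b) < 3) {
    stop("need >= 3 animals in each group", call. = FALSE)
  }
  res <- lapply(rc$regions, function(r) {
    xa <- a[, r]; xb <- b[, r]
    fc <- log2((mean(xb) + 1) / (mean(xa) + 1))
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      data.frame(region = r, mean_a = mean(xa), mean_b = mean(xb),
                 log2_fc = fc, t = NA_real_, p = NA_real_, flagged = TRUE)
    } else {
      tt <- stats::t.test(xb, xa, var.equal = FALSE)
      data.frame(region = r, mean_a = mean(xa), mean_b = mean(xb),
                 log2_fc = fc, t = unname(tt$statistic), p = tt$p.value,
                 flagged = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$q <- adjust_pvalues(ifelse(is.na(out$p), 1, out$p), "bh")
  out$q[is.na(out$p)] <- NA_real_
  out$pass <- !is.na(out$p) & out$log2_fc > 0 & -log10(out$p) > 1.3
  rownames(out) <- NULL
  out
}

#' Region-region coactivation correlation matrix
#'
#' Pairwise correlation of cFos counts across the animals of one treatment
#' group. Constant regions have undefined correlations; their rows/columns
#' are set to `NA` and listed in the `flagged_regions` attribute.
#'
#' @param rc A `region_counts` object.
#' @param group Group label to subset (default first level).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
region_correlation_matrix <- function(rc, group = levels(rc$group)[1],
                                      method = c("pearson", "spearman")) {
  stopifnot(inherits(rc, "region_counts"))
  method <- match.arg(method)
  x <- rc$counts[rc$group == group, , drop = FALSE]
  if (nrow(x) < 3) stop("need >= 3 animals in the group", call. = FALSE)
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(x, method = method))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- 1
  if (any(const)) attr(r, "flagged_regions") <- colnames(x)[const]
  r
}

#' Hierarchical modules of the coactivation matrix
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' 1 - r, cut at `k` modules; also returns the dendrogram ordering used to
#' display the matrix with modules contiguous.
#'
#' @param r Complete correlation matrix (no `NA`).
#' @param k Number of modules (default 4; must not exceed the number of
#'   regions).
#' @param linkage `hclust` agglomeration method (default `"average"`).
#' @return List: `labels` (named module ids), `order` (dendrogram
#'   permutation), `ordered_matrix`, `hclust`.
#' @export
module_clustering <- function(r, k = 4, linkage = "average") {
  if (any(is.na(r))) stop("correlation matrix has undefined entries",
                          call. = FALSE)
  if (k > nrow(r)) stop("k exceeds the number of regions", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, order = hc$order,
       ordered_matrix = r[hc$order, hc$order], hclust = hc)
}

#' Louvain communities of the coactivation graph
#'
#' Builds a weighted graph from the correlation matrix (nodes = regions,
#' edges = correlations; by default only positive correlations are kept as
#' weights, since weighted modularity is defined for nonnegative weights;
#' `edge_rule = "abs"` uses absolute values instead) and partitions it by
#' Louvain modularity maximization with seeded restarts, keeping the best-Q
#' partition. Deterministic for a fixed seed and node order. On graphs of at
#' most `exhaustive_limit` nodes, the result is checked against exhaustive
#' partition search and flagged when it is only a local optimum.
#'
#' @param r Correlation matrix.
#' @param edge_rule `"positive"` (default) or `"abs"`.
#' @param restarts Number of seeded Louvain restarts (default 10).
#' @param seed Base seed for the restarts.
#' @param exhaustive_limit Maximum node count for the exhaustive optimality
#'   check (default 9; set 0 to disable).
#' @return List: `membership` (named integer vector), `Q` (weighted
#'   modularity), `global_optimum` (`TRUE`/`FALSE`/`NA` when unchecked).
#' @export
louvain_communities <- function(r, edge_rule = c("positive", "abs"),
                                restarts = 10, seed = 1,
                                exhaustive_limit = 9) {
  edge_rule <- match.arg(edge_rule)
  if (any(is.na(r))) stop("correlation matrix has undefined entries",
                          call. = FALSE)
  w <- if (edge_rule == "positive") pmax(r, 0) else abs(r)
  diag(w) <- 0
  if (all(w == 0)) stop("empty graph: no edges after thresholding",
                        call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL
  for (i in seq_len(restarts)) {
    cm <- with_seed(seed + i - 1, igraph::cluster_louvain(g))
    q <- igraph::modularity(g, igraph::membership(cm),
                            weights = igraph::E(g)$weight)
    if (is.null(best) || q > best$q + 1e-12) {
      best <- list(membership = as.integer(igraph::membership(cm)), q = q)
    }
  }
  names(best$membership) <- rownames(r)
  global <- NA
  if (exhaustive_limit > 0 && nrow(w) <= exhaustive_limit) {
    opt <- exhaustive_modularity(w)
    global <- best$q >= opt$Q - 1e-9
  }
  list(membership = best$membership, Q = best$q, global_optimum = global)
}

#' Exhaustive weighted-modularity maximization
#'
#' Enumerates every partition of the nodes (restricted growth strings) and
#' returns the one with maximal weighted modularity. Intended as an oracle
#' for small graphs (Bell(9) = 21147 partitions); refuses more than 10
#' nodes.
#'
#' @param w Symmetric nonnegative weight matrix (zero diagonal).
#' @return List: `membership`, `Q`.
#' @export
exhaustive_modularity <- function(w) {
  n <- nrow(w)
  if (n > 10) stop("exhaustive search limited to 10 nodes", call. = FALSE)
  best_q <- -Inf
  best_m <- rep(1L, n)
  part <- integer(n)
  recurse <- function(i, maxg) {
    if (i > n) {
      q <- modularity_q(w, part)
      if (q > best_q + 1e-15) {
        best_q <<- q
        best_m <<- part
      }
      return(invisible())
    }
    for (g in seq_len(maxg + 1L)) {
      part[i] <<- g
      recurse(i + 1L, max(maxg, g))
    }
  }
  recurse(1L, 0L)
  list(membership = best_m, Q = best_q)
}

#' Weighted modularity of a partition
#'
#' Q = (1 / 2m) * sum_ij (w_ij - k_i k_j / 2m) * \[c_i == c_j\], the standard
#' Newman-Girvan modularity with edge weights.
#'
#' @param w Symmetric nonnegative weight matrix (zero diagonal).
#' @param membership Integer community labels.
#' @return Numeric scalar.
#' @export
modularity_q <- function(w, membership) {
  k <- rowSums(w)
  two_m <- sum(k)
  if (two_m == 0) return(0)
  same <- outer(membership, membership, `==`)
  sum((w - outer(k, k) / two_m) * same) / two_m
}

safe_nmi <- function(a, b) {
  if (length(unique(a)) == 1 && length(unique(b)) == 1) return(1)
  igraph::compare(a, b, method = "nmi")
}

#' Between-group community reorganization test
#'
#' Quantifies how much the community structure of the coactivation network
#' differs between two treatment groups. The score is 1 - NMI between the
#' two groups' Louvain partitions (0 = identical structure). Significance is
#' assessed against a null built by permuting animal group labels (keeping
#' group sizes) and recomputing both partitions; the permutation p-value is
#' (1 + #\{perm >= observed\}) / (1 + n_permutations). Per-region change
#' flags mark regions whose community membership differs after matching the
#' two partitions by maximal overlap.
#'
#' This NMI-based statistic is this package's formalization of community
#' "reorganization"; it is one reasonable choice, exposed with its null
#' procedure so it can be swapped out.
#'
#' @param rc A `region_counts` object holding both groups.
#' @param group_a,group_b The two group labels.
#' @param n_permutations Number of label permutations (default 199; fewer
#'   than 100 triggers a warning).
#' @param seed Seed controlling permutations and Louvain restarts.
#' @param method Correlation method.
#' @param restarts Louvain restarts per partition (default 5).
#' @return List: `score`, `p_value`, `changed_regions` (logical, named),
#'   `membership_a`, `membership_b`, `perm_scores`.
#' @export
community_reorganization <- function(rc, group_a = levels(rc$group)[1],
                                     group_b = levels(rc$group)[2],
                                     n_permutations = 199, seed = 1,
                                     method = "pearson", restarts = 5) {
  stopifnot(inherits(rc, "region_counts"))
  if (n_permutations < 100) {
    warning("fewer than 100 permutations: p-value resolution is coarse")
  }
  idx_a <- which(rc$group == group_a)
  idx_b <- which(rc$group == group_b)

  part_pair <- function(rows_a, rows_b, s) {
    ra <- region_correlation_matrix(
      subset_counts(rc, rows_a), group = "g", method = method
    )
    rb <- region_correlation_matrix(
      subset_counts(rc, rows_b), group = "g", method = method
    )
    # a constant region has no coactivation: treat it as an isolated node
    ra[is.na(ra)] <- 0
    rb[is.na(rb)] <- 0
    # identical restart seeds for the two partitions: algorithmic
    # tie-breaking is paired so the score reflects differences in the data,
    # not in the optimizer's randomness (the permutation test is exact for
    # any statistic computed identically on observed and permuted data)
    ma <- louvain_communities(ra, restarts = restarts, seed = s,
                              exhaustive_limit = 0)$membership
    mb <- louvain_communities(rb, restarts = restarts, seed = s,
                              exhaustive_limit = 0)$membership
    list(a = ma, b = mb, score = 1 - safe_nmi(ma, mb))
  }

  obs <- part_pair(idx_a, idx_b, seed)
  perm_scores <- with_seed(seed, {
    all_idx <- c(idx_a, idx_b)
    vapply(seq_len(n_permutations), function(i) {
      sh <- sample(all_idx)
      part_pair(sh[seq_along(idx_a)], sh[-seq_along(idx_a)],
                seed + i * 1000L)$score
    }, numeric(1))
  })
  p <- (1 + sum(perm_scores >= obs$score - 1e-12)) / (1 + n_permutations)

  matched_b <- match_partitions(obs$a, obs$b)
  changed <- matched_b != obs$a
  names(changed) <- rc$regions

  list(score = obs$score, p_value = p, changed_regions = changed,
       membership_a = obs$a, membership_b = obs$b,
       perm_scores = perm_scores)
}

# Relabel partition b to maximize overlap with a (greedy on the contingency
# table); labels of b with no match keep fresh ids.
match_partitions <- function(a, b) {
  tab <- table(b, a)
  out <- integer(length(b))
  mapped_b <- character(0)
  used_a <- character(0)
  repeat {
    if (all(tab == -1)) break
    idx <- which(tab == max(tab), arr.ind = TRUE)[1, , drop = TRUE]
    if (tab[idx[1], idx[2]] <= 0) break
    bl <- rownames(tab)[idx[1]]
    al <- colnames(tab)[idx[2]]
    out[b == as.integer(bl)] <- as.integer(al)
    mapped_b <- c(mapped_b, bl)
    used_a <- c(used_a, al)
    tab[idx[1], ] <- -1
    tab[, idx[2]] <- -1
  }
  fresh <- max(a) + 1L
  for (bl in setdiff(rownames(table(b)), mapped_b)) {
    out[b == as.integer(bl)] <- fresh
    fresh <- fresh + 1L
  }
  out
}

# Internal: re-wrap a subset of animals as a one-group region_counts.
subset_counts <- function(rc, rows) {
  structure(
    list(counts = rc$counts[rows, , drop = FALSE],
         group = factor(rep("g", length(rows))),
         regions = rc$regions),
    class = "region_counts"
  )
}
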