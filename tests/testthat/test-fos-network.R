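test_that("volcano statistics implement the stated pass rule", {
  regs <- paste0("R", 1:8)
  rc <- gen_region_counts(20, regs, list(regs), 0,
                          group_mean_shift = setNames(
                            c(rep(1, 4), rep(1.6, 4)), regs),
                          seed = 1)
  v <- region_volcano(rc)
  # rule is exactly (fc > 0) & (-log10 p > 1.3)
  expect_equal(v$pass, !is.na(v$p) & v$log2_fc > 0 & -log10(v$p) > 1.3)
  expect_true(all(v$pass[5:8]))

  # identical groups: fc ~ 0, no pass
  rc0 <- gen_region_counts(10, regs, list(regs), 0, seed = 2)
  v0 <- region_volcano(rc0)
  expect_true(all(!v0$pass[abs(v0$log2_fc) < 0.01] |
                    -log10(v0$p[abs(v0$log2_fc) < 0.01]) > 1.3))

  # negative fold change never passes even at tiny p
  rc_dn <- gen_region_counts(20, regs, list(regs), 0,
                             group_mean_shift = 0.5, seed = 3)
  v_dn <- region_volcano(rc_dn)
  expect_true(all(!v_dn$pass))

  # zero-variance region flagged with undefined p
  rc_c <- rc0
  rc_c$counts[, "R1"] <- 100L
  v_c <- region_volcano(rc_c)
  expect_true(v_c$flagged[v_c$region == "R1"])
  expect_true(is.na(v_c$p[v_c$region == "R1"]))

  # Welch t matches stats::t.test directly
  tt <- t.test(rc$counts[rc$group == "NIC", "R2"],
               rc$counts[rc$group == "SAC", "R2"], var.equal = FALSE)
  expect_equal(v$t[v$region == "R2"], unname(tt$statistic))
})

test_that("correlation matrix has the contracted structure", {
  regs <- paste0("R", 1:6)
  rc <- gen_region_counts(30, regs, list(regs[1:3], regs[4:6]), 0.8,
                          seed = 4)
  r <- region_correlation_matrix(rc, "SAC")
  expect_equal(diag(r), setNames(rep(1, 6), regs))
  expect_equal(r, t(r))
  expect_true(all(r >= -1 & r <= 1))

  # duplicated region correlates at 1; negated at -1
  rc2 <- rc
  rc2$counts[, "R2"] <- rc2$counts[, "R1"]
  r2 <- region_correlation_matrix(rc2, "SAC")
  expect_equal(r2["R1", "R2"], 1)
  rc3 <- rc
  rc3$counts[, "R2"] <- max(rc3$counts) - rc3$counts[, "R1"]
  r3 <- region_correlation_matrix(rc3, "SAC")
  expect_equal(r3["R1", "R2"], -1)

  # constant region flagged as missing
  rc4 <- rc
  rc4$counts[, "R5"] <- 7L
  r4 <- region_correlation_matrix(rc4, "SAC")
  expect_true(all(is.na(r4["R5", setdiff(regs, "R5")])))
  expect_equal(attr(r4, "flagged_regions"), "R5")

  # planted rho blocks: within > between
  same <- outer(rep(1:2, each = 3), rep(1:2, each = 3), `==`)
  expect_gt(mean(r[same & upper.tri(r)]), mean(r[!same & upper.tri(r)]))
})

test_that("hierarchical modules recover planted blocks and edge cases", {
  # two perfectly correlated blocks
  set.seed(5)
  base <- matrix(rnorm(40), 20, 2)
  x <- cbind(base[, 1], base[, 1] * 2 + 3, base[, 1] * 0.5,
             base[, 2], base[, 2] * 1.5, base[, 2] + 10)
  colnames(x) <- paste0("R", 1:6)
  r <- cor(x)
  mc <- module_clustering(r, k = 2)
  expect_equal(unname(mc$labels[1:3]), rep(mc$labels[[1]], 3))
  expect_equal(unname(mc$labels[4:6]), rep(mc$labels[[4]], 3))
  expect_false(mc$labels[[1]] == mc$labels[[4]])

  expect_equal(unname(module_clustering(r, k = 1)$labels), rep(1L, 6))
  expect_equal(sort(unname(module_clustering(r, k = 6)$labels)), 1:6)
  expect_error(module_clustering(r, k = 7), "exceeds")

  # reordering is a permutation: entries conserved
  expect_equal(sort(as.vector(mc$ordered_matrix)), sort(as.vector(r)))
})

test_that("Louvain finds planted communities and never loses to singletons", {
  # two 4-cliques joined by one edge
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1; w[5:8, 5:8] <- 1
  diag(w) <- 0
  w[4, 5] <- w[5, 4] <- 1
  rownames(w) <- colnames(w) <- paste0("n", 1:8)
  lc <- louvain_communities(w, seed = 1)
  expect_equal(length(unique(lc$membership[1:4])), 1L)
  expect_equal(length(unique(lc$membership[5:8])), 1L)
  expect_false(lc$membership[[1]] == lc$membership[[5]])
  ex <- exhaustive_modularity(w)
  expect_equal(lc$Q, ex$Q, tolerance = 1e-9)
  expect_true(lc$global_optimum)

  # uniform complete graph: partition never worse than singletons
  wu <- matrix(1, 6, 6); diag(wu) <- 0
  rownames(wu) <- colnames(wu) <- paste0("n", 1:6)
  lcu <- louvain_communities(wu, seed = 2)
  q_singletons <- modularity_q(wu, 1:6)
  expect_gte(lcu$Q, q_singletons)

  expect_error(louvain_communities(matrix(0, 3, 3)), "empty graph")
})

test_that("modularity helper agrees with igraph", {
  for (s in 1:5) {
    w <- random_weight_matrix(7, 0.6, seed = s)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    m <- sample(1:3, 7, replace = TRUE)
    expect_equal(modularity_q(w, m),
                 igraph::modularity(g, m, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("planted two-module structure is recovered with high NMI", {
  regs <- paste0("R", 1:10)
  mods <- list(regs[1:5], regs[6:10])
  rc <- gen_region_counts(100, regs, mods, 0.8, seed = 6)
  r <- region_correlation_matrix(rc, "SAC")
  lc <- louvain_communities(r, seed = 3)
  truth <- rep(1:2, each = 5)
  nmi <- igraph::compare(lc$membership, truth, method = "nmi")
  expect_gte(nmi, 0.9)
})

test_that("reorganization score is zero for identical groups and flags swaps", {
  regs <- paste0("R", 1:10)
  mods <- list(regs[1:5], regs[6:10])
  rc <- gen_region_counts(8, regs, mods, 0.7, seed = 7)
  # make the two groups byte-identical
  rc$counts[rc$group == "NIC", ] <- rc$counts[rc$group == "SAC", ]
  cr <- suppressWarnings(
    community_reorganization(rc, n_permutations = 20, seed = 1)
  )
  expect_equal(cr$score, 0)
  expect_true(all(!cr$changed_regions))

  # planted module swap: the moved regions are flagged as changed
  rc2 <- gen_region_counts(100, regs, mods, 0.8, seed = 8)
  swapped_mods <- list(c(regs[1:3], regs[9:10]), c(regs[4:8]))
  rc2b <- gen_region_counts(100, regs, swapped_mods, 0.8, seed = 9)
  rc2$counts[rc2$group == "NIC", ] <- rc2b$counts[rc2b$group == "NIC", ]
  cr2 <- suppressWarnings(
    community_reorganization(rc2, n_permutations = 99, seed = 2)
  )
  expect_gt(cr2$score, 0.5)
  expect_gt(sum(cr2$changed_regions[c("R4", "R5", "R9", "R10")]), 1)

  # planted restructuring (modules merged in one group): permutation p
  # small at n = 100/group. (A balanced swap of equally strong modules has
  # little power by construction: permuted halves tip to whichever
  # structure holds the sampling majority, reproducing the observed score
  # under the null.)
  rc3 <- gen_region_counts(100, regs, mods, 0.8, seed = 10)
  rc3b <- gen_region_counts(100, regs, list(regs), 0.8, seed = 11)
  rc3$counts[rc3$group == "NIC", ] <- rc3b$counts[rc3b$group == "NIC", ]
  cr3 <- community_reorganization(rc3, n_permutations = 199, seed = 3)
  expect_lt(cr3$p_value, 0.05)
})
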