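k8 <- fbn(matrix(1, 8, 8) - diag(8))
empty8 <- fbn(matrix(0, 8, 8))

test_that("the binary complete graph hits all analytic values at once", {
  m <- network_metrics(k8)
  expect_equal(m$D, 7)
  expect_equal(m$C, 1)
  expect_equal(m$L, 1)
  expect_equal(m$E, 1)
  expect_equal(m$BNE, 14, tolerance = 1e-9)  # eigenvalues 7, -1 x 7
  expect_equal(m$unreachable_pair_fraction, 0)
  expect_true(all(node_strength(k8) == 7))
})

test_that("the empty graph is all-zero and has no defined path length", {
  expect_equal(unname(node_strength(empty8)), rep(0, 8))
  expect_equal(unname(node_clustering(empty8)), rep(0, 8))
  expect_equal(global_efficiency(empty8), 0)
  expect_equal(brain_network_energy(empty8), 0)
  expect_error(characteristic_path_length(empty8),
               class = "sleepfbn_disconnected")
  m <- network_metrics(empty8)
  expect_true(is.na(m$L))
  expect_equal(m$unreachable_pair_fraction, 1)
})

test_that("classic small graphs give their textbook values", {
  tri <- fbn(matrix(1, 3, 3) - diag(3), LETTERS[1:3])
  expect_equal(unname(node_clustering(tri)), rep(1, 3))

  star <- matrix(0, 8, 8)
  star[1, 2:8] <- star[2:8, 1] <- 1
  expect_equal(mean(node_clustering(fbn(star))), 0)

  ring <- matrix(0, 8, 8)
  for (i in 1:8) {
    j <- i %% 8 + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  ringnet <- fbn(ring)
  expect_equal(characteristic_path_length(ringnet)$L, 16 / 7,
               tolerance = 1e-9)
  # ring distances from any node: 1,1,2,2,3,3,4
  e_ring <- mean(rep(c(1, 1, 1 / 2, 1 / 2, 1 / 3, 1 / 3, 1 / 4), 8))
  expect_equal(global_efficiency(ringnet), e_ring, tolerance = 1e-9)
})

test_that("all five metrics match brute-force oracles on random graphs", {
  for (s in 1:25) {
    w <- random_weight_matrix(s, 8, density = if (s %% 3) 1 else 0.4)
    net <- fbn(w)
    expect_equal(unname(node_strength(net)), oracle_strength(w),
                 tolerance = 1e-9)
    expect_equal(unname(node_clustering(net)), oracle_clustering(w),
                 tolerance = 1e-9)
    expect_equal(characteristic_path_length(net)$L, oracle_path_length(w),
                 tolerance = 1e-9)
    expect_equal(global_efficiency(net), oracle_efficiency(w),
                 tolerance = 1e-9)
    expect_equal(brain_network_energy(net), oracle_energy(w),
                 tolerance = 1e-9)
  }
})

test_that("shortest paths agree with igraph's independent implementation", {
  for (s in c(3, 14, 15, 92, 65)) {
    w <- random_weight_matrix(s, 8, density = 0.6)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    d_ig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    off <- d_ig[row(d_ig) != col(d_ig)]
    expect_equal(characteristic_path_length(fbn(w))$L,
                 mean(off[is.finite(off)]), tolerance = 1e-9)
    expect_equal(global_efficiency(fbn(w)),
                 mean(ifelse(is.finite(off), 1 / off, 0)), tolerance = 1e-9)
  }
})

test_that("adding an edge never decreases strength or efficiency", {
  for (s in 1:10) {
    w <- random_weight_matrix(s, 8, density = 0.5)
    d0 <- mean(node_strength(fbn(w)))
    e0 <- global_efficiency(fbn(w))
    free <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
    if (nrow(free) == 0) next
    pick <- free[withr::with_seed(s, sample(nrow(free), 1)), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <-
      withr::with_seed(s + 1000, runif(1, 0.05, 1))
    expect_gte(mean(node_strength(fbn(w2))), d0)
    expect_gte(global_efficiency(fbn(w2)), e0)
  }
})

test_that("graph energy respects the spectral lower bound", {
  # BNE >= 2 * sum(w^2) / lambda_max for symmetric non-negative matrices
  for (s in 1:15) {
    w <- random_weight_matrix(s, 8)
    lam <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(brain_network_energy(fbn(w)) + 1e-12,
               2 * sum(w^2) / 2 / max(lam))
  }
})

test_that("summary metrics are invariant under node relabelling", {
  w <- random_weight_matrix(77, 8)
  m <- network_metrics(fbn(w))
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample(8))
    mp <- network_metrics(fbn(w[perm, perm]))
    expect_equal(mp[, c("D", "C", "L", "E", "BNE")],
                 m[, c("D", "C", "L", "E", "BNE")], tolerance = 1e-9)
  }
})

test_that("invalid weight matrices violate the network invariants", {
  bad <- matrix(0, 3, 3); bad[1, 2] <- 0.5  # asymmetric
  expect_error(fbn(bad), class = "sleepfbn_invariant_violation")
  bad2 <- diag(3) * 0.5
  expect_error(fbn(bad2), class = "sleepfbn_invariant_violation")
  bad3 <- matrix(2, 3, 3) - 2 * diag(3)
  expect_error(fbn(bad3), class = "sleepfbn_invariant_violation")
})
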