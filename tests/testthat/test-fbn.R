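test_that("perfect linear dependence gives unit edge weight", {
  set.seed(4)
  base <- rnorm(100)
  seg <- rbind(ch1 = base, ch2 = 2 * base, ch3 = rnorm(100))
  net <- pearson_adjacency(seg)
  expect_equal(net$weights["ch1", "ch2"], 1, tolerance = 1e-12)

  seg_neg <- rbind(ch1 = base, ch2 = -base, ch3 = rnorm(100))
  net_neg <- pearson_adjacency(seg_neg)
  expect_equal(net_neg$weights["ch1", "ch2"], 1, tolerance = 1e-12)
})

test_that("the adjacency equals the covariance-formula oracle element-wise", {
  seg <- withr::with_seed(17, matrix(rnorm(8 * 100), 8, 100))
  rownames(seg) <- fbn_channels()
  net <- pearson_adjacency(seg)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      xi <- seg[i, ]; xj <- seg[j, ]
      r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
        sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      expect_equal(net$weights[i, j], abs(r), tolerance = 1e-12)
    }
  }
  expect_identical(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
})

test_that("degenerate segments are rejected informatively", {
  seg <- rbind(C3 = rnorm(50), C4 = rep(1, 50))
  err <- expect_error(pearson_adjacency(seg),
                      class = "sleepfbn_degenerate_channel")
  expect_match(conditionMessage(err), "C4")
  expect_error(pearson_adjacency(matrix(rnorm(4), 2, 2)),
               class = "sleepfbn_insufficient_samples")
  expect_error(pearson_adjacency(matrix(rnorm(10), 1, 10)),
               class = "sleepfbn_insufficient_samples")
})

test_that("aggregation is the element-wise mean of the segment networks", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.2
  w2 <- matrix(0, 3, 3); w2[1, 2] <- w2[2, 1] <- 0.8
  nets <- list(fbn(w, LETTERS[1:3]), fbn(w2, LETTERS[1:3]))
  agg <- aggregate_networks(nets)
  expect_equal(agg$weights[1, 2], 0.5)
  expect_equal(agg$n_segments_aggregated, 2L)

  ident <- replicate(10, fbn(w, LETTERS[1:3]), simplify = FALSE)
  expect_equal(aggregate_networks(ident)$weights, fbn(w, LETTERS[1:3])$weights)

  rand <- lapply(1:10, function(s) fbn(random_weight_matrix(s, 8)))
  agg_r <- aggregate_networks(rand)
  manual <- Reduce(`+`, lapply(rand, function(x) x$weights)) / 10
  expect_equal(max(abs(agg_r$weights - manual)), 0, tolerance = 1e-12)

  bad <- list(fbn(w, LETTERS[1:3]), fbn(w, c("X", "Y", "Z")))
  expect_error(aggregate_networks(bad),
               class = "sleepfbn_incompatible_network")
  expect_error(aggregate_networks(list()),
               class = "sleepfbn_incompatible_network")
})

test_that("the adjacency is equivariant under channel relabelling", {
  seg <- withr::with_seed(23, matrix(rnorm(8 * 200), 8, 200))
  rownames(seg) <- fbn_channels()
  net <- pearson_adjacency(seg)
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample(8))
    netp <- pearson_adjacency(seg[perm, ])
    expect_equal(netp$weights, net$weights[perm, perm], tolerance = 1e-12)
  }
})

test_that("the adjacency is invariant to positive channel rescaling", {
  seg <- withr::with_seed(29, matrix(rnorm(8 * 200), 8, 200))
  rownames(seg) <- fbn_channels()
  net <- pearson_adjacency(seg)
  scaled <- seg * withr::with_seed(30, runif(8, 0.1, 50))
  expect_equal(pearson_adjacency(scaled)$weights, net$weights,
               tolerance = 1e-12)
})

test_that("thresholding and binarization behave as documented", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.9
  net <- fbn(w, LETTERS[1:3])
  th <- fbn_threshold(net, 0.5)
  expect_equal(th$weights[1, 2], 0)
  expect_equal(th$weights[1, 3], 0.9)
  bin <- fbn_binarize(th)
  expect_equal(bin$weights[1, 3], 1)
  expect_equal(sum(bin$weights), 2)
})

test_that("graded planted couplings are recovered in rank order", {
  # dense tie-free coupling: rank agreement between planted weights and
  # aggregated |PCC| should be near-perfect at SNR ~ 1
  gw <- matrix(0, 8, 8)
  gw[upper.tri(gw)] <- seq(0.1, 0.6, length.out = 28)
  gw <- gw + t(gw)
  rho <- vapply(1:50, function(s) {
    rec <- simulate_eeg(coupling_model(gw, noise_sd = 1, seed = s),
                        duration = 160)
    net <- build_fbn(extract_segments(bandpass_filter(rec)))
    ut <- upper.tri(gw)
    cor(gw[ut], net$weights[ut], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0.8)
})
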