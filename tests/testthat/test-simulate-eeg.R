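test_that("a fully shared source gives perfectly correlated channels", {
  w <- matrix(0, 8, 8)
  w[1, 2] <- w[2, 1] <- 1
  rec <- simulate_eeg(coupling_model(w, noise_sd = 0, seed = 11),
                      duration = 20)
  expect_equal(cor(rec$signal[1, ], rec$signal[2, ]), 1, tolerance = 1e-9)
  expect_identical(rec$channel_labels, fbn_channels())
  expect_equal(rec$fs, 128)
})

test_that("uncoupled channels are nearly uncorrelated on average", {
  m <- vapply(1:20, function(s) {
    rec <- simulate_eeg(coupling_model(noise_sd = 0.2, seed = s),
                        duration = 60)
    cc <- abs(cor(t(rec$signal)))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  expect_lt(mean(m), 0.15)
})

test_that("identical seeds give bit-identical recordings", {
  m <- coupling_model(default_coupling(), noise_sd = 0.5, seed = 42)
  r1 <- simulate_eeg(m, duration = 10)
  r2 <- simulate_eeg(m, duration = 10)
  expect_identical(r1$signal, r2$signal)
  r3 <- simulate_eeg(coupling_model(default_coupling(), noise_sd = 0.5,
                                    seed = 43), duration = 10)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("invalid models and arguments are rejected", {
  w <- matrix(0, 8, 8); w[1, 2] <- 0.5  # not symmetric
  expect_error(coupling_model(w), class = "sleepfbn_invalid_model")
  expect_error(coupling_model(noise_sd = -1), class = "sleepfbn_invalid_model")
  bad_bands <- data.frame(low = 0.1, high = 40, power = 1)
  expect_error(coupling_model(band_profile = bad_bands),
               class = "sleepfbn_invalid_model")
  wd <- diag(8) * 0.5
  expect_error(coupling_model(wd), class = "sleepfbn_invalid_model")
  expect_error(simulate_eeg(coupling_model(), duration = 0),
               class = "sleepfbn_invalid_argument")
  expect_error(simulate_eeg(coupling_model(), duration = -5),
               class = "sleepfbn_invalid_argument")
})

test_that("expected |PCC| increases monotonically with planted coupling", {
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mean_r <- vapply(grid, function(wv) {
    w <- matrix(0, 8, 8)
    w[1, 2] <- w[2, 1] <- wv
    mean(vapply(1:50, function(s) {
      rec <- simulate_eeg(coupling_model(w, noise_sd = 0.5, seed = s * 100 + round(wv * 10)),
                          duration = 15)
      abs(cor(rec$signal[1, ], rec$signal[2, ]))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("simulated power is concentrated in the 0.3-30 Hz analysis band", {
  rec <- simulate_eeg(coupling_model(noise_sd = 0.2, seed = 5),
                      duration = 60)
  frac <- vapply(1:4, function(i) {
    sp <- stats::spec.pgram(stats::ts(rec$signal[i, ], frequency = rec$fs),
                            spans = 15, plot = FALSE, taper = 0)
    sum(sp$spec[sp$freq >= 0.3 & sp$freq <= 30]) / sum(sp$spec)
  }, numeric(1))
  expect_true(all(frac >= 0.9))
})

test_that("non-realizable couplings are projected, preserving validity", {
  # a 0.9-weight star is not jointly realizable as a correlation matrix;
  # the generator must still produce finite signals with high hub coupling
  w <- matrix(0, 8, 8)
  w[1, 2:4] <- w[2:4, 1] <- 0.9
  rec <- simulate_eeg(coupling_model(w, noise_sd = 0, seed = 9),
                      duration = 20)
  expect_true(all(is.finite(rec$signal)))
  r12 <- cor(rec$signal[1, ], rec$signal[2, ])
  expect_gt(r12, 0.5)
})
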