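#' Coupling model for synthetic sleep EEG
#'
#' Describes the ground-truth second-order structure of a simulated
#' multichannel recording: which channel pairs share latent band-limited
#' sources (and how strongly), the additive sensor-noise level, and the
#' spectral profile of the sources. The profile defaults to an NREM-II-like
#' mixture: delta-dominant with a 12--14 Hz sigma (sleep-spindle) band at
#' lower relative power.
#'
#' Channels are generated as a linear mixture of independent band-limited
#' Gaussian sources. The mixing matrix is the principal square root of the
#' target correlation matrix \eqn{R = I + W} (with \eqn{W} the coupling
#' matrix), so in the noise-free case the Pearson correlation between two
#' channels equals their coupling weight; additive white noise of standard
#' deviation `noise_sd` (in units of the per-channel signal SD) shrinks it
#' towards zero by a factor \eqn{1/(1+\sigma^2)}. When the requested
#' coupling is not jointly realizable as a correlation matrix, the nearest
#' positive-semidefinite projection (eigenvalue clipping, then rescaling to
#' unit diagonal) is used.
#'
#' @param coupling Symmetric numeric matrix with zero diagonal and entries
#'   in \[0, 1\]: source-sharing weight for each channel pair. Defaults to
#'   the all-zero matrix (independent channels).
#' @param n_channels Number of channels; 8 gives the canonical montage
#'   [fbn_channels()].
#' @param noise_sd Standard deviation of independent white sensor noise,
#'   relative to the unit per-channel signal SD. `noise_sd = 1` gives
#'   per-channel SNR of about 1. Must be >= 0.
#' @param band_profile Data frame with columns `low`, `high` (Hz, inside
#'   \[0.3, 30\]) and `power` (relative band power, normalized internally).
#'   Default [nrem2_band_profile()].
#' @param amplitude_uv Overall signal scale in microvolts (SD of the
#'   mixed signal before noise).
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#'
#' @return An object of class `coupling_model`.
#' @seealso [simulate_eeg()]
#' @export
#' @examples
#' w <- matrix(0, 8, 8)
#' w[1, 2] <- w[2, 1] <- 0.8
#' m <- coupling_model(coupling = w, noise_sd = 1, seed = 1)
#' m
coupling_model <- function(coupling = NULL, n_channels = 8, noise_sd = 0.2,
                           band_profile = nrem2_band_profile(),
                           amplitude_uv = 20, seed = 1) {
  if (is.null(coupling)) coupling <- matrix(0, n_channels, n_channels)
  coupling <- as.matrix(coupling)
  n_channels <- nrow(coupling)
  if (!isSymmetric(unname(coupling), tol = 0)) {
    abort("`coupling` must be exactly symmetric.", class = "sleepfbn_invalid_model")
  }
  if (any(diag(coupling) != 0)) {
    abort("`coupling` must have a zero diagonal.", class = "sleepfbn_invalid_model")
  }
  if (any(!is.finite(coupling)) || any(coupling < 0) || any(coupling > 1)) {
    abort("`coupling` entries must be finite and in [0, 1].",
          class = "sleepfbn_invalid_model")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    abort("`noise_sd` must be a single value >= 0.", class = "sleepfbn_invalid_model")
  }
  bp <- as.data.frame(band_profile)
  stopifnot(all(c("low", "high", "power") %in% names(bp)))
  if (any(bp$low < 0.3 - 1e-12) || any(bp$high > 30 + 1e-12) ||
      any(bp$low >= bp$high) || any(bp$power < 0)) {
    abort("band ranges must lie within [0.3, 30] Hz with low < high and power >= 0.",
          class = "sleepfbn_invalid_model")
  }
  structure(
    list(coupling = coupling, n_channels = n_channels, noise_sd = noise_sd,
         band_profile = bp, amplitude_uv = amplitude_uv,
         seed = as.integer(seed)),
    class = "coupling_model"
  )
}

#' @export
print.coupling_model <- function(x, ...) {
  n_edges <- sum(x$coupling[upper.tri(x$coupling)] > 0)
  cat("<coupling_model> ", x$n_channels, " channels, ", n_edges,
      " coupled pair(s), noise_sd = ", x$noise_sd,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' NREM-II-like spectral profile
#'
#' Default relative band powers for the synthetic sources: delta-dominant
#' (0.5--4 Hz), with theta, alpha, a 12--14 Hz sigma/spindle band, and a
#' small beta tail, all inside the 0.3--30 Hz analysis band.
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz) and `power`.
#' @export
nrem2_band_profile <- function() {
  tibble::tibble(
    band  = c("delta", "theta", "alpha", "sigma", "beta"),
    low   = c(0.5, 4, 8, 12, 14),
    high  = c(4, 8, 12, 14, 30),
    power = c(0.55, 0.20, 0.10, 0.10, 0.05)
  )
}

# One unit-variance band-limited Gaussian source via frequency-domain
# synthesis: random Fourier coefficients with amplitude sqrt(power density)
# inside the profile's bands, zero outside, Hermitian-symmetrized.
band_limited_source <- function(n, fs, band_profile) {
  freq <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  amp <- numeric(length(freq))
  total <- sum(band_profile$power)
  for (b in seq_len(nrow(band_profile))) {
    idx <- freq >= band_profile$low[b] & freq < band_profile$high[b]
    if (any(idx)) {
      dens <- band_profile$power[b] / total / sum(idx)
      amp[idx] <- sqrt(dens)
    }
  }
  half <- complex(real = rnorm(length(freq)), imaginary = rnorm(length(freq))) * amp
  half[1] <- 0  # no DC
  if (n %% 2 == 0) half[length(half)] <- complex(real = Re(half[length(half)]))
  coef <- c(half, Conj(rev(half[2:(length(half) - (n %% 2 == 0))])))
  x <- Re(fft(coef, inverse = TRUE))
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x / s else x
}

# Mixing matrix: principal square root of R = I + W, projected to the
# nearest correlation matrix if the request is not jointly realizable.
coupling_mixing_matrix <- function(coupling) {
  r <- coupling
  diag(r) <- 1
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    lam <- pmax(e$values, 0)
    r2 <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(r2))
    d[d == 0] <- 1
    r <- r2 / tcrossprod(d)
    e <- eigen(r, symmetric = TRUE)
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate a coupled multichannel sleep-EEG recording
#'
#' Generates `duration` seconds of `fs`-Hz multichannel signal whose
#' channels share latent band-limited Gaussian sources in proportion to the
#' model's coupling matrix, plus independent white sensor noise. For eight
#' channels the canonical montage labels [fbn_channels()] are used and the
#' reference is recorded as Cz.
#'
#' @param model A [coupling_model()].
#' @param duration Recording length in seconds (> 0). Use >= 150 s when the
#'   output will feed extraction of ten 15-s segments.
#' @param fs Sampling rate in Hz (default 128).
#' @param subject_id,timepoint Provenance identifiers carried through the
#'   pipeline.
#' @return An [eeg_recording()] with a `channels x samples` signal matrix
#'   in microvolts.
#' @export
#' @examples
#' w <- matrix(0, 8, 8); w[1, 2] <- w[2, 1] <- 1
#' rec <- simulate_eeg(coupling_model(w, noise_sd = 0, seed = 3), duration = 10)
#' cor(rec$signal[1, ], rec$signal[2, ])  # shared source: exactly 1
simulate_eeg <- function(model, duration = 160, fs = 128,
                         subject_id = "S01", timepoint = "baseline") {
  if (!inherits(model, "coupling_model")) {
    abort("`model` must be a coupling_model.", class = "sleepfbn_invalid_model")
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    abort("`duration` must be a single positive number of seconds.",
          class = "sleepfbn_invalid_argument")
  }
  if (!is.numeric(fs) || fs <= 0) {
    abort("`fs` must be positive.", class = "sleepfbn_invalid_argument")
  }
  n <- round(duration * fs)
  nc <- model$n_channels
  signal <- with_seed_if(model$seed, {
    sources <- matrix(0, nc, n)
    for (k in seq_len(nc)) {
      sources[k, ] <- band_limited_source(n, fs, model$band_profile)
    }
    mix <- coupling_mixing_matrix(model$coupling)
    x <- mix %*% sources
    if (model$noise_sd > 0) {
      x <- x + model$noise_sd * matrix(rnorm(nc * n), nc, n)
    }
    x * model$amplitude_uv
  })
  labels <- if (nc == 8) FBN_CHANNELS else sprintf("CH%02d", seq_len(nc))
  eeg_recording(signal, fs = fs, channel_labels = labels,
                reference_label = "Cz", subject_id = subject_id,
                timepoint = timepoint)
}
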