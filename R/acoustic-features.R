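#' Spectrogram configuration
#'
#' Parameters of the log-power spectrogram used throughout the acoustic
#' computations: a 512-sample Hamming window at 32 kHz with a 128-sample
#' (4 ms) hop, natural-log power after adding a fixed linear-power offset,
#' and removal of the lowest 10 frequency bins (cutoff 625 Hz) for robustness
#' to low-frequency noise.
#'
#' @param window_samples FFT window length in samples.
#' @param hop_samples Hop (non-overlap) between consecutive frames.
#' @param sample_rate Sampling rate in Hz.
#' @param log_offset Linear-power offset added before taking the log.
#' @param low_cut_bins Number of lowest frequency bins removed.
#' @param normalize If `TRUE`, linear power is divided by its maximum before
#'   the offset is added (the offset's scale relative to the signal is
#'   otherwise the caller's responsibility).
#' @param hps_harmonics Number of harmonics multiplied by the Harmonic
#'   Product Spectrum pitch estimator.
#' @return A list of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window_samples = 512L, hop_samples = 128L,
                               sample_rate = 32000, log_offset = 0.1,
                               low_cut_bins = 10L, normalize = FALSE,
                               hps_harmonics = 5L) {
  stopifnot(hop_samples <= window_samples, window_samples > 0,
            sample_rate > 0, log_offset > 0, low_cut_bins >= 0,
            hps_harmonics >= 1)
  structure(list(window_samples = as.integer(window_samples),
                 hop_samples = as.integer(hop_samples),
                 sample_rate = sample_rate, log_offset = log_offset,
                 low_cut_bins = as.integer(low_cut_bins),
                 normalize = isTRUE(normalize),
                 hps_harmonics = as.integer(hps_harmonics)),
            class = "spectrogram_config")
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# One-sided magnitude spectrum of a single window.
magnitude_spectrum <- function(x, n) {
  Mod(stats::fft(x * hamming_window(n)))[seq_len(n %/% 2 + 1L)]
}

#' Harmonic Product Spectrum pitch estimate
#'
#' Estimates the fundamental frequency of a short harmonic segment as the
#' frequency whose downsampled magnitude spectra multiply to the largest
#' product over `hps_harmonics` harmonics: compressing the spectrum by
#' factors 1..H aligns all harmonics of the true fundamental onto one bin,
#' so the estimate is robust even when the fundamental itself is weak or
#' missing.
#'
#' @param waveform_window Numeric vector of exactly
#'   `config$window_samples` samples (16 ms at 32 kHz by default).
#' @param config A [spectrogram_config()].
#' @param f_range Search range for the fundamental in Hz; the upper end is
#'   additionally limited so that all `hps_harmonics` harmonics fit below the
#'   Nyquist frequency.
#' @return Estimated fundamental frequency in Hz (resolution one FFT bin,
#'   `sample_rate / window_samples`).
#' @examples
#' cfg <- spectrogram_config()
#' w <- harmonic_stack(700, n_harmonics = 5, config = cfg)
#' hps_pitch(w, cfg)
#' @export
hps_pitch <- function(waveform_window, config = spectrogram_config(),
                      f_range = c(300, 1500)) {
  n <- config$window_samples
  if (length(waveform_window) != n) {
    stop("expected a window of exactly ", n, " samples")
  }
  if (all(waveform_window == 0)) {
    stop("pitch undefined for an all-zero (silent) window")
  }
  mag <- magnitude_spectrum(waveform_window, n)
  n_bins <- length(mag)
  h <- config$hps_harmonics
  bin_hz <- config$sample_rate / n
  k_max <- min(floor((n_bins - 1L) / h), floor(f_range[2] / bin_hz))
  k_min <- max(1L, ceiling(f_range[1] / bin_hz))
  if (k_min > k_max) stop("empty fundamental search range")
  ks <- k_min:k_max
  # log-domain product of the h compressed spectra
  score <- rowSums(sapply(seq_len(h), function(m) log(mag[ks * m + 1L] + 1e-12)))
  ks[which.max(score)] * bin_hz
}

#' Synthetic harmonic tone stack
#'
#' Generates a windowed sum of sinusoidal harmonics of a given fundamental —
#' the standard fixture for exercising the pitch estimator and spectrogram
#' code without audio recordings.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param n_harmonics Number of harmonics.
#' @param amplitudes Optional per-harmonic amplitudes (default all 1);
#'   setting the first to 0 yields a missing-fundamental stack.
#' @param duration_samples Length in samples.
#' @param config A [spectrogram_config()] (supplies the sampling rate).
#' @param phase Common phase offset in radians.
#' @return Numeric waveform vector.
#' @export
harmonic_stack <- function(f0, n_harmonics = 5L, amplitudes = NULL,
                           duration_samples = 512L,
                           config = spectrogram_config(), phase = 0) {
  if (is.null(amplitudes)) amplitudes <- rep(1, n_harmonics)
  stopifnot(length(amplitudes) == n_harmonics)
  t <- seq_len(duration_samples) / config$sample_rate
  w <- numeric(duration_samples)
  for (m in seq_len(n_harmonics)) {
    w <- w + amplitudes[m] * sin(2 * pi * m * f0 * t + phase)
  }
  w
}

# Linear-power spectrogram (frequency x frame), low bins removed.
linear_power_spectrogram <- function(waveform, config) {
  n <- config$window_samples
  if (length(waveform) < n) stop("waveform shorter than one window")
  starts <- seq(1L, length(waveform) - n + 1L, by = config$hop_samples)
  spec <- vapply(starts, function(s) {
    magnitude_spectrum(waveform[s:(s + n - 1L)], n)^2
  }, numeric(n %/% 2 + 1L))
  if (config$low_cut_bins > 0L) {
    spec <- spec[-seq_len(config$low_cut_bins), , drop = FALSE]
  }
  if (config$normalize && max(spec) > 0) spec <- spec / max(spec)
  spec
}

#' Log-power spectrogram
#'
#' Natural logarithm of the linear-power spectrogram after adding the
#' configured offset, with the lowest frequency bins removed. Rows are
#' frequency bins (starting at `low_cut_bins * sample_rate / window_samples`
#' Hz), columns are frames at the hop interval.
#'
#' @param waveform Numeric waveform vector (mono).
#' @param config A [spectrogram_config()].
#' @return Numeric matrix (frequency x time) of natural-log power.
#' @export
log_power_spectrogram <- function(waveform, config = spectrogram_config()) {
  log(linear_power_spectrogram(waveform, config) + config$log_offset)
}

#' Wiener entropy features of a syllable
#'
#' Per-frame spectral (Wiener) entropy — the log ratio of the geometric to
#' the arithmetic mean of linear power across frequency bins — summarized by
#' its mean and variance over frames. The entropy is 0 for a perfectly flat
#' (noise-like) spectrum and strongly negative for a peaked (tonal) one, so
#' the mean measures syllable noisiness and the variance measures complexity
#' (alternation between tonal and noisy parts).
#'
#' @param x Either a waveform vector or a precomputed linear-power
#'   spectrogram matrix (frequency x time).
#' @param config A [spectrogram_config()] (used when `x` is a waveform).
#' @return List with `mean_entropy` and `variance_entropy` (log units).
#' @export
entropy_features <- function(x, config = spectrogram_config()) {
  spec <- if (is.matrix(x)) x else linear_power_spectrogram(x, config)
  if (ncol(spec) < 2L) stop("entropy variance undefined for a single frame")
  eps <- 1e-300
  per_frame <- apply(spec, 2L, function(p) {
    mean(log(p + eps)) - log(mean(p) + eps)
  })
  list(mean_entropy = mean(per_frame),
       variance_entropy = stats::var(per_frame))
}

#' Spectrogram bias-variance decomposition across two days
#'
#' Quantifies spectral change between two days of renditions of the same
#' syllable: the bias is the Euclidean distance between the two day-mean
#' spectrograms, and each day's variance is the average pixel-wise variance
#' across that day's renditions. All renditions are cropped to the duration
#' (column count) of the shortest rendition before comparison.
#'
#' @param renditions_day_a,renditions_day_b Lists of spectrogram matrices
#'   (same row count; columns may differ and are cropped).
#' @return List with `bias`, `variance_a`, `variance_b`.
#' @export
spectrogram_bias_variance <- function(renditions_day_a, renditions_day_b) {
  stopifnot(is.list(renditions_day_a), is.list(renditions_day_b))
  if (length(renditions_day_a) < 2L || length(renditions_day_b) < 2L) {
    stop("each day needs at least 2 renditions for a variance estimate")
  }
  all_r <- c(renditions_day_a, renditions_day_b)
  n_col <- min(vapply(all_r, ncol, integer(1L)))
  n_row <- unique(vapply(all_r, nrow, integer(1L)))
  if (length(n_row) != 1L) stop("renditions differ in frequency bins")
  crop <- function(lst) lapply(lst, function(m) m[, seq_len(n_col), drop = FALSE])
  a <- crop(renditions_day_a); b <- crop(renditions_day_b)

  day_mean <- function(lst) Reduce(`+`, lst) / length(lst)
  day_var <- function(lst) {
    stack <- simplify2array(lst) # row x col x rendition
    mean(apply(stack, c(1L, 2L), stats::var))
  }
  ma <- day_mean(a); mb <- day_mean(b)
  list(bias = sqrt(sum((ma - mb)^2)),
       variance_a = day_var(a), variance_b = day_var(b))
}
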