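# Cepstral front end: each montaged channel is cut into overlapping frames,
# a tapered power spectrum is passed through a linearly spaced triangular
# filter bank, and log filter-bank outputs are decorrelated by an orthonormal
# DCT-II. Energy, differential energy and regression deltas complete the
# 26-dimensional frame vector.

#' Feature-extraction configuration
#'
#' @param frame_step frame advance in seconds (default 0.1 s).
#' @param analysis_window analysis window length in seconds (default 0.2 s,
#'   i.e. 50% frame overlap).
#' @param n_cepstra number of cepstral coefficients kept (default 7; the
#'   zeroth-order coefficient is always discarded).
#' @param n_filters number of triangular filters (default 24).
#' @param fft_size FFT length in samples (default 64, covering the 0.2 s
#'   window at 250 Hz).
#' @param diff_energy_window differential-energy window in seconds
#'   (default 0.9 s = 9 frames, centered).
#' @param delta_window regression half-window (in frames) for first
#'   derivatives (default 9).
#' @param delta_delta_window regression half-window for second derivatives
#'   (default 3).
#' @param band two-element numeric, filter-bank band edges in Hz
#'   (default c(0, 125), the full band at 250 Hz).
#' @param energy_from either "filterbank" (default: the energy term sums the
#'   filter-bank outputs) or "fft" (sums raw FFT power bins).
#' @param log_floor floor applied inside logarithms (default 1e-10).
#' @return list of class `feature_config`.
#' @export
feature_config <- function(frame_step = 0.1, analysis_window = 0.2,
                           n_cepstra = 7L, n_filters = 24L, fft_size = 64L,
                           diff_energy_window = 0.9, delta_window = 9L,
                           delta_delta_window = 3L, band = c(0, 125),
                           energy_from = c("filterbank", "fft"),
                           log_floor = 1e-10) {
  energy_from <- match.arg(energy_from)
  if (frame_step > analysis_window) stop("frame_step must be <= analysis_window")
  if (n_cepstra >= n_filters) stop("n_cepstra must be < n_filters")
  k <- diff_energy_window / frame_step
  if (abs(k - round(k)) > 1e-9 || round(k) %% 2L != 1L) {
    stop("diff_energy_window must be an odd multiple of frame_step")
  }
  structure(list(frame_step = frame_step, analysis_window = analysis_window,
                 n_cepstra = as.integer(n_cepstra),
                 n_filters = as.integer(n_filters),
                 fft_size = as.integer(fft_size),
                 diff_energy_window = diff_energy_window,
                 delta_window = as.integer(delta_window),
                 delta_delta_window = as.integer(delta_delta_window),
                 band = band, energy_from = energy_from,
                 log_floor = log_floor),
            class = "feature_config")
}

#' Cut one channel into overlapping analysis frames
#'
#' One frame is produced per `frame_step`, so the frame count equals
#' `floor(duration / frame_step)`; the record tail is zero-padded so the
#' final frames exist.
#'
#' @param channel numeric vector of samples.
#' @param rate sampling rate in Hz.
#' @param config a [feature_config()].
#' @return numeric matrix `n_frames x window_samples`.
#' @export
frame_signal <- function(channel, rate, config = feature_config()) {
  step <- round(config$frame_step * rate)
  win <- round(config$analysis_window * rate)
  if (length(channel) < win) {
    stop("channel shorter than one analysis window (", win, " samples)")
  }
  n_frames <- floor(length(channel) / step)
  padded <- c(channel, numeric(win))
  idx <- outer(seq_len(n_frames) - 1L, seq_len(win) - 1L,
               function(f, s) f * step + s + 1L)
  matrix(padded[idx], nrow = n_frames, ncol = win)
}

#' Tapered power spectrum of one frame
#'
#' A Hamming taper is applied, the frame is zero-padded to `fft_size`, and
#' the one-sided power spectrum `|X(k)|^2` is returned
#' (`fft_size/2 + 1` bins).
#'
#' @param frame numeric vector of windowed samples.
#' @param config a [feature_config()].
#' @return numeric vector of non-negative power values.
#' @export
frame_spectrum <- function(frame, config = feature_config()) {
  if (length(frame) == 0L) stop("empty frame")
  nfft <- config$fft_size
  if (nfft < length(frame)) stop("fft_size smaller than analysis window")
  w <- hamming_taper(length(frame))
  x <- c(frame * w, numeric(nfft - length(frame)))
  Mod(stats::fft(x))[seq_len(nfft / 2L + 1L)]^2
}

hamming_taper <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' Frequency-domain energy term
#'
#' The log of the summed spectral energy, `E_f = log(sum(power))`, floored at
#' `log_floor` so silent frames stay finite. By default the sum runs over
#' the filter-bank outputs (the oversampled-filter-bank convention); set
#' `energy_from = "fft"` in the config to sum raw FFT bins instead.
#'
#' @param spectrum non-negative power values (FFT bins or filter outputs).
#' @param config a [feature_config()].
#' @return scalar `E_f`.
#' @export
frequency_energy <- function(spectrum, config = feature_config()) {
  log(max(sum(spectrum), config$log_floor))
}

# triangular filter bank, linearly spaced with 50% overlap over `band`
linear_filterbank <- function(config, rate = 250) {
  nfft <- config$fft_size
  freqs <- (0:(nfft / 2L)) * rate / nfft
  edges <- seq(config$band[1], min(config$band[2], rate / 2),
               length.out = config$n_filters + 2L)
  fb <- matrix(0, nrow = config$n_filters, ncol = length(freqs))
  for (i in seq_len(config$n_filters)) {
    lo <- edges[i]; ce <- edges[i + 1L]; hi <- edges[i + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# orthonormal DCT-II matrix (rows = coefficients)
dct_matrix <- function(n_out, n_in) {
  m <- outer(0:(n_out - 1L), 0:(n_in - 1L),
             function(k, j) cos(pi * k * (2 * j + 1) / (2 * n_in)))
  m <- m * sqrt(2 / n_in)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Linear-frequency cepstral coefficients of one spectrum
#'
#' The power spectrum is pooled by the triangular filter bank, logs are
#' taken (floored), and an orthonormal DCT-II decorrelates the log outputs.
#' Coefficients 1..`n_cepstra` are returned; the zeroth is discarded in
#' favor of the energy term.
#'
#' @param spectrum one-sided power spectrum from [frame_spectrum()].
#' @param config a [feature_config()].
#' @param rate sampling rate in Hz (determines bin frequencies).
#' @return numeric vector of length `n_cepstra`.
#' @export
filterbank_cepstra <- function(spectrum, config = feature_config(), rate = 250) {
  fb <- linear_filterbank(config, rate)
  logs <- log(pmax(as.vector(fb %*% spectrum), config$log_floor))
  dct <- dct_matrix(config$n_cepstra + 1L, config$n_filters)
  as.vector(dct %*% logs)[-1L]
}

#' Differential energy over a sliding window
#'
#' For each frame, the max-minus-min of the frame log-energy over a centered
#' window (default 0.9 s = 9 frames; clipped at the record edges). This
#' separates transient pulse-shaped events from stationary background.
#'
#' @param energy numeric vector of per-frame `E_f` values.
#' @param config a [feature_config()].
#' @return numeric vector `E_d` of the same length, all values >= 0.
#' @export
differential_energy <- function(energy, config = feature_config()) {
  n <- length(energy)
  if (n < 1L) stop("empty energy sequence")
  half <- (round(config$diff_energy_window / config$frame_step) - 1L) %/% 2L
  vapply(seq_len(n), function(t) {
    w <- energy[max(1L, t - half):min(n, t + half)]
    max(w) - min(w)
  }, 0)
}

#' Regression-based derivative of a feature series
#'
#' `d_t = sum_{n=1..N} n (c_{t+n} - c_{t-n}) / (2 sum_{n=1..N} n^2)`, with
#' boundary values replicated beyond the series edges. Applied once for
#' delta features and again (on the deltas) for delta-deltas.
#'
#' @param series numeric vector (or matrix, column-wise).
#' @param N regression half-window in frames.
#' @return derivative series, same shape as `series`.
#' @export
regression_deltas <- function(series, N) {
  if (N < 1L) stop("N must be >= 1")
  if (is.matrix(series)) return(apply(series, 2L, regression_deltas, N = N))
  Tn <- length(series)
  denom <- 2 * sum((1:N)^2)
  idx <- function(t) pmin(pmax(t, 1L), Tn)  # replicate boundaries
  vapply(seq_len(Tn), function(t) {
    n <- 1:N
    sum(n * (series[idx(t + n)] - series[idx(t - n)])) / denom
  }, 0)
}

#' Extract 26-dimensional feature sequences from a montaged record
#'
#' Per channel and frame: seven cepstral coefficients, the frequency-domain
#' energy `E_f` and the differential energy `E_d` (9 absolute features),
#' their nine deltas, and eight delta-deltas (the `E_d` delta-delta is
#' excluded) — 26 features per 0.1 s frame at the defaults.
#'
#' @param record a montaged, 250 Hz [eeg_record()].
#' @param config a [feature_config()].
#' @return list of `feature_sequence` objects, one per channel, each a list
#'   with `frames` (matrix `n_frames x 26`), `frame_step`, `channel_index`.
#' @export
extract_features <- function(record, config = feature_config()) {
  rate <- record$rate
  fb <- linear_filterbank(config, rate)
  dct <- dct_matrix(config$n_cepstra + 1L, config$n_filters)
  lapply(seq_along(record$channel_names), function(ci) {
    frames <- frame_signal(record$samples[, ci], rate, config)
    nfft <- config$fft_size
    w <- hamming_taper(ncol(frames))
    tapered <- sweep(frames, 2L, w, `*`)
    padded <- cbind(tapered, matrix(0, nrow(tapered), nfft - ncol(tapered)))
    spec <- Mod(stats::mvfft(t(padded)))[seq_len(nfft / 2L + 1L), , drop = FALSE]^2
    fbout <- fb %*% spec                       # n_filters x n_frames
    logs <- log(pmax(fbout, config$log_floor))
    ceps <- t((dct %*% logs)[-1L, , drop = FALSE])  # n_frames x n_cepstra
    ef <- if (config$energy_from == "filterbank") {
      log(pmax(colSums(fbout), config$log_floor))
    } else {
      log(pmax(colSums(spec), config$log_floor))
    }
    ed <- differential_energy(ef, config)
    absf <- cbind(ceps, ef, ed)
    d1 <- regression_deltas(absf, config$delta_window)
    d2 <- regression_deltas(d1[, seq_len(ncol(absf) - 1L), drop = FALSE],
                            config$delta_delta_window)
    feats <- cbind(absf, d1, d2)
    colnames(feats) <- c(paste0("c", seq_len(config$n_cepstra)), "Ef", "Ed",
                         paste0("d_", c(paste0("c", seq_len(config$n_cepstra)),
                                        "Ef", "Ed")),
                         paste0("dd_", c(paste0("c", seq_len(config$n_cepstra)),
                                         "Ef")))
    structure(list(frames = feats, frame_step = config$frame_step,
                   channel_index = ci - 1L),
              class = "feature_sequence")
  })
}

#' Feature vector dimension implied by a configuration
#' @param config a [feature_config()].
#' @return integer: `(n_cepstra + 2) * 3 - 1` (26 at the defaults).
#' @export
feature_dimension <- function(config = feature_config()) {
  n_abs <- config$n_cepstra + 2L
  as.integer(n_abs * 3L - 1L)
}
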