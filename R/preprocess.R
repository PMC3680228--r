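#' Bandpass filter specification
#'
#' 4th-order Butterworth, 10-450 Hz by default — the surface-EMG band after
#' amplifier roll-off. Applied zero-phase (forward-backward), so singularity
#' positions are not shifted; the magnitude response is therefore that of an
#' 8th-order filter while the design order stays 4 per pass.
#'
#' @param order per-pass filter order (default 4).
#' @param low_hz,high_hz band edges in Hz.
#' @export
filter_spec <- function(order = 4, low_hz = 10, high_hz = 450) {
  if (order < 1) stop_wmd("filter order must be >= 1")
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop_wmd("need 0 < low_hz < high_hz, got %g and %g", low_hz, high_hz)
  }
  structure(list(order = order, low_hz = low_hz, high_hz = high_hz,
                 family = "butterworth"), class = "filter_spec")
}

signal_vector <- function(x) {
  if (inherits(x, "emg_recording")) x$samples else as.numeric(x)
}

replace_samples <- function(x, samples) {
  if (inherits(x, "emg_recording")) {
    x$samples <- samples
    x
  } else {
    samples
  }
}

#' RMS normalization
#'
#' Divides a recording by a root-mean-square scale. With the default
#' `scale = NULL` the recording's own RMS is used, giving unit output RMS;
#' a session-level constant (e.g. the RMS of a subject's reference-class
#' recording) can be supplied instead so that relative amplitudes between
#' recordings — the volume-conduction information the method relies on —
#' are preserved.
#'
#' @param x numeric vector or [emg_recording()].
#' @param scale positive normalization constant; `NULL` for the input's RMS.
#' @return same type as `x`.
#' @export
rms_normalize <- function(x, scale = NULL) {
  v <- signal_vector(x)
  if (length(v) == 0) stop_wmd("cannot normalize an empty recording")
  s <- scale %||% rms(v)
  if (!is.finite(s) || s <= 0) {
    stop_wmd("degenerate recording: RMS scale is %g (all-zero input?)", s)
  }
  replace_samples(x, v / s)
}

#' Zero-phase Butterworth bandpass
#'
#' @param x numeric vector or [emg_recording()].
#' @param fs sampling rate (taken from the recording if omitted).
#' @param spec a [filter_spec()].
#' @return same type as `x`, filtered forward-backward (no phase shift).
#' @export
bandpass <- function(x, fs = NULL, spec = filter_spec()) {
  v <- signal_vector(x)
  fs <- fs %||% (if (inherits(x, "emg_recording")) x$fs else NULL)
  if (is.null(fs)) stop_wmd("fs is required for plain numeric input")
  if (spec$high_hz >= fs / 2) {
    stop_wmd("high_hz (%g) must be below Nyquist (%g)", spec$high_hz, fs / 2)
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  replace_samples(x, signal::filtfilt(bf, v))
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# Frame a signal into overlapping windows: matrix window_len x n_frames.
frame_signal <- function(v, window_len, hop) {
  starts <- seq(1L, length(v) - window_len + 1L, by = hop)
  vapply(starts, function(s) v[s:(s + window_len - 1L)],
         numeric(window_len))
}

#' Estimate a per-subject noise spectrum template
#'
#' Averages the one-sided magnitude spectrum of Hann-windowed frames of a
#' background (rest) recording, after bandpass filtering. Background noise
#' varies between sessions, so the template is re-estimated per subject and
#' session rather than assumed stationary across the study.
#'
#' @param background numeric vector or [emg_recording()] of rest activity.
#' @param fs sampling rate (from the recording if omitted).
#' @param window_len analysis window length in samples (default 64, i.e.
#'   62.5 ms at 1024 Hz: several times the MUAP duration, so sparse events
#'   stay localized in single frames while the averaged noise spectrum
#'   remains smooth).
#' @param n_windows number of windows to average; must be at least 20.
#'   `NULL` uses every available window.
#' @param overlap fractional window overlap (default 0.5).
#' @param filter a [filter_spec()] applied first, or `NULL` to skip.
#' @return object of class `noise_template` with fields
#'   `magnitude_spectrum` (length `window_len/2 + 1`), `window_len`,
#'   `n_windows_averaged`, `fs`.
#' @export
estimate_noise_template <- function(background, fs = NULL, window_len = 64,
                                    n_windows = NULL, overlap = 0.5,
                                    filter = filter_spec()) {
  v <- signal_vector(background)
  fs <- fs %||% (if (inherits(background, "emg_recording")) background$fs else NULL)
  if (is.null(fs)) stop_wmd("fs is required for plain numeric input")
  if (!is.null(n_windows) && n_windows < 20) {
    stop_wmd("n_windows must be at least 20 (got %d): the template is an average spectrum",
             n_windows)
  }
  if (!is.null(filter)) v <- bandpass(v, fs, filter)
  hop <- max(1L, as.integer(round(window_len * (1 - overlap))))
  avail <- if (length(v) >= window_len) {
    length(seq(1L, length(v) - window_len + 1L, by = hop))
  } else 0L
  need <- n_windows %||% 20L
  if (avail < need) {
    stop_wmd(paste0("background too short: %d samples give %d windows of %d ",
                    "(hop %d), but %d are required"),
             length(v), avail, window_len, hop, need)
  }
  use <- n_windows %||% avail
  frames <- frame_signal(v, window_len, hop)[, seq_len(use), drop = FALSE]
  w <- hann_window(window_len)
  mags <- apply(frames, 2, function(f) Mod(stats::fft(f * w)))
  spectrum <- rowMeans(mags)[seq_len(window_len / 2 + 1)]
  structure(
    list(magnitude_spectrum = spectrum, window_len = as.integer(window_len),
         n_windows_averaged = as.integer(use), fs = fs, overlap = overlap),
    class = "noise_template"
  )
}

#' Adaptive spectral subtraction
#'
#' Short-time Fourier analysis with a Hann window at 50% overlap; in each
#' frame the noise-template magnitude (optionally scaled by an
#' over-subtraction factor `alpha`) is subtracted from the frame magnitude
#' and floored at zero, the noisy phase is kept, and the signal is rebuilt
#' by overlap-add. The Hann/50%-overlap pair sums to a constant, so a zero
#' template reconstructs the input exactly (up to floating point).
#'
#' @param x numeric vector or [emg_recording()].
#' @param template a [estimate_noise_template()] object with matching `fs`.
#' @param alpha over-subtraction factor (default 1).
#' @return same type as `x`, length preserved.
#' @export
spectral_subtract <- function(x, template, alpha = 1) {
  v <- signal_vector(x)
  fs <- if (inherits(x, "emg_recording")) x$fs else template$fs
  if (!inherits(template, "noise_template")) {
    stop_wmd("template must be a noise_template")
  }
  if (!isTRUE(all.equal(fs, template$fs))) {
    stop_wmd("template fs (%g) does not match recording fs (%g)", template$fs, fs)
  }
  L <- template$window_len
  hop <- L %/% 2L
  w <- hann_window(L)
  # full (two-sided) noise magnitude from the one-sided template
  half <- template$magnitude_spectrum
  noise_mag <- c(half, rev(half[2:(L %/% 2)]))

  n <- length(v)
  # pad so every sample is covered by a full complement of windows
  pad <- L
  vp <- c(numeric(pad), v, numeric(pad + L))
  nf <- (length(vp) - L) %/% hop + 1L
  out <- numeric(length(vp))
  wsum <- numeric(length(vp))
  for (m in seq_len(nf)) {
    s <- (m - 1L) * hop + 1L
    idx <- s:(s + L - 1L)
    spec <- stats::fft(vp[idx] * w)
    mag <- Mod(spec)
    cleaned <- pmax(mag - alpha * noise_mag, 0)
    scale <- ifelse(mag > 0, cleaned / mag, 0)
    rec <- Re(stats::fft(spec * scale, inverse = TRUE)) / L
    out[idx] <- out[idx] + rec * w
    wsum[idx] <- wsum[idx] + w^2
  }
  res <- out[(pad + 1L):(pad + n)] / wsum[(pad + 1L):(pad + n)]
  replace_samples(x, res)
}

#' Preprocess one recording
#'
#' The standard chain: zero-phase bandpass, spectral subtraction of the
#' session noise template, then RMS normalization by a session-level scale
#' (or the recording's own RMS when no scale is given).
#'
#' @param x numeric vector or [emg_recording()].
#' @param template [estimate_noise_template()] result, or `NULL` to skip
#'   subtraction.
#' @param fs sampling rate for plain numeric input.
#' @param spec a [filter_spec()].
#' @param scale session normalization constant, or `NULL`.
#' @param alpha over-subtraction factor.
#' @return same type as `x`.
#' @export
preprocess_recording <- function(x, template = NULL, fs = NULL,
                                 spec = filter_spec(), scale = NULL,
                                 alpha = 1) {
  y <- bandpass(x, fs, spec)
  if (!is.null(template)) y <- spectral_subtract(y, template, alpha)
  rms_normalize(y, scale)
}
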