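#' Synthetic MUAP template
#'
#' Builds a smooth, peak-normalized motor-unit action potential (MUAP)
#' waveform. The biphasic shape is the first derivative of a Gaussian, the
#' triphasic shape its second derivative; both are standard idealizations in
#' EMG simulation and present a sharp singularity to the wavelet analysis.
#'
#' @param duration_ms template duration in milliseconds, in \[5, 20\].
#' @param n_phases 2 (biphasic) or 3 (triphasic).
#' @param fs sampling rate in samples/s; must exceed 900 (twice the upper
#'   edge of the surface-EMG band).
#' @return object of class `muap_template`: list with `samples` (peak
#'   absolute value 1), `duration_ms`, `fs`.
#' @examples
#' tpl <- make_muap_template(10, 2, 1024)
#' length(tpl$samples)   # round(10.24) = 10
#' max(abs(tpl$samples)) # 1
#' @export
make_muap_template <- function(duration_ms = 10, n_phases = 2, fs = 1024) {
  if (!is.numeric(duration_ms) || duration_ms <= 0) {
    stop_wmd("duration_ms must be positive, got %s", format(duration_ms))
  }
  if (duration_ms < 5 || duration_ms > 20) {
    stop_wmd("duration_ms must lie in [5, 20] ms, got %g", duration_ms)
  }
  if (!n_phases %in% c(2, 3)) stop_wmd("n_phases must be 2 or 3")
  if (!is.numeric(fs) || fs <= 0) stop_wmd("fs must be positive")
  if (fs <= 2 * 450) stop_wmd("fs must exceed 900 samples/s (2 x 450 Hz band edge)")

  n <- round(duration_ms * fs / 1000)
  # symmetric grid over ~±3.5 sigma so the truncated tails are negligible
  u <- seq(-3.5, 3.5, length.out = n)
  w <- if (n_phases == 2) -u * exp(-u^2 / 2) else (1 - u^2) * exp(-u^2 / 2)
  w <- w / max(abs(w))
  structure(
    list(samples = w, duration_ms = duration_ms, fs = fs),
    class = "muap_template"
  )
}

#' Muscle source description
#'
#' One muscle (or motor-unit pool) as seen by the recording electrode. The
#' `amplitude_gain` encodes volume conduction: potentials are attenuated with
#' distance through anisotropic tissue, so each muscle presents MUAPs of a
#' characteristic magnitude at a fixed electrode.
#'
#' @param amplitude_gain positive scalar multiplying the template.
#' @param firing_rate mean firing rate in pulses/s; 0 silences the source,
#'   otherwise it must lie in \[5, 35\].
#' @param jitter_cv coefficient of variation of the inter-pulse interval,
#'   in \[0, 0.5\].
#' @param template a [make_muap_template()] object.
#' @param seed_offset integer mixed into the simulation seed so a source's
#'   spike train does not depend on its position in the source list.
#' @export
muscle_source <- function(amplitude_gain, firing_rate, jitter_cv = 0.15,
                          template = make_muap_template(), seed_offset = NULL) {
  if (!is.numeric(amplitude_gain) || amplitude_gain <= 0) {
    stop_wmd("amplitude_gain must be > 0")
  }
  if (firing_rate != 0 && (firing_rate < 5 || firing_rate > 35)) {
    stop_wmd("firing_rate must be 0 or in [5, 35] pulses/s, got %g", firing_rate)
  }
  if (jitter_cv < 0 || jitter_cv > 0.5) stop_wmd("jitter_cv must lie in [0, 0.5]")
  if (!inherits(template, "muap_template")) stop_wmd("template must be a muap_template")
  structure(
    list(amplitude_gain = amplitude_gain, firing_rate = firing_rate,
         jitter_cv = jitter_cv, template = template, seed_offset = seed_offset),
    class = "muscle_source"
  )
}

#' EMG recording container
#'
#' @param samples numeric amplitude sequence.
#' @param fs sampling rate in samples/s.
#' @param label one of `"background"`, `"class1"` ... `"class4"`.
#' @param trial_id integer trial index.
#' @param subject_id subject identifier string.
#' @export
emg_recording <- function(samples, fs, label = "background", trial_id = 1L,
                          subject_id = "S1") {
  if (!is.numeric(fs) || fs <= 0) stop_wmd("fs must be > 0")
  labels <- c("background", paste0("class", 1:4))
  if (!label %in% labels) {
    stop_wmd("label must be one of %s", paste(labels, collapse = ", "))
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, label = label,
         trial_id = as.integer(trial_id), subject_id = subject_id),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s trial %d (%s): %d samples @ %g Hz, RMS %.4g\n",
              x$subject_id, x$trial_id, x$label, length(x$samples), x$fs,
              rms(x$samples)))
  invisible(x)
}

# Spike train of one source: renewal process with Gaussian-jittered
# inter-pulse intervals, truncated away from zero so pulses stay ordered.
source_spike_times <- function(source, duration_s) {
  rate <- source$firing_rate
  if (rate <= 0) return(numeric(0))
  isi <- 1 / rate
  times <- numeric(0)
  t <- stats::runif(1, 0, isi)
  while (t < duration_s) {
    times <- c(times, t)
    dt <- isi * (1 + source$jitter_cv * stats::rnorm(1))
    t <- t + max(dt, 0.2 * isi)
  }
  times
}

# Band-limited additive noise: white Gaussian shaped by the 20-450 Hz
# amplifier band (4th-order Butterworth), rescaled to an exact RMS. An
# optional slow sinusoidal drift of the noise level exercises the adaptive
# (template re-estimated per session) spectral-subtraction filter.
band_limited_noise <- function(n, fs, noise_rms, drift = 0) {
  if (noise_rms <= 0) return(numeric(n))
  e <- stats::rnorm(n)
  hi <- min(450, 0.45 * fs)
  bf <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
  e <- signal::filtfilt(bf, e)
  e <- e / rms(e) * noise_rms
  if (drift > 0) {
    e <- e * (1 + drift * sin(2 * pi * 0.1 * seq_len(n) / fs))
  }
  e
}

#' Simulate a single-channel sEMG recording
#'
#' Sums gain-scaled MUAP trains from a set of muscle sources and adds
#' band-limited Gaussian noise. Exactly one source (the `active_index`) fires
#' at its stated rate to represent the flexing muscle; by convention the
#' caller sets the remaining sources to a low background rate or zero.
#'
#' @param sources list of [muscle_source()] objects (non-empty).
#' @param active_index index of the active source (kept for provenance; the
#'   firing rates carried by the sources are used as given).
#' @param duration_s recording length in seconds (> 0).
#' @param fs sampling rate in samples/s.
#' @param noise_rms RMS of the additive band-limited noise (>= 0); the
#'   realized noise component is rescaled to this RMS exactly.
#' @param seed integer seed; fixed seed gives a byte-identical recording.
#' @param noise_drift relative amplitude (0 disables) of a slow sinusoidal
#'   modulation of the noise level.
#' @param label,trial_id,subject_id recording metadata.
#' @return an [emg_recording()].
#' @export
simulate_recording <- function(sources, active_index = 1L, duration_s = 7.5,
                               fs = 1024, noise_rms = 0, seed = NULL,
                               noise_drift = 0, label = "background",
                               trial_id = 1L, subject_id = "S1") {
  if (length(sources) == 0) stop_wmd("sources must be a non-empty list")
  if (duration_s <= 0) stop_wmd("duration_s must be > 0")
  if (noise_rms < 0) stop_wmd("noise_rms must be >= 0")
  n <- round(duration_s * fs)
  x <- numeric(n)
  for (i in seq_along(sources)) {
    src <- sources[[i]]
    sub <- if (is.null(seed)) NULL else derive_seed(seed, src$seed_offset %||% i)
    spikes <- with_seed(sub, source_spike_times(src, duration_s))
    tpl <- src$amplitude_gain * src$template$samples
    for (t in spikes) {
      at <- round(t * fs) + 1L
      idx <- at:(at + length(tpl) - 1L)
      keep <- idx >= 1L & idx <= n
      x[idx[keep]] <- x[idx[keep]] + tpl[keep]
    }
  }
  if (noise_rms > 0) {
    nseed <- if (is.null(seed)) NULL else derive_seed(seed, 999983)
    x <- x + with_seed(nseed, band_limited_noise(n, fs, noise_rms, noise_drift))
  }
  emg_recording(x, fs, label = label, trial_id = trial_id,
                subject_id = subject_id)
}

#' Generate a labeled synthetic sEMG dataset
#'
#' Emulates the recording protocol the analysis expects: four finger-flexion
#' classes, each flexion held for several seconds and repeated a fixed number
#' of times, plus a background (rest) segment per subject for noise-template
#' estimation. Classes are encoded through volume conduction: the four
#' muscles share a MUAP shape but present geometrically spaced amplitudes at
#' the electrode; during a class-k flexion source k fires at the active rate
#' while the other sources tick along at a low background rate.
#'
#' @param n_classes number of flexion classes (default 4).
#' @param reps repetitions per class (default 12).
#' @param flexion_s flexion duration in seconds (default 7.5).
#' @param fs sampling rate, samples/s (default 1024).
#' @param amplitude_gains per-class gains, strictly distinct; default
#'   geometric spacing with ratio 1.5.
#' @param noise_rms additive-noise RMS (default 0.3, relative to the
#'   unit-gain MUAP peak of 1).
#' @param active_rate,background_rate firing rates (pulses/s) of the active
#'   and the non-active sources.
#' @param jitter_cv inter-pulse-interval coefficient of variation.
#' @param background_s duration of the rest recording (default 10 s).
#' @param noise_drift slow noise-level modulation passed to
#'   [simulate_recording()].
#' @param subject_id subject identifier.
#' @param seed master seed; per-trial sub-seeds are derived by counter.
#' @return object of class `wmd_dataset`: list with `recordings` (list of
#'   [emg_recording()]), `class_names`, `amplitude_gains`, `fs`, `seed`.
#' @export
generate_dataset <- function(n_classes = 4, reps = 12, flexion_s = 7.5,
                             fs = 1024,
                             amplitude_gains = 1.5^(seq_len(n_classes) - 1),
                             noise_rms = 0.3, active_rate = 18,
                             background_rate = 5, jitter_cv = 0.15,
                             background_s = 10, noise_drift = 0,
                             subject_id = "S1", seed = 1L) {
  if (length(amplitude_gains) != n_classes) {
    stop_wmd("amplitude_gains must have one entry per class")
  }
  if (anyDuplicated(amplitude_gains)) {
    stop_wmd("amplitude_gains must be distinct (equal gains make classes indistinguishable)")
  }
  tpl <- make_muap_template(10, 2, fs)
  class_names <- paste0("class", seq_len(n_classes))
  recordings <- vector("list", n_classes * reps + 1L)
  counter <- 0L
  for (k in seq_len(n_classes)) {
    for (r in seq_len(reps)) {
      counter <- counter + 1L
      sources <- lapply(seq_len(n_classes), function(j) {
        muscle_source(
          amplitude_gains[j],
          firing_rate = if (j == k) active_rate else background_rate,
          jitter_cv = jitter_cv, template = tpl, seed_offset = j
        )
      })
      recordings[[counter]] <- simulate_recording(
        sources, active_index = k, duration_s = flexion_s, fs = fs,
        noise_rms = noise_rms, seed = derive_seed(seed, counter * 131),
        noise_drift = noise_drift, label = class_names[k], trial_id = r,
        subject_id = subject_id
      )
    }
  }
  # rest segment: muscles electrically silent, so the recording captures the
  # additive noise process alone — this is what the noise template estimates
  rest_sources <- lapply(seq_len(n_classes), function(j) {
    muscle_source(amplitude_gains[j], firing_rate = 0,
                  jitter_cv = jitter_cv, template = tpl, seed_offset = j)
  })
  recordings[[counter + 1L]] <- simulate_recording(
    rest_sources, active_index = 1L, duration_s = background_s, fs = fs,
    noise_rms = noise_rms, seed = derive_seed(seed, 900001),
    noise_drift = noise_drift, label = "background", trial_id = 1L,
    subject_id = subject_id
  )
  structure(
    list(recordings = recordings, class_names = class_names,
         amplitude_gains = amplitude_gains, fs = fs, seed = seed),
    class = "wmd_dataset"
  )
}

#' @export
print.wmd_dataset <- function(x, ...) {
  labs <- vapply(x$recordings, function(r) r$label, character(1))
  cat(sprintf("<wmd_dataset> %d recordings @ %g Hz (seed %d)\n",
              length(x$recordings), x$fs, x$seed))
  print(table(labs))
  invisible(x)
}
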