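# End-to-end pipeline: noise-template estimation, preprocessing, maxima
# detection, feature extraction, classification and evaluation, driven by a
# single validated configuration object.

#' Pipeline configuration
#'
#' Collects every tunable of the WMD pipeline with its default. Unknown
#' fields are rejected so typos cannot silently fall back to defaults.
#'
#' @param fs sampling rate, samples/s.
#' @param filter bandpass [filter_spec()].
#' @param stft_window_len,stft_overlap spectral-subtraction analysis window
#'   (samples) and fractional overlap.
#' @param oversubtraction_alpha spectral over-subtraction factor.
#' @param n_scales,signed_maxima wavelet depth and maxima polarity mode.
#' @param window [window_spec()] for feature windows.
#' @param k clusters per window.
#' @param c1,c2,eps twin-SVM hyperparameters.
#' @param eval_mode,n_train,n_test,n_folds,n_repetitions evaluation protocol.
#' @param granularity `"window"` or `"flexion"` feature rows.
#' @param global_clusters cluster all maxima of a flexion once and count
#'   per-window densities against the shared centroids (default TRUE; see
#'   [wmd_features()]), instead of clustering each window independently.
#' @param seed master seed for the evaluation splits.
#' @return validated list of class `wmd_config`.
#' @export
wmd_config <- function(fs = 1024, filter = filter_spec(),
                       stft_window_len = 64, stft_overlap = 0.5,
                       oversubtraction_alpha = 1,
                       n_scales = 4, signed_maxima = FALSE,
                       window = window_spec(), k = 4,
                       c1 = 1, c2 = 1, eps = 1e-6,
                       eval_mode = "subsample", n_train = 100, n_test = 30,
                       n_folds = 10, n_repetitions = 10,
                       granularity = "window", global_clusters = TRUE,
                       seed = 1L) {
  stopifnot(inherits(filter, "filter_spec"), inherits(window, "window_spec"))
  if (fs <= 2 * filter$high_hz) {
    stop_wmd("fs must exceed twice the bandpass high edge")
  }
  if (!eval_mode %in% c("subsample", "kfold")) {
    stop_wmd("eval_mode must be 'subsample' or 'kfold'")
  }
  if (!granularity %in% c("window", "flexion")) {
    stop_wmd("granularity must be 'window' or 'flexion'")
  }
  structure(
    list(fs = fs, filter = filter, stft_window_len = stft_window_len,
         stft_overlap = stft_overlap,
         oversubtraction_alpha = oversubtraction_alpha,
         n_scales = n_scales, signed_maxima = signed_maxima,
         window = window, k = k, c1 = c1, c2 = c2, eps = eps,
         eval_mode = eval_mode, n_train = n_train, n_test = n_test,
         n_folds = n_folds, n_repetitions = n_repetitions,
         granularity = granularity, global_clusters = global_clusters,
         seed = as.integer(seed)),
    class = "wmd_config"
  )
}

#' Extract WMD features from a whole dataset
#'
#' Estimates the per-subject noise template from the background recordings,
#' preprocesses every flexion recording (bandpass, spectral subtraction,
#' session-level RMS normalization with the class-1 scale), detects
#' persistent maxima and emits the labeled feature table.
#'
#' @param dataset a `wmd_dataset` ([generate_dataset()] or [read_dataset()]).
#' @param config a [wmd_config()].
#' @param verbose print per-stage counts.
#' @return data.frame of labeled feature rows (see [wmd_features()]).
#' @export
wmd_pipeline_features <- function(dataset, config = wmd_config(),
                                  verbose = FALSE) {
  recs <- dataset$recordings
  labels <- vapply(recs, function(r) r$label, character(1))
  subjects <- vapply(recs, function(r) r$subject_id, character(1))

  rows <- list()
  for (subj in unique(subjects)) {
    mine <- recs[subjects == subj]
    mine_labels <- labels[subjects == subj]
    bg <- mine[mine_labels == "background"]
    if (length(bg) == 0) {
      stop_wmd("noise-template stage: subject %s has no background recording",
               subj)
    }
    bg_samples <- unlist(lapply(bg, function(r) r$samples))
    template <- estimate_noise_template(bg_samples, fs = config$fs,
                                        window_len = config$stft_window_len,
                                        overlap = config$stft_overlap,
                                        filter = config$filter)

    flex <- mine[mine_labels != "background"]
    cleaned <- lapply(flex, function(r) {
      y <- bandpass(r, spec = config$filter)
      spectral_subtract(y, template, config$oversubtraction_alpha)
    })
    # one session-level normalization constant: RMS of the subject's class-1
    # recordings after denoising, applied to every class so relative
    # amplitudes (the volume-conduction signature) survive
    ref <- vapply(cleaned, function(r) r$label, character(1)) == "class1"
    if (!any(ref)) ref <- rep(TRUE, length(cleaned))
    scale <- rms(unlist(lapply(cleaned[ref], function(r) r$samples)))
    if (!is.finite(scale) || scale <= 0) {
      stop_wmd("normalization stage: degenerate session scale for %s", subj)
    }
    feats <- lapply(cleaned, function(r) {
      r <- rms_normalize(r, scale)
      wmd_features(r, spec = config$window, n_scales = config$n_scales,
                   signed = config$signed_maxima, k = config$k,
                   granularity = config$granularity,
                   global_clusters = config$global_clusters)
    })
    if (verbose) {
      n_rows <- sum(vapply(feats, nrow, integer(1)))
      message(sprintf("[%s] %d flexion recordings -> %d feature rows (template: %d windows)",
                      subj, length(flex), n_rows, template$n_windows_averaged))
    }
    rows <- c(rows, feats)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full WMD pipeline
#'
#' [wmd_pipeline_features()] followed by [wmd_evaluate()].
#'
#' @param dataset a `wmd_dataset`.
#' @param config a [wmd_config()].
#' @param verbose print per-stage counts.
#' @return list with `features` (the labeled table) and `report`
#'   (a `wmd_evaluation`).
#' @export
run_wmd_pipeline <- function(dataset, config = wmd_config(), verbose = FALSE) {
  features <- wmd_pipeline_features(dataset, config, verbose = verbose)
  report <- wmd_evaluate(features, mode = config$eval_mode,
                         n_repetitions = config$n_repetitions,
                         n_train = config$n_train, n_test = config$n_test,
                         n_folds = config$n_folds, c1 = config$c1,
                         c2 = config$c2, eps = config$eps,
                         seed = config$seed)
  list(features = features, report = report)
}
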