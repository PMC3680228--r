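# Plain-text interchange: recording CSVs (time_s, amplitude), a manifest
# describing a dataset directory, feature tables, and model JSON. Writes go
# through a temp-file-then-rename so a failed write leaves nothing partial.

write_atomic <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a recording to CSV
#'
#' Columns `time_s,amplitude`, '.' decimal separator, UTF-8.
#'
#' @param rec an [emg_recording()].
#' @param path output file.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = (seq_along(rec$samples) - 1) / rec$fs,
                   amplitude = rec$samples)
  write_atomic(function(p) utils::write.csv(df, p, row.names = FALSE), path)
}

#' Read a recording from CSV
#'
#' Expects a `time_s,amplitude` header, strictly monotone time and uniform
#' sampling; the rate is inferred from the median time step.
#'
#' @param path input file.
#' @param label,trial_id,subject_id metadata to attach (usually from the
#'   manifest).
#' @return an [emg_recording()].
#' @export
read_recording <- function(path, label = "background", trial_id = 1L,
                           subject_id = "S1") {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop_wmd("empty recording file: %s", path)
  if (!all(c("time_s", "amplitude") %in% names(df))) {
    stop_wmd("%s must have columns time_s, amplitude", path)
  }
  bad <- which(!is.finite(df$amplitude))
  if (length(bad)) {
    stop_wmd("non-finite amplitude at row %d of %s", bad[1], path)
  }
  if (nrow(df) > 1) {
    dt <- diff(df$time_s)
    if (any(dt <= 0)) stop_wmd("time_s is not strictly increasing in %s", path)
    med <- stats::median(dt)
    if (max(abs(dt - med)) > 1e-6 * med + 1e-12) {
      stop_wmd("non-uniform sampling in %s (max jitter %.3g of the median step)",
               path, max(abs(dt - med)) / med)
    }
    fs <- 1 / med
  } else {
    fs <- 1
  }
  emg_recording(df$amplitude, fs, label = label, trial_id = trial_id,
                subject_id = subject_id)
}

#' Write a dataset directory
#'
#' One CSV per recording plus a `manifest.csv` with columns
#' `file,subject_id,trial_id,label`.
#'
#' @param dataset a [generate_dataset()] result (or compatible list).
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$recordings), function(i) {
    rec <- dataset$recordings[[i]]
    fname <- sprintf("%s_%s_t%02d.csv", rec$subject_id, rec$label, rec$trial_id)
    write_recording(rec, file.path(dir, fname))
    data.frame(file = fname, subject_id = rec$subject_id,
               trial_id = rec$trial_id, label = rec$label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_atomic(function(p) utils::write.csv(manifest, p, row.names = FALSE),
               file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return list with `recordings`, `class_names`, `fs` (class `wmd_dataset`).
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop_wmd("no manifest.csv in %s", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(file.path(dir, manifest$file[i]),
                   label = manifest$label[i],
                   trial_id = manifest$trial_id[i],
                   subject_id = manifest$subject_id[i])
  })
  labs <- setdiff(sort(unique(manifest$label)), "background")
  structure(list(recordings = recordings, class_names = labs,
                 fs = recordings[[1]]$fs, seed = NA_integer_),
            class = "wmd_dataset")
}

#' Write / read a WMD feature table
#'
#' @param features data.frame from [wmd_features()] (rows from several
#'   recordings can be `rbind`-ed).
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  write_atomic(function(p) utils::write.csv(features, p, row.names = FALSE),
               path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a fitted twin SVM to JSON
#'
#' Stores per-class hyperplanes, penalties, standardization vectors, class
#' names and a format-version field; [read_tsvm_model()] restores a model
#' whose predictions equal the original's.
#'
#' @param model a [wmd_tsvm()] fit.
#' @param path JSON path.
#' @export
write_tsvm_model <- function(model, path) {
  payload <- list(
    format_version = 1L,
    class_names = model$class_names,
    scheme = model$scheme,
    center = model$center, scale = model$scale,
    c1 = model$c1, c2 = model$c2, eps = model$eps,
    n_features = model$n_features,
    feature_names = model$feature_names,
    n_train = model$n_train,
    models = lapply(model$models, function(m) list(
      plane_pos = list(w = m$plane_pos$w, b = m$plane_pos$b),
      plane_neg = list(w = m$plane_neg$w, b = m$plane_neg$b)
    ))
  )
  write_atomic(function(p) {
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA)
  }, path)
}

#' @rdname write_tsvm_model
#' @export
read_tsvm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format_version) || p$format_version != 1) {
    stop_wmd("unsupported model format version in %s", path)
  }
  models <- lapply(names(p$models), function(k) {
    m <- p$models[[k]]
    structure(list(
      plane_pos = list(w = as.numeric(m$plane_pos$w), b = m$plane_pos$b),
      plane_neg = list(w = as.numeric(m$plane_neg$w), b = m$plane_neg$b),
      c1 = p$c1, c2 = p$c2, eps = p$eps
    ), class = "tsvm_binary")
  })
  names(models) <- names(p$models)
  structure(
    list(models = models, class_names = p$class_names,
         scheme = p$scheme %||% "ovr",
         center = as.numeric(p$center), scale = as.numeric(p$scale),
         c1 = p$c1, c2 = p$c2, eps = p$eps, n_features = p$n_features,
         feature_names = p$feature_names, n_train = p$n_train),
    class = "wmd_tsvm"
  )
}
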