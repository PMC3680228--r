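# Evaluation harness: repeated stratified random sub-sampling (100 train /
# 30 test by default) and stratified k-fold cross-validation, reporting
# per-class accuracy (one-vs-rest recall), sensitivity and specificity as
# mean +/- SD over repetitions.

# Split n_total points over classes as evenly as integer division allows,
# with the remainder going to the lower class indices.
stratified_counts <- function(n_total, n_classes) {
  base <- n_total %/% n_classes
  extra <- n_total %% n_classes
  base + as.integer(seq_len(n_classes) <= extra)
}

#' Stratified random sub-sampling split
#'
#' Draws disjoint train and test sets, stratified by class as evenly as
#' integer division allows (remainders assigned to the lower class index).
#'
#' @param y class labels.
#' @param n_train,n_test total train/test sizes (default 100/30).
#' @param seed integer seed; same seed gives an identical split.
#' @return list with integer index vectors `train` and `test` (disjoint).
#' @export
random_subsample_split <- function(y, n_train = 100, n_test = 30, seed = NULL) {
  y <- as.character(y)
  classes <- sort(unique(y))
  K <- length(classes)
  tr_counts <- stratified_counts(n_train, K)
  te_counts <- stratified_counts(n_test, K)
  avail <- table(factor(y, levels = classes))
  need <- tr_counts + te_counts
  if (any(avail < need)) {
    short <- which(avail < need)
    stop_wmd("insufficient data: class %s has %d points but %d are required",
             classes[short[1]], avail[short[1]], need[short[1]])
  }
  with_seed(seed, {
    train <- integer(0); test <- integer(0)
    for (k in seq_len(K)) {
      idx <- sample(which(y == classes[k]))
      train <- c(train, idx[seq_len(tr_counts[k])])
      test <- c(test, idx[tr_counts[k] + seq_len(te_counts[k])])
    }
    list(train = sort(train), test = sort(test))
  })
}

#' Confusion matrix
#'
#' @param true,pred label vectors of equal length.
#' @param classes class order (default: sorted union).
#' @return integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, pred, classes = NULL) {
  classes <- classes %||% sort(unique(c(true, pred)))
  table(factor(true, levels = classes), factor(pred, levels = classes))
}

#' Per-class sensitivity and specificity
#'
#' One-vs-rest: sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
#' both in percent. A class absent from the test set has undefined
#' sensitivity, reported as `NA` rather than 0.
#'
#' @param cm confusion matrix (rows = true, columns = predicted).
#' @param class_k class name or index.
#' @return named numeric vector `c(sensitivity, specificity)` in percent.
#' @export
confusion_metrics <- function(cm, class_k) {
  cm <- as.matrix(cm)
  k <- if (is.character(class_k)) match(class_k, rownames(cm)) else class_k
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  sens <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  c(sensitivity = sens, specificity = spec)
}

eval_one_round <- function(X, y, train, test, c1, c2, eps, classes) {
  fit <- wmd_tsvm(X[train, , drop = FALSE], y[train], c1 = c1, c2 = c2,
                  eps = eps)
  pred <- predict(fit, X[test, , drop = FALSE])
  cm <- confusion_matrix(y[test], pred, classes)
  mets <- t(vapply(classes, function(k) confusion_metrics(cm, k), numeric(2)))
  acc <- vapply(classes, function(k) {
    n_k <- sum(cm[k, ])
    if (n_k == 0) NA_real_ else 100 * cm[k, k] / n_k
  }, numeric(1))
  list(cm = cm, accuracy = acc, sensitivity = mets[, 1],
       specificity = mets[, 2],
       overall = 100 * sum(diag(cm)) / sum(cm))
}

#' Evaluate WMD features with the twin SVM
#'
#' Runs the classification protocol on a labeled feature table: either
#' repeated stratified random sub-sampling (default; 100 training and 30
#' test points per repetition) or stratified k-fold cross-validation.
#' Per-class accuracy is one-vs-rest recall of the round's confusion
#' matrix; sensitivity and specificity are the one-vs-rest rates. All
#' metrics are reported in percent as mean and SD over rounds.
#'
#' @param features data.frame with a `label` column and `c*`/`d*` feature
#'   columns (see [wmd_features()]), or a plain matrix plus `y`.
#' @param y labels when `features` is a matrix.
#' @param mode `"subsample"` (default) or `"kfold"`.
#' @param n_repetitions sub-sampling repetitions (default 10).
#' @param n_train,n_test sub-sampling sizes (default 100/30).
#' @param n_folds folds for `"kfold"` (default 10).
#' @param c1,c2,eps twin-SVM hyperparameters.
#' @param seed integer seed for the splits.
#' @return object of class `wmd_evaluation`: per-class and overall
#'   accuracy/sensitivity/specificity means and SDs, the pooled confusion
#'   matrix, and the protocol settings.
#' @export
wmd_evaluate <- function(features, y = NULL,
                         mode = c("subsample", "kfold"),
                         n_repetitions = 10, n_train = 100, n_test = 30,
                         n_folds = 10, c1 = 1, c2 = 1, eps = 1e-6,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (is.data.frame(features) && "label" %in% names(features)) {
    X <- feature_matrix(features)
    y <- as.character(features$label)
  } else {
    X <- as.matrix(features)
    if (is.null(y)) stop_wmd("y is required when features has no label column")
    y <- as.character(y)
  }
  classes <- sort(unique(y))
  K <- length(classes)

  rounds <- if (mode == "subsample") {
    lapply(seq_len(n_repetitions), function(r) {
      sp <- random_subsample_split(y, n_train, n_test,
                                   seed = derive_seed(seed, r))
      eval_one_round(X, y, sp$train, sp$test, c1, c2, eps, classes)
    })
  } else {
    counts <- table(factor(y, levels = classes))
    if (any(counts < n_folds)) {
      short <- which(counts < n_folds)[1]
      stop_wmd("class %s has only %d points; use at most %d folds",
               classes[short], counts[short], counts[short])
    }
    folds <- with_seed(seed, {
      f <- integer(length(y))
      for (k in classes) {
        idx <- sample(which(y == k))
        f[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      f
    })
    lapply(seq_len(n_folds), function(fd) {
      eval_one_round(X, y, which(folds != fd), which(folds == fd),
                     c1, c2, eps, classes)
    })
  }

  agg <- function(field) {
    m <- do.call(rbind, lapply(rounds, `[[`, field))
    list(mean = colMeans(m, na.rm = TRUE),
         sd = apply(m, 2, stats::sd, na.rm = TRUE))
  }
  overall <- vapply(rounds, `[[`, numeric(1), "overall")
  pooled <- Reduce(`+`, lapply(rounds, function(r) unclass(r$cm)))

  structure(
    list(per_class_accuracy = agg("accuracy"),
         per_class_sensitivity = agg("sensitivity"),
         per_class_specificity = agg("specificity"),
         overall_mean = mean(overall), overall_sd = stats::sd(overall),
         pooled_confusion = pooled, class_names = classes,
         n_rounds = length(rounds), mode = mode, seed = seed,
         settings = list(n_train = n_train, n_test = n_test,
                         n_folds = n_folds, n_repetitions = n_repetitions,
                         c1 = c1, c2 = c2)),
    class = "wmd_evaluation"
  )
}

#' @export
print.wmd_evaluation <- function(x, ...) {
  cat(sprintf("WMD evaluation (%s, %d rounds, seed %d)\n",
              x$mode, x$n_rounds, x$seed))
  fmt <- function(a) sprintf("%.2f (+/- %.2f)", a$mean, a$sd)
  tab <- data.frame(
    class = x$class_names,
    `accuracy %` = fmt(x$per_class_accuracy),
    `sensitivity %` = fmt(x$per_class_sensitivity),
    `specificity %` = fmt(x$per_class_specificity),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  cat(sprintf("Overall accuracy: %.2f (+/- %.2f)%%\n",
              x$overall_mean, x$overall_sd))
  invisible(x)
}
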