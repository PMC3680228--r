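# Linear twin support vector machine. Each binary problem fits two
# nonparallel hyperplanes, one hugging each class, by solving a pair of
# small convex QPs; a point is assigned to the class whose plane it is
# closer to (normalized distance). The pair of duals are box-constrained
# QPs over the opposite class's multipliers, solved here by cyclic
# coordinate descent with clipping.

# min_a 1/2 a' M a - e' a  s.t. 0 <= a <= C.  M is PSD (a tiny relative
# ridge guards against round-off indefiniteness). Primal active-set method:
# solve the equality-constrained problem on the free variables, step to the
# first bound crossing, and release the worst KKT violator once the free
# set is optimal. Exact and robust on the small, often ill-conditioned
# duals that arise here; finite termination for strictly convex problems.
solve_box_qp <- function(M, C, tol = 1e-10, max_iter = NULL) {
  n <- nrow(M)
  if (is.null(max_iter)) max_iter <- 100L * n + 1000L
  ridge <- max(diag(M), 0) * 1e-12 + 1e-300
  a <- numeric(n)
  state <- rep(-1L, n)     # -1 at lower bound, 0 free, 1 at upper bound
  for (it in seq_len(max_iter)) {
    free <- which(state == 0L)
    moved <- FALSE
    if (length(free)) {
      up <- which(state == 1L)
      rhs <- rep(1, length(free))
      if (length(up)) {
        rhs <- rhs - drop(M[free, up, drop = FALSE] %*% rep(C, length(up)))
      }
      Mff <- M[free, free, drop = FALSE] + diag(ridge, length(free))
      target <- tryCatch(solve(Mff, rhs), error = function(e) NULL)
      if (is.null(target)) {
        g <- drop(M %*% a) - 1
        target <- a[free] - g[free] / pmax(diag(M)[free], ridge)
      }
      dir <- target - a[free]
      if (max(abs(dir)) > tol * (1 + C)) {
        tmax <- 1
        hit <- 0L
        hit_bound <- 0L
        for (j in seq_along(free)) {
          if (dir[j] < 0 && a[free[j]] + dir[j] < 0) {
            tj <- -a[free[j]] / dir[j]
            if (tj < tmax) { tmax <- tj; hit <- free[j]; hit_bound <- -1L }
          } else if (dir[j] > 0 && a[free[j]] + dir[j] > C) {
            tj <- (C - a[free[j]]) / dir[j]
            if (tj < tmax) { tmax <- tj; hit <- free[j]; hit_bound <- 1L }
          }
        }
        a[free] <- a[free] + tmax * dir
        if (hit > 0L) {
          a[hit] <- if (hit_bound == 1L) C else 0
          state[hit] <- hit_bound
        }
        moved <- TRUE
      }
    }
    if (!moved) {
      # free variables optimal: check bound multipliers, release the worst
      g <- drop(M %*% a) - 1
      scale <- max(1, max(abs(g)))
      viol <- (state == -1L & g < -tol * scale) |
        (state == 1L & g > tol * scale)
      if (!any(viol)) break
      cand <- which(viol)
      state[cand[which.max(abs(g[cand]))]] <- 0L
    }
  }
  pmin(pmax(a, 0), C)
}

#' Train one binary twin SVM
#'
#' Fits the plane pair for a positive/negative sample split. Plane 1 lies
#' close to the positive samples and at least unit (slack-softened) distance
#' from the negative samples; plane 2 is the mirrored problem. Primal
#' solutions are recovered from the box-constrained duals through the
#' regularized normal equations.
#'
#' @param X_pos,X_neg numeric matrices (rows = samples) of the two classes.
#' @param c1,c2 slack penalties (> 0) of the two problems.
#' @param eps Tikhonov ridge added to the normal-equation matrices when they
#'   are ill-conditioned (default 1e-6; applied with a warning if the
#'   unregularized matrix is rank-deficient).
#' @return object of class `tsvm_binary`: `plane_pos` and `plane_neg` (each
#'   `w`, `b`), penalties, and the dual objective values.
#' @export
tsvm_binary <- function(X_pos, X_neg, c1 = 1, c2 = 1, eps = 1e-6) {
  X_pos <- as.matrix(X_pos); X_neg <- as.matrix(X_neg)
  if (nrow(X_pos) < 1 || nrow(X_neg) < 1) {
    stop_wmd("each class needs at least one sample")
  }
  if (!all(is.finite(X_pos)) || !all(is.finite(X_neg))) {
    stop_wmd("features must be finite")
  }
  if (c1 <= 0 || c2 <= 0) stop_wmd("penalties c1, c2 must be > 0")
  H <- cbind(X_pos, 1)   # augmented positive-class matrix [A e]
  G <- cbind(X_neg, 1)   # augmented negative-class matrix [B e]

  plane1 <- tsvm_solve_pair(H, G, c1, eps, negate = TRUE)
  plane2 <- tsvm_solve_pair(G, H, c2, eps, negate = FALSE)

  structure(
    list(plane_pos = plane1$plane, plane_neg = plane2$plane,
         c1 = c1, c2 = c2, eps = eps,
         dual_objective = c(pos = plane1$objective, neg = plane2$objective)),
    class = "tsvm_binary"
  )
}

# Shared solver: own-class matrix Hm (plane should pass through these),
# other-class matrix Gm (unit-distance constraints). Dual:
#   max e'a - 1/2 a' Gm (Hm'Hm + eps I)^-1 Gm' a,  0 <= a <= C
# Primal recovery u = -+ (Hm'Hm + eps I)^-1 Gm' a.
tsvm_solve_pair <- function(Hm, Gm, C, eps, negate) {
  HtH <- crossprod(Hm)
  p <- ncol(HtH)
  if (rcond(HtH) < 1e-12) {
    if (eps <= 0) {
      stop_wmd("rank-deficient normal-equation matrix; set eps > 0")
    }
    warning("rank-deficient normal-equation matrix; applying Tikhonov eps = ",
            format(eps))
  }
  R <- solve(HtH + eps * diag(p))
  GR <- Gm %*% R
  M <- GR %*% t(Gm)
  M <- (M + t(M)) / 2
  a <- solve_box_qp(M, C)
  obj <- sum(a) - 0.5 * drop(crossprod(a, M %*% a))
  u <- drop(R %*% crossprod(Gm, a))
  if (negate) u <- -u
  d <- length(u) - 1L
  list(plane = list(w = u[seq_len(d)], b = u[d + 1L]), objective = obj)
}

plane_distance <- function(plane, X) {
  nw <- sqrt(sum(plane$w^2))
  if (nw == 0) stop_wmd("degenerate hyperplane with zero-norm weight vector")
  abs(as.matrix(X) %*% plane$w + plane$b) / nw
}

#' Predict with a binary twin SVM
#'
#' @param model a [tsvm_binary()] fit.
#' @param X matrix (rows = points) or single numeric vector.
#' @return data.frame `class` (`"pos"`/`"neg"`; ties go to `"pos"`),
#'   `dist_pos`, `dist_neg` (normalized plane distances).
#' @export
predict_tsvm_binary <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  dp <- plane_distance(model$plane_pos, X)
  dn <- plane_distance(model$plane_neg, X)
  data.frame(class = ifelse(dp <= dn, "pos", "neg"),
             dist_pos = as.numeric(dp), dist_neg = as.numeric(dn),
             stringsAsFactors = FALSE)
}

#' Multiclass linear twin support vector machine
#'
#' Assembles binary twin SVMs into a multiclass decision. The default
#' scheme is one-vs-one voting: one plane pair per unordered class pair,
#' prediction by majority vote with the pair decided by minimum normalized
#' plane distance; vote ties break by total distance, then class order.
#' A one-vs-rest scheme (`scheme = "ovr"`: one plane pair per class,
#' prediction by nearest own-class plane) is also provided, but note that
#' its own-plane constraint demands all remaining classes on one side of
#' the plane, which degenerates when a class lies between the others in
#' feature space — as the amplitude-ordered WMD classes do.
#'
#' The twin formulation solves two small QPs per pair instead of one large
#' one and makes no assumption that the classes share a distribution,
#' which keeps it usable on unbalanced training sets. Features are
#' standardized with training-split statistics (centroid magnitudes and
#' densities live on different scales).
#'
#' @param x numeric feature matrix (rows = samples), or a formula.
#' @param y class labels (factor or character), one per row.
#' @param c1,c2 slack penalties.
#' @param eps Tikhonov ridge.
#' @param scheme `"ovo"` (one-vs-one voting, default) or `"ovr"`
#'   (one-vs-rest, nearest own plane).
#' @param standardize z-score features with training statistics (default
#'   TRUE).
#' @param data,... formula-method arguments.
#' @return object of class `wmd_tsvm` with `models` (named list of
#'   [tsvm_binary()] fits), `class_names`, `center`, `scale`, `scheme`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' y <- rep(c("a", "b"), each = 20)
#' fit <- wmd_tsvm(x, y)
#' table(predict(fit, x), y)
#' @export
wmd_tsvm <- function(x, ...) UseMethod("wmd_tsvm")

#' @rdname wmd_tsvm
#' @export
wmd_tsvm.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- wmd_tsvm.default(X, y, ...)
  fit$formula <- x
  fit
}

#' @rdname wmd_tsvm
#' @export
wmd_tsvm.default <- function(x, y, c1 = 1, c2 = 1, eps = 1e-6,
                             scheme = c("ovo", "ovr"), standardize = TRUE,
                             ...) {
  scheme <- match.arg(scheme)
  X <- as.matrix(x)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop_wmd("x and y sizes disagree")
  class_names <- sort(unique(y))
  if (length(class_names) < 2) stop_wmd("need at least 2 classes")
  counts <- table(factor(y, levels = class_names))
  if (any(counts == 0)) {
    stop_wmd("classes with zero samples: %s",
             paste(names(counts)[counts == 0], collapse = ", "))
  }
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  } else {
    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  if (scheme == "ovo") {
    pairs <- utils::combn(class_names, 2, simplify = FALSE)
    models <- lapply(pairs, function(pr) {
      tsvm_binary(Xs[y == pr[1], , drop = FALSE],
                  Xs[y == pr[2], , drop = FALSE],
                  c1 = c1, c2 = c2, eps = eps)
    })
    names(models) <- vapply(pairs, paste, character(1), collapse = "|")
  } else {
    models <- lapply(class_names, function(k) {
      tsvm_binary(Xs[y == k, , drop = FALSE], Xs[y != k, , drop = FALSE],
                  c1 = c1, c2 = c2, eps = eps)
    })
    names(models) <- class_names
  }
  structure(
    list(models = models, class_names = class_names, scheme = scheme,
         center = center, scale = scale, c1 = c1, c2 = c2, eps = eps,
         n_features = ncol(X), feature_names = colnames(X),
         n_train = nrow(X)),
    class = "wmd_tsvm"
  )
}

#' Predict finger-flexion classes with a fitted twin SVM
#'
#' @param object a [wmd_tsvm()] fit.
#' @param newdata feature matrix or data.frame (feature columns of a WMD
#'   feature table are picked out automatically).
#' @param type `"class"` (default) or `"scores"` for the per-class
#'   normalized distances to each class's own plane.
#' @param ... unused.
#' @return character vector of classes, or a distance matrix.
#' @export
predict.wmd_tsvm <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata) &&
           any(grepl("^[cd][0-9]+$", names(newdata)))) {
    feature_matrix(newdata)
  } else {
    as.matrix(newdata)
  }
  if (is.null(dim(X)) || ncol(X) == 1 && object$n_features > 1) {
    X <- matrix(as.numeric(X), nrow = 1)
  }
  if (ncol(X) != object$n_features) {
    stop_wmd("newdata has %d features but the model was trained on %d",
             ncol(X), object$n_features)
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  cls <- object$class_names
  if ((object$scheme %||% "ovr") == "ovo") {
    votes <- matrix(0, nrow(Xs), length(cls), dimnames = list(NULL, cls))
    dist_sum <- matrix(0, nrow(Xs), length(cls), dimnames = list(NULL, cls))
    for (nm in names(object$models)) {
      pr <- strsplit(nm, "|", fixed = TRUE)[[1]]
      p <- predict_tsvm_binary(object$models[[nm]], Xs)
      win_pos <- p$class == "pos"
      votes[win_pos, pr[1]] <- votes[win_pos, pr[1]] + 1
      votes[!win_pos, pr[2]] <- votes[!win_pos, pr[2]] + 1
      dist_sum[, pr[1]] <- dist_sum[, pr[1]] + p$dist_pos
      dist_sum[, pr[2]] <- dist_sum[, pr[2]] + p$dist_neg
    }
    if (type == "scores") return(votes)
    # majority vote; ties by smaller accumulated distance, then class order
    apply_order <- function(i) {
      v <- votes[i, ]
      top <- which(v == max(v))
      if (length(top) > 1) top <- top[order(dist_sum[i, top])]
      cls[top[1]]
    }
    return(vapply(seq_len(nrow(Xs)), apply_order, character(1)))
  }
  D <- vapply(cls, function(k) {
    as.numeric(plane_distance(object$models[[k]]$plane_pos, Xs))
  }, numeric(nrow(Xs)))
  D <- matrix(D, nrow = nrow(Xs), dimnames = list(NULL, cls))
  if (type == "scores") return(D)
  cls[apply(D, 1, which.min)]
}

#' @export
print.wmd_tsvm <- function(x, ...) {
  cat(sprintf("Linear twin SVM (%s): %d classes (%s), %d features, %d training points\n",
              x$scheme %||% "ovr", length(x$class_names),
              paste(x$class_names, collapse = ", "),
              x$n_features, x$n_train))
  cat(sprintf("Penalties c1 = %g, c2 = %g; eps = %g\n", x$c1, x$c2, x$eps))
  invisible(x)
}

#' @export
coef.wmd_tsvm <- function(object, ...) {
  rows <- lapply(names(object$models), function(nm) {
    m <- object$models[[nm]]
    rbind(c(m$plane_pos$w, m$plane_pos$b), c(m$plane_neg$w, m$plane_neg$b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- as.vector(vapply(names(object$models), function(nm)
    paste0(nm, c(":pos", ":neg")), character(2)))
  colnames(out) <- c(object$feature_names %||%
                       paste0("x", seq_len(object$n_features)), "b")
  out
}

#' @export
summary.wmd_tsvm <- function(object, ...) {
  print(object)
  cat("\nHyperplanes (standardized feature space):\n")
  print(round(coef(object), 4))
  invisible(object)
}
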