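test_that("a separable singleton pair is classified by the nearest plane", {
  m <- suppressWarnings(
    tsvm_binary(matrix(c(1, 0), 1), matrix(c(-1, 0), 1), c1 = 1, c2 = 1))
  p <- predict_tsvm_binary(m, rbind(c(1, 0), c(-1, 0)))
  expect_equal(p$class, c("pos", "neg"))
})

test_that("the dual solver matches a generic convex-QP oracle", {
  skip_if_not_installed("pracma")
  worst_obj <- 0
  worst_plane <- 0
  for (rep in 1:10) {
    d <- with_seed_test(100 + rep, sample(2:8, 1))
    np <- with_seed_test(200 + rep, sample((d + 1):10, 1))
    nn <- with_seed_test(300 + rep, sample((d + 1):10, 1))
    A <- with_seed_test(400 + rep, matrix(rnorm(np * d), np))
    B <- with_seed_test(500 + rep, matrix(rnorm(nn * d, 1), nn))
    fit <- tsvm_binary(A, B, c1 = 1, c2 = 1, eps = 1e-6)
    H <- cbind(A, 1); G <- cbind(B, 1)
    for (pl in 1:2) {
      Hm <- if (pl == 1) H else G
      Gm <- if (pl == 1) G else H
      R <- solve(crossprod(Hm) + 1e-6 * diag(d + 1))
      M <- Gm %*% R %*% t(Gm); M <- (M + t(M)) / 2
      sol <- pracma::quadprog(M + 1e-9 * diag(nrow(M)), -rep(1, nrow(M)),
                              lb = rep(0, nrow(M)), ub = rep(1, nrow(M)))
      a_o <- sol$xmin
      obj_o <- sum(a_o) - 0.5 * drop(crossprod(a_o, M %*% a_o))
      u_o <- drop(R %*% crossprod(Gm, a_o)) * (if (pl == 1) -1 else 1)
      mine <- if (pl == 1) fit$plane_pos else fit$plane_neg
      worst_obj <- max(worst_obj,
                       abs(obj_o - unname(fit$dual_objective[pl])))
      worst_plane <- max(worst_plane,
                         max(abs(u_o - c(mine$w, mine$b))))
    }
  }
  expect_lt(worst_obj, 1e-5)
  expect_lt(worst_plane, 1e-4)
})

test_that("reflecting the data through the origin mirrors the planes", {
  A <- with_seed_test(7, matrix(rnorm(12), 6))
  B <- with_seed_test(8, matrix(rnorm(12, 2), 6))
  f1 <- tsvm_binary(A, B)
  f2 <- tsvm_binary(-A, -B)
  # the reflected plane {x: w'x + b = 0} maps to {-x}, i.e. (-w, b)
  expect_equal(f2$plane_pos$w, -f1$plane_pos$w, tolerance = 1e-7)
  expect_equal(f2$plane_pos$b, f1$plane_pos$b, tolerance = 1e-7)
  expect_equal(f2$plane_neg$w, -f1$plane_neg$w, tolerance = 1e-7)
  expect_equal(f2$plane_neg$b, f1$plane_neg$b, tolerance = 1e-7)
})

test_that("binary prediction uses normalized distances with pos tie-break", {
  m <- structure(list(
    plane_pos = list(w = c(1, 0), b = 0),     # plane x = 0
    plane_neg = list(w = c(1, 0), b = -4)     # plane x = 4
  ), class = "tsvm_binary")
  p <- predict_tsvm_binary(m, rbind(c(0, 3), c(4, 0), c(2, 1)))
  expect_equal(p$class, c("pos", "neg", "pos"))  # equidistant -> pos

  # rescaling (w, b) leaves distances unchanged
  m2 <- m; m2$plane_pos$w <- 2 * m$plane_pos$w; m2$plane_pos$b <- 0
  expect_equal(predict_tsvm_binary(m2, c(3, 1))$dist_pos,
               predict_tsvm_binary(m, c(3, 1))$dist_pos)

  bad <- m; bad$plane_pos$w <- c(0, 0)
  expect_error(predict_tsvm_binary(bad, c(1, 1)), "zero-norm")
})

test_that("multiclass training separates well-separated clusters exactly", {
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(with_seed_test(10 + k, matrix(rnorm(40, sd = 0.4), 20)),
          2, centers[k, ], `+`)))
  y <- rep(paste0("class", 1:4), each = 20)
  fit <- wmd_tsvm(X, y)
  expect_equal(mean(predict(fit, X) == y), 1)

  # determinism and permutation invariance of the decision function
  fit2 <- wmd_tsvm(X, y)
  expect_equal(coef(fit), coef(fit2))
  perm <- with_seed_test(30, sample(nrow(X)))
  fit3 <- wmd_tsvm(X[perm, ], y[perm])
  grid <- with_seed_test(31, matrix(rnorm(40), 20))
  expect_equal(predict(fit, grid), predict(fit3, grid))

  expect_error(wmd_tsvm(X, rep("a", nrow(X))), "2 classes")
  expect_error(predict(fit, matrix(rnorm(10), 2)), "features")
})

test_that("the formula interface and both multiclass schemes work", {
  df <- data.frame(
    a = c(rnorm(15, 0), rnorm(15, 5)),
    b = c(rnorm(15, 0), rnorm(15, 5)),
    label = rep(c("x", "y"), each = 15)
  )
  f_form <- wmd_tsvm(label ~ a + b, data = df)
  expect_s3_class(f_form, "wmd_tsvm")
  expect_equal(mean(predict(f_form, as.matrix(df[, 1:2])) == df$label), 1)

  f_ovr <- wmd_tsvm(as.matrix(df[, 1:2]), df$label, scheme = "ovr")
  expect_equal(f_ovr$scheme, "ovr")
  expect_equal(mean(predict(f_ovr, as.matrix(df[, 1:2])) == df$label), 1)

  sc <- predict(f_form, as.matrix(df[, 1:2]), type = "scores")
  expect_equal(dim(sc), c(30, 2))
})

test_that("large penalties drive separable training error to zero", {
  X <- rbind(with_seed_test(41, matrix(rnorm(30, 0, 0.5), 15)),
             with_seed_test(42, matrix(rnorm(30, 5, 0.5), 15)))
  y <- rep(c("p", "q"), each = 15)
  fit <- wmd_tsvm(X, y, c1 = 100, c2 = 100)
  expect_equal(mean(predict(fit, X) == y), 1)
})

test_that("the twin SVM holds up on 10:1 imbalanced classes", {
  maj <- with_seed_test(51, matrix(rnorm(400, 0, 1), 200))
  mnr <- with_seed_test(52, matrix(rnorm(40, 3, 1), 20))
  X <- rbind(maj, mnr)
  y <- c(rep("maj", 200), rep("min", 20))
  te_maj <- with_seed_test(53, matrix(rnorm(200, 0, 1), 100))
  te_min <- with_seed_test(54, matrix(rnorm(200, 3, 1), 100))

  fit <- wmd_tsvm(X, y)
  tsvm_min_acc <- mean(predict(fit, te_min) == "min")

  # nearest-centroid baseline on the same data
  cm_maj <- colMeans(maj); cm_min <- colMeans(mnr)
  nc <- function(M) ifelse(
    sqrt(rowSums(sweep(M, 2, cm_min)^2)) < sqrt(rowSums(sweep(M, 2, cm_maj)^2)),
    "min", "maj")
  expect_gte(tsvm_min_acc, mean(nc(te_min) == "min"))
})
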