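test_that("the undecimated decomposition is linear and position-aligned", {
  z <- swt_decompose(numeric(2048), 4)
  expect_true(all(vapply(z$details, function(d) all(d == 0), logical(1))))
  expect_length(z$details[[1]], 2048)

  x <- with_seed_test(1, rnorm(2048))
  d1 <- swt_decompose(x, 3)
  d2 <- swt_decompose(3 * x, 3)
  for (j in 1:3) expect_equal(d2$details[[j]], 3 * d1$details[[j]],
                              tolerance = 1e-9)

  y <- with_seed_test(2, rnorm(2048))
  ds <- swt_decompose(x + y, 3)
  for (j in 1:3) {
    expect_equal(ds$details[[j]],
                 d1$details[[j]] + swt_decompose(y, 3)$details[[j]],
                 tolerance = 1e-9)
  }

  expect_error(swt_decompose(rnorm(64), 4), "maximum feasible depth")
  expect_error(swt_decompose(rnorm(2048), 1), "n_scales")
})

test_that("an impulse reproduces the analysis filter at the finest scale", {
  n <- 1024
  x <- numeric(n); x[500] <- 1
  d <- swt_decompose(x, 2)
  # independent direct-summation oracle: centered convolution of the
  # impulse with the level-1 high-pass filter lays the filter taps out
  # around the impulse position
  hi <- sqrt(2) / 8 * c(0, 0, -2, 6, -6, 2, 0, 0)
  expected <- numeric(n)
  shift <- (length(hi) - 1L) %/% 2L
  for (j in seq_along(hi)) {
    pos <- 500 - shift + (j - 1L)
    if (pos >= 1 && pos <= n) expected[pos] <- expected[pos] + hi[j]
  }
  expect_equal(d$details[[1]], expected, tolerance = 1e-10)
})

test_that("strict interior modulus maxima match the exhaustive-scan oracle", {
  # spec'd hand cases
  m <- find_local_maxima(c(0, 1, 0, -2, 0))
  expect_equal(m$position, c(2, 4))
  expect_equal(m$magnitude, c(1, 2))

  expect_equal(nrow(find_local_maxima(c(0, 1, 1, 0))), 0)   # plateau
  expect_equal(nrow(find_local_maxima(1:10)), 0)            # monotone ramp
  expect_equal(nrow(find_local_maxima(c(5, 1))), 0)         # too short

  # signed mode keeps only signed peaks
  s <- find_local_maxima(c(0, 1, 0, -2, 0), signed = TRUE)
  expect_equal(s$position, 2)

  # randomized equivalence with an independent O(N) scan
  for (r in 1:200) {
    v <- with_seed_test(1000 + r, rnorm(512))
    got <- find_local_maxima(v)
    want <- brute_maxima(v)
    expect_identical(got$position, want$position)
    expect_equal(got$magnitude, want$magnitude)
  }
})

test_that("cross-scale linking keeps complete chains only", {
  # a single impulse gives exactly one chain with small drift
  x <- numeric(2048); x[1000] <- 1
  pm <- persistent_maxima(x, 4)
  expect_equal(nrow(pm), 1)
  expect_lt(abs(pm$position - 1000), 8)

  # maxima at scale 1 only -> no chains
  per_scale <- list(
    data.frame(position = c(100, 200), magnitude = c(1, 2)),
    data.frame(position = numeric(0), magnitude = numeric(0)),
    data.frame(position = numeric(0), magnitude = numeric(0))
  )
  expect_equal(nrow(link_across_scales(per_scale)), 0)

  # two impulses far apart -> two chains
  y <- numeric(4096); y[1200] <- 1; y[2800] <- -1.5
  pm2 <- persistent_maxima(y, 4)
  expect_equal(nrow(pm2), 2)
  expect_lt(abs(pm2$position[1] - 1200), 8)
  expect_lt(abs(pm2$position[2] - 2800), 8)
  expect_equal(pm2$magnitude[2] / pm2$magnitude[1], 1.5, tolerance = 1e-6)
})

test_that("persistent maxima are linear in amplitude and empty for silence", {
  expect_equal(nrow(persistent_maxima(numeric(2048), 4)), 0)

  x <- with_seed_test(5, rnorm(4096))
  a <- persistent_maxima(x, 3)
  b <- persistent_maxima(2.5 * x, 3)
  expect_identical(a$position, b$position)
  expect_equal(b$magnitude, 2.5 * a$magnitude, tolerance = 1e-9)
})

test_that("persistence filters transients: noise chain rate well below scale-1 maxima rate", {
  nz <- with_seed_test(6, rnorm(8192))
  pm <- persistent_maxima(nz, 4)
  m1 <- find_local_maxima(swt_decompose(nz, 4)$details[[1]])
  expect_lt(nrow(pm), 0.5 * nrow(m1))
})

test_that("translation shifts chain positions by the same amount", {
  base <- with_seed_test(7, rnorm(4000))
  k <- 32
  shifted <- c(numeric(k), base)[1:4000]
  a <- persistent_maxima(base, 3)
  b <- persistent_maxima(shifted, 3)
  interior_a <- a$position[a$position > 300 & a$position < 3400]
  interior_b <- b$position[b$position > 300 + k & b$position < 3400 + k] - k
  expect_gt(length(intersect(interior_a, interior_b)) /
              length(interior_a), 0.95)
})

test_that("strong singularities in noise are all chained and dominate the ranking", {
  n <- 10240
  nz <- with_seed_test(10, rnorm(n))
  pos_true <- round(seq(600, n - 600, length.out = 10))
  sig <- numeric(n)
  sig[pos_true] <- 30            # well above the noise floor
  pm <- persistent_maxima(sig + nz, 4)

  # every event owns a chain near its position ...
  detected <- vapply(pos_true,
                     function(p) any(abs(pm$position - p) <= 16), logical(1))
  expect_true(all(detected))

  # ... and the 10 largest finest-scale magnitudes are exactly the events
  top10 <- pm[order(-pm$magnitude), ][1:10, ]
  hits <- vapply(top10$position,
                 function(p) min(abs(p - pos_true)) <= 16, logical(1))
  expect_true(all(hits))
})
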