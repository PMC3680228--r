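# Shared fixtures, built in code at test time.

# A reduced-size labeled dataset: same structure as the full protocol but
# shorter flexions and fewer repetitions, for fast pipeline tests.
small_dataset <- function(seed = 42, noise_rms = 0.3) {
  generate_dataset(reps = 3, flexion_s = 2.5, background_s = 6,
                   noise_rms = noise_rms, seed = seed)
}

# Band-limited Gaussian noise matching the simulator's amplifier band.
bl_noise <- function(n, fs = 1024, noise_rms = 1, seed = 1) {
  with_seed_test(seed, wmdemg:::band_limited_noise(n, fs, noise_rms))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Exhaustive-scan oracle for strict interior modulus maxima (independent of
# the package implementation).
brute_maxima <- function(coefs) {
  v <- abs(coefs)
  pos <- integer(0)
  for (n in 2:(length(v) - 1)) {
    if (v[n] > v[n - 1] && v[n] > v[n + 1] && v[n] > 0) pos <- c(pos, n)
  }
  data.frame(position = pos, magnitude = v[pos])
}

# Exhaustive contiguous-partition oracle for optimal 1-D k-clustering SSE.
brute_kmeans_sse <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    b <- c(0, splits[, j], n)
    sse <- 0
    for (m in seq_len(k)) {
      seg <- x[(b[m] + 1):(b[m + 1])]
      sse <- sse + sum((seg - mean(seg))^2)
    }
    best <- min(best, sse)
  }
  best
}
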