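# Undecimated (a trous) biorthogonal wavelet decomposition and modulus-maxima
# chaining. Positions stay sample-aligned across scales, so "a maximum that
# travels from the finest to the coarsest scale" is testable by position
# proximity; isolated single-scale maxima are rejected as random transients.

# bior3.3 decomposition filters, exact closed form.
bior33_dec_lo <- function() sqrt(2) / 64 * c(3, -9, -7, 45, 45, -7, -9, 3)
bior33_dec_hi <- function() sqrt(2) / 8 * c(0, 0, -2, 6, -6, 2, 0, 0)

# Insert 2^(level-1)-1 zeros between taps (a trous upsampling).
upsample_filter <- function(f, level) {
  if (level == 1) return(f)
  step <- 2^(level - 1)
  out <- numeric((length(f) - 1) * step + 1)
  out[seq(1, length(out), by = step)] <- f
  out
}

# Centered same-length convolution under symmetric (half-point) extension.
# Output sample i is the filter centered at input sample i, so features stay
# position-aligned across scales.
conv_sym_same <- function(x, f) {
  n <- length(x)
  L <- length(f)
  p <- min(L, n)
  ext <- c(x[p:1], x, x[n:(n - p + 1)])
  full <- stats::convolve(ext, rev(f), type = "open")
  shift <- p + (L - 1L) %/% 2L
  full[(shift + 1L):(shift + n)]
}

#' Undecimated bior3.3 wavelet decomposition
#'
#' Stationary (a trous) wavelet transform with the biorthogonal 3.3 analysis
#' filters. Detail coefficients are undecimated and position-aligned with
#' the input, which is what makes cross-scale tracking of maxima meaningful.
#'
#' @param x numeric signal (or [emg_recording()]).
#' @param n_scales decomposition depth, >= 2; scale 1 is the finest.
#' @return list of class `wmd_decomposition`: `details` (list of numeric
#'   vectors, one per scale, each the length of `x`), `approx` (coarsest
#'   smooth), `n_scales`, `filter_len` (support of the coarsest effective
#'   filter, used for boundary trimming).
#' @export
swt_decompose <- function(x, n_scales = 4) {
  v <- signal_vector(x)
  if (n_scales < 2) stop_wmd("n_scales must be >= 2")
  L0 <- length(bior33_dec_lo())
  max_depth <- max(1, floor(log2(length(v) / L0)))
  if (length(v) < 2^n_scales * L0) {
    stop_wmd("signal of %d samples is too short for %d scales (maximum feasible depth: %d)",
             length(v), n_scales, max_depth)
  }
  details <- vector("list", n_scales)
  a <- v
  for (j in seq_len(n_scales)) {
    hi <- upsample_filter(bior33_dec_hi(), j)
    lo <- upsample_filter(bior33_dec_lo(), j)
    details[[j]] <- conv_sym_same(a, hi)
    a <- conv_sym_same(a, lo)
  }
  structure(
    list(details = details, approx = a, n_scales = n_scales,
         filter_len = (L0 - 1L) * 2^(n_scales - 1L) + 1L),
    class = "wmd_decomposition"
  )
}

#' Local maxima of wavelet coefficients at one scale
#'
#' A position `n` (with `n` from 2 to N-1) is a maximum when its coefficient
#' is strictly greater than both neighbours. By default the strict-peak test
#' is applied to the modulus of the coefficients, so singularities of either
#' polarity are kept (MUAPs are biphasic); `signed = TRUE` applies it to the
#' signed coefficients instead. Endpoints are never returned and plateaus
#' fail the strict inequality.
#'
#' @param coefs numeric coefficient vector for one scale.
#' @param signed apply the peak test to signed coefficients (default FALSE:
#'   modulus maxima).
#' @param floor_rel peaks whose magnitude is below `floor_rel` times the
#'   largest coefficient modulus are dropped; this keeps the "magnitude > 0"
#'   requirement meaningful in floating point, where FFT-based convolution
#'   leaves a round-off ripple on coefficients that are analytically zero.
#' @return data.frame with `position` (sample index) and `magnitude`
#'   (modulus of the coefficient), positions ascending.
#' @export
find_local_maxima <- function(coefs, signed = FALSE, floor_rel = 1e-10) {
  v <- if (signed) coefs else abs(coefs)
  n <- length(v)
  if (n < 3) return(data.frame(position = integer(0), magnitude = numeric(0)))
  mid <- 2:(n - 1)
  hit <- v[mid] > v[mid - 1] & v[mid] > v[mid + 1]
  pos <- mid[hit]
  mag <- abs(coefs)[pos]
  keep <- mag > floor_rel * max(abs(coefs))
  data.frame(position = pos[keep], magnitude = mag[keep])
}

# Per-scale maxima for chaining: at scale j the strict-peak test is taken
# over a +/- 2^(j-1)-sample neighborhood instead of the immediate
# neighbours. The undecimated transform keeps positions comparable across
# scales, but its coarse-scale details retain high-frequency imaging from
# the short biorthogonal filters; widening the peak neighbourhood to the
# scale's own resolution restores the dyadic maxima density that makes
# cross-scale persistence reject random transients, without aliasing
# against a subsampling grid.
scale_grid_maxima <- function(coefs, scale_index, signed = FALSE,
                              floor_rel = 1e-10) {
  w <- 2^(scale_index - 1L)
  if (w == 1L) return(find_local_maxima(coefs, signed = signed,
                                        floor_rel = floor_rel))
  v <- if (signed) coefs else abs(coefs)
  n <- length(v)
  if (n < 2L * w + 1L) {
    return(data.frame(position = integer(0), magnitude = numeric(0)))
  }
  # neighbourhood max excluding the centre, via shifted pmax
  nb <- rep(-Inf, n)
  for (s in c(-(w:1), 1:w)) {
    shifted <- rep(-Inf, n)
    src <- seq_len(n) + s
    ok <- src >= 1L & src <= n
    shifted[ok] <- v[src[ok]]
    nb <- pmax(nb, shifted)
  }
  mid <- (w + 1L):(n - w)
  pos <- mid[v[mid] > nb[mid]]
  mag <- abs(coefs)[pos]
  keep <- mag > floor_rel * max(abs(coefs))
  data.frame(position = pos[keep], magnitude = mag[keep])
}

#' Link maxima across scales into persistent chains
#'
#' Greedy nearest-position matching from the finest scale outward: each
#' scale-1 maximum tries to find a partner at scale 2 within the linking
#' tolerance, that partner a match at scale 3, and so on. The tolerance
#' grows as `2^s` samples at scale `s`, mirroring the widening cone of
#' influence. Each maximum joins at most one chain; when two chains contend
#' for the same coarse maximum the one with the larger finest-scale
#' magnitude wins. Only complete chains — one member at every scale — are
#' returned; everything else is discarded as a random transient.
#'
#' @param per_scale list of [find_local_maxima()] data.frames, finest first.
#' @param tolerance function of the scale index giving the matching window
#'   in samples (default `function(s) 2^s`).
#' @return data.frame with one row per chain: `position` and `magnitude`
#'   (finest scale), plus `position_s<k>` for each coarser scale.
#' @export
link_across_scales <- function(per_scale, tolerance = function(s) 2^s) {
  n_scales <- length(per_scale)
  base <- per_scale[[1]]
  if (nrow(base) == 0 || n_scales < 2) {
    return(empty_chains(n_scales))
  }
  # process chains in order of decreasing finest magnitude so contention for
  # a shared coarse maximum is resolved toward the stronger event
  ord <- order(-base$magnitude)
  chains <- lapply(ord, function(i) list(
    positions = base$position[i], magnitude = base$magnitude[i], alive = TRUE
  ))
  for (s in 2:n_scales) {
    cand <- per_scale[[s]]
    used <- rep(FALSE, nrow(cand))
    tol <- tolerance(s - 1)
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      if (!ch$alive) next
      cur <- ch$positions[length(ch$positions)]
      if (nrow(cand) == 0) { chains[[ci]]$alive <- FALSE; next }
      d <- abs(cand$position - cur)
      d[used] <- Inf
      j <- which(d == min(d))
      if (length(j) > 1) j <- j[which.max(cand$magnitude[j])]
      if (length(j) == 0 || !is.finite(d[j]) || d[j] > tol) {
        chains[[ci]]$alive <- FALSE
      } else {
        used[j] <- TRUE
        chains[[ci]]$positions <- c(ch$positions, cand$position[j])
      }
    }
  }
  keep <- Filter(function(ch) ch$alive, chains)
  if (length(keep) == 0) return(empty_chains(n_scales))
  out <- data.frame(
    position = vapply(keep, function(ch) ch$positions[1], numeric(1)),
    magnitude = vapply(keep, function(ch) ch$magnitude, numeric(1))
  )
  for (s in 2:n_scales) {
    out[[paste0("position_s", s)]] <-
      vapply(keep, function(ch) ch$positions[s], numeric(1))
  }
  out[order(out$position), , drop = FALSE]
}

empty_chains <- function(n_scales) {
  out <- data.frame(position = numeric(0), magnitude = numeric(0))
  if (n_scales >= 2) {
    for (s in 2:n_scales) out[[paste0("position_s", s)]] <- numeric(0)
  }
  out
}

#' Persistent wavelet maxima of a signal
#'
#' Full singularity-detection chain: undecimated bior3.3 decomposition,
#' strict modulus maxima per scale (each scale examined on its natural
#' dyadic grid), greedy cross-scale linking, and boundary
#' trimming (chains whose finest-scale position falls within the coarsest
#' effective filter support of either end are discarded as edge artifacts).
#' Returns the finest-scale magnitude of each surviving maximum — the
#' quantity the feature extraction clusters.
#'
#' @param x numeric signal or [emg_recording()].
#' @param n_scales decomposition depth (default 4).
#' @param signed passed to [find_local_maxima()].
#' @param tolerance passed to [link_across_scales()].
#' @return data.frame `position`, `magnitude`, sorted by position.
#' @export
persistent_maxima <- function(x, n_scales = 4, signed = FALSE,
                              tolerance = function(s) 2^s) {
  v <- signal_vector(x)
  dec <- swt_decompose(v, n_scales)
  per_scale <- lapply(seq_len(n_scales), function(j) {
    scale_grid_maxima(dec$details[[j]], j, signed = signed)
  })
  chains <- link_across_scales(per_scale, tolerance)
  margin <- dec$filter_len
  keep <- chains$position > margin & chains$position <= length(v) - margin
  chains <- chains[keep, c("position", "magnitude"), drop = FALSE]
  rownames(chains) <- NULL
  chains
}
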