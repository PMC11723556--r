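#' Windowed trigonometric decomposition of concentration timeseries
#'
#' Splits each source's signal into (by default half-overlapping) segments,
#' applies the window weights, z-scores each windowed segment (mean
#' subtracted, divided by the population standard deviation, i.e. the 1/L
#' variance), and converts the DFT of the result into cosine/sine
#' coefficients: for normalized DFT coefficients `X[k]/L = u_k + j v_k`,
#' the trigonometric coefficients are `a_k = 2 u_k` (except `k = 0` and,
#' for even segment lengths, `k = L/2`, where `a_k = u_k`) and
#' `b_k = -2 v_k`, so that the z-scored segment is exactly
#' `sum_k a_k cos(2 pi k t / L) + b_k sin(2 pi k t / L)`.
#'
#' Population (1/L) normalization makes the per-harmonic correlation
#' components sum exactly to the Pearson correlation of the windowed,
#' z-scored segments. Trailing samples that do not fill a window are
#' dropped (no padding). Segments whose windowed values have zero variance
#' are degenerate: their coefficients are set to `NA` and they are excluded
#' from all downstream pooling, with a warning.
#'
#' @param series a [plume_series()] (or a plain samples x sources matrix,
#'   in which case `sample_rate` is taken to be 1 Hz).
#' @param window a [window_spec()].
#' @return An object of class `trig_coefficients`: a list with
#'   - `a`, `b`: arrays of dim (windows, sources, harmonics) holding the
#'     cosine and sine coefficients for harmonics `1..floor(L/2)`,
#'   - `segment_length`: L in samples, `fundamental_hz`: 1/window length,
#'   - `n_harmonics`: floor(L/2), `frequency_hz`: per-harmonic frequency,
#'   - `degenerate`: logical windows x sources matrix,
#'   - `window`, `sample_rate`, `positions`, `pitch` metadata.
#' @export
decompose <- function(series, window = window_spec()) {
  if (!inherits(series, "plume_series")) {
    series <- plume_series(series, sample_rate = 1,
                           positions = seq_len(ncol(as.matrix(series))))
  }
  fs <- series$sample_rate
  L <- round(window$length_s * fs)
  if (L < 4) stop("window length must be at least 4 samples")
  hop <- max(1L, round(L * (1 - window$overlap)))
  n_win <- floor((nrow(series$values) - L) / hop) + 1L
  if (n_win < 1L) stop("signal shorter than one window")
  w <- window_weights(window, L)
  H <- L %/% 2L
  n_src <- ncol(series$values)

  a <- array(NA_real_, dim = c(n_win, n_src, H))
  b <- array(NA_real_, dim = c(n_win, n_src, H))
  degenerate <- matrix(FALSE, n_win, n_src)

  for (s in seq_len(n_src)) {
    for (j in seq_len(n_win)) {
      seg <- series$values[(j - 1L) * hop + seq_len(L), s] * w
      mu <- mean(seg)
      sd_pop <- sqrt(mean((seg - mu)^2))
      if (sd_pop == 0) {
        degenerate[j, s] <- TRUE
        next
      }
      z <- (seg - mu) / sd_pop
      X <- stats::fft(z) / L
      k <- seq_len(H) + 1L              # DFT bins 1..H (0-based k = 1..H)
      ak <- 2 * Re(X[k])
      bk <- -2 * Im(X[k])
      if (L %% 2L == 0L) ak[H] <- Re(X[H + 1L])  # Nyquist term, weight 1
      a[j, s, ] <- ak
      b[j, s, ] <- bk
    }
  }
  if (any(degenerate))
    warning(sum(degenerate), " zero-variance segment(s) flagged degenerate",
            " and excluded from pooling")

  structure(
    list(a = a, b = b,
         segment_length = L,
         fundamental_hz = fs / L,
         n_harmonics = H,
         frequency_hz = seq_len(H) * fs / L,
         degenerate = degenerate,
         window = window,
         sample_rate = fs,
         positions = series$positions,
         pitch = series$pitch),
    class = "trig_coefficients")
}

#' @export
print.trig_coefficients <- function(x, ...) {
  cat(sprintf(
    "<trig_coefficients> %d windows x %d sources x %d harmonics (L = %d, fundamental %g Hz)\n",
    dim(x$a)[1], dim(x$a)[2], x$n_harmonics, x$segment_length,
    x$fundamental_hz))
  if (any(x$degenerate))
    cat(sprintf("  %d degenerate segment(s)\n", sum(x$degenerate)))
  invisible(x)
}

#' Reconstruct the z-scored windowed segment from its coefficients
#'
#' Inverse of the trigonometric conversion used by [decompose()]; intended
#' for checking the decomposition identity. The DC term is zero for
#' z-scored segments, so only harmonics `1..floor(L/2)` contribute.
#'
#' @param coeffs a `trig_coefficients` object.
#' @param window_index,source_index which segment to reconstruct.
#' @return numeric vector of length `segment_length`.
#' @export
reconstruct_segment <- function(coeffs, window_index, source_index) {
  L <- coeffs$segment_length
  t <- seq_len(L) - 1
  ak <- coeffs$a[window_index, source_index, ]
  bk <- coeffs$b[window_index, source_index, ]
  x <- numeric(L)
  for (k in seq_len(coeffs$n_harmonics)) {
    x <- x + ak[k] * cos(2 * pi * k * t / L) + bk[k] * sin(2 * pi * k * t / L)
  }
  x
}

#' Per-harmonic correlation components between two sources
#'
#' The contribution of harmonic n to the Pearson correlation of two
#' windowed, z-scored segments is `r_n = (a_n c_n + b_n d_n) / 2`, where
#' (a, b) are the cosine/sine coefficients of the first segment and (c, d)
#' of the second. For even segment lengths the Nyquist harmonic enters
#' with weight 1 instead of 1/2 (its cosine carries the full sample
#' energy), which keeps the sum over harmonics exactly equal to the
#' Pearson correlation.
#'
#' @param coeffs a `trig_coefficients` object.
#' @param i,j source indices (columns of the original series). `pairs` may
#'   be given instead as a 2-column matrix of (i, j) pairs.
#' @param pairs optional 2-column integer matrix of source pairs.
#' @return An object of class `harmonic_correlations`: list with `r`
#'   (windows x pairs x harmonics array; `NA` where either segment was
#'   degenerate), `pair_index`, and `frequency_hz`.
#' @export
harmonic_correlations <- function(coeffs, i = 1L, j = 2L, pairs = NULL) {
  stopifnot(inherits(coeffs, "trig_coefficients"))
  if (is.null(pairs)) pairs <- cbind(i, j)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  H <- coeffs$n_harmonics
  wt <- harmonic_weights(coeffs)
  n_win <- dim(coeffs$a)[1]
  r <- array(NA_real_, dim = c(n_win, nrow(pairs), H))
  for (p in seq_len(nrow(pairs))) {
    i_p <- pairs[p, 1]; j_p <- pairs[p, 2]
    rp <- (coeffs$a[, i_p, , drop = FALSE] * coeffs$a[, j_p, , drop = FALSE] +
           coeffs$b[, i_p, , drop = FALSE] * coeffs$b[, j_p, , drop = FALSE])
    rp <- matrix(rp, n_win, H) * rep(wt, each = n_win)
    bad <- coeffs$degenerate[, i_p] | coeffs$degenerate[, j_p]
    rp[bad, ] <- NA_real_
    r[, p, ] <- rp
  }
  structure(list(r = r, pair_index = pairs,
                 frequency_hz = coeffs$frequency_hz),
            class = "harmonic_correlations")
}

# Per-harmonic weights in r_n = w_n (a c + b d): 1/2 for interior
# harmonics, 1 at the Nyquist harmonic of an even-length segment.
harmonic_weights <- function(coeffs) {
  H <- coeffs$n_harmonics
  wt <- rep(0.5, H)
  if (coeffs$segment_length %% 2L == 0L) wt[H] <- 1
  wt
}

#' Recompose windowed Pearson correlations from harmonic components
#'
#' Sums the per-harmonic correlation components over harmonics, giving the
#' Pearson correlation of the windowed, z-scored segment pair in each
#' window.
#'
#' @param hc a `harmonic_correlations` object.
#' @return numeric matrix, windows x pairs.
#' @export
recompose <- function(hc) {
  stopifnot(inherits(hc, "harmonic_correlations"))
  apply(hc$r, c(1, 2), sum)
}
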