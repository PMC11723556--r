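#' Surrogate-dataset specification
#'
#' Describes a multisource surrogate dataset: signals whose per-harmonic
#' trigonometric coefficients are drawn from a zero-mean Gaussian with a
#' prescribed covariance kernel, so the distance decay of the coefficient
#' correlations — and hence the spatial information at each frequency —
#' is known by construction.
#'
#' Presets (distance is the source-index difference `|i - j|`):
#' \describe{
#'   \item{equal_informative}{`G(d) = 2 exp(-d/12) - 1` at every harmonic:
#'     all frequencies equally informative.}
#'   \item{high_gt_low}{`G(d, n) = exp(-d / R(n))` with `R(n) = 12` for
#'     harmonics in the lower half of the range and `R(n) = 2` in the
#'     upper half: correlations decay six times faster at high
#'     frequencies, making them more informative at small separations.}
#'   \item{custom}{user-supplied `G(d, n)` function.}
#' }
#' The per-harmonic power is `S(n) = P(n, alpha)` of [power_spectrum()]:
#' a 1/f-type spectrum with a 1 Hz cutoff (`alpha = 4` is plume-like,
#' `alpha = 0` white).
#'
#' @param M number of sources (>= 2).
#' @param n_harmonics number of positive harmonics `floor(L/2)` (>= 2);
#'   signals have `2 * n_harmonics + 1` samples.
#' @param fs nominal sample rate in Hz. The default, `2 * n_harmonics + 1`,
#'   places harmonic n at n Hz.
#' @param alpha power-law exponent (default 4).
#' @param kernel `"equal_informative"`, `"high_gt_low"`, or `"custom"`.
#' @param G for `kernel = "custom"`: function `G(d, n)` of index distance
#'   and harmonic.
#' @param n_realizations independent signal draws, standing in for time
#'   windows (default 2000).
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(M = 16, n_harmonics = 20, fs = 2 * n_harmonics + 1,
                           alpha = 4,
                           kernel = c("equal_informative", "high_gt_low",
                                      "custom"),
                           G = NULL, n_realizations = 2000) {
  kernel <- match.arg(kernel)
  stopifnot(M >= 2, n_harmonics >= 2, alpha >= 0, fs > 0,
            n_realizations >= 1)
  if (kernel == "custom" && !is.function(G))
    stop("custom kernel requires a function G(d, n)")
  structure(list(M = M, n_harmonics = n_harmonics, fs = fs, alpha = alpha,
                 kernel = kernel, G = G, n_realizations = n_realizations),
            class = "surrogate_spec")
}

#' @export
print.surrogate_spec <- function(x, ...) {
  cat(sprintf(
    "<surrogate_spec> %s: %d sources x %d harmonics, alpha = %g, %d realizations @ %g Hz\n",
    x$kernel, x$M, x$n_harmonics, x$alpha, x$n_realizations, x$fs))
  invisible(x)
}

#' Per-harmonic power with a 1 Hz cutoff
#'
#' `P(n, alpha) = max(n * fs / (2 H + 1), 1)^(-alpha)` where `H` is the
#' number of positive harmonics: power follows `1/f^alpha` above 1 Hz and
#' is flat at 1 below the cutoff.
#'
#' @param n harmonic index (>= 1); vectorized.
#' @param alpha power-law exponent.
#' @param n_harmonics number of positive harmonics H.
#' @param fs sample rate in Hz.
#' @return power values S(n).
#' @export
power_spectrum <- function(n, alpha, n_harmonics, fs = 2 * n_harmonics + 1) {
  stopifnot(all(n >= 1))
  pmax(n * fs / (2 * n_harmonics + 1), 1)^(-alpha)
}

# Correlation function G(d, n) for a spec.
kernel_G <- function(spec, d, n) {
  switch(spec$kernel,
    equal_informative = 2 * exp(-d / 12) - 1,
    high_gt_low = {
      R <- if (n < spec$n_harmonics / 2) 12 else 2
      exp(-d / R)
    },
    custom = spec$G(d, n))
}

#' Build the block-diagonal coefficient covariance kernel
#'
#' The kernel matrix has one `M x M` block per harmonic (coefficients at
#' different harmonics are uncorrelated, so cross-harmonic blocks are
#' exactly zero); block `n` has entries `k(i, j, n) = S(n) G(|i - j|, n)`.
#' Each block must be positive semidefinite; numerically indefinite
#' blocks are repaired with an escalating diagonal jitter
#' (`1e-10 * trace/dim`, escalated tenfold up to 3 times, never silently).
#'
#' @param spec a [surrogate_spec()].
#' @return An object of class `kernel_matrix`: list with `blocks` (list of
#'   M x M matrices per harmonic), `S` (per-harmonic power), `spec`,
#'   and `jitter` (per-harmonic jitter applied, 0 when none).
#' @export
build_kernel <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  M <- spec$M; H <- spec$n_harmonics
  S <- power_spectrum(seq_len(H), spec$alpha, H, spec$fs)
  d <- abs(outer(seq_len(M), seq_len(M), "-"))
  blocks <- vector("list", H)
  jitter <- numeric(H)
  for (n in seq_len(H)) {
    K <- S[n] * matrix(kernel_G(spec, d, n), M, M)
    ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8 * max(1, sum(diag(K)) / M)) {
      j <- 1e-10 * sum(diag(K)) / M
      for (esc in 1:3) {
        Kj <- K + diag(j, M)
        if (min(eigen(Kj, symmetric = TRUE,
                      only.values = TRUE)$values) >= 0) break
        j <- j * 10
      }
      Kj <- K + diag(j, M)
      if (min(eigen(Kj, symmetric = TRUE, only.values = TRUE)$values) < 0)
        stop(sprintf(
          "kernel block %d not positive semidefinite (min eigenvalue %.3e)",
          n, ev_min))
      warning(sprintf("kernel block %d jittered by %.3e", n, j))
      K <- Kj
      jitter[n] <- j
    }
    blocks[[n]] <- K
  }
  structure(list(blocks = blocks, S = S, spec = spec, jitter = jitter),
            class = "kernel_matrix")
}

#' Full kernel matrix
#'
#' Assembles the `M H x M H` block-diagonal matrix with block `n` at rows
#' and columns `M (n - 1) + (1..M)`.
#'
#' @param kernel a [build_kernel()] result.
#' @return symmetric numeric matrix.
#' @export
kernel_full_matrix <- function(kernel) {
  M <- kernel$spec$M; H <- kernel$spec$n_harmonics
  K <- matrix(0, M * H, M * H)
  for (n in seq_len(H)) {
    idx <- (n - 1L) * M + seq_len(M)
    K[idx, idx] <- kernel$blocks[[n]]
  }
  K
}

#' Sample surrogate signals and their generating coefficients
#'
#' Per realization and per harmonic block, draws independent standard
#' normal vectors `u` and `v` and sets the cosine coefficients to `L u`
#' and the sine coefficients to `L v`, where `K = L L^T` is the Cholesky
#' factor of the block (the sine and cosine sets are therefore i.i.d. and
#' mutually independent — the generator has zero out-of-phase
#' correlation by construction). Signals of length `2 H + 1` are
#' synthesized as
#' `x_m(t) = sum_n c_mn cos(pi n t / H) + s_mn sin(pi n t / H)`.
#'
#' @param spec a [surrogate_spec()].
#' @param seed RNG seed (all randomness in the draw).
#' @param kernel optionally a prebuilt [build_kernel()].
#' @return An object of class `surrogate_data`: list with
#'   - `coefficients`: list `a` (cosine), `b` (sine), each an array of dim
#'     (realizations, M, H) — the ground truth,
#'   - `series`: a [plume_series()] with realizations concatenated in time
#'     (sources at unit y-spacing, pitch 1 source index),
#'   - `kernel`, `spec`, `seed`.
#' @export
sample_signals <- function(spec, seed = 0, kernel = NULL) {
  stopifnot(inherits(spec, "surrogate_spec"))
  if (is.null(kernel)) kernel <- build_kernel(spec)
  set.seed(seed)
  M <- spec$M; H <- spec$n_harmonics; R <- spec$n_realizations
  Lt <- 2L * H + 1L

  a <- array(0, dim = c(R, M, H))
  b <- array(0, dim = c(R, M, H))
  for (n in seq_len(H)) {
    K <- kernel$blocks[[n]]
    Lchol <- chol_psd(K)
    if (all(K == 0)) {
      next  # zero kernel block: coefficients stay zero
    }
    a[, , n] <- matrix(stats::rnorm(R * M), R, M) %*% t(Lchol)
    b[, , n] <- matrix(stats::rnorm(R * M), R, M) %*% t(Lchol)
  }

  t_idx <- 0:(Lt - 1L)
  cosmat <- sapply(seq_len(H), function(n) cos(pi * n * t_idx / H))  # Lt x H
  sinmat <- sapply(seq_len(H), function(n) sin(pi * n * t_idx / H))
  values <- matrix(0, R * Lt, M)
  for (m in seq_len(M)) {
    # realizations concatenated along time: (R*Lt) vector per source
    xs <- cosmat %*% t(matrix(a[, m, ], R, H)) +
      sinmat %*% t(matrix(b[, m, ], R, H))   # Lt x R
    values[, m] <- as.vector(xs)
  }
  series <- plume_series(values, sample_rate = spec$fs,
                         positions = seq_len(M) - 1,
                         pitch = 1, label = paste0("surrogate:", spec$kernel))
  structure(list(coefficients = list(a = a, b = b), series = series,
                 kernel = kernel, spec = spec, seed = seed),
            class = "surrogate_data")
}

# Lower-triangular factor for a PSD matrix: Cholesky with pivot-free
# retry using escalating diagonal jitter (1e-10 trace/dim, x10, max 3).
chol_psd <- function(K) {
  if (all(K == 0)) return(K)
  j <- 0
  base <- 1e-10 * sum(diag(K)) / nrow(K)
  for (esc in 0:3) {
    out <- tryCatch(t(chol(K + diag(j, nrow(K)))), error = function(e) NULL)
    if (!is.null(out)) return(out)
    j <- if (j == 0) base else j * 10
  }
  stop("Cholesky failed after jitter escalation")
}

#' @export
print.surrogate_data <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  seed %d; series: %d samples x %d sources\n", x$seed,
              nrow(x$series$values), ncol(x$series$values)))
  invisible(x)
}

#' Treat surrogate ground-truth coefficients as a decomposition result
#'
#' Wraps the generating coefficients of [sample_signals()] into a
#' `trig_coefficients` object (realizations as windows) so they can be fed
#' directly into [pair_stats()] and the Fisher pipeline. Separations are
#' in source-index units.
#'
#' @param surr a `surrogate_data` object.
#' @return a `trig_coefficients` object.
#' @export
surrogate_coefficients <- function(surr) {
  stopifnot(inherits(surr, "surrogate_data"))
  spec <- surr$spec
  R <- spec$n_realizations
  structure(
    list(a = surr$coefficients$a, b = surr$coefficients$b,
         segment_length = 2L * spec$n_harmonics + 1L,
         fundamental_hz = spec$fs / (2 * spec$n_harmonics + 1),
         n_harmonics = spec$n_harmonics,
         frequency_hz = seq_len(spec$n_harmonics) * spec$fs /
           (2 * spec$n_harmonics + 1),
         degenerate = matrix(FALSE, R, spec$M),
         window = window_spec(length_s = (2 * spec$n_harmonics + 1) / spec$fs,
                              shape = "boxcar", overlap = 0),
         sample_rate = spec$fs,
         positions = cbind(x = 0, y = seq_len(spec$M) - 1),
         pitch = 1),
    class = "trig_coefficients")
}
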