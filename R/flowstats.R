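#' Velocity transect for integral length-scale computation
#'
#' Velocity component timeseries at a reference point and at positive
#' displacements `r = n * dr` along one axis (and optionally at the
#' mirrored negative displacements). Column 1 of each matrix is the
#' reference series; column `n + 1` sits at displacement `n * dr`.
#'
#' @param u_plus time x displacement matrix toward positive displacement.
#' @param u_minus optional matching matrix toward negative displacement
#'   (one-sided transects are allowed, as at domain edges).
#' @param dr displacement step in metres (> 0); the conventional choice
#'   is 0.02 pitch.
#' @param axis `"y"` or `"x"` (metadata only).
#' @return An object of class `velocity_transect`.
#' @export
velocity_transect <- function(u_plus, u_minus = NULL, dr, axis = c("y", "x")) {
  axis <- match.arg(axis)
  u_plus <- as.matrix(u_plus)
  stopifnot(dr > 0, ncol(u_plus) >= 2)
  if (!is.null(u_minus)) {
    u_minus <- as.matrix(u_minus)
    stopifnot(nrow(u_minus) == nrow(u_plus))
  }
  if (stats::var(u_plus[, 1]) == 0)
    stop("reference series has zero variance")
  structure(list(u_plus = u_plus, u_minus = u_minus, dr = dr, axis = axis),
            class = "velocity_transect")
}

#' Normalized velocity autocorrelation function
#'
#' `Q+(r) = <u(t; p) u(t; p + r)>_t`, `Q-(r)` likewise toward negative
#' displacement; `Q(r)` averages the two (or uses whichever side exists).
#' The time mean is removed from each series before correlating, and the
#' function is normalized by its value at zero displacement, so
#' `f(0) = 1` and `f` is invariant to rescaling the velocities.
#'
#' @param transect a [velocity_transect()].
#' @return list with `r` (displacements) and `f` (normalized
#'   autocorrelation, `f[1] = 1`).
#' @export
velocity_autocorrelation <- function(transect) {
  stopifnot(inherits(transect, "velocity_transect"))
  one_side <- function(u) {
    u <- sweep(u, 2, colMeans(u))
    ref <- u[, 1]
    colMeans(u * ref)
  }
  qp <- one_side(transect$u_plus)
  if (!is.null(transect$u_minus)) {
    qm <- one_side(transect$u_minus)
    n <- max(length(qp), length(qm))
    q <- vapply(seq_len(n), function(k) {
      vals <- c(if (k <= length(qp)) qp[k], if (k <= length(qm)) qm[k])
      mean(vals)
    }, 0)
  } else {
    q <- qp
  }
  if (q[1] == 0) stop("zero variance at reference point")
  list(r = (seq_along(q) - 1) * transect$dr, f = q / q[1])
}

#' Integral length scale
#'
#' Rectangle-rule integral of the normalized autocorrelation function
#' over the available displacement range: `L_U = sum_n f(n dr) dr`.
#' Negative lobes of `f` are included by default; setting
#' `truncate_at_zero = TRUE` stops the sum at the first zero crossing.
#'
#' @param f normalized autocorrelation values at displacements
#'   `0, dr, 2 dr, ...` (or the list returned by
#'   [velocity_autocorrelation()]).
#' @param dr displacement step; taken from `f` when it is a list.
#' @param truncate_at_zero truncate at the first zero crossing
#'   (default FALSE).
#' @return the integral length scale (same units as `dr`).
#' @export
integral_length_scale <- function(f, dr = NULL, truncate_at_zero = FALSE) {
  if (is.list(f)) {
    if (is.null(dr)) dr <- f$r[2] - f$r[1]
    f <- f$f
  }
  stopifnot(!is.null(dr), dr > 0)
  if (truncate_at_zero) {
    zc <- which(f <= 0)
    if (length(zc)) f <- f[seq_len(zc[1] - 1)]
  }
  sum(f) * dr
}
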