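#' Group ordered source pairs by signed separation
#'
#' Sources are paired by the signed difference of their positions along
#' one axis, `d = y_i - y_j` (the convention used when sources lie on a
#' line transverse to the flow). Every ordered pair, including each source
#' paired with itself at separation 0, is assigned to exactly one signed
#' separation bin.
#'
#' @param positions sources x 2 matrix of (x, y) coordinates, or a numeric
#'   vector of scalar positions.
#' @param axis which coordinate carries the separation, `"y"` (default) or
#'   `"x"`; ignored when `positions` is a vector.
#' @param units `"metres"` (native units of `positions`) or `"pitch"`
#'   (positions divided by `pitch` before differencing).
#' @param pitch pitch in the same units as `positions`; required for
#'   `units = "pitch"`.
#' @param separations optional numeric vector restricting the separations
#'   returned; a requested separation with no pair yields an empty,
#'   flagged group.
#' @param tol matching tolerance when binning separations (default 1e-9).
#'
#' @return An object of class `pair_set`: list with `separations` (sorted
#'   signed values), `pairs_at` (list of 2-column ordered (i, j) matrices),
#'   `units`, and `tol`. `N_of(pairset, s, n_windows)` gives the pooled
#'   sample count 2 x windows x pairs.
#' @export
build_pairs <- function(positions, axis = c("y", "x"),
                        units = c("metres", "pitch"), pitch = NULL,
                        separations = NULL, tol = 1e-9) {
  units <- match.arg(units)
  axis <- match.arg(axis)
  if (is.null(dim(positions))) {
    pos <- as.numeric(positions)
  } else {
    pos <- positions[, if (axis == "y") 2L else 1L]
  }
  if (units == "pitch") {
    if (is.null(pitch)) stop("`pitch` required for pitch units")
    pos <- pos / pitch
  }
  n <- length(pos)
  if (n < 2L) stop("need at least 2 sources")
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  d <- pos[grid$i] - pos[grid$j]
  # bin by tolerance: snap to the first representative within tol
  key <- round(d / tol)
  reps <- tapply(d, key, function(v) v[1])
  sep_all <- sort(unname(reps))
  if (is.null(separations)) {
    separations <- sep_all
  }
  pairs_at <- lapply(separations, function(s) {
    sel <- abs(d - s) <= tol
    cbind(i = grid$i[sel], j = grid$j[sel])
  })
  empty <- vapply(pairs_at, nrow, 0L) == 0L
  if (any(empty))
    warning("no source pair at separation(s): ",
            paste(signif(separations[empty], 6), collapse = ", "))
  structure(list(separations = separations, pairs_at = pairs_at,
                 units = units, tol = tol),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d signed separations (%s units)\n",
              length(x$separations), x$units))
  invisible(x)
}

#' Pooled sample count at a separation
#'
#' `N(s) = 2 x windows x ordered pairs at s`: the factor 2 counts the
#' concatenated sine and cosine coefficients.
#'
#' @param pairset a [build_pairs()] result.
#' @param s separation (matched within `pairset$tol`).
#' @param n_windows number of time windows per source.
#' @return integer count.
#' @export
N_of <- function(pairset, s, n_windows) {
  2L * n_windows * nrow(pairs_at(pairset, s))
}

pairs_at <- function(pairset, s) {
  k <- which(abs(pairset$separations - s) <= pairset$tol)
  if (length(k) != 1L) stop("separation not present in pair set: ", s)
  pairset$pairs_at[[k]]
}

#' Stack paired coefficients into a 2 x N(s) matrix
#'
#' Row 1 concatenates the harmonic-n cosine then sine coefficients over
#' all windows and all first sources of the ordered pairs at separation
#' `s`; row 2 holds the corresponding coefficients of the second sources.
#' Windows in which either source's segment is degenerate are dropped.
#'
#' @param coeffs a `trig_coefficients` object.
#' @param pairset a [build_pairs()] result.
#' @param n harmonic index (1-based, `1..n_harmonics`).
#' @param s signed separation present in `pairset`.
#' @return 2 x N(s) numeric matrix.
#' @export
stack_pairs <- function(coeffs, pairset, n, s) {
  stopifnot(inherits(coeffs, "trig_coefficients"))
  if (n < 1L || n > coeffs$n_harmonics) stop("harmonic out of range: ", n)
  pr <- pairs_at(pairset, s)
  row1 <- c(); row2 <- c()
  for (p in seq_len(nrow(pr))) {
    i <- pr[p, 1]; j <- pr[p, 2]
    ok <- !(coeffs$degenerate[, i] | coeffs$degenerate[, j])
    row1 <- c(row1, coeffs$a[ok, i, n], coeffs$b[ok, i, n])
    row2 <- c(row2, coeffs$a[ok, j, n], coeffs$b[ok, j, n])
  }
  rbind(row1, row2, deparse.level = 0)
}

#' Principal variances of paired coefficients
#'
#' Variances of the projections of the 2 x N data matrix onto the major
#' (`[1, 1]/sqrt(2)`) and minor (`[1, -1]/sqrt(2)`) axes. Second moments
#' are uncentred: stationarity makes the coefficients zero-mean, and
#' uncentred moments keep the principal-variance and product-moment
#' estimators of the coefficient correlation exactly equal.
#'
#' @param data 2 x N matrix from [stack_pairs()].
#' @return named numeric vector `c(lambda = , mu = )`.
#' @export
principal_variances <- function(data) {
  stopifnot(nrow(data) == 2L, ncol(data) >= 2L)
  c(lambda = mean(((data[1, ] + data[2, ]) / sqrt(2))^2),
    mu = mean(((data[1, ] - data[2, ]) / sqrt(2))^2))
}

#' Pooled marginal coefficient variance for one harmonic
#'
#' The distance-independent marginal variance `sigma_n^2` equals half the
#' major-axis variance of the self-paired data at separation 0, i.e. the
#' pooled uncentred second moment of all harmonic-n coefficients across
#' sources and windows.
#'
#' @param coeffs a `trig_coefficients` object.
#' @param n harmonic index.
#' @return scalar variance.
#' @export
sigma2_pooled <- function(coeffs, n) {
  stopifnot(inherits(coeffs, "trig_coefficients"))
  if (n < 1L || n > coeffs$n_harmonics) stop("harmonic out of range: ", n)
  ok <- !coeffs$degenerate
  mean(c(coeffs$a[, , n][ok], coeffs$b[, , n][ok])^2)
}

#' Coefficient coupling statistics at one harmonic and separation
#'
#' Estimates, from the pooled coefficient pairs, the in-phase correlation
#' `rho = <ac + bd> / (2 sigma^2)` (algebraically equal to
#' `(lambda - mu) / (2 sigma^2)`), the out-of-phase (quadrature)
#' correlation `rho_perp = <bc - ad> / (2 sigma^2)`, the coupling gain
#' `beta = sqrt(rho^2 + rho_perp^2)`, phase `theta = atan2(rho_perp, rho)`,
#' and residual variance `eta2 = sigma^2 (1 - beta^2)`.
#'
#' @param coeffs a `trig_coefficients` object.
#' @param pairset a [build_pairs()] result.
#' @param n harmonic index.
#' @param s signed separation.
#' @param sigma2 optional pooled variance; default [sigma2_pooled()].
#' @return one-row data.frame with the statistics and the pooled count.
#' @export
coupling_stats <- function(coeffs, pairset, n, s, sigma2 = NULL) {
  if (is.null(sigma2)) sigma2 <- sigma2_pooled(coeffs, n)
  if (sigma2 <= 0) stop("degenerate harmonic: sigma2 = 0")
  pr <- pairs_at(pairset, s)
  ac_bd <- 0; bc_ad <- 0; lam <- 0; mu <- 0; n_tot <- 0L
  for (p in seq_len(nrow(pr))) {
    i <- pr[p, 1]; j <- pr[p, 2]
    ok <- !(coeffs$degenerate[, i] | coeffs$degenerate[, j])
    a <- coeffs$a[ok, i, n]; b <- coeffs$b[ok, i, n]
    cc <- coeffs$a[ok, j, n]; d <- coeffs$b[ok, j, n]
    ac_bd <- ac_bd + sum(a * cc) + sum(b * d)
    bc_ad <- bc_ad + sum(b * cc) - sum(a * d)
    lam <- lam + sum((a + cc)^2) / 2 + sum((b + d)^2) / 2
    mu <- mu + sum((a - cc)^2) / 2 + sum((b - d)^2) / 2
    n_tot <- n_tot + 2L * sum(ok)
  }
  rho <- ac_bd / n_tot / sigma2
  rho_perp <- bc_ad / n_tot / sigma2
  beta <- sqrt(rho^2 + rho_perp^2)
  data.frame(harmonic = n, separation = s, sigma2 = sigma2,
             lambda = lam / n_tot, mu = mu / n_tot,
             rho = rho, rho_perp = rho_perp,
             beta = beta, theta = atan2(rho_perp, rho),
             eta2 = sigma2 * (1 - beta^2), n_samples = n_tot)
}

#' Coefficient statistics over all harmonics and separations
#'
#' Tidy table of the bivariate-Gaussian coefficient statistics for every
#' harmonic and every signed separation in the pair set. Equivalent to
#' looping [coupling_stats()], but computed through per-harmonic
#' cross-moment matrices so that large window counts stay cheap.
#'
#' @param coeffs a `trig_coefficients` object.
#' @param pairset a [build_pairs()] result; default: all signed
#'   separations of `coeffs$positions` in metres.
#' @param harmonics harmonic indices to include (default all).
#' @param window_index optional integer vector of windows to use (with
#'   repetitions allowed; used by the bootstrap).
#' @param clip_rho clip `rho` and `rho_perp` into \[-clip, clip\] before
#'   derived quantities; default 0.999 (guards 1 - rho^2 divisions
#'   downstream). Use `clip_rho = 1` for raw estimates.
#' @return data.frame with columns harmonic, frequency_hz, separation,
#'   sigma2, lambda, mu, rho, rho_perp, beta, theta, eta2, n_samples.
#' @export
pair_stats <- function(coeffs, pairset = NULL, harmonics = NULL,
                       window_index = NULL, clip_rho = 0.999) {
  stopifnot(inherits(coeffs, "trig_coefficients"))
  if (is.null(pairset)) pairset <- build_pairs(coeffs$positions)
  if (is.null(harmonics)) harmonics <- seq_len(coeffs$n_harmonics)
  wins <- if (is.null(window_index)) seq_len(dim(coeffs$a)[1]) else window_index
  n_src <- dim(coeffs$a)[2]
  any_degen <- any(coeffs$degenerate[wins, ])

  out <- vector("list", length(harmonics))
  for (h in seq_along(harmonics)) {
    n <- harmonics[h]
    if (!any_degen) {
      A <- coeffs$a[wins, , n, drop = FALSE]; dim(A) <- c(length(wins), n_src)
      B <- coeffs$b[wins, , n, drop = FALSE]; dim(B) <- c(length(wins), n_src)
      W <- length(wins)
      Cin <- (crossprod(A) + crossprod(B)) / W    # <a_i a_j + b_i b_j>
      Cout <- (crossprod(B, A) - crossprod(A, B)) / W  # <b_i a_j - a_i b_j>
      sig2 <- mean(diag(Cin)) / 2
      rows <- lapply(seq_along(pairset$separations), function(k) {
        pr <- pairset$pairs_at[[k]]
        if (nrow(pr) == 0L) return(NULL)
        idx <- cbind(pr[, 1], pr[, 2])
        sum_in <- mean(Cin[idx])     # <ac + bd> per pair, averaged
        sum_out <- mean(Cout[idx])   # <bc - ad>
        marg <- mean(diag(Cin)[pr[, 1]] + diag(Cin)[pr[, 2]]) / 4
        data.frame(harmonic = n, separation = pairset$separations[k],
                   sigma2 = sig2, lambda = marg + sum_in / 2,
                   mu = marg - sum_in / 2,
                   rho = sum_in / (2 * sig2),
                   rho_perp = sum_out / (2 * sig2),
                   n_samples = 2L * W * nrow(pr))
      })
      out[[h]] <- do.call(rbind, rows)
    } else {
      # degenerate segments present: fall back to the explicit pooled path
      sub <- subset_windows(coeffs, wins)
      rows <- lapply(pairset$separations, function(s) {
        if (nrow(pairs_at(pairset, s)) == 0L) return(NULL)
        cs <- coupling_stats(sub, pairset, n, s)
        cs[, c("harmonic", "separation", "sigma2", "lambda", "mu",
               "rho", "rho_perp", "n_samples")]
      })
      out[[h]] <- do.call(rbind, rows)
    }
  }
  tab <- do.call(rbind, out)
  tab$rho <- pmin(pmax(tab$rho, -clip_rho), clip_rho)
  tab$rho_perp <- pmin(pmax(tab$rho_perp, -clip_rho), clip_rho)
  tab$beta <- sqrt(tab$rho^2 + tab$rho_perp^2)
  tab$theta <- atan2(tab$rho_perp, tab$rho)
  tab$eta2 <- tab$sigma2 * (1 - tab$beta^2)
  tab$frequency_hz <- coeffs$frequency_hz[tab$harmonic]
  rownames(tab) <- NULL
  tab[, c("harmonic", "frequency_hz", "separation", "sigma2", "lambda",
          "mu", "rho", "rho_perp", "beta", "theta", "eta2", "n_samples")]
}

# Restrict a trig_coefficients object to a set of window indices
# (repetitions allowed; used by the bootstrap).
subset_windows <- function(coeffs, window_index) {
  out <- coeffs
  out$a <- coeffs$a[window_index, , , drop = FALSE]
  out$b <- coeffs$b[window_index, , , drop = FALSE]
  out$degenerate <- coeffs$degenerate[window_index, , drop = FALSE]
  out
}
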