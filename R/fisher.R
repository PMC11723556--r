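#' Exponential-decay fit of correlation versus separation
#'
#' Fits the distance dependence of the in-phase coefficient correlation by
#' nonlinear least squares. Three model forms are available:
#' \describe{
#'   \item{offset}{`rho(s) = (1 - b) exp(-s/gamma) + b` with `gamma, b >= 0`
#'     (the constrained form used for plume correlations; initialized at
#'     `gamma = 1, b = 0`).}
#'   \item{pure}{`rho(s) = exp(-s/gamma)`.}
#'   \item{affine2}{`rho(s) = 2 exp(-s/gamma) - 1` (the equal-informative
#'     surrogate kernel's own form).}
#' }
#' Only separations with `|s| <= fit_range_max` are used (the decay length
#' is allowed to change beyond roughly a pitch, so the fit is restricted
#' to the near range). Near-flat inputs produce a very large `gamma` and
#' are flagged.
#'
#' @param s numeric vector of separations (use absolute/folded values).
#' @param rho correlation estimates at `s`.
#' @param model `"offset"`, `"pure"`, or `"affine2"`.
#' @param fit_range_max maximum |separation| used (default `Inf`; set to
#'   one pitch for plume data).
#' @param weights optional fit weights.
#' @return An object of class `decay_fit`: list with `gamma`, `b` (`NA`
#'   for models without an offset parameter), `model`, `fit_range_max`,
#'   `residual_norm`, `n_points`, `converged`, `flags`.
#' @export
fit_decay <- function(s, rho, model = c("offset", "pure", "affine2"),
                      fit_range_max = Inf, weights = NULL) {
  model <- match.arg(model)
  keep <- is.finite(s) & is.finite(rho) & abs(s) <= fit_range_max
  s_f <- abs(s[keep]); r_f <- rho[keep]
  if (is.null(weights)) w <- rep(1, sum(keep)) else w <- weights[keep]
  if (length(unique(s_f)) < 3L) stop("need >= 3 separations within range")

  flags <- character(0)
  pred <- switch(model,
    offset = function(p, x) (1 - p[2]) * exp(-x / p[1]) + p[2],
    pure = function(p, x) exp(-x / p[1]),
    affine2 = function(p, x) 2 * exp(-x / p[1]) - 1)
  npar <- if (model == "offset") 2L else 1L
  start <- if (model == "offset") c(gamma = 1, b = 0) else c(gamma = 1)
  lower <- rep(1e-9, npar)

  fit <- tryCatch({
    df <- data.frame(x = s_f, y = r_f)
    form <- switch(model,
      offset = y ~ (1 - b) * exp(-x / gamma) + b,
      pure = y ~ exp(-x / gamma),
      affine2 = y ~ 2 * exp(-x / gamma) - 1)
    minpack.lm::nlsLM(form, data = df, start = as.list(start),
                      lower = lower, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    par <- c(cf[["gamma"]], if (npar == 2L) cf[["b"]] else NA_real_)
    converged <- TRUE
  } else {
    # fallback: bounded quasi-Newton on the SSE
    sse <- function(p) sum(w * (r_f - pred(p, s_f))^2)
    op <- stats::optim(start, sse, method = "L-BFGS-B", lower = lower)
    par <- c(op$par[1], if (npar == 2L) op$par[2] else NA_real_)
    converged <- op$convergence == 0
    if (!converged) flags <- c(flags, "non-convergence")
  }
  resid <- r_f - pred(c(par[1], par[2]), s_f)
  if (stats::sd(r_f) < 1e-12 || par[1] > 1e3 * max(s_f))
    flags <- c(flags, "near-flat")
  structure(list(gamma = par[1], b = par[2], model = model,
                 fit_range_max = fit_range_max,
                 residual_norm = sqrt(sum(resid^2)),
                 n_points = length(s_f), converged = converged,
                 flags = flags),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s: gamma = %.4g%s (%d points%s)\n",
              x$model, x$gamma,
              if (is.finite(x$b)) sprintf(", b = %.4g", x$b) else "",
              x$n_points,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Fisher information under the exponential-decay correlation model
#'
#' Closed form for the information that one harmonic's correlation
#' component carries about intersource separation, when the in-phase
#' correlation decays as `rho(s) = (1 - b) exp(-s/gamma) + b`:
#' `I(s) = (2/gamma^2) (1 - b) exp(-2 s_n) /
#'   ((1 + b + (1 - b) exp(-s_n)) (1 - exp(-s_n)))` with `s_n = s/gamma`.
#' This is algebraically identical to `2 rho'(s)^2 / (1 - rho(s)^2)`.
#' The expression diverges at `s = 0` (returned as `Inf`) and is
#' identically 0 when `b = 1`. Units are 1/length^2 in the units of
#' `gamma` and `s`.
#'
#' @param decay a `decay_fit` (offset model) or a list with `gamma`, `b`.
#' @param s separations (>= 0).
#' @return information values.
#' @export
fisher_info <- function(decay, s) {
  if (any(s < 0)) stop("s must be >= 0")
  g <- decay$gamma; b <- decay$b
  if (!is.finite(b)) b <- 0
  if (b == 1) return(rep(0, length(s)))
  sn <- s / g
  out <- 2 / g^2 * (1 - b) * exp(-2 * sn) /
    ((1 + b + (1 - b) * exp(-sn)) * (1 - exp(-sn)))
  out[s == 0] <- Inf
  out
}

#' Fisher information of the two-sided exponential correlation law
#'
#' General expression for arbitrary distance dependence of the in-phase
#' and out-of-phase correlations. Writing `lam = sigma^2 rho`,
#' `lam_perp = sigma^2 rho_perp`, and `Z = sqrt(sigma^4 - lam_perp^2)`
#' (so `Z' = -lam_perp lam_perp' / Z`), the expectation of the squared
#' score of the two-sided exponential density gives
#' `I = -(Z'/Z)^2 + (1/Z) ((Z' + lam')^2/(Z + lam) +
#'  (Z' - lam')^2/(Z - lam))`.
#' With `rho_perp = 0` this reduces exactly to
#' `2 rho'^2 / (1 - rho^2)`.
#'
#' @param rho,drho_ds in-phase correlation and its derivative in `s`.
#' @param sigma2 marginal coefficient variance (default 1; the information
#'   is invariant to it when `rho_perp` scales accordingly).
#' @param rho_perp,drho_perp_ds out-of-phase correlation and derivative
#'   (default 0).
#' @return information values.
#' @export
fisher_info_general <- function(rho, drho_ds, sigma2 = 1, rho_perp = 0,
                                drho_perp_ds = 0) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  if (any(abs(rho_perp) >= 1)) stop("|rho_perp| must be < 1")
  lam <- sigma2 * rho
  lamp <- sigma2 * drho_ds
  lperp <- sigma2 * rho_perp
  lperpp <- sigma2 * drho_perp_ds
  z <- sqrt(sigma2^2 - lperp^2)
  zp <- -lperp * lperpp / z
  -(zp / z)^2 + (1 / z) * ((zp + lamp)^2 / (z + lam) +
                             (zp - lamp)^2 / (z - lam))
}

#' Bootstrap over time windows
#'
#' Resamples window indices with replacement (jointly across all sources,
#' preserving the cross-source pairing within each window), re-evaluates a
#' statistic on each resample, and reports percentile bands.
#'
#' @param n_windows number of windows in the original dataset.
#' @param statistic function taking an integer vector of window indices
#'   and returning a numeric vector (of constant length).
#' @param n_boot number of bootstrap datasets (default 50).
#' @param seed RNG seed.
#' @param probs percentiles to report (default 5th, 50th, 95th).
#' @return list with `percentiles` (matrix, probs x statistic length),
#'   `replicates` (n_boot x length matrix), `n_boot`, `seed`.
#' @export
bootstrap_windows <- function(n_windows, statistic, n_boot = 50, seed = 0,
                              probs = c(0.05, 0.5, 0.95)) {
  set.seed(seed)
  reps <- NULL
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n_windows, n_windows, replace = TRUE)
    val <- statistic(idx)
    if (is.null(reps)) reps <- matrix(NA_real_, n_boot, length(val))
    reps[bb, ] <- val
  }
  pct <- apply(reps, 2, stats::quantile, probs = probs, na.rm = TRUE,
               names = FALSE)
  pct <- matrix(pct, nrow = length(probs))
  rownames(pct) <- paste0("p", probs * 100)
  list(percentiles = pct, replicates = reps, n_boot = n_boot, seed = seed)
}

#' Robust slope of log-information on frequency ("elbow" regression)
#'
#' For each separation, regresses `log10(I)` on frequency (Hz) over the
#' frequency band `freq_range`, after dropping non-finite, non-positive
#' information values, using Huber robust regression (`MASS::rlm`, Huber
#' psi, iteration cap 10000). Fewer than 3 valid frequencies leaves the
#' slope `NA` (undefined, not zero). A positive slope means high
#' frequencies carry more information at that separation.
#'
#' @param I_grid numeric matrix of information, frequencies x separations.
#' @param frequency_hz frequencies (rows of `I_grid`).
#' @param separations separations (columns); used only for labels.
#' @param freq_range inclusive frequency band used (default `c(1, 15)` Hz).
#' @return data.frame with `separation`, `slope`, `n_valid`.
#' @export
elbow_regression <- function(I_grid, frequency_hz, separations = NULL,
                             freq_range = c(1, 15)) {
  I_grid <- as.matrix(I_grid)
  stopifnot(nrow(I_grid) == length(frequency_hz))
  if (is.null(separations)) separations <- seq_len(ncol(I_grid))
  in_band <- frequency_hz >= freq_range[1] & frequency_hz <= freq_range[2]
  out <- data.frame(separation = separations,
                    slope = NA_real_, n_valid = 0L)
  for (k in seq_len(ncol(I_grid))) {
    ii <- I_grid[in_band, k]
    ff <- frequency_hz[in_band]
    ok <- is.finite(ii) & ii > 0
    out$n_valid[k] <- sum(ok)
    if (sum(ok) < 3L) next
    y <- log10(ii[ok]); x <- ff[ok]
    fit <- tryCatch(
      MASS::rlm(y ~ x, psi = MASS::psi.huber, maxit = 10000),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- stats::lm(y ~ x)
    }
    out$slope[k] <- unname(stats::coef(fit)[2])
  }
  out
}
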