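#' Sandwiched two-sided distributions for correlation components
#'
#' A "sandwich" distribution glues a nonnegative-support base family and a
#' mirrored copy at zero with a shared normalizer:
#' `p(x) = f(x; theta+) / (Z(theta+) + Z(theta-))` for `x >= 0` and
#' `f(|x|; theta-) / (Z(theta+) + Z(theta-))` for `x < 0`.
#' Base families:
#' \describe{
#'   \item{exponential}{`f(x; lambda) = exp(-x/lambda)`, `Z = lambda`.
#'     The sandwich is the asymmetric Laplacian.}
#'   \item{gamma}{`f(x; lambda, k) = x^(k-1) exp(-x/lambda)`,
#'     `Z = Gamma(k) lambda^k`; reduces to exponential at `k = 1`.}
#'   \item{gig}{generalized inverse Gaussian
#'     `f(x; lambda, k, alpha) = x^(k-1) exp(-alpha (x/lambda + lambda/x)/2)`,
#'     `Z = 2 lambda^k K_k(alpha)` (modified Bessel function of the second
#'     kind); approaches the gamma as `alpha * lambda -> 0` at fixed scale
#'     `2 lambda / alpha`.}
#' }
#'
#' @param family `"exponential"`, `"gamma"`, or `"gig"`.
#' @param pos,neg named numeric vectors of branch parameters: `lambda`
#'   (scale, in \[1e-6, 10\]) plus, for gamma, `k` (shape, \[0, 10\]) and,
#'   for gig, `k` and `alpha` (\[1e-6, 10\]). `neg` parameters play the
#'   roles conventionally written mu, m, beta.
#' @return An object of class `sandwich_params`.
#' @export
sandwich_params <- function(family = c("exponential", "gamma", "gig"),
                            pos, neg) {
  family <- match.arg(family)
  need <- switch(family, exponential = "lambda", gamma = c("lambda", "k"),
                 gig = c("lambda", "k", "alpha"))
  for (nm in need) {
    if (is.null(pos[[nm]]) || is.null(neg[[nm]]))
      stop("missing parameter `", nm, "` for family ", family)
  }
  structure(list(family = family, pos = as.list(pos)[need],
                 neg = as.list(neg)[need]),
            class = "sandwich_params")
}

#' @export
print.sandwich_params <- function(x, ...) {
  fmt <- function(p) paste(sprintf("%s=%.4g", names(p), unlist(p)),
                           collapse = ", ")
  cat(sprintf("<sandwich_params> %s | pos: %s | neg: %s\n",
              x$family, fmt(x$pos), fmt(x$neg)))
  invisible(x)
}

# Normalizer Z(theta) of one branch.
branch_z <- function(family, p) {
  lam <- max(p$lambda, 1e-12)
  switch(family,
    exponential = lam,
    gamma = {
      k <- max(p$k, 1e-6)
      gamma(k) * lam^k
    },
    gig = {
      2 * lam^p$k * besselK(p$alpha, p$k)
    })
}

# Unnormalized branch density f(x; theta) on x >= 0.
branch_f <- function(family, x, p) {
  lam <- max(p$lambda, 1e-12)
  switch(family,
    exponential = exp(-x / lam),
    gamma = {
      k <- max(p$k, 1e-6)
      x^(k - 1) * exp(-x / lam)
    },
    gig = ifelse(x > 0,
                 x^(p$k - 1) * exp(-p$alpha * (x / lam + lam / x) / 2),
                 0))
}

# Branch CDF F(x; theta) on x >= 0 (normalized within the branch).
branch_cdf <- function(family, x, p) {
  lam <- max(p$lambda, 1e-12)
  switch(family,
    exponential = stats::pexp(x, rate = 1 / lam),
    gamma = stats::pgamma(x, shape = max(p$k, 1e-6), scale = lam),
    gig = {
      z <- branch_z(family, p)
      vapply(x, function(xx) {
        if (xx <= 0) return(0)
        v <- tryCatch(
          stats::integrate(function(t) branch_f(family, t, p) / z,
                           0, xx, rel.tol = 1e-8,
                           stop.on.error = FALSE)$value,
          error = function(e) NaN)
        v
      }, 0)
    })
}

#' Sandwich density
#'
#' @param params a [sandwich_params()].
#' @param r numeric vector of correlation values.
#' @return density values.
#' @export
sandwich_pdf <- function(params, r) {
  z_tot <- branch_z(params$family, params$pos) +
    branch_z(params$family, params$neg)
  ifelse(r >= 0,
         branch_f(params$family, r, params$pos),
         branch_f(params$family, -r, params$neg)) / z_tot
}

#' Sandwich cumulative distribution
#'
#' Values that come out non-finite or outside \[0, 1\] (possible for the
#' generalized inverse Gaussian's numerically integrated branch CDF) are
#' returned as `NaN` so callers can exclude them rather than clamp.
#'
#' @param params a [sandwich_params()].
#' @param r numeric vector of correlation values.
#' @return cumulative probabilities, `NaN` where evaluation was invalid.
#' @export
sandwich_cdf <- function(params, r) {
  zp <- branch_z(params$family, params$pos)
  zn <- branch_z(params$family, params$neg)
  z_tot <- zp + zn
  out <- ifelse(r >= 0,
                zn / z_tot + (zp / z_tot) *
                  branch_cdf(params$family, pmax(r, 0), params$pos),
                (zn / z_tot) *
                  (1 - branch_cdf(params$family, pmax(-r, 0), params$neg)))
  out[!is.finite(out) | out < 0 | out > 1] <- NaN
  out
}

#' Asymmetric Laplacian implied by the Gaussian coefficient model
#'
#' Under the bivariate-Gaussian coefficient model the correlation
#' component `r = (ac + bd)/2` follows a two-sided exponential law with
#' density `p(r) = (1/Z) exp(-2|r| / (Z + sign(r) sigma^2 rho))` where
#' `Z = sigma^2 sqrt(1 - rho_perp^2)`. This maps those Gaussian-model
#' parameters onto an exponential [sandwich_params()] with branch scales
#' `(Z + sigma^2 rho)/2` and `(Z - sigma^2 rho)/2`. With `rho_perp = 0`
#' the scales reduce to `sigma^2 (1 + rho)/2` and `sigma^2 (1 - rho)/2`,
#' and the mean of the distribution is `sigma^2 rho`.
#'
#' @param sigma2 marginal coefficient variance (> 0).
#' @param rho in-phase coefficient correlation, |rho| < 1.
#' @param rho_perp out-of-phase correlation, |rho_perp| < 1 (default 0).
#' @return an exponential-family [sandwich_params()].
#' @export
alap_from_gaussian <- function(sigma2, rho, rho_perp = 0) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (abs(rho_perp) >= 1) stop("|rho_perp| must be < 1")
  stopifnot(sigma2 > 0)
  z <- sigma2 * sqrt(1 - rho_perp^2)
  sandwich_params("exponential",
                  pos = list(lambda = (z + sigma2 * rho) / 2),
                  neg = list(lambda = (z - sigma2 * rho) / 2))
}

#' Draw samples from a sandwich distribution
#'
#' @param params a [sandwich_params()].
#' @param n number of draws.
#' @return numeric vector. (GIG branches are drawn by inverse-CDF on a
#'   fine grid; exponential and gamma branches use the standard
#'   generators.)
#' @export
sandwich_sample <- function(params, n) {
  zp <- branch_z(params$family, params$pos)
  zn <- branch_z(params$family, params$neg)
  pos <- stats::runif(n) < zp / (zp + zn)
  draw <- function(p, m) {
    if (m == 0L) return(numeric(0))
    switch(params$family,
      exponential = stats::rexp(m, rate = 1 / p$lambda),
      gamma = stats::rgamma(m, shape = max(p$k, 1e-6), scale = p$lambda),
      gig = {
        # inverse CDF on a log-spaced grid
        q <- stats::runif(m)
        hi <- p$lambda * (2 / p$alpha) * 50 + 10 * p$lambda
        grid <- exp(seq(log(1e-8), log(hi), length.out = 2048))
        cdf <- cumsum(branch_f(params$family, grid, p) *
                        c(grid[1], diff(grid)))
        cdf <- cdf / cdf[length(cdf)]
        grid[pmax(1L, findInterval(q, cdf) + 1L)]
      })
  }
  out <- numeric(n)
  out[pos] <- draw(params$pos, sum(pos))
  out[!pos] <- -draw(params$neg, sum(!pos))
  out
}

#' Intermittency mixture parameters
#'
#' Intermittent observation model: with probability `iota` an observation
#' is a true correlation from the sandwich model, otherwise zero-mean
#' Gaussian noise with variance `nu2`. The intermittency estimate is
#' shrunk toward a Beta-prior mean `prior_mean` with strength
#' `prior_strength`.
#'
#' @param iota fraction of observations that are true correlations.
#' @param nu2 noise variance.
#' @param prior_mean prior mean of iota.
#' @param prior_strength prior strength (default 1).
#' @return An object of class `intermittency_params`.
#' @export
intermittency_params <- function(iota, nu2, prior_mean = 0.5,
                                 prior_strength = 1) {
  stopifnot(iota >= 0, iota <= 1, nu2 >= 0)
  structure(list(iota = iota, nu2 = nu2, prior_mean = prior_mean,
                 prior_strength = prior_strength),
            class = "intermittency_params")
}

# Mixture density / CDF of the intermittent model.
mixture_pdf <- function(params, interm, y) {
  p_corr <- sandwich_pdf(params, y)
  if (is.null(interm)) return(p_corr)
  nu <- sqrt(max(interm$nu2, 1e-300))
  interm$iota * p_corr + (1 - interm$iota) * stats::dnorm(y, 0, nu)
}

mixture_cdf <- function(params, interm, y) {
  f_corr <- sandwich_cdf(params, y)
  if (is.null(interm)) return(f_corr)
  nu <- sqrt(max(interm$nu2, 1e-300))
  interm$iota * f_corr + (1 - interm$iota) * stats::pnorm(y, 0, nu)
}

# Parameter bounds used by the EM M-step optimizers.
scale_bounds <- c(1e-6, 10)
shape_bounds <- c(0, 10)
gig_shape_bounds <- c(1e-6, 10)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Closed-form M-step for the sandwiched-exponential scales: solves the
# score equations of the two-sided exponential likelihood restricted to
# the correlation-flagged observations.
exp_mstep <- function(y) {
  n <- length(y)
  yp <- y[y >= 0]; yn <- -y[y < 0]
  a <- length(yp) * if (length(yp)) mean(yp) else 0
  b <- length(yn) * if (length(yn)) mean(yn) else 0
  lam <- (a + sqrt(a * b)) / (n + 1e-8)
  mu <- (b + sqrt(a * b)) / (n + 1e-8)
  list(lambda = clip(lam, scale_bounds[1], scale_bounds[2]),
       mu = clip(mu, scale_bounds[1], scale_bounds[2]))
}

# Branch sufficient statistics for the gamma/GIG M-step objectives:
# per-branch counts and the means of |y|, log|y| and 1/|y| over the
# correlation-flagged observations (|y| floored at 1e-12 so exact zeros
# cannot produce infinite statistics).
branch_stats <- function(y) {
  yp <- pmax(y[y >= 0], 1e-12); yn <- pmax(-y[y < 0], 1e-12)
  list(np = length(yp), nn = length(yn), n = length(y),
       mp = if (length(yp)) mean(yp) else NA_real_,
       mn = if (length(yn)) mean(yn) else NA_real_,
       mlogp = if (length(yp)) mean(log(yp)) else NA_real_,
       mlogn = if (length(yn)) mean(log(yn)) else NA_real_,
       minvp = if (length(yp)) mean(1 / yp) else NA_real_,
       minvn = if (length(yn)) mean(1 / yn) else NA_real_)
}

# M-step objective for the gamma sandwich: mean negative log likelihood
# of the correlation-flagged observations, via branch sufficient
# statistics (mean y and mean log y per branch; the log-mean shortcut is
# unbounded below in (k, lambda) and is not used).
gamma_mstep_nll <- function(par, st) {
  lam <- par[1]; mu <- par[2]; k <- max(par[3], 1e-6); m <- max(par[4], 1e-6)
  v <- log(gamma(m) * mu^m + gamma(k) * lam^k)
  if (st$np > 0)
    v <- v + st$np / (st$n + 1e-8) * (st$mp / lam - (k - 1) * st$mlogp)
  if (st$nn > 0)
    v <- v + st$nn / (st$n + 1e-8) * (st$mn / mu - (m - 1) * st$mlogn)
  if (!is.finite(v)) 1e10 else v
}

# M-step objective for the GIG sandwich (mean NLL via branch sufficient
# statistics: mean y, mean log y, mean 1/y).
gig_mstep_nll <- function(par, st) {
  lam <- par[1]; mu <- par[2]; k <- par[3]; m <- par[4]
  al <- par[5]; be <- par[6]
  v <- log(2 * lam^k * besselK(al, k) + 2 * mu^m * besselK(be, m))
  if (st$np > 0)
    v <- v + st$np / (st$n + 1e-8) *
      (-(k - 1) * st$mlogp + al / (2 * lam) * st$mp +
         al * lam / 2 * st$minvp)
  if (st$nn > 0)
    v <- v + st$nn / (st$n + 1e-8) *
      (-(m - 1) * st$mlogn + be / (2 * mu) * st$mn +
         be * mu / 2 * st$minvn)
  if (!is.finite(v)) 1e10 else v
}

# Bounded Nelder-Mead: optimize over unconstrained space via projection.
nm_bounded <- function(par, fn, lower, upper, ...) {
  proj <- function(p) clip(p, lower, upper)
  res <- stats::optim(proj(par), function(p) fn(proj(p), ...),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000))
  list(par = proj(res$par), value = res$value)
}

#' Fit a correlation model by expectation-maximization
#'
#' Fits a sandwich distribution (exponential, gamma, or generalized
#' inverse Gaussian), optionally with an intermittency mixture, to a set
#' of observed correlation components.
#'
#' The E-step flags an observation as a true correlation when the
#' log-ratio of the correlation density to the Gaussian noise density
#' exceeds `log((1 - iota)/iota)` (ties counted as correlations);
#' non-intermittent fits flag every observation. The M-step shrinks the
#' data intermittency toward the prior mean with strength `prior_strength`,
#' sets the noise variance to the mean square of the noise-flagged
#' observations (falling back to `var(y)/1000` when none are flagged),
#' updates the exponential scales in closed form, and updates gamma/GIG
#' parameters by bounded Nelder-Mead on the branch-statistic likelihood,
#' warm-started at the previous iterate (GIG steps damped by 0.5).
#' Families are initialized ancestrally: exponential closed form, then
#' gamma from the exponential (shapes 1), then GIG from the gamma (small
#' alpha at matched scale).
#'
#' @param y numeric vector of observations (>= 10).
#' @param family `"exponential"`, `"gamma"`, or `"gig"`.
#' @param intermittent logical; fit the intermittency mixture?
#' @param prior_mean prior mean of the intermittency parameter (used when
#'   `intermittent`); default 0.5.
#' @param prior_strength strength of the intermittency prior; default 1.
#' @param max_iter,tol EM stopping rule: stop when the observed-data
#'   log-likelihood changes by less than `tol` (default 1e-8) or after
#'   `max_iter` (default 500) iterations.
#'
#' Intermittent fits are run from two deterministic noise-variance starts
#' — a narrow one (`var(y)/1000`, the update rule's own fallback value)
#' and a wide one (`var(y)`, all variance attributed to noise) — and the
#' start with the higher final observed-data log-likelihood is kept. The
#' two-sided exponential and the Gaussian noise branch are weakly
#' discriminable at matched scale, so hard-assignment EM has two basins
#' (correlation-dominated and noise-dominated); the likelihood decides
#' between them.
#' @return An object of class `corr_model_fit`: list with `params`
#'   ([sandwich_params()]), `interm` ([intermittency_params()] or NULL),
#'   `z_hat` (per-observation indicator), `loglik` (trace), `converged`,
#'   and `n_iter`.
#' @export
em_fit <- function(y, family = c("exponential", "gamma", "gig"),
                   intermittent = FALSE, prior_mean = 0.5,
                   prior_strength = 1, max_iter = 500, tol = 1e-8) {
  family <- match.arg(family)
  y <- as.numeric(y[is.finite(y)])
  if (length(y) < 10L) stop("need at least 10 observations")
  n <- length(y)
  if (all(y == 0)) {
    warning("all observations zero: returning noise-only fit")
    params <- sandwich_params("exponential", pos = list(lambda = 1e-6),
                              neg = list(lambda = 1e-6))
    interm <- intermittency_params(0, 0, prior_mean, prior_strength)
    return(structure(list(params = params, interm = interm,
                          z_hat = rep(0L, n), loglik = -Inf,
                          converged = TRUE, n_iter = 0L),
                     class = "corr_model_fit"))
  }

  if (intermittent) {
    # two deterministic noise-variance starts; keep the better likelihood
    fits <- lapply(c(stats::var(y) / 1000, stats::var(y)), function(nu2_0)
      em_fit_one(y, family, TRUE, prior_mean, prior_strength,
                 max_iter, tol, nu2_0))
    lls <- vapply(fits, function(f) utils::tail(f$loglik, 1), 0)
    return(fits[[which.max(lls)]])
  }
  em_fit_one(y, family, FALSE, prior_mean, prior_strength, max_iter, tol,
             0)
}

em_fit_one <- function(y, family, intermittent, prior_mean, prior_strength,
                       max_iter, tol, nu2_init) {
  n <- length(y)
  # ancestral initialization
  init_exp <- exp_mstep(y)
  par <- switch(family,
    exponential = list(lambda = init_exp$lambda, mu = init_exp$mu),
    gamma = list(lambda = init_exp$lambda, mu = init_exp$mu, k = 1, m = 1),
    gig = {
      g <- em_fit(y, "gamma", intermittent = FALSE, max_iter = 50)
      al <- 0.02
      list(lambda = al * g$params$pos$lambda / 2,
           mu = al * g$params$neg$lambda / 2,
           k = g$params$pos$k, m = g$params$neg$k, alpha = al, beta = al)
    })
  params <- par_to_sandwich(family, par)

  iota <- if (intermittent) prior_mean else 1
  nu2 <- if (intermittent) nu2_init else 0
  interm <- if (intermittent)
    intermittency_params(iota, nu2, prior_mean, prior_strength) else NULL

  z <- rep(1L, n)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step
    if (intermittent) {
      lr <- log(pmax(sandwich_pdf(params, y), 1e-300)) -
        stats::dnorm(y, 0, sqrt(max(interm$nu2, 1e-300)), log = TRUE)
      z <- as.integer(lr >= log((1 - interm$iota) / max(interm$iota, 1e-12)))
    }
    y_corr <- y[z == 1L]
    # M-step: intermittency
    if (intermittent) {
      iota_bar <- mean(z)
      iota <- (prior_strength * prior_mean + iota_bar) / (prior_strength + 1)
      n0 <- sum(z == 0L)
      nu2 <- if (n0 > 0) sum(y[z == 0L]^2) / n0 else stats::var(y) / 1000
      interm <- intermittency_params(iota, nu2, prior_mean, prior_strength)
    }
    # M-step: family parameters
    if (length(y_corr) >= 2L) {
      par <- mstep_family(family, y_corr, par)
      params <- par_to_sandwich(family, par)
    }
    ll <- sum(log(pmax(mixture_pdf(params, interm, y), 1e-300)))
    if (!is.finite(ll)) stop("non-finite likelihood in EM")
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(params = params, interm = interm, z_hat = z,
                 loglik = ll_trace, converged = converged,
                 n_iter = length(ll_trace)),
            class = "corr_model_fit")
}

par_to_sandwich <- function(family, par) {
  switch(family,
    exponential = sandwich_params("exponential",
                                  pos = list(lambda = par$lambda),
                                  neg = list(lambda = par$mu)),
    gamma = sandwich_params("gamma",
                            pos = list(lambda = par$lambda, k = par$k),
                            neg = list(lambda = par$mu, k = par$m)),
    gig = sandwich_params("gig",
                          pos = list(lambda = par$lambda, k = par$k,
                                     alpha = par$alpha),
                          neg = list(lambda = par$mu, k = par$m,
                                     alpha = par$beta)))
}

mstep_family <- function(family, y_corr, par) {
  if (family == "exponential") {
    u <- exp_mstep(y_corr)
    return(list(lambda = u$lambda, mu = u$mu))
  }
  st <- branch_stats(y_corr)
  if (family == "gamma") {
    p0 <- clip(c(par$lambda, par$mu, par$k, par$m),
               c(scale_bounds[1], scale_bounds[1], shape_bounds[1],
                 shape_bounds[1]),
               c(scale_bounds[2], scale_bounds[2], shape_bounds[2],
                 shape_bounds[2]))
    res <- nm_bounded(p0, gamma_mstep_nll,
                      lower = c(scale_bounds[1], scale_bounds[1], 0, 0),
                      upper = c(scale_bounds[2], scale_bounds[2], 10, 10),
                      st = st)
    return(list(lambda = res$par[1], mu = res$par[2], k = res$par[3],
                m = res$par[4]))
  }
  # gig: damped update toward the bounded minimizer
  p0 <- clip(c(par$lambda, par$mu, par$k, par$m, par$alpha, par$beta),
             c(scale_bounds[1], scale_bounds[1], 0, 0,
               gig_shape_bounds[1], gig_shape_bounds[1]),
             c(scale_bounds[2], scale_bounds[2], 10, 10,
               gig_shape_bounds[2], gig_shape_bounds[2]))
  res <- nm_bounded(p0, gig_mstep_nll,
                    lower = c(scale_bounds[1], scale_bounds[1], 0, 0,
                              gig_shape_bounds[1], gig_shape_bounds[1]),
                    upper = c(scale_bounds[2], scale_bounds[2], 10, 10,
                              gig_shape_bounds[2], gig_shape_bounds[2]),
                    st = st)
  newp <- 0.5 * p0 + 0.5 * res$par
  list(lambda = newp[1], mu = newp[2], k = newp[3], m = newp[4],
       alpha = newp[5], beta = newp[6])
}

#' @export
print.corr_model_fit <- function(x, ...) {
  print(x$params)
  if (!is.null(x$interm))
    cat(sprintf("  intermittency: iota=%.3f, nu2=%.4g\n",
                x$interm$iota, x$interm$nu2))
  cat(sprintf("  EM: %d iteration(s), %sconverged, loglik %.4f\n",
              x$n_iter, if (x$converged) "" else "NOT ",
              utils::tail(x$loglik, 1)))
  invisible(x)
}

#' CDF-based fit quality
#'
#' Compares the model's predicted CDF (`iota * F_corr + (1-iota) *
#' F_noise` for intermittent fits) to the empirical CDF `F(r_i) = i/N` on
#' the sorted observations, returning `1 - max |F_pred - F_data|` over the
#' points where the predicted CDF evaluated to a valid probability.
#' 1 is perfect agreement; 0 means disjoint supports.
#'
#' @param fit a `corr_model_fit` (or a [sandwich_params()], treated as a
#'   non-intermittent fit).
#' @param y observations to evaluate against (>= 2).
#' @return list with `value` and `n_valid` (CDF points used).
#' @export
fit_quality <- function(fit, y) {
  if (inherits(fit, "sandwich_params"))
    fit <- list(params = fit, interm = NULL)
  y <- sort(as.numeric(y[is.finite(y)]))
  if (length(y) < 2L) stop("need at least 2 observations")
  f_data <- seq_along(y) / length(y)
  f_pred <- mixture_cdf(fit$params, fit$interm, y)
  ok <- is.finite(f_pred)
  if (!any(ok)) stop("no valid CDF points")
  list(value = 1 - max(abs(f_pred[ok] - f_data[ok])), n_valid = sum(ok))
}

#' Model grid for nested cross-validation
#'
#' @param families subset of `c("exponential", "gamma", "gig")`.
#' @param intermittent `"both"`, `"yes"`, or `"no"`.
#' @param prior_means grid of intermittency prior means (default
#'   `seq(0.1, 0.9, by = 0.1)`).
#' @return data.frame with one row per hyperparameter setting.
#' @export
model_grid <- function(families = c("exponential", "gamma", "gig"),
                       intermittent = c("both", "yes", "no"),
                       prior_means = seq(0.1, 0.9, by = 0.1)) {
  intermittent <- match.arg(intermittent)
  rows <- list()
  if (intermittent %in% c("both", "no"))
    rows <- c(rows, lapply(families, function(f)
      data.frame(family = f, intermittent = FALSE, prior_mean = NA_real_)))
  if (intermittent %in% c("both", "yes"))
    for (f in families) for (p in prior_means)
      rows <- c(rows, list(
        data.frame(family = f, intermittent = TRUE, prior_mean = p)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank correlation models by nested cross-validation
#'
#' Outer loop: `n_outer` random 67/33 train/test splits; each setting is
#' fitted on the training set and its performance is the mean test-set
#' [fit_quality()]. Inner loop: within each outer training set,
#' `n_inner` random 67/33 sub-splits rank the settings by mean validation
#' fit quality (ties averaged); the reported rank is the mean rank across
#' outer iterations, so ranks and performances are never estimated from
#' the same data.
#'
#' @param y observations (>= 30).
#' @param grid hyperparameter settings from [model_grid()].
#' @param n_outer,n_inner number of outer and inner splits (default 3, 3).
#' @param seed RNG seed governing all splits.
#' @return data.frame: grid columns plus `performance` (mean held-out fit
#'   quality) and `mean_rank`, sorted by `mean_rank`.
#' @export
nested_cv <- function(y, grid = model_grid(), n_outer = 3, n_inner = 3,
                      seed = 0) {
  y <- as.numeric(y[is.finite(y)])
  if (length(y) < 30L) stop("need at least 30 observations for splitting")
  set.seed(seed)
  n <- length(y)
  n_set <- nrow(grid)
  fit_eval <- function(train, test) {
    vapply(seq_len(n_set), function(g) {
      fit <- tryCatch(
        em_fit(train, family = as.character(grid$family[g]),
               intermittent = grid$intermittent[g],
               prior_mean = if (grid$intermittent[g])
                 grid$prior_mean[g] else 0.5,
               max_iter = 100),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      tryCatch(fit_quality(fit, test)$value, error = function(e) NA_real_)
    }, 0)
  }
  perf <- matrix(NA_real_, n_outer, n_set)
  ranks <- matrix(NA_real_, n_outer, n_set)
  for (o in seq_len(n_outer)) {
    idx <- sample.int(n, size = round(2 * n / 3))
    train <- y[idx]; test <- y[-idx]
    perf[o, ] <- fit_eval(train, test)
    inner_q <- matrix(NA_real_, n_inner, n_set)
    for (i in seq_len(n_inner)) {
      jdx <- sample.int(length(train), size = round(2 * length(train) / 3))
      inner_q[i, ] <- fit_eval(train[jdx], train[-jdx])
    }
    ranks[o, ] <- rank(-colMeans(inner_q, na.rm = TRUE),
                       ties.method = "average")
  }
  out <- grid
  out$performance <- colMeans(perf, na.rm = TRUE)
  out$mean_rank <- colMeans(ranks, na.rm = TRUE)
  out[order(out$mean_rank), ]
}
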