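# Shared test helpers: small random signal sets and Gaussian coefficient
# draws used across the suite.

# Random multisource series with n_windows full windows of length L.
random_series <- function(n_sources = 2, L = 32, n_windows = 4, seed = 1,
                          positions = seq_len(n_sources) - 1) {
  set.seed(seed)
  plume_series(matrix(rnorm(L * n_windows * n_sources),
                      ncol = n_sources),
               sample_rate = L, positions = positions, pitch = 1)
}

# Draw (a, b, c, d) from the joint Gaussian coefficient model with
# in-phase correlation rho and out-of-phase correlation rho_perp
# (covariance built from the coupling gain/phase parameterization).
rcoef_gaussian <- function(n, sigma2 = 1, rho = 0, rho_perp = 0) {
  S <- sigma2 * rbind(
    c(1, 0, rho, -rho_perp),
    c(0, 1, rho_perp, rho),
    c(rho, rho_perp, 1, 0),
    c(-rho_perp, rho, 0, 1))
  x <- matrix(rnorm(4 * n), n) %*% chol(S)
  colnames(x) <- c("a", "b", "c", "d")
  x
}

# Empirical Kolmogorov distance between samples and a CDF function.
ks_distance <- function(x, cdf_fun) {
  x <- sort(x)
  fe <- seq_along(x) / length(x)
  fp <- cdf_fun(x)
  ok <- is.finite(fp)
  max(abs(fe[ok] - fp[ok]))
}

# Direct trigonometric projection of a z-scored windowed segment:
# brute-force oracle for the decomposition.
project_segment <- function(x, w) {
  L <- length(x)
  xw <- x * w
  z <- (xw - mean(xw)) / sqrt(mean((xw - mean(xw))^2))
  t <- seq_len(L) - 1
  H <- L %/% 2
  a <- b <- numeric(H)
  for (k in seq_len(H)) {
    ck <- cos(2 * pi * k * t / L)
    sk <- sin(2 * pi * k * t / L)
    if (L %% 2 == 0 && k == H) {
      a[k] <- sum(z * ck) / L   # Nyquist: cos(pi t) has energy L
      b[k] <- 0
    } else {
      a[k] <- 2 * sum(z * ck) / L
      b[k] <- 2 * sum(z * sk) / L
    }
  }
  list(a = a, b = b, z = z)
}
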