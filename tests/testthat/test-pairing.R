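test_that("pair census matches brute-force enumeration", {
  # 3 collinear sources spaced delta
  ps <- build_pairs(c(0, 0.5, 1))
  expect_true(all(c(-1, -0.5, 0, 0.5, 1) %in% ps$separations))
  expect_equal(nrow(plumecorr:::pairs_at(ps, 0.5)), 2L)
  expect_equal(nrow(plumecorr:::pairs_at(ps, 1)), 1L)
  expect_equal(nrow(plumecorr:::pairs_at(ps, 0)), 3L)

  # 16 equally spaced sources: 15 ordered pairs at +delta
  ps16 <- build_pairs(seq(0, 15))
  expect_equal(nrow(plumecorr:::pairs_at(ps16, 1)), 15L)

  # cross-stream grid: +/-0.00375 start, 0.0075 spacing, 8 mirrored pairs
  y <- sort(c(seq(0.00375, by = 0.0075, length.out = 8),
              -seq(0.00375, by = 0.0075, length.out = 8)))
  psg <- build_pairs(y)
  d_brute <- outer(y, y, "-")
  for (s in ps_sub <- unique(round(as.vector(d_brute), 9))) {
    expect_equal(nrow(plumecorr:::pairs_at(psg, s)),
                 sum(abs(d_brute - s) <= 1e-9))
  }
  # every ordered pair appears exactly once across bins
  expect_equal(sum(vapply(psg$pairs_at, nrow, 0L)), 16L * 16L)
})

test_that("requested separation with no pair yields an empty flagged group", {
  expect_warning(ps <- build_pairs(c(0, 1, 2), separations = c(1, 5)),
                 "no source pair")
  expect_equal(nrow(ps$pairs_at[[2]]), 0L)
})

test_that("stacked matrix matches naive per-pair assembly and the N(s) count", {
  s <- random_series(n_sources = 3, L = 16, n_windows = 3, seed = 3,
                     positions = c(0, 1, 2))
  co <- decompose(s, window_spec(1, "boxcar", overlap = 0))
  ps <- build_pairs(co$positions)
  d <- stack_pairs(co, ps, n = 2, s = 1)
  expect_equal(ncol(d), N_of(ps, 1, 3))          # 2 pairs x 3 windows x 2
  # naive assembly: pairs (2,1) and (3,2)
  naive1 <- c(co$a[, 2, 2], co$b[, 2, 2], co$a[, 3, 2], co$b[, 3, 2])
  naive2 <- c(co$a[, 1, 2], co$b[, 1, 2], co$a[, 2, 2], co$b[, 2, 2])
  expect_equal(sort(d[1, ]), sort(naive1))
  expect_equal(sort(d[2, ]), sort(naive2))
  # s = 0: self pairs, rows identical
  d0 <- stack_pairs(co, ps, n = 2, s = 0)
  expect_equal(d0[1, ], d0[2, ])
})

test_that("principal variances behave for perfectly correlated, anticorrelated and bivariate data", {
  set.seed(4)
  x <- rnorm(500)
  pv_same <- principal_variances(rbind(x, x))
  expect_equal(unname(pv_same["mu"]), 0)
  expect_equal(unname(pv_same["lambda"]), 2 * mean(x^2))
  pv_neg <- principal_variances(rbind(x, -x))
  expect_equal(unname(pv_neg["lambda"]), 0)

  xc <- rcoef_gaussian(1e5, sigma2 = 1, rho = 0.6)
  d <- rbind(c(xc[, "a"], xc[, "b"]), c(xc[, "c"], xc[, "d"]))
  pv <- principal_variances(d)
  expect_equal(unname((pv["lambda"] - pv["mu"]) / (pv["lambda"] + pv["mu"])),
               0.6, tolerance = 0.01)
})

test_that("pooled sigma2 equals the brute-force second moment and scales quadratically", {
  s <- random_series(n_sources = 3, L = 16, n_windows = 4, seed = 6,
                     positions = c(0, 1, 2))
  co <- decompose(s, window_spec(1, "boxcar"))
  n <- 3
  brute <- mean(c(co$a[, , n], co$b[, , n])^2)
  expect_equal(sigma2_pooled(co, n), brute)
  co2 <- co
  co2$a <- 2 * co$a; co2$b <- 2 * co$b
  expect_equal(sigma2_pooled(co2, n), 4 * sigma2_pooled(co, n))
  # lambda(0)/2 route agrees
  ps <- build_pairs(co$positions)
  pv <- principal_variances(stack_pairs(co, ps, n, 0))
  expect_equal(unname(pv["lambda"]) / 2, sigma2_pooled(co, n))
})

test_that("coupling statistics: identity at s = 0, quadrature fixture, and known covariance", {
  s <- make_fixture("quadrature", seed = 1)
  co <- decompose(s, window_spec(1, "boxcar"))
  ps <- build_pairs(co$positions)
  cs0 <- coupling_stats(co, ps, 3, 0)
  expect_equal(cs0$rho, 1, tolerance = 1e-6)
  expect_equal(cs0$rho_perp, 0, tolerance = 1e-6)
  expect_equal(cs0$beta, 1, tolerance = 1e-6)
  expect_equal(cs0$theta, 0, tolerance = 1e-6)
  expect_equal(cs0$eta2, 0, tolerance = 1e-5)

  cs1 <- coupling_stats(co, ps, 3, -1)   # source 2 delayed by 90 degrees
  expect_lt(abs(cs1$rho), 0.05)
  expect_gt(abs(cs1$rho_perp), 0.95)

  # coefficients sampled from the stated covariance with beta, theta
  set.seed(11)
  beta <- 0.8; theta <- 0.3
  xc <- rcoef_gaussian(1e5, 1, beta * cos(theta), beta * sin(theta))
  co2 <- structure(list(
    a = array(c(xc[, "a"], xc[, "c"]), dim = c(1e5, 2, 1)),
    b = array(c(xc[, "b"], xc[, "d"]), dim = c(1e5, 2, 1)),
    segment_length = 3L, fundamental_hz = 1, n_harmonics = 1L,
    frequency_hz = 1, degenerate = matrix(FALSE, 1e5, 2),
    window = window_spec(), sample_rate = 3,
    positions = cbind(x = 0, y = c(0, 1)), pitch = 1),
    class = "trig_coefficients")
  cs <- coupling_stats(co2, build_pairs(c(0, 1), separations = -1), 1, -1)
  expect_equal(cs$rho, beta * cos(theta), tolerance = 0.01)
  expect_equal(cs$rho_perp, beta * sin(theta), tolerance = 0.01)
  expect_equal(cs$beta, beta, tolerance = 0.01)
  expect_equal(cs$theta, theta, tolerance = 0.02)
  expect_equal(cs$eta2, 1 - beta^2, tolerance = 0.01)
})

test_that("estimator identities: (lambda-mu)/2 = <ac+bd>/2 and <r_n> = sigma2 * rho", {
  s <- make_fixture("ar1-pair", seed = 9, n_windows = 20)
  co <- decompose(s, window_spec(1, "hann"))
  ps <- build_pairs(co$positions)
  for (n in c(2, 5)) {
    cs <- coupling_stats(co, ps, n, 1)
    expect_equal((cs$lambda - cs$mu) / 2, cs$rho * cs$sigma2,
                 tolerance = 1e-9)
    # mean harmonic correlation equals sigma2 * rho (Nyquist-free harmonic)
    hc <- harmonic_correlations(co, pairs = plumecorr:::pairs_at(ps, 1))
    expect_equal(mean(hc$r[, , n]), cs$sigma2 * cs$rho, tolerance = 1e-9)
  }
})

test_that("fast pair_stats path equals the explicit pooled route", {
  s <- random_series(n_sources = 4, L = 24, n_windows = 6, seed = 12,
                     positions = c(0, 1, 2, 3))
  co <- decompose(s, window_spec(1, "hann"))
  ps <- build_pairs(co$positions)
  tab <- pair_stats(co, ps, clip_rho = 1)
  for (n in c(1, 4)) {
    for (s_i in c(-2, 0, 1)) {
      cs <- coupling_stats(co, ps, n, s_i)
      row <- tab[tab$harmonic == n & tab$separation == s_i, ]
      expect_equal(row$rho, cs$rho, tolerance = 1e-12)
      expect_equal(row$rho_perp, cs$rho_perp, tolerance = 1e-12)
      expect_equal(row$lambda, cs$lambda, tolerance = 1e-12)
      expect_equal(row$mu, cs$mu, tolerance = 1e-12)
      expect_equal(row$n_samples, cs$n_samples)
    }
  }
})

test_that("degenerate harmonic errors and clipping bounds rho", {
  co <- decompose(random_series(L = 16, n_windows = 3, seed = 1),
                  window_spec(1, "boxcar"))
  ps <- build_pairs(co$positions)
  expect_error(coupling_stats(co, ps, 1, 1, sigma2 = 0), "degenerate")
  tab <- pair_stats(co, ps)
  expect_true(all(abs(tab$rho) <= 0.999))
})
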