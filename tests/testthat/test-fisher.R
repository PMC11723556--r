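test_that("decay fit recovers exact exponential data and flags flat input", {
  s <- seq(0, 3, by = 0.25)
  fit <- fit_decay(s, exp(-s / 2), model = "offset")
  expect_equal(fit$gamma, 2, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)

  fit2 <- fit_decay(s, (1 - 0.2) * exp(-s / 0.7) + 0.2, model = "offset")
  expect_equal(fit2$gamma, 0.7, tolerance = 1e-6)
  expect_equal(fit2$b, 0.2, tolerance = 1e-6)

  flat <- fit_decay(s, rep(0.4, length(s)), model = "offset")
  expect_equal(flat$b + (1 - flat$b) * exp(-1 / flat$gamma) * 0, flat$b,
               tolerance = 1e-9)  # prediction at large s is b
  expect_true("near-flat" %in% flat$flags ||
                abs(flat$b - 0.4) < 0.05 || flat$gamma > 100)

  expect_error(fit_decay(c(0, 1), c(1, 0.5)), ">= 3")
})

test_that("decay fit recovers parameters under noise across seeds", {
  s <- seq(0.2, 3, length.out = 10)
  g_hat <- b_hat <- numeric(50)
  for (i in 1:50) {
    set.seed(i)
    rho <- (1 - 0.2) * exp(-s / 0.7) + 0.2 + rnorm(10, 0, 0.01)
    f <- fit_decay(s, rho, model = "offset")
    g_hat[i] <- f$gamma; b_hat[i] <- f$b
  }
  expect_lt(abs(mean(g_hat) - 0.7), 0.05)
  expect_lt(abs(mean(b_hat) - 0.2), 0.03)
})

test_that("fit range restriction uses only near separations", {
  s <- c(seq(0, 1, by = 0.1), 5, 10)
  rho <- exp(-s / 0.5)
  rho[s > 1] <- 0.5            # far field deviates from the model
  f <- fit_decay(s, rho, model = "offset", fit_range_max = 1)
  expect_equal(f$n_points, sum(s <= 1))
  expect_equal(f$gamma, 0.5, tolerance = 0.05)
})

test_that("closed-form information equals the derivative form over a parameter grid", {
  set.seed(21)
  for (rep in 1:20) {
    g <- runif(1, 0.2, 5); b <- runif(1, 0, 0.9)
    s <- seq(0.01, 6, length.out = 50)
    I_closed <- fisher_info(list(gamma = g, b = b), s)
    rho <- (1 - b) * exp(-s / g) + b
    drho <- -(1 - b) * exp(-s / g) / g
    I_deriv <- 2 * drho^2 / (1 - rho^2)
    expect_lt(max(abs(I_closed - I_deriv) / I_deriv), 1e-10)
  }
  expect_equal(fisher_info(list(gamma = 1, b = 1), c(0.5, 2)), c(0, 0))
  expect_identical(fisher_info(list(gamma = 1, b = 0), 0), Inf)
  expect_equal(fisher_info(list(gamma = 1, b = 0), 1),
               2 * exp(-2) / (1 - exp(-2)), tolerance = 1e-12)
  expect_error(fisher_info(list(gamma = 1, b = 0), -1), ">= 0")
})

test_that("information decays monotonically and scales as 1/length^2", {
  s <- seq(0.05, 5, length.out = 200)
  I <- fisher_info(list(gamma = 1.3, b = 0.3), s)
  expect_true(all(diff(I) < 0))
  # multiplying s and gamma by c multiplies I by c^-2
  cc <- 3.7
  I_scaled <- fisher_info(list(gamma = 1.3 * cc, b = 0.3), s * cc)
  expect_equal(I_scaled, I / cc^2, tolerance = 1e-12)
})

test_that("general information reduces to the simplified form and matches an MC oracle", {
  rho <- seq(-0.9, 0.9, by = 0.1)
  drho <- runif(length(rho), -1, 1)
  expect_equal(fisher_info_general(rho, drho),
               2 * drho^2 / (1 - rho^2), tolerance = 1e-10)
  expect_equal(fisher_info_general(0.5, 0, rho_perp = 0.2,
                                   drho_perp_ds = 0), 0)
  expect_error(fisher_info_general(1, 0.1), "rho")

  # MC Fisher information of the two-sided exponential law at a test
  # point with nonzero out-of-phase correlation
  set.seed(3)
  s0 <- 0.5; h <- 1e-4; n <- 5e5
  rho_f <- function(s) 0.6 * exp(-s)
  rp_f <- function(s) 0.3 * exp(-s / 2)
  logp <- function(r, s) {
    lam <- rho_f(s); z <- sqrt(1 - rp_f(s)^2)
    -log(z) - 2 * abs(r) / (z + sign(r) * lam)
  }
  lam <- rho_f(s0); z <- sqrt(1 - rp_f(s0)^2)
  tp <- z + lam; tn <- z - lam
  pos <- runif(n) < tp / (2 * z)
  r <- ifelse(pos, rexp(n, 2 / tp), -rexp(n, 2 / tn))
  score <- (logp(r, s0 + h) - logp(r, s0 - h)) / (2 * h)
  I_mc <- mean(score^2)
  se <- sd(score^2) / sqrt(n)
  I_an <- fisher_info_general(rho_f(s0), -0.6 * exp(-s0), 1,
                              rp_f(s0), -0.15 * exp(-s0 / 2))
  expect_lt(abs(I_an - I_mc), 3 * se)
})

test_that("window bootstrap: zero-width band on constants, normal-theory width, determinism", {
  const <- rep(2.5, 40)
  b1 <- bootstrap_windows(40, function(idx) mean(const[idx]), n_boot = 30,
                          seed = 1)
  expect_equal(unname(b1$percentiles["p95", 1] - b1$percentiles["p5", 1]), 0)

  set.seed(10)
  x <- rnorm(200)
  b2 <- bootstrap_windows(200, function(idx) mean(x[idx]), n_boot = 400,
                          seed = 2)
  width <- unname(b2$percentiles["p95", 1] - b2$percentiles["p5", 1])
  expect_lt(abs(width - 2 * 1.645 / sqrt(200)) / (2 * 1.645 / sqrt(200)),
            0.2)

  b3 <- bootstrap_windows(200, function(idx) mean(x[idx]), n_boot = 400,
                          seed = 2)
  expect_identical(b2$replicates, b3$replicates)
})

test_that("elbow regression: flat, log-linear, and contaminated inputs", {
  f <- 1:15
  I_flat <- matrix(rep(3, 15), ncol = 1)
  expect_equal(elbow_regression(I_flat, f)$slope, 0, tolerance = 1e-9)

  I_lin <- matrix(10^(0.1 * f), ncol = 1)
  expect_equal(elbow_regression(I_lin, f)$slope, 0.1, tolerance = 1e-9)

  I_bad <- I_lin
  I_bad[3, 1] <- Inf
  I_bad[7, 1] <- -2
  res <- elbow_regression(I_bad, f)
  expect_equal(res$slope, 0.1, tolerance = 1e-9)
  expect_equal(res$n_valid, 13L)

  # fewer than 3 valid points: slope missing, not zero
  I_sparse <- matrix(c(1, 2, rep(NA, 13)), ncol = 1)
  expect_true(is.na(elbow_regression(I_sparse, f)$slope))

  # frequency band restriction
  I2 <- matrix(10^(0.1 * (1:30)), ncol = 1)
  r2 <- elbow_regression(I2, 1:30, freq_range = c(1, 15))
  expect_equal(r2$n_valid, 15L)
})
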