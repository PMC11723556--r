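test_that("every sandwich density integrates to 1 within quadrature tolerance", {
  set.seed(42)
  draw_pars <- function(family) {
    p <- list(lambda = runif(1, 0.05, 5))
    if (family != "exponential") p$k <- runif(1, 0.2, 5)
    if (family == "gig") p$alpha <- runif(1, 0.1, 5)
    p
  }
  for (family in c("exponential", "gamma", "gig")) {
    for (rep in seq_len(if (family == "gig") 20 else 40)) {
      par <- sandwich_params(family, draw_pars(family), draw_pars(family))
      total <- integrate(function(x) sandwich_pdf(par, x), 0, Inf,
                         rel.tol = 1e-9)$value +
        integrate(function(x) sandwich_pdf(par, x), -Inf, 0,
                  rel.tol = 1e-9)$value
      expect_equal(total, 1, tolerance = 1e-6)
    }
  }
})

test_that("asymmetric Laplacian from Gaussian parameters: symmetry, mean, and nesting", {
  # rho = 0: symmetric, p(0) = 1 for sigma2 = 1
  par0 <- alap_from_gaussian(1, 0)
  expect_equal(sandwich_pdf(par0, 0), 1)
  expect_equal(sandwich_pdf(par0, 0.5), exp(-1))
  expect_equal(sandwich_cdf(par0, 0), 0.5)

  # mean equals sigma2 * rho (closed-form integral over both branches)
  for (cfg in list(c(1, 0.5), c(2, -0.3), c(0.7, 0))) {
    par <- alap_from_gaussian(cfg[1], cfg[2])
    m <- integrate(function(x) x * sandwich_pdf(par, x), -Inf, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(m, cfg[1] * cfg[2], tolerance = 1e-7)
  }
  expect_error(alap_from_gaussian(1, 1.2), "rho")

  # gamma with unit shapes reduces to the exponential sandwich
  pe <- sandwich_params("exponential", list(lambda = 0.4),
                        list(lambda = 0.15))
  pg <- sandwich_params("gamma", list(lambda = 0.4, k = 1),
                        list(lambda = 0.15, k = 1))
  x <- seq(-2, 2, length.out = 201)
  expect_equal(sandwich_pdf(pg, x), sandwich_pdf(pe, x), tolerance = 1e-9)

  # gig approaches gamma as alpha*lambda -> 0 at fixed scale 2*lambda/alpha
  scale <- 0.4; k <- 1.3
  al <- 1e-4
  pgig <- sandwich_params("gig",
                          list(lambda = al * scale / 2, k = k, alpha = al),
                          list(lambda = al * scale / 2, k = k, alpha = al))
  pgam <- sandwich_params("gamma", list(lambda = scale, k = k),
                          list(lambda = scale, k = k))
  xx <- seq(-1.5, 1.5, length.out = 101)
  expect_lt(max(abs(sandwich_pdf(pgig, xx) - sandwich_pdf(pgam, xx))),
            1e-3)
})

test_that("simulated Gaussian-model correlations follow the asymmetric Laplacian law", {
  set.seed(99)
  for (rho in c(-0.8, -0.4, 0, 0.4, 0.8)) {
    xc <- rcoef_gaussian(1e5, 1, rho)
    r <- (xc[, "a"] * xc[, "c"] + xc[, "b"] * xc[, "d"]) / 2
    par <- alap_from_gaussian(1, rho)
    expect_lt(ks_distance(r, function(x) sandwich_cdf(par, x)), 0.01)
  }
})

test_that("closed-form exponential M-step equals the Nelder-Mead MLE oracle", {
  set.seed(7)
  for (rep in 1:50) {
    lam <- runif(1, 0.05, 1); mu <- runif(1, 0.05, 1)
    y <- sandwich_sample(sandwich_params("exponential",
                                         list(lambda = lam),
                                         list(lambda = mu)), 400)
    cf <- plumecorr:::exp_mstep(y)
    nll <- function(p) {
      if (any(p <= 0)) return(1e10)
      -sum(log(sandwich_pdf(sandwich_params("exponential",
                                            list(lambda = p[1]),
                                            list(lambda = p[2])), y)))
    }
    o <- optim(c(0.3, 0.3), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    expect_equal(cf$lambda, o$par[1], tolerance = 1e-4)
    expect_equal(cf$mu, o$par[2], tolerance = 1e-4)
  }
})

test_that("EM recovers exponential-sandwich scales within 5%", {
  set.seed(31)
  lam_hat <- mu_hat <- numeric(10)
  for (i in 1:10) {
    y <- sandwich_sample(sandwich_params("exponential",
                                         list(lambda = 0.3),
                                         list(lambda = 0.1)), 1e4)
    f <- em_fit(y, "exponential")
    lam_hat[i] <- f$params$pos$lambda
    mu_hat[i] <- f$params$neg$lambda
    expect_true(f$converged)
    # non-intermittent exponential EM: loglik trace non-decreasing
    expect_true(all(diff(f$loglik) > -1e-8))
  }
  expect_lt(abs(median(lam_hat) - 0.3) / 0.3, 0.05)
  expect_lt(abs(median(mu_hat) - 0.1) / 0.1, 0.05)
})

test_that("intermittent EM recovers the mixture and collapses on pure noise", {
  set.seed(32)
  y <- {
    z <- rbinom(1e4, 1, 0.7)
    ifelse(z == 1,
           sandwich_sample(sandwich_params("exponential",
                                           list(lambda = 0.5),
                                           list(lambda = 0.2)), 1e4),
           rnorm(1e4, 0, 0.01))
  }
  f <- em_fit(y, "exponential", intermittent = TRUE, prior_mean = 0.7)
  expect_gt(f$interm$iota, 0.6)
  expect_lt(f$interm$iota, 0.8)
  expect_lt(abs(f$params$pos$lambda - 0.5) / 0.5, 0.1)
  expect_lt(abs(f$params$neg$lambda - 0.2) / 0.2, 0.1)

  y0 <- rnorm(500, 0, 0.01)
  f0 <- em_fit(y0, "exponential", intermittent = TRUE, prior_mean = 0.5)
  expect_lt(f0$interm$iota, 0.5)          # shrunk toward noise
  expect_gt(mean(f0$z_hat == 0), 0.5)     # most observations flagged noise

  expect_warning(fz <- em_fit(rep(0, 50), "exponential",
                              intermittent = TRUE), "noise-only")
  expect_equal(fz$interm$iota, 0)
})

test_that("fit quality: self-fit near 1, disjoint-support fit near 0, misfit signature", {
  set.seed(33)
  par <- sandwich_params("exponential", list(lambda = 0.4),
                         list(lambda = 0.2))
  y <- sandwich_sample(par, 1e5)
  expect_gt(fit_quality(par, y)$value, 0.99)

  # nearly all mass far above the data
  far <- sandwich_params("gamma", list(lambda = 10, k = 10),
                         list(lambda = 1e-6, k = 1e-6))
  expect_lt(fit_quality(far, y)$value, 0.1)

  # gamma data with small shape: exponential misfits, gamma matches
  yk <- sandwich_sample(sandwich_params("gamma",
                                        list(lambda = 0.5, k = 0.3),
                                        list(lambda = 0.3, k = 0.3)), 5000)
  q_exp <- fit_quality(em_fit(yk, "exponential"), yk)$value
  q_gam <- fit_quality(em_fit(yk, "gamma"), yk)$value
  expect_gt(q_gam, q_exp + 0.05)
  expect_error(fit_quality(par, numeric(1)), "at least 2")
})

test_that("gamma EM recovers generating shape and scale", {
  set.seed(34)
  y <- sandwich_sample(sandwich_params("gamma",
                                       list(lambda = 0.4, k = 0.5),
                                       list(lambda = 0.2, k = 0.7)), 1e4)
  f <- em_fit(y, "gamma")
  expect_lt(abs(f$params$pos$lambda - 0.4) / 0.4, 0.15)
  expect_lt(abs(f$params$pos$k - 0.5) / 0.5, 0.15)
  expect_gt(fit_quality(f, y)$value, 0.98)
})

test_that("nested CV identifies the generating family and is reproducible", {
  set.seed(35)
  y <- sandwich_sample(sandwich_params("exponential",
                                       list(lambda = 0.4),
                                       list(lambda = 0.15)), 2000)
  grid <- model_grid(families = c("exponential", "gamma"),
                     intermittent = "both", prior_means = c(0.3, 0.7))
  res1 <- nested_cv(y, grid, seed = 5)
  res2 <- nested_cv(y, grid, seed = 5)
  expect_identical(res1, res2)
  # exponential variants near the top; held-out quality high
  top <- res1[1, ]
  expect_gt(max(res1$performance[res1$family == "exponential"]), 0.97)
  best_exp <- min(res1$mean_rank[res1$family == "exponential"])
  expect_lte(best_exp, min(res1$mean_rank) + 1)
  # duplicated settings tie in expected rank
  grid2 <- model_grid("exponential", "no")
  grid2 <- rbind(grid2, grid2)
  res3 <- nested_cv(y, grid2, seed = 2)
  expect_equal(res3$mean_rank[1], res3$mean_rank[2])
  expect_error(nested_cv(y[1:10], grid), "at least 30")
})
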