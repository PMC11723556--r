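#' Pipeline configuration
#'
#' Bundles the tunable parameters of the full analysis: windowing, pair
#' units, decay-fit range, correlation-model grid, bootstrap and elbow
#' settings. Serializes losslessly to/from YAML.
#'
#' @param window a [window_spec()].
#' @param pair_units `"metres"` or `"pitch"`.
#' @param fold_separations pool +s and -s together (default TRUE; the
#'   coefficient statistics are symmetric for symmetric configurations).
#' @param fit_model decay model for rho(s): see [fit_decay()].
#' @param fit_range_max maximum separation used in decay fits, in
#'   `pair_units` (default 1, i.e. one pitch when `pair_units = "pitch"`).
#' @param fit_families,fit_intermittent correlation-model grid passed to
#'   [model_grid()]; set `fit_families = NULL` to skip distribution fits.
#' @param n_boot bootstrap datasets (default 50).
#' @param freq_range frequency band for the elbow regression, Hz.
#' @param seed RNG seed for all stochastic stages.
#' @param clip_rho correlation clip used before Fisher formulas.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = window_spec(),
                            pair_units = c("pitch", "metres"),
                            fold_separations = TRUE,
                            fit_model = "offset",
                            fit_range_max = 1,
                            fit_families = NULL,
                            fit_intermittent = "both",
                            n_boot = 50,
                            freq_range = c(1, 15),
                            seed = 0,
                            clip_rho = 0.999) {
  pair_units <- match.arg(pair_units)
  structure(list(window = window, pair_units = pair_units,
                 fold_separations = fold_separations,
                 fit_model = fit_model, fit_range_max = fit_range_max,
                 fit_families = fit_families,
                 fit_intermittent = fit_intermittent,
                 n_boot = n_boot, freq_range = freq_range, seed = seed,
                 clip_rho = clip_rho),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_config` returns the path invisibly; `read_config`
#'   returns a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$window <- unclass(x$window)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  w <- x$window
  pipeline_config(
    window = window_spec(w$length_s, w$shape, w$overlap, w$kaiser_beta),
    pair_units = x$pair_units, fold_separations = x$fold_separations,
    fit_model = x$fit_model, fit_range_max = x$fit_range_max,
    fit_families = unlist(x$fit_families),
    fit_intermittent = x$fit_intermittent,
    n_boot = x$n_boot, freq_range = unlist(x$freq_range), seed = x$seed,
    clip_rho = x$clip_rho)
}

# Fold a pair_stats table over signed separations: average rho (etc.)
# over +s / -s, weighting by sample count.
fold_stats <- function(stats_tab) {
  stats_tab$sep_abs <- abs(stats_tab$separation)
  sp <- split(stats_tab, list(stats_tab$harmonic, stats_tab$sep_abs),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    w <- g$n_samples
    data.frame(harmonic = g$harmonic[1], frequency_hz = g$frequency_hz[1],
               separation = g$sep_abs[1], sigma2 = g$sigma2[1],
               lambda = sum(g$lambda * w) / sum(w),
               mu = sum(g$mu * w) / sum(w),
               rho = sum(g$rho * w) / sum(w),
               rho_perp = sum(g$rho_perp * w) / sum(w),
               n_samples = sum(w))
  }))
  out <- out[order(out$harmonic, out$separation), ]
  rownames(out) <- NULL
  out
}

# Decay fits + Fisher grid from a (folded) stats table.
fisher_from_stats <- function(tab, fit_model, fit_range_max) {
  harmonics <- sort(unique(tab$harmonic))
  seps <- sort(unique(tab$separation[tab$separation > 0]))
  fits <- lapply(harmonics, function(n) {
    sub <- tab[tab$harmonic == n, ]
    tryCatch(
      fit_decay(sub$separation, sub$rho, model = fit_model,
                fit_range_max = fit_range_max),
      error = function(e) NULL)
  })
  I_grid <- matrix(NA_real_, length(harmonics), length(seps))
  for (h in seq_along(harmonics)) {
    if (is.null(fits[[h]])) next
    I_grid[h, ] <- fisher_info(fits[[h]], seps)
  }
  list(harmonics = harmonics, separations = seps, fits = fits,
       I = I_grid,
       gamma = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$gamma,
                      0),
       b = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$b, 0))
}

#' Run the full separation-information pipeline
#'
#' Decompose -> pooled pair statistics -> (optional) correlation-model
#' fits -> decay fits -> Fisher information grid -> bootstrap -> elbow
#' regression. All stochastic stages are governed by `config$seed`.
#'
#' @param data a [plume_series()], or a precomputed `trig_coefficients`
#'   object (e.g. from [surrogate_coefficients()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs are
#'   written as CSV/JSON with config hash and seed recorded.
#' @return list with elements `coeffs`, `stats` (tidy coefficient
#'   statistics), `decay` (per-harmonic fits, `gamma`, `b`),
#'   `fisher` (`I` grid, frequencies x separations), `elbow` (slopes with
#'   bootstrap percentiles), `model_fits` (when requested), `config`,
#'   `provenance`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  coeffs <- if (inherits(data, "trig_coefficients")) data
    else decompose(data, config$window)

  pairset <- build_pairs(coeffs$positions, units = config$pair_units,
                         pitch = coeffs$pitch)
  tab <- pair_stats(coeffs, pairset, clip_rho = config$clip_rho)
  folded <- if (config$fold_separations) fold_stats(tab) else tab

  fg <- fisher_from_stats(folded, config$fit_model, config$fit_range_max)
  freq <- coeffs$frequency_hz[fg$harmonics]

  elbow <- elbow_regression(fg$I, freq, fg$separations,
                            freq_range = config$freq_range)

  # bootstrap over windows: recompute rho, decay fits, I, elbow slopes
  n_windows <- dim(coeffs$a)[1]
  slope_stat <- function(idx) {
    tb <- pair_stats(coeffs, pairset, window_index = idx,
                     clip_rho = config$clip_rho)
    fb <- if (config$fold_separations) fold_stats(tb) else tb
    fgb <- fisher_from_stats(fb, config$fit_model, config$fit_range_max)
    elbow_regression(fgb$I, freq, fgb$separations,
                     freq_range = config$freq_range)$slope
  }
  boot <- if (config$n_boot > 0 && n_windows >= 10)
    bootstrap_windows(n_windows, slope_stat, n_boot = config$n_boot,
                      seed = config$seed)
  else NULL
  if (!is.null(boot)) {
    elbow$p5 <- boot$percentiles["p5", ]
    elbow$p50 <- boot$percentiles["p50", ]
    elbow$p95 <- boot$percentiles["p95", ]
  }

  model_fits <- NULL
  if (!is.null(config$fit_families)) {
    grid <- model_grid(config$fit_families, config$fit_intermittent)
    model_fits <- list()
    for (n in fg$harmonics) {
      # per-separation observations of r_n, pooled over pairs and windows
      for (k in seq_along(pairset$separations)) {
        pr <- pairset$pairs_at[[k]]
        if (nrow(pr) == 0L) next
        obs <- as.vector(harmonic_correlations(coeffs, pairs = pr)$r[, , n])
        obs <- obs[is.finite(obs)]
        if (length(obs) < 30L) next
        key <- sprintf("h%d_s%g", n, pairset$separations[k])
        model_fits[[key]] <- nested_cv(obs, grid, seed = config$seed)
      }
    }
  }

  prov <- list(seed = config$seed,
               config_hash = config_hash(config),
               package_version = as.character(
                 utils::packageVersion("plumecorr")))

  out <- list(coeffs = coeffs, stats = tab, folded = folded,
              decay = list(harmonics = fg$harmonics, gamma = fg$gamma,
                           b = fg$b, fits = fg$fits),
              fisher = list(I = fg$I, frequency_hz = freq,
                            separations = fg$separations),
              elbow = elbow, model_fits = model_fits,
              config = config, provenance = prov)
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  # small stable string hash (djb2)
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- result$provenance
  utils::write.csv(cbind(result$stats,
                         config_hash = meta$config_hash, seed = meta$seed),
                   file.path(out_dir, "pair_stats.csv"), row.names = FALSE)
  fish <- result$fisher
  fgrid <- data.frame(frequency_hz = rep(fish$frequency_hz,
                                         times = length(fish$separations)),
                      separation = rep(fish$separations,
                                       each = length(fish$frequency_hz)),
                      I = as.vector(fish$I))
  utils::write.csv(cbind(fgrid, config_hash = meta$config_hash,
                         seed = meta$seed),
                   file.path(out_dir, "fisher.csv"), row.names = FALSE)
  utils::write.csv(cbind(result$elbow, config_hash = meta$config_hash,
                         seed = meta$seed),
                   file.path(out_dir, "elbow.csv"), row.names = FALSE)
  jsonlite::write_json(meta, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Deterministic miniature datasets for testing and examples
#'
#' \describe{
#'   \item{tone}{two sources playing the same pure cosine at harmonic 3 of
#'     the window (64-sample windows), plus faint noise: a single-harmonic
#'     coefficient pattern.}
#'   \item{quadrature}{source 2 is source 1 delayed by a quarter period of
#'     the tone: in-phase correlation near 0, out-of-phase near -1/+1 at
#'     the tone harmonic.}
#'   \item{ar1-pair}{two AR(1) processes driven by correlated innovations
#'     (correlation 0.6), a stationary pair with known cross-spectrum.}
#' }
#'
#' @param kind `"tone"`, `"quadrature"`, or `"ar1-pair"`.
#' @param seed RNG seed.
#' @param n_windows number of 64-sample windows' worth of data
#'   (default 16).
#' @return a [plume_series()] (sample rate 64 Hz, unit pitch).
#' @export
make_fixture <- function(kind = c("tone", "quadrature", "ar1-pair"),
                         seed = 0, n_windows = 16) {
  kind <- match.arg(kind)
  set.seed(seed)
  L <- 64L
  n <- L * n_windows
  t <- seq_len(n) - 1
  harmonic <- 3
  omega <- 2 * pi * harmonic / L
  vals <- switch(kind,
    tone = {
      x <- cos(omega * t)
      cbind(x + 1e-3 * stats::rnorm(n), x + 1e-3 * stats::rnorm(n))
    },
    quadrature = {
      x <- cos(omega * t)
      y <- cos(omega * t - pi / 2)  # quarter-period delay
      cbind(x + 1e-3 * stats::rnorm(n), y + 1e-3 * stats::rnorm(n))
    },
    `ar1-pair` = {
      phi <- 0.7
      innov <- matrix(stats::rnorm(2 * (n + 100)), ncol = 2) %*%
        chol(matrix(c(1, 0.6, 0.6, 1), 2))
      x <- stats::filter(innov[, 1], phi, method = "recursive")
      y <- stats::filter(innov[, 2], phi, method = "recursive")
      cbind(x[101:(n + 100)], y[101:(n + 100)])
    })
  plume_series(vals, sample_rate = L, positions = c(0, 1), pitch = 1,
               label = paste0("fixture:", kind))
}
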