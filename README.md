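# plumecorr

Spectral correlation analysis and Fisher information for multisource
odour plumes.

Concentration signals from two odour sources, measured downwind at a
common probe in a turbulent flow, covary more strongly the closer the
sources sit. Their Pearson correlation therefore carries information
about the intersource separation — and because the correlation of two
windowed signals decomposes exactly into per-frequency components,
`plumecorr` can ask *which frequency bands* of that correlation are most
informative about source separation. The intended users are researchers
in sensory neuroscience, olfactory navigation, and environmental fluid
dynamics who have (simulated or measured) multisource concentration
timeseries and want a statistically explicit answer.

## The method in brief

Each signal is windowed (Hann by default), z-scored, and converted to
trigonometric coefficients; harmonic *n* contributes
*r<sub>n</sub>* = ½(*a<sub>n</sub>c<sub>n</sub>* + *b<sub>n</sub>d<sub>n</sub>*)
to the window's Pearson correlation, and Σ<sub>n</sub> *r<sub>n</sub>*
equals that correlation exactly. Pooling coefficients over all ordered
source pairs at each signed separation *s* yields the marginal variance
σ<sub>n</sub>² and the in-phase coefficient correlation ρ<sub>n</sub>(*s*)
(plus its quadrature counterpart ρ<sub>n</sub><sup>⊥</sup>). Under a
Gaussian coefficient model, *r<sub>n</sub>* follows an asymmetric
Laplacian with branch scales σ<sub>n</sub>²(1 ± ρ<sub>n</sub>)/2;
sandwiched Gamma and generalized-inverse-Gaussian variants with an
intermittency mixture are fitted by EM when a closer account of the
observed correlation distribution is wanted. Fitting
ρ<sub>n</sub>(*s*) = (1 − *b*) e<sup>−*s*/γ</sup> + *b* gives the Fisher
information per harmonic in closed form,

  I(s) = (2/γ²) (1−b) e^(−2s/γ) / [(1 + b + (1−b) e^(−s/γ)) (1 − e^(−s/γ))]
       = 2 ρ′(s)² / (1 − ρ(s)²),

and a Huber regression of log₁₀ I on frequency (the "elbow" slope)
summarizes, per separation, whether high or low frequencies carry more
information. Window-bootstrap percentiles quantify uncertainty. A
surrogate generator draws multisource signals whose per-harmonic
coefficient correlations follow a prescribed distance-decay kernel, so
the whole chain can be validated against known ground truth. See the
methods vignette (`vignettes/spectral-information.Rmd`) for the full
account.

## Worked example

Generate a surrogate dataset in which correlations decay with a length
constant of 12 source spacings for the lower half of the harmonic range
and 2 for the upper half (so high frequencies are more informative when
sources are close), then run the full pipeline:

```r
library(plumecorr)

spec <- surrogate_spec(M = 16, n_harmonics = 20, alpha = 4,
                       kernel = "high_gt_low", n_realizations = 2000)
surr   <- sample_signals(spec, seed = 1)
coeffs <- surrogate_coefficients(surr)   # ground-truth coefficients

cfg <- pipeline_config(fit_range_max = 15, n_boot = 50, seed = 1)
res <- run_pipeline(coeffs, cfg)

round(res$decay$gamma, 2)
#>  [1] 10.93 11.67 11.75 12.07 12.26 10.36 11.25 11.75 12.15  2.02  2.00  1.91
#> [13]  1.95  2.03  2.00  2.01  2.00  1.95  2.05  1.98

res$elbow[c(1, 5, 15), c("separation", "slope", "p5", "p95")]
#>    separation   slope      p5     p95
#> 1           1  0.0559  0.0553  0.0564
#> 5           5 -0.0485 -0.0500 -0.0469
#> 15         15 -0.3789 -0.3852 -0.3714
```

The fitted decay lengths recover the generating kernel: about 12 source
spacings for harmonics 1–9, about 2 for harmonics 10–20. The elbow
slopes tell the information story: at the smallest separation the slope
of log₁₀ I on frequency is positive (+0.056 per Hz — high frequencies
more informative), it crosses zero near separation 4, and is clearly
negative at large separations, where only the slowly decaying
low-frequency correlations still change with distance. The `p5`/`p95`
columns are window-bootstrap percentile bands (50 resamples).

For real data, build a `plume_series` from a samples × sources matrix
(or `read_plume_csv()` for CSV + JSON-sidecar files), and start the same
pipeline from `decompose()`.

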