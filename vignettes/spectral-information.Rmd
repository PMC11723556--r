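---
title: "Spectral Fisher information in multisource plume correlations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral Fisher information in multisource plume correlations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumecorr)
```

## The problem

Two odour sources released into a turbulent flow produce concentration
timeseries that, measured downwind at a common probe, covary more strongly
the closer together the sources are. Their Pearson correlation therefore
carries information about the intersource separation — and because the
correlation can be decomposed across frequency bands, that information has
a spectral profile. `plumecorr` quantifies it: which frequency bands of the
correlation between two concentration signals are most informative about
how far apart their sources are?

The package is organized as a pipeline:

1. **Spectral decomposition.** Each signal is cut into (by default
   half-overlapping) windows; each windowed segment is multiplied by the
   window weights, z-scored, and converted to cosine/sine coefficients
   $(a_n, b_n)$. The contribution of harmonic $n$ to the Pearson
   correlation of two segments is $r_n = \tfrac12 (a_n c_n + b_n d_n)$,
   and $\sum_n r_n$ equals the Pearson correlation of the windowed,
   z-scored segments exactly.
2. **Coefficient statistics.** Coefficients are pooled over all ordered
   source pairs at each signed separation $s$, giving the marginal
   variance $\sigma_n^2$ and the in-phase and out-of-phase coefficient
   correlations $\rho_n(s)$, $\rho_n^\perp(s)$.
3. **Correlation models.** Under a Gaussian model of the coefficients,
   $r_n$ follows an asymmetric Laplacian whose branch scales are
   $\sigma_n^2 (1 \pm \rho_n(s))/2$; more flexible sandwiched Gamma and
   generalized-inverse-Gaussian models, with an optional intermittency
   mixture, are fitted directly to observed $r_n$ by EM.
4. **Fisher information.** $\rho_n(s)$ is summarized by a constrained
   exponential decay $\rho_n(s) = (1-b_n) e^{-s/\gamma_n} + b_n$, from
   which the Fisher information about $s$ has the closed form below.
   A robust regression of $\log_{10} I$ on frequency (the "elbow" slope)
   summarizes, per separation, whether high or low frequencies are more
   informative.
5. **Surrogates.** A generator draws multisource signals whose
   per-harmonic coefficient correlations follow a prescribed
   distance-decay kernel, so every stage can be validated against known
   ground truth.

## Windowing and the decomposition identity

Window weights are applied **before** z-scoring, and the z-score uses the
population (1/L) standard deviation. These two choices make the harmonic
decomposition of the correlation exact: with normalized DFT coefficients
$X[k]/L = u_k + j v_k$, the trigonometric coefficients are $a_k = 2u_k$
($a_k = u_k$ at DC and, for even segment lengths, at the Nyquist bin) and
$b_k = -2v_k$, and the per-harmonic weight in $r_n$ is $\tfrac12$ except
at the Nyquist harmonic of an even-length segment, where the cosine
carries the full sample energy and the weight is 1. With those
conventions $\sum_n r_n$ reproduces the segment Pearson correlation to
machine precision for boxcar, Hann, and Kaiser windows and both segment
parities — this identity is enforced in the test suite at $10^{-9}$.

Tapered windows matter scientifically, not just cosmetically: plume
spectra fall off steeply (roughly $1/f^4$), so a boxcar window leaks
low-frequency power into high-frequency bins and can mask genuinely
distinct decay rates across bands. The default analysis window is the
1-second Hann window; Kaiser windows default to $\beta = 16$.

Degenerate (zero-variance) windowed segments have no defined z-score or
correlation; they are flagged, excluded from all pooling, and reported
with a warning — never zero-filled. Trailing samples that do not fill a
window are dropped (no padding).

## Pooling and estimator conventions

All second moments are **uncentred**: temporal stationarity makes the
coefficients zero-mean, and uncentred moments keep the two natural
estimators of $\rho_n(s)$ — the principal-variance route
$(\lambda - \mu)/(2\sigma_n^2)$ and the product-moment route
$\langle ac + bd \rangle / (2\sigma_n^2)$ — exactly equal, which is also
asserted in tests. $\sigma_n^2$ is the pooled uncentred second moment of
all harmonic-$n$ coefficients (equivalently half the major-axis variance
of the self-paired data at $s = 0$).

Separations are signed ($y_i - y_j$) and binned with a $10^{-9}$
tolerance; for symmetric source configurations the $\pm s$ bins can be
folded. Finite-sample $\hat\rho$ can exceed 1 in magnitude; estimates are
clipped to $[-0.999, 0.999]$ before entering any expression containing
$1 - \rho^2$.

## Correlation models and EM

The two-sided ("sandwich") families glue a nonnegative-support density
and a mirrored copy at zero with a shared normalizer. The exponential
sandwich is the asymmetric Laplacian; the Gamma sandwich adds shape
parameters $k, m$ (a shape below 1 concentrates mass near zero, matching
the intermittency signature of turbulent signals); the generalized
inverse Gaussian, $p(r) \propto r^{k-1} e^{-\alpha(r/\lambda +
\lambda/r)/2}$ with normalizer $2\lambda^k K_k(\alpha)$, adds a further
small-value control and recovers the Gamma as $\alpha\lambda \to 0$ at
fixed scale $2\lambda/\alpha$. Parameter bounds follow the fitting
protocol: scales in $[10^{-6}, 10]$, shapes in $[0, 10]$ (GIG shape
$\alpha$ in $[10^{-6}, 10]$).

Intermittency is a Bernoulli mixture: with probability $\iota$ an
observation is a true correlation, otherwise zero-mean Gaussian noise
with variance $\nu^2$. EM uses a hard E-step (an observation is a
correlation when the log density ratio exceeds
$\log\frac{1-\iota}{\iota}$; ties count as correlations) and M-steps
that (i) shrink $\iota$ toward a Beta-prior mean with strength 1,
(ii) set $\nu^2$ to the mean square of the noise-flagged observations
(falling back to $\mathrm{var}(y)/1000$ when none are flagged), and
(iii) update the family parameters: closed form for the exponential
scales, bounded Nelder–Mead on the branch-sufficient-statistic likelihood
for Gamma and GIG (GIG steps damped by 0.5), warm-started at the previous
iterate, with families initialized ancestrally
(exponential → Gamma → GIG). Two details are deliberate design choices:

* **Gamma/GIG M-step statistics.** The branch objectives use the exact
  sufficient statistics $\overline{\log |y|}$ and $\overline{1/|y|}$,
  not $\log \overline{|y|}$ and $1/\overline{|y|}$: with the
  log-of-the-mean shortcut the objective is unbounded below (the shape
  can run to its bound while the scale collapses), and Jensen's gap
  between $\overline{\log|y|}$ and $\log\overline{|y|}$ is exactly what
  keeps the likelihood bounded. The Gamma ancestral initialization uses
  shape 1 (the exponential special case); a shape of 0 is not a
  normalizable density.
* **Two noise starts.** A two-sided exponential and a Gaussian noise
  branch of matched scale are only weakly discriminable, so
  hard-assignment EM has two basins: correlation-dominated and
  noise-dominated. Intermittent fits are run from two deterministic
  noise-variance starts — narrow ($\mathrm{var}(y)/1000$) and wide
  ($\mathrm{var}(y)$) — and the final fit with the higher observed-data
  log-likelihood is kept. This recovers generating mixtures and still
  collapses correctly onto the noise branch for pure-noise input.

EM stops when the observed-data log-likelihood changes by less than
$10^{-8}$ or after 500 iterations. Fit quality is CDF-based:
$1 - \max_i |F_{\mathrm{pred}}(r_i) - F_{\mathrm{data}}(r_i)|$ over
sorted observations, with numerically invalid predicted CDF values
(possible for the GIG's integrated branch CDF) excluded rather than
clamped. Model ranking uses nested cross-validation — three random 67/33
outer train/test splits for performance, three inner sub-splits of each
training set for ranks, ranks averaged over outer iterations — so ranks
and performances never come from the same data. A single seed governs
all splits.

## Fisher information

With $\rho_n(s) = (1-b_n)e^{-s/\gamma_n} + b_n$ ($\gamma_n, b_n \ge 0$,
fitted by nonlinear least squares starting at $\gamma = 1, b = 0$, and —
for plume data, where decay lengths drift at large separations — using
only $s$ up to about one pitch), the information per harmonic is

$$
I(s) \;=\; \frac{2}{\gamma_n^2}\,
\frac{(1-b_n)\, e^{-2 s_n}}
{\bigl(1 + b_n + (1-b_n) e^{-s_n}\bigr)\bigl(1 - e^{-s_n}\bigr)},
\qquad s_n = s/\gamma_n,
$$

which is algebraically identical to $2\rho'^2/(1-\rho^2)$ — an identity
the test suite enforces at $10^{-10}$ relative over a $(\gamma, b, s)$
grid rather than trusting any one printed grouping of the denominator.
$I$ diverges at $s = 0$ (reported as `Inf` and excluded from elbow
regressions), is identically zero at $b = 1$, decreases monotonically in
$s$, and scales as $1/\gamma^2$ under a change of length units.

For nonzero out-of-phase correlation the package provides the general
expression derived from the score of the two-sided exponential law with
$Z(s) = \sigma^2\sqrt{1 - \rho^\perp(s)^2}$:

$$
I \;=\; -\Bigl(\tfrac{Z'}{Z}\Bigr)^2 + \frac{1}{Z}\left[
\frac{(Z' + \lambda')^2}{Z + \lambda} +
\frac{(Z' - \lambda')^2}{Z - \lambda}\right],
\qquad \lambda = \sigma^2 \rho .
$$

This was derived from scratch by taking the expectation of the squared
score under the asymmetric Laplacian (the positive branch contributes
branch mass $\frac{Z+\lambda}{2Z}$ with exponential moments, the negative
branch its mirror), reduces exactly to $2\rho'^2/(1-\rho^2)$ when
$\rho^\perp \equiv 0$, and is verified in tests against a Monte-Carlo
Fisher-information oracle (finite-difference scores on samples from the
law) at a test point with $\rho^\perp \ne 0$.

Uncertainty comes from a window bootstrap: window indices are resampled
with replacement to the original count, jointly across sources so the
cross-source pairing inside each window is preserved; all statistics
(correlations, decay fits, information, elbow slopes) are recomputed per
resample, and 5th/50th/95th percentiles are reported. 50 bootstrap
datasets are the default. Elbow slopes use Huber robust regression
(`MASS::rlm`, tuning constant 1.345, iteration cap 10000) of
$\log_{10} I$ on frequency over 1–15 Hz by default, after dropping
non-finite and non-positive values; fewer than three valid frequencies
leaves a slope missing, never zero.

## The surrogate generator

The generator is the package's validation instrument. For $M$ sources and
$H$ harmonics it builds a block-diagonal covariance kernel — one
$M \times M$ block per harmonic, entries
$k(i,j,n) = S(n)\, G(|i-j|, n)$; cross-harmonic covariances are exactly
zero — and draws cosine and sine coefficients as $L u$ and $L v$ with
$K = LL^{T}$ and $u, v$ independent standard normal vectors. Sine and
cosine sets are therefore i.i.d. and independent: the generator has zero
out-of-phase correlation by construction. Signals of length $2H+1$ are
synthesized from the waveforms $\cos(\pi n t/H)$, $\sin(\pi n t/H)$.

The power term is $S(n) = \max(n f_s/(2H+1), 1)^{-\alpha}$: flat below a
1 Hz cutoff, $1/f^\alpha$ above. $\alpha = 4$ emulates the steep plume
spectrum; $\alpha = 0$ is white. Two preset correlation kernels are
provided, in source-index distance units:

* **equal-informative** — $G(d) = 2e^{-d/12} - 1$ at every harmonic, so
  every frequency carries the same spatial information;
* **high > low** — $G(d, n) = e^{-d/R(n)}$ with $R(n) = 12$ for harmonics
  below half the range and $R(n) = 2$ above, so high-frequency
  correlations decay six times faster and dominate the information at
  small separations.

Defaults are $M = 16$ sources, $H = 20$ harmonics, 2000 realizations
(realizations stand in for windows), and a nominal sample rate
$f_s = 2H + 1 = 41$ Hz so that harmonic $n$ sits at $n$ Hz — which puts
the power cutoff at the fundamental and spreads the default 1–15 Hz
elbow band across both halves of the kernel. These sizes recover the
kernel decay lengths to a few percent while keeping a full two-preset
analysis with a 50-resample bootstrap around half a minute per preset on
one core; all are configurable. Numerically indefinite kernels are
repaired by an escalating diagonal jitter ($10^{-10}\,\mathrm{tr}/d$,
escalated tenfold at most three times), always with a warning, never
silently.

What the surrogates do **not** emulate: non-Gaussian and intermittent
concentration statistics, nonstationarity, out-of-phase coupling, and
any genuine fluid dynamics. Passing the surrogate suite therefore
validates the estimator chain (decomposition → pooling → decay fits →
information → elbow), not the physical fidelity of any flow model; on
real plume data the Gaussian-model asymmetric Laplacian is known to be
only an approximation, which is exactly why the direct correlation-model
fits with intermittency exist.

A note on the synthesis basis: the waveforms $\cos(\pi n t/H)$ have
period $2H$ while the signal length is $2H + 1$, so re-decomposing the
raw surrogate signals with a boxcar window of that length incurs a small
deterministic leakage (and z-scoring adds per-window scale noise). The
round-trip test therefore checks kernel recovery within Monte-Carlo
error, while exact ground-truth work uses the generating coefficients
directly via `surrogate_coefficients()`.

## Integral length scales

To contextualize separations relative to eddy sizes, the package
computes integral length scales from velocity autocorrelation functions:
$Q^{\pm}(r)$ are time-averaged products of the velocity at a reference
point and at displacements $\pm r$ (means removed first — the standard
turbulence convention), averaged where both sides exist (one-sided at
domain edges), normalized by $Q(0)$, and summed with the rectangle rule
$L_U \approx \sum_n f(n\Delta r)\,\Delta r$. Negative lobes of $f$ are
included by default; truncation at the first zero crossing is available
but off. The conventional displacement step is $0.02$ pitch. The result
is invariant to velocity rescaling, and converges at $O(\Delta r)$.

## Numerical choices and degenerate inputs

* Population (1/L) z-scoring; exactness of the decomposition identity
  is preferred over the unbiased-variance convention.
* Nyquist harmonic of even-length segments enters $r_n$ with weight 1.
* Zero-variance segments: excluded with a warning (a constant segment
  has undefined correlation).
* $\hat\rho$ clipping at 0.999; decay fits flagged `near-flat` when the
  input is constant or $\gamma$ exceeds $10^3 \times$ the largest
  separation.
* Decay fits use `minpack.lm::nlsLM` with non-negativity bounds and fall
  back to bounded quasi-Newton on the sum of squares when the
  Levenberg–Marquardt path fails (e.g. exactly flat input).
* E-step ties assign $z = 1$ (measure-zero event).
* GIG branch CDFs are computed by adaptive quadrature; values outside
  $[0, 1]$ are excluded from fit quality, not clamped.
* All stochastic stages (sampling, EM restarts via their data splits,
  bootstrap, CV) run under a single user-supplied seed and are
  bit-reproducible.

## Known limitations

* The Fisher-information summary uses the non-intermittent asymmetric
  Laplacian; the better-fitting intermittent/Gamma/GIG models would
  require modeling how their extra parameters vary with separation.
* The decay fit is global in $s$: misfit at large separations can bias
  $\gamma$ and hence $I$ at small separations. Restricting the fit range
  (default one pitch) mitigates but does not remove this; spline-type
  local fits are out of scope.
* Correlation components at separation 0 are informative about nothing
  ($I$ diverges); elbow regressions start at the smallest positive
  separation.
* Only single-window STFT decomposition is provided (no multitaper or
  Welch averaging), since per-window correlation components are the
  object of study, not the spectrum itself.
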