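---
title: "Complexity and fractality of CGM glucose dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity and fractality of CGM glucose dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(cgmfractal)
```

Continuous glucose monitoring (CGM) produces a reading every few minutes for
days. Classical summaries (mean, time in range, coefficient of variation)
ignore the *dynamics* of the fluctuations. This package quantifies those
dynamics with four estimators that are standard in physiological time-series
analysis, applied here to glucose: the distribution of glucose increments,
the power-spectral scaling exponent, multiscale sample entropy, and
multifractal detrended fluctuation analysis. This vignette documents the
models, parameter choices, numerical details, and validation strategy; the
README shows the worked end-to-end example.

## The data model

All analyses consume a `glucose_series`: a uniformly sampled trace (values
in mmol/L, nominal sampling interval `dt = 300` s, i.e. 5-minute CGM over
roughly 3 days, ~860 readings). `read_cgm_csv()` + `regularize()` produce
this from raw CSV exports. Gap policy: runs of up to `max_gap = 2` missing
grid points (10 minutes) are filled by linear interpolation; longer holes
are a hard error, because every estimator below assumes a contiguous record
and interpolation across long gaps would fabricate low-frequency structure.
Timestamps are stored at second resolution; the estimators use only the
values and `dt`.

## Increment distributions: alpha-stable vs Gaussian

Glucose increments `x[i+1] - x[i]` are split into positive and negative
magnitude samples (zeros, common under CGM quantization, are dropped by
default). Each sample is fitted with

* a Gaussian (maximum likelihood: sample mean, population-normalized SD), and
* a four-parameter alpha-stable law (tail index `alpha`, skew, scale,
  location), the family closed under summation whose heavy tails capture
  occasional large glucose excursions that a Gaussian cannot.

The stable density has no closed form; `stable_pdf()` inverts the
characteristic function on a 32768-point FFT grid (spacing 0.04 in
standardized units, half-range ~655), switching to the first-order Pareto
tail expansion `alpha * c_alpha * (1 +/- skew) * |z|^(-alpha-1)` beyond
|z| = 300. Because the FFT periodizes the density, the wrapped images of
the heavy tails from the first three neighboring periods are subtracted
again; without this the density would be biased by a few 1e-6 and its
integral by a few 1e-3. We use Nolan's S0 parameterization internally so
the density is continuous in `alpha` (including at `alpha = 1`); results
are reported in the conventional 4-tuple order (alpha, skew, scale,
location). At `alpha = 2` the law is exactly Normal(location, 2 scale^2),
which the tests exploit as a closed-form oracle.

`fit_stable()` initializes with quantile matching in the McCulloch style —
the lookup table relating the quantile ratios `(q95-q05)/(q75-q25)` and
`(q95+q05-2 q50)/(q95-q05)` to (alpha, skew) is computed at run time from
the package's own quantile function rather than transcribed from print —
then refines by Nelder-Mead maximum likelihood on transformed coordinates
(alpha in (0.4, 2), |skew| < 1, scale > 0). A minimum sample size of 50 is
enforced: below that the quantile initializer is unstable. Skew is fitted
freely; one-sided magnitude samples naturally drive it toward 1, and
constraining it would hide fit pathologies. `compare_fits()` declares the
better law by log-likelihood (both models have four vs two fixed
parameters; no information criterion is applied, and formal model-selection
tests are out of scope).

## Spectral exponent by lowPSD_we

For fractal signals the power spectrum follows `P(f) ~ c / f^beta`. The
estimator: (e)ndpoint-match (subtract the line through the first and last
samples), remove the residual mean, taper with the parabolic (Welch) window
`1 - (2j/(N+1) - 1)^2`, take the raw periodogram, and fit `log10 P` on
`log10 f` by OLS over `0 < f <= fs/8` only — the high-frequency region
`(fs/8, fs/2)` is excluded before fitting. `beta` is the negative slope.
The intermediate mean removal matters: tapering a nonzero-mean segment
leaks DC power into exactly the low-frequency bins the slope is fitted on,
which we measured to bias `beta` for anti-persistent noise by ~0.2; with it,
fBm traces of length 4096 recover `beta = 2H + 1` and fGn traces
`beta = 2H - 1` to within 0.15 (mean over 20 seeds) for H in {0.2, 0.5, 0.8}.

Classification follows the spectral-exponent ranges: `beta` in (-1, 1) is
fGn-like (stationary), (1, 3) is fBm-like (nonstationary); exactly 1 or
outside both is "ambiguous". The Hurst exponent is derived as
`H = (beta - 1)/2` (fBm) or `H = (beta + 1)/2` (fGn), clamped with a
warning to (0, 1).

## Multiscale sample entropy

Sample entropy SampEn(m, r) is the negative log conditional probability
that sequences matching for `m` points (Chebyshev distance, inclusive
tolerance `r`) still match at point `m + 1`, in the Richman-Moorman
convention: the same `N - m` templates for both lengths, self-matches
excluded. The pair counting is an O(N^2) C++ kernel; an independent R
double-loop implementation serves as the exactness oracle in the tests.

Multiscale entropy coarse-grains the series by non-overlapping block means
at scale factors k (default 1-10 for ~860-point records; scale 10 leaves 86
points, just above the enforced floor of `10 * (m + 1)` points). Defaults
`m = 2`, `r = 0.15 * SD` follow the accepted optimum for short
physiological records. The tolerance is anchored to the SD of the original
series and *not* recomputed per scale — the standard convention; for iid
Gaussian noise this gives the closed-form prediction
`SampEn(k) = -ln erf(0.15 sqrt(k) / 2)`, which the tests verify to within
0.15 at n = 10^4. Undefined entropies (zero match counts) are flagged
explicitly, never silently dropped.

## Multifractal detrended fluctuation analysis

MF-DFA of the profile (cumulative sum of the mean-subtracted series):
windows of size s are taken from both ends (2 floor(N/s) total, covering
the tail remainder), an order-2 polynomial is removed per window, and the
residual variances v are aggregated into `F_q(s) = mean(v^(q/2))^(1/q)`
(logarithmic-average limit at q = 0). `H(q)` is the slope of `log2 F_q` on
`log2 s`; the mass exponent is `tau(q) = q H(q) - 1`; the spectrum
`(h, D)` comes from the Legendre transform with `h = dtau/dq` by central
finite differences (one-sided at the ends — no parametric fit of tau), and
the headline width is `delta_h = h_max - h_min`. The default q grid is 21
values in [-5, 5]; q = 2 reduces to ordinary DFA, checked against an
independent per-window `lm()` implementation to 1e-8.

The glucose series is analyzed directly (no pre-differencing), so `H(q)`
near or above 1 is expected for fBm-like records and reported as-is. The
default scale band is `2^4..2^9`; on an ~860-point record the largest scale
admits only 2 windows, which is accepted and visible in `fit_r2`.

Degenerate windows (zero residual variance, e.g. an exactly quadratic
segment under order-2 detrending) would blow up negative orders; they are
excluded with a warning and counted.

**Validation choice.** The binomial multiplicative cascade (multiplier
`a`), whose generalized Hurst exponent has the closed form
`H(q) = 1/q - ln(a^q + (1-a)^q)/(q ln 2)`, is the multifractal oracle. Its
partition sums reproduce that formula exactly at all dyadic scales, but
DFA-style polynomial detrending of such a singular measure exhibits a long
small-scale crossover: local slopes of `log2 F_2` vs `log2 s` climb from
~0.60 at s = 16 toward the asymptote 0.839 (a = 0.75) only at large s. The
cascade validation therefore uses scales `2^6..2^12` on a 2^14-point
series, where the estimates sit within 0.1 of the closed form at
q in {-5, -2, 2, 5}; the spectrum width is compared against the
closed-form Legendre range `dtau/dq(-5) - dtau/dq(+5) ~ 1.572`, the
quantity the finite-difference transform actually estimates (not the
H(q) range, which is a different number for a cascade).

## Bootstrap error bars

Error bars use an ordered-subsequence bootstrap: delete a uniformly random
5% of the points, keep the remaining 95% in original order, re-run the
statistic; the SD across 100 replicates is the error bar. The deleted-point
reading of "ordered subsequences containing 95% of the data" is the default;
a contiguous-window variant (one random 95%-length window per replicate) is
available via `mode = "window"` since the phrase is genuinely ambiguous —
neither mode is asserted against any external value. Subsampled series are
treated as uniformly sampled by the downstream estimators (index-based, not
time-based). A master seed spawns per-replicate seeds deterministically, so
reports are bit-reproducible; more than 50% undefined replicates aborts with
an error rather than reporting a misleading SD.

## The synthetic-data module

Because no patient CGM recording ships with the package, the generators are
first-class, tested code and define every validation condition:

* `gen_fgn()` — fractional Gaussian noise by exact Davies-Harte circulant
  embedding, so the autocovariance
  `0.5 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})` holds exactly in expectation
  (an unbiased oracle for the spectral-exponent recovery, unlike
  approximate spectral synthesis); `gen_fbm()` is its cumulative sum.
* `gen_binomial_cascade()` — deterministic binomial measure with the
  closed-form `H(q)` above; sums to exactly 1.
* `gen_stable()` — Chambers-Mallows-Stuck sampler, shifted to the same S0
  parameterization as the density, so fit round trips are exact in
  distribution.
* `gen_cgm_trace()` — a CGM-like fixture: baseline + amplitude-scaled fBm
  + optional log-normal-shaped meal bumps, clipped to [2, 25] mmol/L,
  864 points at 300 s (3 days; the largest default MF-DFA scale 512 remains
  feasible). Defaults: Hurst 0.8 (glucose records are strongly persistent,
  spectral exponent near 2), baseline 7 mmol/L, amplitude 1.5 mmol/L —
  plausible for a diabetic record under treatment.

What the traces do *not* emulate: glucose-insulin physiology, sensor noise
and calibration drift, quantization, circadian structure beyond optional
meal bumps, or gaps. Passing tests therefore demonstrate estimator
correctness on signals with known scaling structure in the CGM data regime
— not clinical validity on real sensor data.

The two-period study used by the acceptance script pairs a smoother trace
(Hurst 0.9, "Period-1-like") with a rougher one (Hurst 0.3,
"Period-2-like"). On such pairs the pipeline must report sample entropy
*increased* and `H(q)` *decreased* — the direction in which "global"
complexity rises while smoothness falls — at every seed; this is the
qualitative, reproducible core of the two-period comparison, whereas the
patient-specific magnitudes are not reproducible from synthetic data.

## Numerical and design notes

* All randomness is routed through explicit seeds (`with_seed` internally
  restores the caller's RNG state); fixed seed implies bit-identical
  output, including the serialized JSON reports.
* Problem sizes in the test suite (series of 4096-16384 points, 10-20
  seeds per recovery check, 5000-draw stable fits) were chosen as the
  smallest at which the Monte-Carlo spread is comfortably inside each
  stated tolerance.
* `verdict` vocabulary in `compare_periods()`: a vector quantity is
  "increased"/"decreased" only when at least 80% of its per-element
  differences agree in sign, otherwise "mixed"; exact zero differences give
  "none". The comparison is antisymmetric by construction.
* Degenerate inputs (constant series, all-identical increments, exactly
  polynomial segments) are detected and flagged per stage; `run_period()`
  records a failed stage and continues rather than aborting the report.

## Known limitations

* Stable ML fitting is accurate but not fast (~seconds per fit at
  n = 5000); profile-likelihood or FFT-reuse across optimizer steps would
  speed it up.
* The spectral, MSE and MF-DFA estimators assume contiguity and uniform
  sampling; records with long sensor dropouts must be split into periods
  rather than interpolated.
* MF-DFA on ~860-point records with the conventional `2^4..2^9` band is
  noisy at the largest scales (2 windows) and for strongly negative q;
  bootstrap SDs make this visible but cannot remove it.
* No surrogate testing (e.g. shuffled or phase-randomized controls) is
  wired into the pipeline; `gen_binomial_cascade(shuffle = TRUE)` provides
  the raw material for a distribution-vs-correlation multifractality check
  if needed.
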