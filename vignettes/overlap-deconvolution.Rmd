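---
title: "Overlap-corrected regression ERPs: models, bases, and design choices"
author: "erpdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-corrected regression ERPs: models, bases, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdeconv)
```

## The problem and the model

Event-related potentials (ERPs) are classically estimated by cutting the
continuous EEG into epochs around event onsets and averaging. When events
follow each other faster than the brain's responses decay — stimuli
followed by button presses, involuntary microsaccades during a trial,
rapid multisensory streams — the recorded signal at any moment is the sum
of several overlapping responses, and averaging mixes them together. The
result can be spurious condition differences driven purely by differences
in timing (e.g. faster reaction times in one condition).

This package treats the continuous recording `y(t)` as a linear
superposition of unknown event-locked responses and recovers them by
regression. The massive univariate model, fitted per local time point
$\tau$ relative to onset,

$$\mu_{i,\tau} = X_i\,\beta_\tau,\qquad
  y_{i,\tau} \sim \mathcal N(\mu_{i,\tau}, \sigma_\tau),$$

ignores overlap. The deconvolution model instead describes every
continuous-time sample as

$$\mu_t = X_{dc,t}\,\beta,\qquad y_t \sim \mathcal N(\mu_t, \sigma),$$

where $X_{dc}$ is the *time-expanded* design matrix: each predictor column
of the instance-level design matrix $X$ (one row per event instance) is
expanded into one column per local time point of the estimation window,
and each event instance writes its predictor values into the rows around
its onset. Where windows of neighbouring events overlap, their
contributions are **summed** in the shared cells — that summation is what
encodes the overlap, and solving the single large least-squares problem
disentangles it. Identifiability comes from the natural jitter of
inter-event intervals; with perfectly rhythmic events the shifted copies
would be collinear.

Conventions used throughout: sample indices are 0-based; the local window
$[\tau_{\min}, \tau_{\max}]$ maps to samples
`round(tau_min * srate) .. round(tau_max * srate)` inclusive; onsets are
converted with half-to-even rounding; partial windows at the recording
edges are truncated rather than zero-padded (padding would fabricate
data).

## Model specification

Models are written per event type in Wilkinson notation:

```{r formula}
parse_formula("y ~ 1 + cat(is_face) + luminance")
```

`cat()` marks categorical predictors (treatment coding by default:
alphabetically first level is the reference, so the intercept time-course
is the reference-condition ERP and each factor coefficient is a difference
wave; effects/sum coding is available, with the alphabetically last level
carrying the $-1$ row). Plain names are linear covariates, left in their
original units (no centering or scaling, so a luminance coefficient is
"per luminance unit"). Non-linear covariates use `spl(x, n)` (cubic
B-splines), `2dspl(a, b, n)` (tensor product, $n^2$ columns), and
`circspl(x, n, lo, hi)` (periodic splines for angles and phases).
Interactions with `*`/`:` are restricted to categorical and linear terms;
non-linear interactions are expressed through `2dspl()`, which is the
dedicated mechanism for that purpose. A formula that wraps the same
predictor in both `cat()` and a spline term is rejected as ambiguous
rather than resolved by precedence.

## Spline bases

For `spl(x, n)` the knots are placed on the empirical quantiles of the
observed predictor: $n - 2$ quantile levels spread evenly over $[0, 1]$
(so the outermost knots are the minimum and maximum), with each boundary
value repeated to multiplicity 4. This puts spline resolution where the
data are dense, and gives the full knot vector $n + 4$ entries — the
number of basis functions equals the knot count minus 4. With
multiplicity-4 boundaries the basis is *clamped* (`(1, 0, ..., 0)` at the
left boundary) and forms a partition of unity over the whole predictor
range; both properties are asserted in the tests. A consequence worth
knowing: at least 4 cubic basis functions are needed for these properties
to be satisfiable at all, so `spl(x, 2)` and `spl(x, 3)` are accepted by
the parser but rejected at evaluation time.

Because a partition of unity is collinear with the intercept, one basis
column must be removed when the model has an intercept. The column whose
peak lies closest to the predictor's median is dropped: this keeps the
retained basis roughly symmetric around the bulk of the data, and makes
the dropped peak the natural *reference point* of the effect.
`evaluate_spline_effect()` therefore reports effects relative to that
point — it computes
$\mathrm{effect}(\tau, x) = \sum_j (B_j(x) - B_j(x_{\mathrm{ref}}))\,
\beta_j(\tau)$, which is exactly zero at $x_{\mathrm{ref}}$ and uses the
identical knots and dropped column as the fit. Out-of-range predictor
values are clamped to the boundary knots at evaluation time; cubic
extrapolation beyond the data is never attempted.

Cyclic splines are wrapped cubic B-splines on uniform knots over the
cycle (`mgcv::cSplineDes`), so `basis(lo)` equals `basis(hi)` and the
partition of unity is preserved. The number of splines is a modelling
choice made before the analysis; automatic selection by cross-validation
or penalization is deliberately out of scope (about 5 splines is a
reasonable default for effects like saccade amplitude; many more invites
overfitting).

## Temporal bases

Time expansion defaults to *stick functions* (FIR): one indicator column
per local sample, no smoothing, maximal temporal fidelity — the
recommended choice. Two alternatives reduce the column count and smooth
the estimate:

* **Temporal splines** (`temporal_basis("spline", n_basis)`): cubic
  B-splines on equally spaced knots across the window. No column is
  dropped here because local time has no intercept.
* **Truncated Fourier set** (`temporal_basis("fourier", K)`): a constant
  column plus the first $K$ cosine/sine pairs at integer cycles per
  window, each column $\ell_2$-normalized. Truncation acts as a hard
  low-pass filter: the fitted time-course provably contains no energy
  above harmonic $K$ (asserted to $10^{-10}$ relative energy in the
  acceptance tests). The exact phase/scaling convention of a Fourier set
  is not canonical; ours (constant $1/\sqrt{n}$, unnormalized frequencies
  $k/n$, no special Nyquist handling beyond the `2K + 1 <= n_local`
  guard) is documented here and pinned by tests.

## Artifacts

Deconvolution needs continuous data, so contaminated stretches cannot be
cut out — removing them would also remove the overlap information of
neighbouring clean events. Instead, intervals are *detected* (moving
window of `winlen` seconds, stepping by `step`, default `winlen/2` since
no canonical step exists; flagged whenever any channel's peak-to-peak
amplitude in the window exceeds the threshold — the whole window is
flagged, a deliberate conservative choice) and the corresponding rows of
$X_{dc}$ are *blanked* (set to zero). Zero rows have zero leverage, so
they cannot bias the coefficients. The response is zeroed on the same
rows and those rows are excluded from the residual-scale estimate
$\sigma$; otherwise raw artifact voltages would inflate $\sigma$ without
affecting $\beta$. Blanked-row fits agree with row-deleted fits to
numerical precision (tested via the normal-equations identity).

## Solvers

$X_{dc}$ has as many rows as the recording has samples and is extremely
sparse under the stick basis. The default solver is LSMR, an iterative
Krylov method for sparse least squares, implemented in the package and
validated against dense QR solves on random systems (to $10^{-6}$ over
100 systems of up to 200 columns) — no installed R package provides LSMR.
The default tolerance of $10^{-10}$ is tight because noise-free recovery
tests require it; it is exposed in the configuration. Channels share one
design matrix and are solved independently (verified: joint and
per-channel fits are identical).

For noisy, collinear designs the elastic net
($\frac{1}{2n}\lVert y - X\beta\rVert^2 + \lambda(\alpha\lVert\beta\rVert_1
+ \frac{1-\alpha}{2}\lVert\beta\rVert^2)$, via glmnet) trades bias for
variance. Two choices depart from glmnet defaults, both deliberate:
columns are **not** standardized and there is **no unpenalized
intercept** — every column of $X_{dc}$ is part of an estimated response
time-course, and an unpenalized global intercept has no meaning here. The
penalty weight $\lambda$ is chosen per channel by K-fold cross-validation
over a log-spaced path, with folds formed as **contiguous temporal
blocks**: continuous EEG samples are strongly autocorrelated, and random
per-sample folds would leak information between train and test. Block CV
is implemented in the package (one glmnet path fit per fold), which also
permits `cv_folds = 2`.

A mass-univariate twin fit (`fit_mass_univariate()`) runs the identical
instance-level model per local time point on epoched data, without
overlap correction — useful to quantify what overlap does to a given
dataset. With events spaced farther apart than the window, deconvolved
and mass-univariate estimates coincide (to $10^{-8}$ in the tests), and
the intercept-only mass-univariate fit is exactly the epoch average.

## Missing predictor values

Dropping an event with a missing covariate is worse in the deconvolution
setting than in epoched analyses, because the dropped event's response
still overlaps its neighbours and would go unmodeled (the package warns
accordingly). Imputation by the column mean or median (within event
type) is available; "marginal" imputation we read as a seeded uniform
draw from the observed empirical marginal of the column — the name alone
does not pin down a definition, and the empirical-marginal draw is the
least parametric reading.

## The simulator

`preset()` provides the validation scenarios used by the test suite and
the acceptance script:

* `fig10_*`: 5 s at 200 Hz, inter-event intervals
  $\mathcal N(0.25\,\mathrm s, 0.05\,\mathrm s)$ truncated below at 2
  samples (roughly 18–20 events), one of four kernels — boxcar, Dirac,
  a parametric ERP-like waveform, pink noise — each 0.8 s long, no
  noise. Responses overlap their neighbours about threefold, yet an
  intercept-only stick-basis fit recovers each kernel to machine
  precision.
* `fig7`: 38 events, ERP kernel, a linear covariate effect (effect size
  0.5 per SD) plus a second covariate with **no** effect but correlated
  $r = 0.85$ with the first (Gaussian copula), Gaussian noise of SD 1 at
  100 Hz. Ridge regression shrinks the null covariate's time-course
  variance far below the OLS fit's (ratio about 0.05 in the acceptance
  run).
* `fig1`: a stimulus-discrimination experiment at 100 Hz, 80 s: faces
  vs houses (extra N170-like negativity for faces), a logarithmic
  luminance effect on the P1 component with luminance 15 units higher
  for faces on average, and button presses at stimulus onset plus a
  reaction time that is 100 ms faster for faces
  ($\mathcal N(0.38, 0.06)$ vs $\mathcal N(0.48, 0.06)$ s). Naive
  condition averages show spurious differences from both confounds;
  the deconvolution model with a luminance spline removes them.

The parametric "auditory ERP" kernel is a three-Gaussian waveform of our
own construction (P1 +0.5 at 50 ms / 15 ms width, N1 −1.0 at 100 ms /
25 ms, P2 +0.8 at 200 ms / 45 ms); all recovery comparisons are against
this kernel itself, so its exact shape carries no risk. Sampling rates,
durations, effect sizes and reaction-time distributions beyond those
listed are package defaults chosen to be typical of EEG practice, fixed
once here. The simulator emulates linear superposition, covariate
modulation, correlated covariates and white Gaussian noise; it does
**not** emulate autocorrelated (1/f) background EEG, spatial structure
across channels, non-stationarity, or violations of the linearity and
time-invariance assumptions — passing recovery tests therefore
demonstrates correctness of the estimator, not robustness of the method
on real data.

## Numerical choices and degenerate inputs

* Half-to-even rounding for onset-to-sample conversion (deterministic
  tie-break).
* Quantiles use the linear-interpolation definition (`type = 7`).
* Same-cell collisions in time expansion are summed; two identical
  events at the same onset produce cells of 2 — and a rank-deficient
  model, which the iterative solver resolves to a minimum-norm-like
  solution without error. A warning (not an error) is raised for
  identically zero design columns and for underdetermined expansions.
* A constant predictor given to `spl()` is a degenerate-predictor error;
  a single-level factor is a validation diagnostic.
* Blanking everything yields an all-zero design; fitting it is an error.
* ISI distributions whose mean does not exceed the 2-sample truncation
  bound are rejected as infeasible.

## Worked example

```{r example}
sc <- preset("fig10_boxcar", seed = 1)
sim <- simulate_scenario(sc)
X <- expand_model(sim$events, model_spec("stim", "y ~ 1", c(0, 0.8)),
                  sim$n_samples, sc$srate)
fit <- fit_lsmr(X, sim$data)
max(abs(fit$coefficients[1, ] - sim$truth$stim$kernel))
```

## Validation problem sizes

The shipped validation uses desk-scale problems: 5–19 s of single-channel
data at 100–200 Hz (500–2,000 samples), expanded designs of up to a few
hundred columns, 100-trial oracle comparisons against dense QR solves and
a textbook Cox–de Boor recursion, and the three preset scenarios above.
These sizes were chosen so the entire suite re-runs in minutes on one
core; the estimator itself scales to realistic recordings because the
expanded matrix is sparse and LSMR touches only its nonzeros.

## Known limitations

* No automatic selection of the number of splines or the temporal basis
  resolution.
* No mixed-effects (group-level) estimation; exported betas are intended
  for standard second-level statistics.
* No lagged expansion of time-continuous covariates (a continuous
  covariate enters as a single column, not as a temporal response
  function).
* The EEG-container import adapter is intentionally absent from the core;
  plain delimited/binary interchange is the supported path.
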