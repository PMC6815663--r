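# erpdeconv

Overlap-corrected regression ERPs (rERPs) for continuous multichannel
electrophysiological recordings, in R.

## The problem

Event-related potentials are traditionally estimated by averaging epochs
around event onsets. In realistic paradigms — speeded responses,
eye movements during trials, fast multisensory streams — the brain's
responses to neighbouring events overlap, and averaging mixes them:
condition differences in *timing* (e.g. faster reaction times for faces
than houses) masquerade as condition differences in the *brain response*.
`erpdeconv` is for EEG/MEG (and pupillometry, skin-conductance, …)
researchers who need to disentangle overlapping event-locked responses
and simultaneously control linear and non-linear covariate effects.

## The model

The continuous recording is modeled as a linear superposition of unknown
event-locked responses. With instance-level design matrix $X$ (one row
per event, one column per coded predictor), *time expansion* builds a
sparse matrix $X_{dc}$ spanning the whole recording — each predictor
column becomes one column per local time point $\tau$ of the estimation
window, and every event writes its predictor values into the rows around
its onset, overlapping contributions being summed. The model

$$\mu_t = X_{dc,t}\,\beta, \qquad y_t \sim \mathcal N(\mu_t, \sigma)$$

is solved per channel by sparse iterative least squares (LSMR) or
cross-validated elastic net (glmnet with contiguous temporal CV blocks).
The estimated $\beta$, reshaped over $\tau$, are overlap-corrected rERP
waveforms. Models are written per event type in Wilkinson notation,
with GAM-style non-linear covariates:

```
y ~ 1 + cat(is_face) + spl(luminance, 5)     # stimulus events
y ~ 1                                         # button-press events
```

`spl()` expands a covariate into cubic B-splines on quantile knots
(basis count = knot count − 4), `2dspl(a, b, n)` into an $n^2$-column
tensor basis, `circspl(x, n, lo, hi)` into periodic splines. Time
expansion can use stick (FIR) functions — the default — or temporal
spline / truncated Fourier bases; truncating the Fourier set at harmonic
$K$ low-passes the estimate exactly. Artifact stretches are detected by
a moving-window peak-to-peak threshold and *blanked* (zeroed) in
$X_{dc}$ rather than cut out, so clean neighbouring overlap is kept. A
mass-univariate twin fit of the identical model (no overlap correction)
is built in for comparison.

## Worked example

Simulate 5 s of heavily overlapped data (inter-event intervals
normal(0.25 s, 0.05 s), boxcar response kernel), then deconvolve with an
intercept-only stick-basis model:

```r
library(erpdeconv)

sc  <- preset("fig10_boxcar", seed = 1)
sim <- simulate_scenario(sc)
X   <- expand_model(sim$events, model_spec("stim", "y ~ 1", c(0, 0.8)),
                    sim$n_samples, sc$srate)
X
#> <expanded design> 1000 samples x 161 columns (1 event type(s), 1.74% nonzero)

fit <- fit_lsmr(X, sim$data)
fit
#> <fit> lsmr: 1 channel(s) x 161 coefficient(s), sigma 7.009e-10

max(abs(fit$coefficients[1, ] - sim$truth$stim$kernel))
#> [1] 1.468829e-09
cor(fit$coefficients[1, ], sim$truth$stim$kernel)
#> [1] 1
```

The 19 simulated responses overlap their neighbours roughly threefold,
yet the recovered intercept time-course equals the true boxcar kernel to
about $10^{-9}$ (a naive epoch average is badly distorted — try
`fit_mass_univariate()` on the same data). `extract_erps()` turns
coefficients into waveforms, `evaluate_spline_effect()` evaluates
non-linear effects at chosen covariate values relative to the model's
reference point, `baseline_correct()` subtracts a baseline-window mean
from the betas, and `export_long()` writes a long-format CSV:

```
"channel","event_type","term","effect","time_s","beta"
1,"stim","1","(Intercept)","0","7.28682534559e-10"
1,"stim","1","(Intercept)","0.005","3.92042638934e-11"
...
```

A command-line front end (`exec/erpdeconv`) wraps the same functions:
`erpdeconv simulate` writes a simulated recording and event table,
`erpdeconv fit --config config.yaml` runs the full pipeline
(import → design → time expansion → artifact blanking → solve → export)
from a YAML configuration, `erpdeconv massuni` adds the mass-univariate
twin, `erpdeconv export` reshapes the long CSV to a wide matrix. See
`?run_pipeline` for the configuration schema and the package vignette
(`vignettes/overlap-deconvolution.Rmd`) for the methods account.

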