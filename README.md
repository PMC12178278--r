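# psft

Voxel-wise **population spatial frequency tuning** (pSFT) estimation from
fMRI BOLD time series, and analysis of how feature-based attention
modulates it.

## What problem this solves

Early visual cortex encodes spatial frequency (SF) — the density of
spatial detail — and each fMRI voxel pools many neurons with different SF
preferences. Given a per-second stimulus sequence of band-limited probes
with known center SFs and a voxel's BOLD percent-signal-change series,
this package estimates the voxel's aggregate SF response profile: its
preferred SF (peak) and tuning bandwidth. Comparing those estimates
between attention conditions (attend a 0.5 cpd letter stream, attend a
2 cpd letter stream, or attend fixation as baseline) quantifies how
attending an SF reshapes population tuning across the visual field —
e.g. attractive shifts of the peak toward the attended SF.

It is aimed at visual/computational neuroscientists who want a tested,
desk-scale implementation of the full estimation-and-inference chain, and
it ships a synthetic-data generator with known ground truth so every
stage is verifiable by parameter recovery without any scan data.

## The model

A voxel's response to SF `f` is log-Gaussian,

    R(f) = exp( -(log f - log mu)^2 / (2 sigma^2) ),

with peak `mu` (cpd) and bandwidth `sigma`. The predicted BOLD series is

    B(t) = beta0 + beta * ( R[f(t)] * h )(t),

where `h` is a gamma hemodynamic impulse response (time constant 1.08 s,
phase delay 3, onset delay 2.05 s) and `f(t)` the per-TR stimulus SF
(blanks carry a 1e-4 cpd sentinel). Per voxel and condition, blocks are
spliced across runs (18 per condition in the default 9-run session) and
`(mu, sigma, beta, beta0)` are fitted by a 10×10 coarse grid, a 100×100
fine grid, then bounded nonlinear least squares within
`mu ∈ [0.009, 6]`, `sigma ∈ [0.1, 4]`, `beta ∈ [-25, 25]`,
`beta0 ∈ [-10, 10]`. Downstream: pRF- and fit-based voxel selection with
a 3-SD group outlier screen, attentional modulation indices
`AMI = 100 (A - B)/(A + B)`, octave dissimilarity
`log2(mu_baseline / attended_SF)`, subject-wise slopes, bootstrap Cohen's
d, noncentral-t minimum detectable effects, and repeated-measures
correlation. See `vignettes/psft-methods.Rmd` for the full account.

## Worked example

```r
library(psft)

pop    <- sample_population(60, seed = 1)                  # ground truth
models <- default_shift_models(peak_slope = -10, bandwidth_slope = 3)
sched  <- build_session_schedule(9, seed = 1)              # 9 runs x 6 blocks
pop    <- calibrate_noise_sd(pop, sched[[1]],
            build_probe_sf_sequence(sched[[1]], seed = sched[[1]]$seed))
sess   <- simulate_session(pop, sched, seed = 1, models = models)

fits <- do.call(rbind, lapply(psft_conditions(), function(cn)
  fit_population(sess, cn)))
kept <- select_voxels(pop, fits)
attr(kept, "attrition")
#>          input      after_prf     after_psft after_outliers
#>             60             54             54             53

mod <- compute_modulation(as.data.frame(kept), pop)
subject_slopes(mod, outcome = "ami_peak")
#>   subject roi condition predictor  outcome  slope intercept n_voxels
#> 1      S1  V2 AttendLSF    dissim ami_peak  -8.07    -3.323       23
#> 2      S1  V3 AttendLSF    dissim ami_peak -18.34     9.414        7
#> 3      S1  V1 AttendLSF    dissim ami_peak -10.72     2.034       23
#> 4      S1  V2 AttendHSF    dissim ami_peak -11.56    -2.728       23
#> 5      S1  V3 AttendHSF    dissim ami_peak  -6.35     4.223        7
#> 6      S1  V1 AttendHSF    dissim ami_peak -11.07     0.754       23
```

The attrition log shows 6 of 60 voxels failing the pRF screen and one
removed as a 3-SD outlier. The fitted slopes of peak-AMI against octave
dissimilarity scatter around the generating value of −10 %/octave
(negative = attractive shift toward the attended SF); the small-count V3
groups scatter most. A single-voxel fit looks like:

```r
cc <- concatenate_condition_blocks(sess, "AttendFixation")
fit_psft(rebaseline_to_blanks(cc$series, cc$sf_track)[1, ], cc$sf_track)
#> pSFT fit: mu = 0.3597 cpd, sigma = 1.289, beta = 1.339, beta0 = -0.3419
#>   SSE = 120.481, R2 = 40.84%, converged = TRUE
```

against a ground truth of `mu = 0.380`, `sigma = 1.408` for that voxel —
about 0.08 octaves of peak error at the ~40% variance-explained noise
level the generator was calibrated to.

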