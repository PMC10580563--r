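---
title: "Methods: simulating and analyzing closed-loop DMN/FPN neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing closed-loop DMN/FPN neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropda)
```

neuropda implements, at desk scale, the complete computational chain of a
mindfulness-based real-time fMRI neurofeedback (mbNF) protocol for
adolescents with depression symptoms: personalized localization of the
default mode network (DMN) and frontoparietal network (FPN) from
resting-state data, a per-voxel incremental GLM that turns each incoming
EPI volume into network activation z-scores, a Positive Diametric Activity
(PDA) feedback controller with adaptive calibration, and the pre-registered
connectivity and dosing analyses. Because no study data exist for such a
protocol before acquisition, every stage is exercised against a synthetic
BOLD phantom with known ground truth; the package is therefore equally a
simulator and an analysis toolkit.

## The synthetic world

`make_phantom()` partitions a 24×24×24 voxel grid (2 mm isotropic) into
quasi-compact regions: the two DMN hubs (mPFC 300, PCC 300 voxels), the
remaining DMN (2000), the FPN (2600), white matter (800), CSF (400), and
unlabeled brain. DMN and FPN templates deliberately exceed 2000 voxels so
that top-2000 thresholding is a real selection, and both hub ROIs sit above
the 200-voxel floor used by the connectivity stage.

`simulate_run()` gives each region a latent AR(1) Gaussian timecourse with
unit variance. The DMN and FPN latents are cross-correlated at
`network_corr` (default −0.35, a moderate resting anticorrelation); the
mPFC and PCC latents load on the shared DMN factor so their mutual
correlation equals `mpfc_pcc_corr` (default 0.5). Voxel series add linear
drift, white noise (default SNR 1: unit network amplitude against unit
noise SD), a constant bright-brain intensity (so intensity-threshold brain
extraction is meaningful), and a motion-coupled nuisance term proportional
to the relative displacement trace — making the real-time engine's
nuisance-regression premise literally true, as rigid-body resampling is out
of scope. Motion itself is a slow random walk with optional spike volumes;
framewise displacement is the translation displacement plus 50 mm times the
rotation displacement, the standard head-radius convention.

One deliberate departure from a minimal reading of the design: the
unlabeled brain is subdivided into ~28 parcels, each with an independent
latent. A 35-component decomposition of a world with only seven sources
over-factors catastrophically — components split the planted networks into
sub-blobs and no single component covers a network. Real resting data
contain dozens of coherent sources, which is precisely why the protocol
extracts 35 components "to ensure broad coverage"; giving the phantom
comparable richness is a realism fix, not a tuning knob, and it is set once
here. HRF convolution is omitted throughout: feedback operates on the
measured signal, not stimulus-locked responses, and the correlational
structure the analyses rely on is fully expressed without it.

What a green test does *not* establish: the phantom has no k-space physics,
distortion, physiological noise, or true head-motion resampling, so
pipeline performance here bounds nothing about scanner data; it verifies
the algorithms, not the acquisition.

## Personalized network localization

`localize_networks()` follows the protocol's speed-first recipe:
brain extraction (an intensity threshold on the mean image standing in for
BET2), 5 mm FWHM Gaussian smoothing, 0.01 Hz high-pass (an FFT-domain
DC-and-low-frequency cut), concatenation of the two resting runs — the
second run is used only if it has ≥ 125 volumes, the longer run is trimmed
from the end, runs are mean-removed and translation-registered
(center-of-mass alignment; the synthetic frame is shared by construction,
so full affine registration is a non-goal) — then 35-component spatial ICA
and template matching.

The ICA is the package's own fixed-point implementation (none ships with
the R stack): temporal PCA to 35 whitened spatial sources, then symmetric
FastICA with the cube contrast. The cube (kurtosis) nonlinearity was chosen
because the sources of interest are sparse spatial maps, for which it is
well-suited — and because the logcosh contrast exhibited stable period-2
oscillations on this data class (correlated latents violate strict
independence). Residual oscillations are handled by deterministic
retries with increasing update damping (0 → 0.3 → 0.5 → 0.7); everything is
seeded and bit-reproducible.

Components are matched to each network template by the highest absolute
spatial correlation; a negative winner is sign-flipped so that "highest
positive weights" is well-defined (the protocol's wording leaves the
negative-correlation case open — the flip is this package's reading, logged
in the selection report, not an assertion of the authors' intent). If one
component wins both networks it serves the network with the larger
correlation and the runner-up serves the other. The personalized mask keeps
the 2000 strongest positive weights inside the template support, with ties
broken by ascending voxel index for determinism; fewer than 2000 positive
voxels yields all of them plus a warning. Unusable resting data (first run
shorter than 125 volumes) trigger the template-fallback path with
provenance recorded. Whether maps are z-scored before thresholding is
immaterial — ranking is invariant to monotone scaling — so maps are left in
unit-variance source scale.

## The real-time engine

Each voxel in the (one-voxel-eroded, 6-connectivity) brain-masked DMN and
FPN carries an incremental least-squares fit on eight nuisance regressors:
an intercept, the six relative head displacements, and a linear drift term.
The update is Gentleman's square-root-free Givens algorithm (AS 75), with
one shared triangular factor for the common design and per-voxel rotated
right-hand sides — one volume costs O(p² + p·n~voxels~) and runs in
milliseconds on the default grid, far inside the 1.2 s TR.

Numerical choices, all surfaced because the protocol leaves them open:

* **Intercept** — included. The protocol lists only motion and drift, but
  without an intercept, baseline z-scoring would conflate mean signal with
  activation; this is a deliberate, logged addition.
* **Drift scaling** — centered volume index scaled by the planned run
  length (known in advance), for conditioning; with an intercept present,
  any affine rescaling leaves residuals unchanged.
* **Early volumes** — residuals are defined as 0 until the design reaches
  full column rank; dependent columns get zero coefficients for that solve.
* **Baseline** — at volume 25 (30 s), residuals of volumes 1–25 from the
  volume-25 fit form one coherent baseline sample; their per-voxel mean and
  sample SD (n−1) are frozen. Sample-vs-population SD is unstated in the
  protocol; n−1 is this package's choice.
* **Efficiency weighting** — network activation is the inverse-baseline-
  variance weighted mean of voxel z-scores, weights normalized to sum 1.
  Zero-variance voxels are excluded and logged; if *every* voxel is
  noiseless (a degenerate phantom), the activation is defined as 0 rather
  than erroring.

A volume is an outlier when either network's |z| exceeds 2; non-finite
voxel values reject the volume and flag it. The incremental residuals are
verified against batch OLS refits at every timepoint to 10⁻⁸.

## The feedback controller

PDA = z~FPN~ − z~DMN~ sets the ball's per-volume velocity (gain default
0.05 screen units per PDA·volume: a sustained |PDA| of 1 reaches a circle
in ~20 volumes, a deliberate design choice). Outlier volumes pause the
ball; a hit flashes the circle for one movement-free volume, returns the
ball to center, and shrinks the hit circle's radius by 10%. Between runs
the gain multiplies by 1.25 (< 3 hits), 0.75 (> 5 hits), or 1 (3–5 hits).

The protocol's geometry is genuinely ambiguous: a hit is "reaching the
center of the circle", yet the circle's *radius* shrinks — a
center-reaching criterion is unaffected by radius. Both readings are
implemented behind `radius_mode`: `"boundary"` (default) maps a smaller
radius to a farther hit threshold (|y| ≥ 2 − radius), making the 10% shrink
consequential as the adaptive-difficulty device it is described as;
`"cosmetic"` keeps the threshold at ±1 and treats the radius as display
only. In boundary mode the ball is clipped at the current thresholds, so
positions can exceed 1 once a radius has shrunk — the stated [−1, 1] range
holds in cosmetic mode and for unshrunk radii. Radii reset at each run
start (per-run difficulty), the gain persists across runs; both behaviors
are configurable, as the protocol does not state them.

`run_session()` composes the full visit: localizer runs → personalized
masks (or template fallback) → the dose schedule — min15:
rest×2, no-NF, NF×5, no-NF, rest×2; min30 adds NF×5 and a third no-NF — with
the engine and controller per feedback run, gain carried forward, and the
four rest runs retained for connectivity analysis. No-neurofeedback runs
execute the engine and logging with an inert display.

## Post-hoc connectivity and the pre-registered models

`clean_run()` regresses out 12 motion terms (6 parameters + first
differences), the top-5 principal components of WM and of CSF (aCompCor), a
linear drift, and optionally the mean gray-matter signal (GSR; analyses are
meant to be reported with and without it), then bandpasses 0.008–0.09 Hz.
The bandpass is an order-4 Butterworth realized as its squared-magnitude
response in the FFT domain — the zero-phase gain that `filtfilt` would
apply, chosen because no time-domain filtering package is available; this
changes edge behavior slightly but not the passband. Volumes above the FD
censoring threshold (0.3 mm default — the protocol defers the exact value
to "current standards", so it is configurable and echoed in outputs) are
flagged after filtering and excluded from correlation (filter-then-censor,
logged). `roi_connectivity()` takes the product-moment correlation of the
mean mPFC and PCC series over retained volumes and Fisher-transforms it,
with r clipped to ±(1 − 10⁻⁷) so the transform is finite; a personalized
ROI under 200 voxels is replaced by its template and flagged.

`fit_primary_model()` and `fit_dose_model()` implement the Aim-1/Aim-2
mixed models (`fisher_z ~ time + mean_fd + age_c + (time | id)`, and with
`dose*time`), with the random-effects structure chosen by AIC between
random-intercept and random-slope variants. AIC comparison uses ML fits —
REML likelihoods are not comparable across random-effects structures — and
the winner is refit by REML. Wald 95% CIs and two-sided normal p-values are
reported (no Satterthwaite machinery is available in this stack; at the
planned sample sizes the normal approximation is standard). "Robust
estimation" when any outcome sits ≥ 3 SD from the mean is realized as
Huber-weighted iterative reweighting around the mixed fit — the protocol
names no estimator. Non-convergent mixed fits fall back, flagged, to a
fixed-effects fit; Bayesian refitting is deliberately out of scope beyond
this flagged hook. The dose model refuses single-dose data (the interaction
is inestimable) and also fits the pre-registered no-dose-main-effect
sensitivity variant.

`bh_adjust()` applies Benjamini–Hochberg step-up within the plan's two
secondary families (4 depression tests, 3 rumination tests).
`mnar_sensitivity()` refits the focal model with missing outcomes replaced
across a −2…+2 SD grid; `item_impute()` performs person-mean item
imputation below 10% item missingness and declares the score missing at or
above it.

`simulate_study()` closes the loop at cohort scale: a shared compact
phantom, per-participant latent mPFC–PCC coupling with a planted pre→post
Fisher-z drop, full cleaning and ROI extraction per run, and the tidy
records table the models consume. Measured effects are attenuated relative
to the latent drop (voxel noise, band-limiting) — the recovery tests assert
direction and significance, not the latent magnitude.

## Power

`rm_power()` uses the G*Power convention for within factors:
λ = f²·N·m/(1−ρ)·ε, df₁ = (m−1)ε (× (groups−1) for interactions),
df₂ = (N−groups)(m−1)ε, power = P(F′ > F~crit~). `required_n()` brackets by
doubling and bisects over integers. The measurement count m is an explicit
argument (m = 2, pre/post, for the primary design) because the protocol
does not report it.

Two independent checks pin the implementation down: it reproduces the
widely circulated reference case for this convention exactly (f = 0.25,
ρ = 0.5, m = 2 → N = 34 with λ = 8.5), and a Monte-Carlo repeated-measures
ANOVA oracle matches the analytic power within ±0.02 at 10⁴ replicates.
Under these verified conventions, f = 0.19, ρ = 0.3, m = 2 requires
**N = 79**, not the protocol's printed 76 (power at 76 is 0.789): the
printed figure corresponds to f ≈ 0.193, consistent with "f > 0.19" being a
rounded report of the value actually entered. The package reports the
computed value with λ, dfs and achieved power so the discrepancy is
auditable; it does not adjust inputs to match the print. The companion
"38 per group" figure for the dosing interaction is not reproducible under
any single standard convention and is treated as documentation.

## Randomization

`randomize()` assigns the 15- vs 30-minute arm by permuted blocks (size 2 —
the protocol does not state the mechanism) within the 16 strata spanned by
site, sex assigned at birth, prior mindfulness experience, and current
treatment, seeded and reproducible.

## Reproducibility and scale

Every stochastic step takes a named seed; derived sub-seeds keep streams
independent and below 2³¹. Default test and demonstration scales (24³ grid,
250-volume localizers, cohorts of tens) run the full localizer in seconds
and a complete session in well under a minute on one CPU; the protocol's
30–40 min mask-generation window applies to full-resolution data and is out
of scope here. I/O uses uncompressed NIfTI-1 (a minimal reader/writer
validated against nibabel), TSV motion/ground-truth traces, CSV records,
and JSON reports.
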