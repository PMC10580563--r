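# neuropda

Desk-scale simulation and analysis of **mindfulness-based real-time fMRI
neurofeedback (mbNF)** targeting the default mode network (DMN) and
frontoparietal network (FPN).

Clinical trials of real-time neurofeedback pre-register their entire
computational chain before a single volume is acquired: how personalized
network masks are derived, how each incoming EPI volume becomes a feedback
signal, how the display adapts to performance, and how target engagement is
tested afterwards. `neuropda` implements that chain end to end and — because
no study data exist before acquisition — pairs it with a synthetic BOLD
phantom with known ground truth, so every stage is testable today. It is
aimed at methodologists and trialists who want to exercise, audit, or power
such a protocol.

## What it computes

* **Synthetic acquisition** (`make_phantom()`, `simulate_run()`,
  `stream_volumes()`): a voxel grid partitioned into DMN (with mPFC/PCC
  hubs), FPN, WM, CSF and background parcels; latent AR(1) network
  timecourses with controllable DMN–FPN correlation *r* and mPFC–PCC
  coupling; drift, noise, motion traces with spikes, and volume-by-volume
  streaming that emulates the scanner feed.
* **Personalized localization** (`localize_networks()`): brain extraction,
  5 mm smoothing, 0.01 Hz high-pass, run concatenation (second run used
  only if ≥ 125 volumes; trimmed to equal length), 35-component spatial
  ICA, selection of the component maximizing |spatial correlation| with
  each network template, and binarization to the 2000 strongest positive
  weights inside the template — with a template-fallback path.
* **Real-time engine** (`init_engine()`, `ingest()`): one incremental GLM
  per masked voxel, updated by Gentleman's algorithm as each volume
  arrives, with nuisance regressors (intercept, six relative head
  displacements, linear drift). Residuals are z-scored against the frozen
  first-25-volume baseline and combined by inverse-baseline-variance
  ("efficiency") weighting into z<sub>DMN</sub>, z<sub>FPN</sub> and the
  **Positive Diametric Activity** metric

  PDA(t) = z<sub>FPN</sub>(t) − z<sub>DMN</sub>(t).

* **Feedback controller** (`feedback_step()`, `run_session()`): PDA sets
  the ball's velocity; |z| > 2 outliers pause it; a hit shrinks the hit
  circle by 10% within a run; between runs the gain ×1.25 / ×0.75 / ×1
  for < 3 / > 5 / 3–5 hits; 15- and 30-minute dose schedules (5 vs 10
  neurofeedback runs, 2 vs 3 no-neurofeedback runs, 2+2 rest runs).
* **Post-hoc analysis** (`clean_run()`, `roi_connectivity()`,
  `fit_primary_model()`, `fit_dose_model()`, `bh_adjust()`,
  `mnar_sensitivity()`): 12-motion + aCompCor + drift (± GSR) nuisance
  regression, 0.008–0.09 Hz bandpass, FD censoring; Fisher-z mPFC–PCC
  correlation; the pre-registered mixed models
  `fisher_z ~ time + mean_fd + age + (time | id)` (and `dose*time`) with
  AIC-chosen random effects, Huber-robust triggering, BH families, and an
  MNAR replacement grid.
* **Design utilities**: repeated-measures ANOVA power via the noncentral F
  distribution (`rm_power()`, `required_n()`) and stratified
  permuted-block randomization (`randomize()`).

## Worked example

```r
library(neuropda)

ph <- make_phantom(phantom_spec(), seed = 2)
ph
#> <npda_phantom> 24x24x24 grid, 2 mm voxels
#>   regions: DMN_mPFC=300, DMN_PCC=300, DMN_other=2000, FPN=2600, WM=800, CSF=400, other_brain=4248

sess <- run_session(ph, dose = "min15", feedback_effect = 0.6, seed = 11)
sess
#> <npda_session> dose min15: 11 runs (5 neurofeedback)
#>   hits per NF run: 1 2 3 3 2
```

The session localized personalized 2000-voxel DMN/FPN masks from two
simulated resting runs, streamed each feedback run through the incremental
GLM and controller, and recalibrated the gain between runs (1 hit < 3 →
gain ×1.25 for the next run, and so on). `autoplot(sess)` draws the ball
trajectories with hits marked.

Power for the within-participant target-engagement design (Cohen's
f = 0.19, α = 0.05, 2 occasions, r = 0.3 between repeated measures,
sphericity):

```r
required_n(power_spec())
#> # A tibble: 1 × 8
#>   n_total lambda   df1   df2 f_crit power n_per_group target_power
#>     <dbl>  <dbl> <dbl> <dbl>  <dbl> <dbl>       <dbl>        <dbl>
#> 1      79   8.15     1    78   3.96 0.805          79          0.8
```

79 participants reach 80% power under this noncentral-F convention
(λ = f²·N·m/(1−ρ)); the report carries λ, the degrees of freedom and the
achieved power so any convention difference is auditable.

A small simulated cohort with a planted pre→post connectivity drop,
analyzed with the pre-registered primary model:

```r
rec <- simulate_study(n_participants = 12, true_drop_z = 0.25, seed = 19)
glance(fit_primary_model(rec))
#> # A tibble: 1 × 11
#>   focal_term estimate conf.low conf.high   p.value random_effects   aic n_obs
#>   <chr>         <dbl>    <dbl>     <dbl>     <dbl> <chr>          <dbl> <int>
#> 1 time         -0.282   -0.414    -0.151 0.0000262 intercept       14.2    48
```

The negative `time` coefficient is the pre→post decrease in Fisher-z
mPFC–PCC connectivity — the protocol's target-engagement signature —
recovered here from fully synthetic imaging data.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance targets from
scratch against the installed package: the required sample size for the
within-participant power design, and the personalized mask voxel count
produced by running the full localizer pipeline on a freshly simulated
resting run. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/neuropda-methods.Rmd`) documents the
generative model and its defaults, every numerical choice the protocol
leaves open (baseline SD convention, drift scaling, hit-geometry
interpretation, filter realization, censoring threshold), and the known
limitations of phantom-based validation.
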