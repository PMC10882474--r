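---
title: "Receptivity, momentary affect, and the bias of model-triggered EMAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptivity, momentary affect, and the bias of model-triggered EMAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ambulatory studies prompt participants several times a day to report their
momentary emotional state, while wearables record physiology continuously.
Ground truth for affect exists only when the participant answers — and
whether they answer (their *receptivity*) is itself related to how they
feel. A trigger policy that uses a receptivity model to decide when to
prompt will therefore preferentially sample particular emotional states.
`receptr` quantifies that sampling bias on synthetic cohorts in which the
affect-receptivity coupling is planted and therefore known.

## The composite affect score

The instrument has nine negative items and four positive items, each on a
1-7 scale. The composite is the sum of the negative items plus the
inverted (`8 - x`) positive items, giving a 13-91 range where higher means
more negative. Events with any missing item are treated as nonresponses
for labelling: a partial response has no composite ground truth.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate the structure of a
45-participant, 10-day study: 10 prompts a day at uniform random gaps of
15-90 minutes, a 90-second window to open the survey (log-normal onset
latencies with median about 9 s and mean about 20 s; draws beyond the cap
become nonresponses), and four signal streams per participant.

The latent momentary affect trace is, per participant, a clipped AR(1)
process at 1-minute resolution plus occasional *negative-mood episodes* —
step elevations of `episode_magnitude` (default 20) points lasting 30-90
minutes, at about two per day. Defaults: mean 24.5, AR coefficient 0.985
per minute (mood half-life about 46 minutes — pseudo-labels tens of
minutes before a prompt remain informative, which is the premise of the
labelling design), innovation SD 1 (stationary SD about 5.8). The
realised composite mean sits near 26 on the 13-91 scale, concentated at
the positive end as ambulatory cohorts of healthy participants are.

Two causes of a missed prompt:

* **affect-driven** — response probability
  `plogis(base_response_logit - coupling_beta (affect - affect_mean))`,
  defaults 1.9 and 0.08, so responding is less likely in more negative
  states; with the activity mechanism this lands the overall response
  rate near the high-70s percent;
* **activity-driven** — with probability 0.08 the prompt is missed
  regardless of affect, and a walking-style accelerometer bout is placed
  around the notification.

Physiology follows the trace: minute heart rate is
`baseline_hr + hr_affect_slope (affect - affect_mean)` (default slope
0.35 bpm per score point) with RR intervals drawn around `60000 / HR`;
electrodermal activity is a slow tonic drift plus Poisson-rate phasic
responses whose rate rises with affect; skin temperature is a slow
sinusoid (random phase per participant) plus noise; the accelerometer is
baseline noise plus bouts. **Every coupling form is a stand-in chosen for
plausibility** — the study the package emulates deposits no data and
states no generative model — so passing tests demonstrate that the
pipeline recovers *planted* relationships at the stated sizes, not that
any particular physiological model is correct.

What the generator does not emulate: circadian structure, sensor
artifacts and detachment, engagement drift over days, floor effects in
item usage beyond what the score distribution imposes.

## Features, segmentation, labelling

The battery (see `feature_battery_names()`) covers time-domain HRV
(RMSSD, SDNN, CVSD, CVNNI, NNI20/50, PNNI20/50, and distributional
statistics with zero-cross counted as sign changes about the window
mean and the mode computed on values rounded to 2 decimals),
Lomb-Scargle band powers on the uneven RR tachogram (VLF is reported
missing on windows shorter than its period — a 1-minute window cannot
resolve 0.003 Hz), IQR-cleaned temperature statistics, electrodermal
raw/smoothed/block-wavelet statistics (1-level Haar block means at 1-s
and 0.5-s scales; first and second differences summarised), and
low-passed accelerometer means with a peak-count step stand-in. RR
streams are validated by the criterion-beat-difference rule: a beat is
rejected outside 300-2000 ms or when it deviates from the running median
of the last five accepted beats by more than
`max(0.2 x median, 50 ms)` (constants configurable).

Segments are 1-minute windows stepping by 30 s; historic windows extend
backward from the segment end. A segment ending within the label window
before a notification inherits that notification's labels (nearest
upcoming notification on overlap; segments after the notification are
never labelled). Splits are grouped at the notification level and
stratified by response; participants with fewer than two groups in
either class are excluded.

## Models

Receptivity: a random forest with inverse-frequency class weights and a
balanced per-tree bootstrap, hyperparameters chosen by exhaustive grid
search under grouped stratified cross-validation (selection metric F1,
responded positive). Affect: three dense ReLU layers (default widths
256/128/64) with a two-unit linear head `(mu, ln sigma)` trained
full-batch with Adam on the Gaussian heteroscedastic loss

```
L = (y - mu)^2 / (2 sigma^2) + log sigma .
```

With `sigma` fixed at 1 this is half the squared error; at fixed error
`e` the loss is minimised at `sigma^2 = e^2`, so the second output is an
error-scale estimate. The network trains on the standardised score scale
and predictions are mapped back and clipped to 13-91 (the scale is
bounded; ReLU networks extrapolate linearly). Predictions with
`sigma >= 6` score points are filtered out before any affect inference,
mirroring the source procedure's cutoff; the comparison is strict.

Per-participant normalisation supports two modes: `"train_stats"`
(default; test rows transformed with training statistics — leakage-safe)
and `"literal"` (each partition normalised with its own statistics,
reproducing the original evaluation procedure). The 99%-variance PCA
projection is fitted on training rows only and feeds every model except
the forest.

Baselines: a classifier sampling labels i.i.d. from the training
distribution — its true-positive fraction is analytically
`p_train x p_test` — and a regressor drawing from
`Normal(mean, SD)` of the training scores, clipped to the scale.

## The relationship analysis

Model-quality metrics (accuracy/precision/recall/F1, RMSSE as RMSE of
the composite) are computed on held-out notification groups only. The
relationship analysis — agreement (Cohen's kappa between predicted
response and predicted-positive-state, binarised at the participant's
training-median composite; point-biserial between predicted response and
predicted score), cluster profiles, ECDF comparisons, and the trigger
bias — uses predictions on *all* labelled segments: inferring affect at
every nonresponse moment is the point of the exercise, and nonresponse
groups never contribute affect labels to training in any case.

Clustering selects the `m = 10` features most correlated with
receptivity, then k-means (maximum 300 iterations, multiple restarts)
with the candidate k chosen by mean silhouette (default candidate set
`{2}` in the pipeline, matching the two-cluster design). Profiles report
per-cluster receptivity rates, mean reported PA/NA/composite, the
chi-square test of cluster x response independence, and a one-way F on
participant-mean-centred composites — the within-participant contrast a
repeated-measures analysis targets, used here instead of a mixed-model
engine.

The trigger-bias estimate contrasts mean predicted affect between
predicted-nonresponse and predicted-response segments. Because models are
personalised, the contrast is computed per participant and averaged;
pooling segments would weight participants by how often their model
predicts nonresponse. It is reported in score points and in units of the
SD of reported scores. Bimodality of the nonresponse prediction density
is described by the count of local maxima of a Gaussian kernel density at
the Silverman bandwidth.

## Desk-scale simulation profile

`desk_config()` is the package's profile for simulation studies (and the
acceptance suite): 5 participants x 2 days x 10 prompts/day, EDA at 4 Hz
and accelerometer at 16 Hz (features are rate-aware; the couplings live
at minute scale), the 5-minute label window, momentary + 5-minute
lookbacks, the single most-common forest permutation
(60 trees, depth 3, leaf 2, split 2, sqrt features) with
prevalence-calibrated prediction, and a 5-member ensemble of small
(8/4) networks with weight decay 0.3 trained ~1200 epochs, whose
mixture-moment sigma adds epistemic spread that the sigma filter can act
on. Choices that deserve a word:

* **5-minute label window.** With only 20 prompts per participant, the
  wider windows multiply segments per notification without adding
  independent information, while their labels sit up to 30-120 minutes
  from the prompt. At 5 minutes the label's autocorrelation with the
  latent trace is ~0.96 and runtime drops fivefold. The package default
  remains 30 minutes, the window the emulated study selected for its
  data volume.
* **Calibrated forest prediction.** Balanced-bootstrap forests overstate
  minority votes; thresholding the nonresponse vote fraction at the
  training-prevalence quantile restores the expected nonresponse rate
  while keeping the forest's ranking.
* **Small, strongly-decayed network ensemble.** Each participant
  contributes only ~14 training notification groups; segments within a
  group are near-duplicates. Without heavy regularisation the network
  memorises groups; the ensemble's member disagreement feeds the
  uncertainty filter.

At this scale the per-cohort trigger-bias estimate rests on roughly five
nonresponse groups per participant, so its across-seed dispersion is
inherently large; the null-calibration study (20 decoupled cohorts)
checks that it is centred on zero, and the planted-coupling study checks
the direction and the cluster/ECDF patterns. Single-cohort estimates at
this size should be read as directional, not quantitative.

A candid note on the bimodality descriptor: under the generator's
defaults the affect-driven nonresponse component is an upshifted tail of
the ordinary-state distribution rather than a well-separated cluster, so
the kernel-density mode count frequently reports a single mode — even on
the latent scores with a perfect model, and at full cohort scale. The
two-component structure is better read from the cause-stratified latent
means (which differ by construction) and from the right shoulder of the
nonresponse density than from a mode count.

## Numerical notes and limitations

* Determinism: every stochastic stage derives its seed from the run
  seed; identical configurations reproduce byte-identical analyses.
  Forest fits additionally depend on the R RNG stream, which the
  pipeline seeds per participant.
* Degenerate inputs: constant features pass through normalisation with
  scale 1; constant-variance correlation checks are flagged undefined
  rather than propagating NaN; empty prediction strata are flagged.
* The Lomb-Scargle band powers use a frequency grid at twice the natural
  resolution; a band whose lowest frequency is unresolvable in the
  window is missing, not zero.
* Zero-phase filters use reflection padding to suppress edge transients
  on short windows; streams are filtered once per participant (the
  filters are linear and time-invariant) rather than per window.
* Kappa/point-biserial units are segments; a notification-level
  aggregate can be formed from the per-segment predictions if desired.
* The package makes no causal claims: the bias estimate describes what a
  receptivity-triggered design would collect, under models trained and
  evaluated within the same cohort.
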