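---
title: "Methods: single-trial conditioning dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial conditioning dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condadapt)
```

`condadapt` analyses how conditioned responses evolve over a long
differential-conditioning block: a CS+ intermittently reinforced by an
aversive US, a CS− never reinforced, and ~120 trials so that adaptation
has room to unfold. This vignette explains each stage's model and
assumptions, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the design decisions
made where the methodology was genuinely open.

## The experimental design generator

`generate_design()` builds one block: equal numbers of CS+ and CS− trials
in pseudo-random order, 1-s cue presentations, and intertrial intervals
drawn from a normal distribution with mean 4.6 s and SD 1.5 s, truncated
below at 1.5 s (the untruncated distribution has ~2% of its mass below
that floor, so truncation shifts the realised mean by only ~0.07 s, well
inside sampling noise for a 120-trial block). "Pseudo-random" is
operationalised as *no more than four consecutive trials of one
condition*; sequences are drawn sequentially with restart on the rare
dead end.

Reinforcement is exact-count, not Bernoulli: the first four CS+ trials
are always paired with the US (onset 0.5 s after CS onset, 1-s duration,
co-terminating with the cue), and exactly `round(0.25 × 56) = 14` of the
remaining 56 CS+ trials are paired, for 18 reinforced trials per block.
A rate description like "25% of CS+ trials" is ambiguous between *all*
CS+ trials and the post-initial remainder; we adopt the remainder
reading, under which the realised rate among non-initial trials is 25%
exactly. Reinforced trials are simulated in full (including the US-evoked
response) but excluded from every downstream analysis, because US-evoked
activity contaminates the cue response.

## Forward model for ROI BOLD data

`simulate_bold_roi()` is an explicit linear forward model: trial $t$
contributes $a_t \, v_t \, h(\tau - \text{onset}_t)$ per voxel, where
$a_t$ is the planted amplitude, $v_t$ the trial's voxel pattern and $h$
the boxcar-convolved canonical HRF. The pattern is
$v_t = (1 - c_t)\,p_{\text{shared}} + c_t\,p_{\text{cond}}$ with
separation coefficient $c_t \in [0, 1]$; the heterogeneity components of
$p_{\text{CS+}}$ and $p_{\text{CS−}}$ are built exactly orthogonal, so
$c = 0$ gives identical condition patterns (dissimilarity 0) and $c = 1$
uncorrelated ones (dissimilarity 1). Patterns have unit mean, so the
ROI-average response per trial equals $a_t$ up to sampling noise — the
same simulation drives both the univariate and the pattern analyses. A
polynomial drift per voxel, white noise, and a baseline of 100 complete
the model.

Two consequences are intentional. First, the simulator uses the same
regressor construction as the GLM, so the noiseless β series reproduces
the planted trial-by-voxel amplitudes to machine precision — the
round-trip test separates estimator bugs from model mismatch. Second,
the simulator emulates an ROI in isolation. It does **not** emulate:
spatially structured (AR) noise, physiological cardiac/respiratory
aliasing, motion, susceptibility dropout, or the surrounding brain.
Passing tests therefore demonstrate correctness of the estimators under
the stated linear model, not robustness to every artefact of real
recordings.

### Global scaling in ROI-only simulations

`global_scale()` divides each scan by its spatial mean (×100), the
conventional proportional scaling used to remove the global signal. In a
whole-brain recording the global mean is dominated by thousands of
non-task voxels; in a 30-voxel simulated ROI the spatial mean *is* the
planted signal, and proportional scaling removes it to machine precision.
`estimate_beta_series()` therefore keeps scaling on by default (the
realistic preprocessing path, and both on/off paths are supported as a
control analysis), while `pipeline_config()` turns it off for synthetic
runs. This is a property of the simulation geometry, not of the scaling
operator, and the scaling operator itself is tested directly (per-scan
mean exactly 100, idempotence, gain invariance).

## β-series estimation

Every stimulus is a regressor: one column per CS trial (boxcar of the
trial duration convolved with the double-gamma HRF — response delay 6 s,
undershoot delay 16 s, unit dispersions, ratio 1/6, 32-s support, peak
normalised to 1), optionally one column per US event (default on; the
alternative of folding the US into the paired-trial regressor is
supported via `include_us_regressors = FALSE`), then nuisance columns and
an intercept. Regressors are built at 1/20th of the TR and sampled at
scan times; each column is normalised to unit peak so a β of $b$ means a
peak evoked response of $b$ signal units.

All trials of a block enter one GLM (the classic β-series formulation)
rather than the iterated one-trial-versus-rest variant; with ~5.6-s
onsets and a 1.98-s TR the single-model design is well conditioned, and a
condition-number warning (default bound 1e8) plus a rank check guard the
pathological cases. Estimation is plain per-voxel OLS; a ridge option
exists but is off by default, since the method specifies an ordinary GLM.

High-pass filtering regresses each voxel on a discrete-cosine basis
spanning periods ≥ 128 s. The same basis is appended to the design matrix
as confounds, which by Frisch–Waugh makes the trial βs identical whether
the data are pre-filtered or not — data and regressors are treated
consistently.

## Univariate dynamics

The per-trial ROI value is the mean β across voxels (the natural
ROI-level summary when a single amplitude per trial is required).
`split_early_late()` assigns trials with onset < 336 s (5.6 min) to the
early period — splitting on time-on-task, not trial count, avoids biasing
periods toward either stimulus; the boundary is open on the right (onset
exactly 336 s is late). Early/late differentials are tested across
subjects with a paired *t* test per ROI and Benjamini–Hochberg FDR across
the ROI set; the per-subject-then-paired-t reading is the only one
consistent with a paired test.

`smooth_curves()` uses a Nadaraya–Watson Gaussian kernel over onset time,
with the kernel SD expressed in trials (default 5) times the mean
inter-trial spacing. The source method does not state its smoother width;
5 trials (~28 s) suppresses trial-to-trial noise while preserving a
change of trend at mid-block, and `smoothing_sensitivity()` re-runs the
analysis at σ ∈ {3, 5, 8} so conclusions can be checked against this
choice. Kernel weights are renormalised at the block edges (no padding),
so constants are reproduced exactly but the smoother has the usual
boundary bias for trends. The differential curve is the smoothed CS+
curve minus the smoothed CS− curve; because the two conditions are
smoothed over different trial sets, an additive condition-independent
drift $g(t)$ cancels exactly only when constant, and to a few percent of
its amplitude when slowly varying — the differencing is a
variance-reduction device, not an exact projection.

The per-trial contrast series — the smoothed CS+ minus smoothed CS−
values evaluated at the unreinforced CS+ onsets — is how interleaved
conditions are reduced to a single series for change-point analysis (the
source method leaves this construction unstated; evaluation at CS+ trial
times keeps one value per analysed CS+ trial). The adaptation slope is
the OLS slope of this series against trial index.

## Change-point analysis

`cusum_chart()` cumulates deviations from the series mean; the magnitude
of change is max − min of the chart; `permutation_confidence()` reorders
the series 1000 times and reports the percentage of permuted magnitudes
*strictly* smaller than the observed one (ties count against
significance), compared to a 95% threshold. The change-point estimator is
the index maximising $|S_i|$: the method description says "maximum of the
chart", but an adapting (declining) series produces a predominantly
one-signed chart whose informative extremum may be a minimum; the
absolute value handles both directions and agrees with the signed maximum
whenever the chart is one-signed positive. Ties break to the earliest
index, and indices are reported 1-based.

Two caveats are deliberate. The permutation null assumes exchangeability,
which holds for raw contrasts but not for *smoothed* series, whose
autocorrelation inflates the observed magnitude relative to permuted
ones; group-level confidence on smoothed curves should therefore be read
as descriptive, while the calibration tests (type-I error within the 95%
binomial interval over 1000 null series) use unsmoothed input. Both
smoothed (default, matching the curve construction) and raw contrasts can
be fed to `cusum_test()`. Second, only a single change point is modelled.

`roi_concordance()` stacks per-subject change points into a subjects ×
ROIs matrix: one-way ANOVA with ROI as factor (df = k−1 and k(n−1)), PCA
on the correlation matrix — correlation, not covariance, because the
columns share units but not necessarily variance — and a Pearson test of
PC1 scores against a covariate. PC1's sign is fixed so its loadings sum
positive, making the covariate correlation's sign interpretable. Under
independence the PC1 variance fraction is exactly $1/k$
(`pc1_fraction_independent()`), the reference against which concordance
is judged.

## Representational dissimilarity

`window_dissimilarity()` slides a 50-trial window (step 2) over the
chronologically ordered *analysed* trials. Reinforced trials are excluded
before windowing — the source method does not say whether they count
toward the window length; excluding them keeps the CS+/CS− counts in
every window near balance. Within a window the per-condition mean voxel
patterns are Pearson-correlated, and $D = 1 - r \in [0, 2]$. The input β
series should come from spatially unsmoothed data, and a minimum-voxel
guard warns below 4 voxels, where pattern correlations are unreliable.

`group_curve()` averages on the Fisher-z scale (the variance-stabilising
scale for correlations) and transforms back before subtracting from 1;
per-subject curves and slopes stay on the plain $1 - r$ scale, because
z-averaging is specifically a group operation in this method — both
scales are trivially available from the stored `r`. Curves from different
subjects align by window index (same length, step and count); window
*centers* differ slightly across subjects because reinforced trials fall
at different positions, and are averaged for the group curve. The slope
regressor is the window index, since windows are equally spaced in
trials. `endpoint_test()` compares the first and last 10 windows per
subject with a paired *t* test.

## Heart rate

`instantaneous_hr()` converts RR intervals to a step function at 60/RR
beats/min; intervals outside a 0.2–3-s guard are linearly interpolated
from neighbours (rather than dropped, so the rate function stays defined
over every trial window) and reported. `weighted_bin()` computes exact
time-weighted means over 1-s bins from −1 to +5 s around each onset — the
integral of the step function is piecewise linear, so the bin values are
analytic, and the tests verify agreement with 1-ms numerical integration
to 1e−9. Each trial's bins are baseline-corrected by its prestimulus bin.

The per-trial scalar response is the mean change over 1–4 s post-onset
(the deceleration window; the orienting deceleration in this paradigm
peaks 2–3 s after cue onset, and the window is configurable). These
scalars then flow through the same early/late and smoothing machinery as
the β series, and the per-subject acquisition-mean CS+ minus CS−
difference is the covariate for the change-point concordance — the
cross-modal scalar is not pinned down by the source description, and the
acquisition-mean of the deceleration-window change is adopted as the
most direct summary of the conditioning effect.

The RR simulator integrates a rate function (baseline minus Gaussian
deceleration bumps, amplitude 5 bpm for CS+ and 1 bpm for CS− by default,
latency 2.5 s, width 1 s) and places beats where the integrated rate
crosses whole numbers. Rate noise is piecewise-constant on 1-s knots:
genuinely white noise on the integration grid would average out over an
RR interval and have no effect on the beat sequence. The simulator does
not emulate respiratory sinus arrhythmia or ectopic beats.

## The full pipeline and its study conditions

`run_full()` executes the whole chain for a configured number of
subjects, with every random stream derived deterministically from one
root seed. The default configuration is the study's condition set: 18
subjects, three ROIs, 120 trials, planted change point at trial 60 with
an early CS+ minus CS− difference of 1 (in units of the CS− amplitude)
declining linearly to 0, pattern separation decaying 0.8 → 0.1, BOLD
noise SD 0.5, HR deceleration difference decaying with the same
normalised curve. Habituation-style runs (`truth_type = "null"`) plant no
condition difference anywhere and are used to check that the early/late
FDR procedure stays silent under the null.

Test problem sizes are chosen to exercise each claim at the smallest
scale that makes the statistics meaningful: 1000 null series of n = 80
for permutation calibration, 200 replicates for change-point recovery
(2σ shift at trial 60 of 120, median |error| ≤ 5), 18 synthetic subjects
for the RSA endpoint test, and 50 habituation-style pipeline replicates
for the end-to-end null calibration.

## Known limitations

* The GLM assumes linear superposition of trial responses with a fixed
  HRF (no derivatives, no per-subject HRF variability).
* The CUSUM permutation test is anti-conservative on autocorrelated
  (smoothed) series; see above.
* One change point per series; gradual declines are localised at the
  chart extremum, which for a trend sits after the actual onset of
  decline.
* Pattern analyses need enough voxels; below ~4 voxels the dissimilarity
  is noise-dominated (a warning fires).
* The synthetic data are an idealisation: white noise, polynomial drift,
  exact forward/inverse model match. Recovery results bound estimator
  correctness, not real-data performance.
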