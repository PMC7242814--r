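---
title: "Measuring neural dedifferentiation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neural dedifferentiation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dediffr)
```

## The scientific problem

Category-selective visual cortex responds preferentially to particular
stimulus classes: the parahippocampal place area (PPA) and retrosplenial
cortex (RSC) to scenes, the fusiform and occipital face areas (FFA, OFA) to
faces. With increasing age this selectivity tends to weaken — *neural
dedifferentiation* — and the degree of selectivity an individual retains
predicts memory performance. `dediffr` implements the two standard
measurement instruments for this phenomenon in an associative-encoding,
subsequent-memory design, together with a fully synthetic cohort generator
so that every stage of the analysis can be exercised and validated without
access to scanner data.

Two complementary selectivity metrics are provided, both computed from
single-trial response amplitudes ("betas") in a region of interest (ROI):

* the **univariate differentiation index**
  $$\mathrm{DI} = \frac{\mu_\text{pref} - \mu_\text{non\mbox{-}pref}}
  {\sqrt{(\sigma^2_\text{pref} + \sigma^2_\text{non\mbox{-}pref})/2}},$$
  where $\mu$ and $\sigma$ are the mean and SD across trials of the ROI-mean
  response to the region's preferred and non-preferred categories; and
* the **within − between pattern-similarity index**: the average Fisher-z
  transformed voxel-pattern correlation among same-category trial pairs
  minus the average among different-category pairs, with all pairs taken
  across different scanning sessions.

Both are scale-free: adding a constant to all betas or multiplying them by a
positive gain (differences in hemodynamic coupling) changes neither metric.

## The experimental design being emulated

The synthetic design generator reproduces the structure of a two-cycle
study–test experiment. Each participant studies word–image pairs across
four scanning sessions (two study blocks per cycle, 48 critical pairs per
block, half paired with a face and half with a scene image, interleaved with
24 null trials per sub-list), then is tested with the studied words plus new
words. Lists are pseudorandomized by rejection sampling under two
constraints: no more than three consecutive trials of the same image class
and no more than two consecutive null trials. The retry budget (default
1,000 shuffles per list) makes constraint failures explicit rather than
silent. Trials follow a fixed 4.5-s slot (0.5-s fixation, 2-s stimulus, 2-s
ITI), and each session contains a 30-s rest period midway, after which a
configurable number of filler trials (default 2) restart the stream; fillers
are never analyzed.

At test, a studied word is recognized ("old") with a per-category hit
probability; recognized words draw a source judgment (correct category,
"don't know", or the wrong category), and new words draw false alarms. Item
recognition is scored as `pR = hit rate − false-alarm rate` per category;
source memory uses the single high-threshold estimate
$$\mathrm{pSR} = \frac{h - 0.5\,(1-k)}{1 - 0.5\,(1-k)},$$
with `h` the proportion of recognized items given the correct source and `k`
the proportion given a don't-know response, collapsed across categories
(each recognized item has exactly two candidate sources, so guessing is
corrected at 1/2 and don't-know responses leave the guessing pool).
Participants with `pSR < 0.1` are excluded, as are participants with fewer
than `min_bin_trials` (default 10) study trials in any category ×
subsequent-memory bin.

Response-validity windows are 450–4500 ms poststimulus at study and
500–4500 ms at test; we treat both endpoints as inclusive ("between x and
y ms") and exclude trials with no response or multiple presses. The windows
are arguments, so an exclusive reading costs one line.

## The generative model of trial-wise patterns

For one participant and one ROI with `n_voxels` voxels, a trial of category
$c$ has voxel vector
$$\mathbf{y} = a_c + \kappa_c \,\mathbf{t}_c + \boldsymbol\varepsilon,
\qquad \boldsymbol\varepsilon \sim \mathcal N(0, \sigma^2 I),$$
where $a_c$ is a scalar mean amplitude added to every voxel (the univariate
component), $\mathbf{t}_c$ is a unit-norm template drawn fresh per
participant and category (the multivariate component), and $\kappa_c \ge 0$
weights the template's reliability. The ROI-mean response therefore has
across-trial SD $\sigma/\sqrt{n_\text{voxels}}$, and two same-category
trials correlate across voxels at approximately
$\kappa^2 / (\kappa^2 + n_\text{voxels}\,\sigma^2)$
(`kappa_from_reliability()` inverts this relation so parameters can be
stated as target correlations). Dedifferentiation is expressed directly in
the parameters: *attenuation* lowers $a_\text{pref}$ (and
$\kappa_\text{pref}$), *broadening* raises $a_\text{non-pref}$.

Two optional between-participant SDs, `amp_sd` and `kappa_sd`, add
individual differences in amplitude and pattern reliability. They default to
0 in `neural_params()` — the minimal model — but the packaged study
conditions set them to nonzero values because real group comparisons are
dominated by between-participant variance: without it, the denominator of a
group Welch t contains only trial-sampling noise and effect sizes become
implausibly large. With the packaged values the PPA age contrast lands in
the d ≈ 1–1.5 regime typical of this literature.

The BOLD forward model (`simulate_bold()`) pushes true single-trial
amplitudes through the same design matrix used for estimation — a 2-s boxcar
at each onset convolved with the canonical double-gamma HRF (response gamma
delay 6 s, undershoot delay 16 s, dispersions 1 s, undershoot ratio 1/6,
32-s support, unit peak) — and adds white noise. Because generator and
estimator share the convolution kernel, noiseless recovery is exact to
machine precision, which is the property the round-trip tests assert.

## Least-squares-all estimation

`build_lsa_design()` gives every modeled trial its own regressor in one
simultaneous GLM across concatenated sessions, with nuisance columns for the
six motion parameters (when supplied), one mean per session, and optionally
a rest-block box. Convolution happens on a microtime grid of TR/16 and is
sampled at scan onsets. `fit_lsa()` is ordinary least squares with an
explicit condition-number guard (default 1e8): closely spaced events make
single-trial regressors collinear, and we prefer a hard failure advising
wider spacing over silently unstable betas. No high-pass filter or
autocorrelation model is applied; sessions are modeled with their own means
only. Trials are flagged for motion when any scan overlapping the trial's
window — onset to offset plus the HRF peak lag (≈5 s), a deliberately
conservative covering — exceeds 1 mm translation or 1° rotation on any axis,
with strict inequality at the threshold.

ROIs are defined by thresholding a second-level category-contrast t map at
uncorrected p < 0.01 (one-tailed in the contrast's direction) and
intersecting with an anatomical mask; the per-voxel statistic pools
participants across age groups (one-sample t on face-minus-scene difference
scores), since group is not a factor in ROI definition.

## Numerical and design choices

* **DI axis.** $\mu$ and $\sigma$ are computed across trials of the
  *ROI-mean* response, matching the "mean BOLD response per trial" reading;
  pooling trial × voxel observations instead is available as
  `estimator = "voxel_pooled"`. Sample SDs use the n − 1 denominator
  throughout.
* **Similarity scope.** The within-category average includes same-category
  pairs of *both* categories by default (`within_scope = "both_categories"`),
  which follows the letter of the standard description; restricting to the
  preferred category is exposed as `"preferred_only"` and reported alongside
  in the pipeline when requested. Pearson correlations are used (the Fisher
  transform presupposes them); pairs are unordered and counted once; and any
  pair with |r| = 1 is a hard error since its Fisher z is infinite.
* **Cross-session restriction.** Same-session pairs are excluded from both
  the within and the between average. Session-shared noise inflates
  same-session correlations only; the test suite shows that a naive
  all-pairs average is biased by such noise while the cross-session
  estimator is not.
* **Mixed ANOVA.** `mixed_anova()` uses the type-III multivariate
  linear-model route (effects coding) and reports Greenhouse–Geisser
  corrected p values for within-subject effects by default; Huynh–Feldt is
  an option, and HF epsilon is capped at 1. For two-level within factors
  sphericity cannot be violated and epsilon is exactly 1. Effect sizes are
  partial-η² = SS_effect / (SS_effect + SS_error). The choice of GG as the
  default nonsphericity correction follows the convention of the afex-style
  toolchain this analysis emulates.
* **Welch everywhere.** All pairwise group comparisons are Welch unequal-
  variance t tests with Satterthwaite df; Cohen's d uses the pooled
  (n − 1-weighted) SD, sign convention first-sample-minus-second (young
  minus older in pipeline reports). No multiple-comparison adjustment is
  applied to follow-up tests, mirroring standard reporting; users can adjust
  p columns with `p.adjust()`.
* **Interaction screening.** Regressions of memory on a neural index fit
  the index-by-group interaction first; when it does not reach α = 0.05 the
  additive model is refit and the index's partial correlation controlling
  for group is reported. The partial correlation residualizes both variables
  by QR projection, which remains well defined in the r → ±1 limit.
* **Factor scores.** Neuropsychological factor scores are computed by
  standardizing each test across the sample and weighting by the packaged
  varimax-rotated loadings (treated as fixed external weights, not
  re-estimated); Thurstone-style regression scoring is out of scope.
* **Reproducibility.** Every simulator takes a mandatory seed. The pipeline
  derives per-stage seeds from the master seed by seeding the generator once
  and drawing one sub-seed per stage; the run manifest records the seed and
  the MD5 of the serialized configuration, which suffice to reproduce any
  run bit-for-bit.

## What the generator does and does not emulate

The synthetic data reproduce the list structure, response-window censoring,
the two-component (amplitude + pattern) selectivity structure, group
differences as attenuation/broadening, and subsequent-memory conditioning.
They do **not** include spatial autocorrelation between voxels, scanner
drift, physiological noise, heterogeneity of behavioral response
probabilities across participants (between-participant variance in memory
scores is purely binomial, so behavioral group effect sizes run larger than
empirical ones), or any within-participant coupling between neural
selectivity and memory accuracy — consequently the synthetic partial
correlations between DI and memory are null, and the pipeline's
Table-6-style output should be read as a negative control rather than a
replication of the empirical brain–behavior association. Passing tests
therefore certify the estimators and the inferential layer, not the
realism of the noise model.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances while keeping the default suite fast:
design-count checks use the full default design; estimator-bias checks use
32-voxel ROIs with 96 trials per category against 10,000-replicate oracles;
the end-to-end power check runs 100 replications of a trimmed two-ROI
configuration (80- and 44-voxel ROIs, reduced lists) at n = 24 per group;
and null calibrations use 1,000–2,000 replications with binomial tolerance
bands. All tolerances are stated as multiples of the relevant Monte-Carlo
standard error.

## Known limitations

Item-level (trial-unique) similarity is deliberately out of scope, as are
searchlight analyses, voxel selection by top-N selectivity, signal-detection
models beyond the single high-threshold correction, and any preprocessing
(realignment, normalization, smoothing). The GLM assumes white noise within
session; an AR model is a natural extension point. The attenuation/
broadening decomposition compares raw category means and therefore — unlike
the DI and similarity indices — is not gain-invariant; this mirrors its
standard usage.
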