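---
title: "Background connectivity with a ground-truth simulator: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background connectivity with a ground-truth simulator: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backconn)
```

## The scientific question and the measurement model

Task fMRI confounds two sources of inter-regional correlation: shared
stimulus-evoked responses, and intrinsic ("background") fluctuations whose
coupling the task state may modulate. Background connectivity separates the
two under the assumption that they are *linearly superimposed*: after the
evoked response and nuisance signals are regressed out of each region's
timeseries, the residual correlation indexes intrinsic coupling in that task
context.

`backconn` implements this logic for a blocked 2x2 design in which
cue-action-outcome sequences are trained at two timescales (a stimulus set
learned three days before scanning vs one learned immediately before) and
actions are either predictive (95/5 outcome contingency given the button
press) or nonpredictive (50/50). Blocks of the two predictiveness levels
alternate within a run; runs alternate between the two stimulus sets; each
block holds 5 trials over 22.5 s and is followed by 18 s of fixation.

The per-voxel generative model of the simulator, and the measurement model
the analysis assumes, is

$$ y_v(t) = B\,\bigl(1 + \tfrac{e_c(t)}{100} + \tfrac{p_v(t)}{100}\bigr)
          + \gamma\, w_v\, g_r(t) + \mathbf{m}_v^\top \mathbf{n}(t)
          + \varepsilon_v(t), $$

where \(B\) is the baseline, \(e_c\) the condition's evoked response (percent
signal change), \(p_v\) event-locked multivoxel pattern signal, \(g_r\) the
region's intrinsic latent with loading \(w_v\) and gain \(\gamma\),
\(\mathbf{n}\) the nuisance set (6 motion parameters, white matter,
ventricles), and \(\varepsilon\) AR(1)-plus-white voxel noise. Because the
construction is strictly additive, simulating with and without any one
component changes the data by exactly that component -- the package's tests
exploit this superposition property directly.

### Condition-coupled latents

The hippocampal latent \(g_{hip}\) is a unit-variance AR(1) process. Inside
the analysis window of a condition-\(c\) block the EVC latent is

$$ g_{evc}(t) = \rho_c\, g_{hip}(t - \ell) + \sqrt{1 - \rho_c^2}\,\eta(t), $$

with \(\eta\) an independent unit-variance AR(1) fluctuation shared across
EVC voxels and \(\ell \in \{0, 1\}\) TRs of hippocampal lead. The latent
cross-correlation at lag \(\ell\) therefore equals \(\rho_c\) *exactly*
inside coupled windows, which makes condition-specific coupling a controlled
quantity rather than an emergent one. Between windows the regions are
uncoupled. The coupling state extends over the full 34.5 s analysis window
(block plus 12 s of fixation) rather than the 22.5 s block alone: the
analysis reads out coupling at exactly that granularity, and a
hemodynamically sluggish task state is the natural interpretation of the
window the analysis itself uses.

## The residualization chain

`residualize()` applies, per run and region:

1. **High-pass filtering** (`high_pass()`): projection onto the complement
   of a discrete-cosine basis with periods longer than 128 s.
2. **Nuisance regression** (`regress_nuisance()`): OLS removal of the six
   motion series plus white-matter and ventricle series (themselves
   high-passed, so the steps commute).
3. **FIR deconvolution** (`fit_fir()`): one delta regressor per TR bin per
   condition, 27 bins spanning the 40.5 s block + fixation cycle, pooling a
   condition's four blocks within the run. OLS estimates capture the evoked
   timecourse with no HRF assumption; the residual is the background series.

A deliberate numerical choice: although the steps run sequentially (the
order in which the confounds are conceptualized), the FIR regressors are
first residualized against the already-removed confounds, so by the
Frisch-Waugh theorem the sequential result equals the joint projection onto
all regressors at once. Without this, a naive chain of projections would
leave a small evoked remnant whenever the drift basis and the FIR basis are
not orthogonal, and the across-run control below would not be exactly null
even in the noiseless limit.

Estimation is OLS throughout. An optional single-iteration Cochrane-Orcutt
AR(1) prewhitening (`prewhiten = TRUE`) is available for sensitivity
analyses; group-level conclusions on the synthetic data do not depend on
first-level whitening, and the residual series itself is always the
full-length OLS projection so that window correlations stay interpretable.

### Evoked quantification

`evoked_psc()` averages the FIR estimates over bins 5-19 (1-based; the
block duration shifted 6 s forward for hemodynamic lag) and scales by the
voxel baseline. The generator's evoked shape is a saturating exponential
rise with time constant 4.5 s that decays over fixation -- any shape keyed
to block onset and confined to the 27-bin cycle is exactly representable by
the FIR basis, which is what makes "remove the evoked response" a
well-posed operation here.

## Connectivity variants

All variants z-score residuals within run, extract a 34.5 s window per
block (23 samples at TR 1.5 s; from block onset to 12 s after the last
trial ends), and Fisher-transform Pearson correlations (clipped at
\(|r| = 1 - 10^{-12}\)).

* **Within-run** (`background_connectivity()`): windows of a condition are
  concatenated within run, correlated between regions, and z values
  averaged across runs.
* **Across-run control** (`across_run_control()`): the same windows, but
  one region's residuals come from the stimulus- and order-matched partner
  run (both directions averaged). Any surviving evoked signal is shared
  across the pair, so nonzero control correlations expose incomplete
  removal; with FIR-representable evoked signal the control is exactly
  zero.
* **Time-lagged** (`lagged_connectivity()`): per *block*, the leader's
  0-33 s window against the follower's 1.5-34.5 s window (22 samples), z
  averaged over blocks then runs. The concatenated-then-correlate rule is
  used for the main variant and the per-block rule for the lagged variant
  deliberately -- each matches how the respective quantity is defined.
* **ROI dilation** (`dilation_profile()`): the target signal is rebuilt as
  the mean of the top-k voxels by localizer score (ties broken by voxel
  index) for k in {50, 100, 500, 1000, 5000, all}, then run through the
  standard pipeline.
* **Voxelwise** (`voxelwise_map()`): every target voxel against the seed
  signal; zero-variance voxels yield NA and are counted.

The window start index is `round(onset / TR)`; block onsets in the default
design land exactly on TR multiples, so the rounding is inert there.

## Multivoxel pattern similarity

`fit_event_glm()` estimates one amplitude per cue-outcome transition per
run (boxcar of the mean trial duration, clamped to 2188-2643 ms, convolved
with a double-gamma HRF; temporal derivatives by finite differences; the
single counter-predicted trial and missed trials get their own regressors
and are excluded from similarity; six motion covariates ride along).

In the primary scheme, predictive transitions keep (cue, action) identity
while nonpredictive transitions are averaged across actions to (cue,
outcome) identity. This balances the number of trials per pattern
(~5 per run in both conditions), which is what equates the
contrast-to-noise ratio of the pattern estimates across conditions -- the
package asserts this operationally (equal observation counts, matched
estimator variance on noise-only simulations) rather than via a CNR
formula. Betas are averaged across a set's four runs before similarity.

*Within-cue* similarity correlates the two patterns sharing a cue with
different outcomes; *across-cue* similarity pairs patterns with disjoint
cue and outcome stimuli (and different actions for predictive transitions,
mirroring the within-cue comparison). Both are computed from the identical
averaged patterns. Stimulus sets are never mixed, since they are presented
in separate runs.

The *resampled split control* (`resampled_split_similarity()`) re-models
nonpredictive transitions per (cue, action, outcome) and randomly splits
predictive trials into two partitions per (cue, action) -- about 2.5 trials
per run per pattern in both conditions -- then measures nonpredictive
within-cue similarity across different actions *and* outcomes, and
predictive similarity within partitions, averaging correlations afterwards.
Partitions are drawn per run under a dedicated seed with bounded retries if
one would be empty.

## Behavior

Choice RTs are summarized per condition after excluding missed trials and
RTs above 1500 ms (the boundary value is included: the response window is
(0, 1500] ms). Verbal-test eligibility demands perfect accuracy for
predictive sequences with at most one retake per test, the retake replacing
the original. The consistency of verbal predictions for *nonpredictive*
actions uses only the pre- and post-scan tests: each of the four
nonpredictive cue-action combinations contributes four responses, scored by
the modal-outcome proportion \(\max(k, 4-k)/4\), and the participant's
score is the mean over combinations (range [0.5, 1]; "fully consistent"
means 4/4 on every combination). The modal-proportion definition was an
open design choice; it is the simplest statistic for which "100%
consistent" is well defined, and it is invariant to outcome relabeling.

## Group inference

`rm_anova_2x2()` computes within-participant main effects and the
interaction as 1-df contrasts, for which \(F = t^2\) holds exactly (checked
against `aov()` with an `Error()` stratum in the tests). ROI-level tests
are two-tailed with no multiple-comparison correction. Voxelwise maps use a
sign-flip permutation test: participant difference maps are randomly
negated, the one-sample t map is enhanced with threshold-free cluster
enhancement (TFCE; E = 0.5, H = 2, 100 integration steps, 26-connectivity
-- the established defaults of the correction), and family-wise-error p
values are read from the maximum-statistic null. The TFCE kernel is
compiled (Rcpp) because connected-component labelling at 100 thresholds
runs inside the permutation loop; it is validated against a plain-R
flood-fill oracle and the single-voxel closed form \(v^3/3\).

## What the simulator does and does not emulate

Emulated: the full trial/block/run structure with matched run pairs and the
one counter-predicted trial per run; condition-modulated inter-ROI coupling
with optional 1-TR lag; FIR-representable evoked responses; event-locked
multivoxel patterns with controllable within-cue overlap; nuisance
contamination; AR(1)+white voxel noise; localizer scores, optionally
concentrating the coupled loading on high-scoring voxels
(`coupling_profile = "localizer"`) on top of a spatially uniform private
fluctuation, which is what makes connectivity *fall* as the ROI dilates.

Not emulated: spatial autocorrelation and smoothing, physiological noise,
head-motion spikes, registration/segmentation errors, full-brain coverage,
and the true effect sizes of the real dataset. Passing tests therefore
validate the estimators' logic and calibration under the stated model, not
claims about any real acquisition. Real-data effect sizes for connectivity
differences are not published as parameters anywhere we could adopt them
from, so the default coupling values (day3 0.35/0.15, no-delay 0.25/0.25)
are fixture choices that encode the qualitative result pattern
(an interaction driven by the 3-day conditions) at a plausible fMRI
correlation scale.

## Defaults and problem sizes

| Parameter | Default | Why |
|---|---|---|
| TR | 1.5 s | acquisition protocol |
| Runs / blocks / trials | 8 / 8 / 5 | study design (320 trials) |
| Trial pacing | 4.5 s | 22.5 s / 5 trials; components 1000 + <=1500 + 1000 ms |
| Run length | 330 s (220 TRs) | 6 s lead-in + 8 x 40.5 s |
| High-pass cutoff | 128 s | standard drift period |
| FIR bins | 27 | tiles one block + fixation cycle |
| Peak bins | 5-19 | block duration shifted 6 s for hemodynamic lag |
| Window | 34.5 s (23 TRs) | block start to 12 s after the last trial ends |
| RT cutoff | 1500 ms | scanner response window |
| rho (day3 p/np; nodelay p/np) | .35/.15; .25/.25 | fixture encoding the interaction |
| Latent AR(1) phi | 0.4 | smooth intrinsic fluctuations at TR 1.5 s |
| Noise AR(1) phi | 0.3 | simplest autocorrelated noise |
| Evoked amplitude | 1% PSC | typical blocked visual response |
| Pattern overlap (day3 p/np; nodelay p/np) | .2/.6; .4/.6 | differentiation strongest for remote predictive cues |
| ROI sizes | hippocampus 200, EVC 1000 voxels | desk-scale stand-ins for subfield and V1/V2 ROIs |
| Verbal consistency propensity | day3 0.88, nodelay 0.95 | cohort means ~0.88/0.95 with a minority fully consistent |

Validation suites run at deliberately reduced sizes chosen to keep each
property statistically decisive: coupling-recovery and lag-asymmetry checks
use 100 replicates of 4-run datasets with 6-8 voxels per ROI; the
permutation type-I check uses 20 null cohorts of 12 participants on a
16 x 16 x 8 grid with 500 sign flips each.

## Numerical conventions and degenerate inputs

* Sample i corresponds to \(t = (i-1)\,TR\); windows are half-open
  `[start, start + length)`.
* Correlations are clipped to \(|r| \le 1 - 10^{-12}\) before `atanh`.
* An exactly constant series is an error in `zscore_run()`. A residual
  series whose variance is numerically zero *relative to the voxel
  baseline* (below \(10^{-7} B\); only possible when the model removed the
  signal exactly) carries no background signal: it is zeroed, and
  correlations against it are 0 rather than the scale-invariant noise a
  Pearson correlation of rounding error would produce.
* Rank-deficient nuisance matrices drop columns with a warning; empty event
  regressors are dropped with a warning and reported as missing.
* Localizer-score ties in the dilation ranking break by voxel index, so
  top-k sets are stable and nested.
* Master seeds fan out to named sub-seeds (design, BOLD, behavior,
  resampling, permutation) via `derive_seeds()`, so any stage can be rerun
  in isolation and full runs are bit-reproducible.

## Known limitations

* The hemispheric averaging of the original ROI analyses is represented
  only as an optional averaging of simulated sub-ROIs; the simulator's ROIs
  are bilateral composites.
* FILM-style local autocorrelation correction is out of scope; OLS with
  optional global AR(1) prewhitening is the estimator.
* The consistency-score definition and the matched-pair assignment (runs
  paired in presentation order within a set) are interpretations where the
  protocol leaves details open; both are stated here and implemented in one
  place each.
* `simulate_cohort()` materializes whole datasets; `run_study()` streams
  participants to keep memory flat. Both derive identical per-participant
  seeds from the master seed.
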