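---
title: "Classifying postural sway indices as universal or individual-specific"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying postural sway indices as universal or individual-specific}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaylab)
```

## The problem

Quiet-standing balance is usually summarized by scalar indices of the
center-of-pressure (CoP) trajectory — sway area, mean velocity, spectral
slopes, sway-density and stabilogram-diffusion measures. Different indices
capture different things: some reflect the slow, putatively neurally
controlled component of sway; others reflect fast oscillatory dynamics that
depend mostly on body mechanics; still others mostly encode a person's
standing habits. `swaylab` implements a statistical screening pipeline that
sorts a battery of 73 classical indices into three groups:

* **universal** — the index's distribution is essentially the same for every
  subject, so it is a candidate descriptor of control mechanisms shared
  across healthy young adults;
* **individual-specific** — the index discriminates who is standing on the
  plate, usually because it tracks body parameters or personal habits;
* **other** — neither property holds robustly.

The study design the pipeline expects is a crossed layout: subjects measured
on several days, at several times of day, with several 70 s trials per
session (the default emulates 15 subjects x 3 days x 5 times x 4 trials =
900 trials at 60 Hz).

## The pipeline

1. **Preprocessing.** Both CoP channels are low-pass filtered with a
   fourth-order zero-phase Butterworth filter at 10 Hz. Velocities are
   central differences of the filtered position; an additional zero-phase
   low-pass (default 1.5 Hz, see "Numerical choices") is applied before
   velocity zero crossings are counted.
2. **Index battery.** All 73 indices are computed per trial with validity
   flags: positional means and crossings, 95% confidence-ellipse geometry,
   two-segment log-log PSD fits (Slope-L, Slope-H, critical frequency),
   band power and power frequencies (PF50/PF95), path length and mean
   velocities, Gamma fits of velocity inter-zero-cross intervals
   (log-Alpha, Beta), sway-density measures (MT/MP/MD over radii 2-5 mm),
   fractal dimension, sway-area rate, mean frequency, and
   stabilogram-diffusion quantities on linear and log scales.
3. **Elimination.** An index whose estimation failure rate across trials
   exceeds 10% is dropped. The critical-frequency and log-scale
   diffusion critical-point indices fail by construction whenever a record
   shows a single power-law regime, which reproduces the classical 73 to 65
   reduction on such data.
4. **Standardization and screening.** Conventionally log-named indices are
   log10-transformed; each index is standardized to pooled mean 0 / SD 1
   over all trials of all subjects; Lilliefors' test is run per subject and
   an index is kept for the discriminant step only if it passes for
   strictly more than 70% of subjects (11+ of 15).
5. **Discriminant selection.** Forward-stepwise multi-class LDA (pooled
   covariance, equal priors) ordered by an additional-information AIC (see
   below); apparent and leave-one-trial-out error-rate curves over the
   ordering; the individual-specific candidate set is the smallest prefix
   with both rates under 10%.
6. **VM-VV selection.** Per index, VM is the variance across subjects of
   the per-subject z-score means, VV the variance across subjects of the
   per-subject variances; indices within 0.35 of the origin (and not
   already individual-specific) are universal candidates.
7. **Correlation expansion and clustering.** Any index with |Pearson r| >
   0.8 to a member of a candidate group joins that group (one pass, no
   chaining); a group-average (UPGMA) dendrogram on the distance 1 - r
   summarizes redundancy structure.
8. **Mixed-model confirmation.** For each universal candidate, a REML
   linear mixed model with crossed random intercepts for subject, day,
   time and their two-way interactions decomposes the variance; the
   candidate is confirmed universal when the subject-to-residual variance
   ratio is at most 1.0.
9. **Interpretation.** Every index is correlated with the standardized
   moment-of-inertia proxy m h^2; a Wilcoxon rank-sum test compares |r|
   between the universal and individual-specific groups.

```{r pipeline, eval = FALSE}
cfg <- synth_config(seed = 1)      # the synthetic study design
ds <- generate_cop_dataset(cfg)
res <- sway_pipeline(ds$trials, ds$profiles)
print(res)
plot(res, type = "vmvv")
plot(res, type = "error_curves")
```

## The stepwise AIC

The subset-selection criterion treats every candidate subset on the same
footing: all models describe the full standardized data, and a subset `s`
asserts that only its variables carry class-mean information. Up to a
constant shared by all subsets, minus twice the profiled log-likelihood is
`N log Lambda(s)` with Wilks' `Lambda(s) = |W_s| / |T_s|` (within- over
total-scatter determinants restricted to `s`), and each selected variable
adds `p - 1` free discriminant-mean parameters for `p` classes, giving

    AIC(s) = N log(|W_s| / |T_s|) + 2 q (p - 1),   q = |s|.

A naive alternative — the raw Gaussian class-conditional likelihood of the
selected columns plus a parameter count — is not comparable across subsets
of different dimension (every added variable pays the `N (1 + log 2 pi)`
entropy term), and in practice admits only near-perfect discriminators.
The Wilks form is the standard additional-information criterion for
variable selection in discriminant analysis and behaves correctly in the
package's oracle tests: planted informative indices enter first, perfectly
redundant duplicates never both enter (a collinearity guard skips
candidates whose conditional variance given the selected set is below
1e-6 of their marginal variance), and on small problems the greedy search
almost always attains the exhaustive-subset optimum.

## The synthetic CoP generator

No public CoP corpus accompanies this kind of study design, so the
generator is a first-class, tested component. It is phenomenological
(spectral), not biomechanical. Each channel is

    CoP(t) = offset + slow(t) + fast(t) + very_fast(t) + noise(t)

with all three structured components synthesized by random-phase spectral
synthesis:

* **slow** — a two-segment power law: `f^-beta_slow` from 0.01 Hz up to a
  0.5 Hz knee, continuing as `f^-beta_high` (default exponent 3.5) up to
  5 Hz. The tail matters: without it the spectrum has a hole between the
  knee and the fast bump, the cumulative power curve develops a plateau,
  and PF50 becomes bimodal — tiny slow-power deficits fling it across the
  gap, which real CoP spectra (monotone, double-power-law) do not do.
* **fast** — a narrowband Gaussian bump centred at the subject's fast
  frequency (population mean 0.85 Hz within the 0.5-1.0 Hz band,
  bandwidth 0.07 Hz). Random spectral phases make it a stochastically
  amplitude-modulated oscillation, so inter-zero-cross intervals of the
  velocity have a proper spread rather than a degenerate point mass.
* **very fast** — the same construction centred at the subject's very fast
  frequency (population mean 1.8 Hz within 1.0-2.5 Hz, bandwidth 0.15 Hz).

Every generative parameter follows the crossed hierarchy `value =
population mean + subject + day + time effects + trial noise`, mirroring
the variance decomposition the mixed model estimates, so parameter-recovery
tests are possible.

**Planted structure.** The defaults encode the contrast the pipeline is
meant to detect:

* the slow component's shape (`beta_slow`, subject SD 0.015) and the
  component power *ratios* are population-shared, so spectral-slope and
  PF50 indices should come out universal;
* subject identity lives in (a) the stance offsets (subject SDs 6 and
  17 mm for ML and AP, sharing a latent postural-habit (lean) factor
  almost completely (correlation 0.97), so the two mean-position indices
  form one cluster), (b) a *common* amplitude factor applied to all
  components (subject SD 0.10 dex) that is coupled to the standardized
  moment of inertia (0.10 dex per SD), and (c) the fast and very fast
  frequencies (subject SDs 0.10 and 0.45 Hz) together with the very fast
  component's amplitude (subject SD 0.14 dex) — jointly a "very-fast
  content" axis that drives the Gamma-interval, velocity-zero-cross and
  PF95 indices. Mean-velocity, power,
  path-length, sway-density, Gamma-interval and velocity-zero-cross
  indices therefore discriminate subjects, and the amplitude-linked ones
  correlate with m h^2.

A deliberate design constraint: the slow and fast component amplitudes
carry no component-specific subject variance (only the shared factor).
If the fast amplitude had its own large subject SD, the slow/fast power
ratio — and hence PF50 — would inherit a subject effect, contradicting the
planted "PF50 is universal" structure. The very fast amplitude is the one
exception (subject SD 0.14 dex): its band carries only a few percent of
the total power, so PF50 is insensitive to it, while the interval and
crossing indices are strongly driven by it. Calibration of the absolute levels (slow
RMS 2.5/4.5 mm ML/AP, fast 0.8/1.25 mm, very fast 0.3/0.4 mm, measurement
noise 0.02 mm) keeps the raw index values in the magnitude ranges reported
for healthy young adults (mean AP offset ~51 mm, Slope-L near -1, PF50
near 0.33 Hz, Beta-AP near 0.1, MP3 of a few seconds, log mean velocity
near 1).

**What the generator does not emulate:** mechanistic inverted-pendulum
dynamics, intermittent control switching, non-Gaussian heavy-tailed
excursions, drifts or nonstationarity within a trial, and any dependence
structure between trials beyond the parameter hierarchy. Passing the
recovery tests therefore shows the pipeline recovers structure of this
spectral-hierarchical kind; it is not evidence about mechanisms that only
real data contain.

## Numerical choices

* **Zero-phase filtering.** Butterworth designs come from `signal::butter`;
  the forward-backward pass is implemented in C++ (direct-form II
  transposed) with odd-reflection padding of 3 x order samples *and*
  steady-state initial conditions per pass. The initial conditions matter:
  with zero initial state the first ~1 s of a 70 s record is distorted and
  even a constant input is not reproduced exactly.
* **Velocity zero-cross cutoff.** The additional velocity low-pass for the
  zero-cross indices defaults to 1.5 Hz. A strict 1.0 Hz cutoff caps the
  crossing rate at 2 per second — at most 140 crossings in 70 s — whereas
  the reported typical value for this index in comparable cohorts is about
  146, implying the effective filter passed content above 1 Hz. At 1.5 Hz
  the count keeps full sensitivity to the fast component and partial
  sensitivity to the lower end of the very fast band. The cutoff is
  configurable (`velocity_cutoff_hz`).
* **Welch PSD.** Hann window, 2048-sample segments (~34 s), 50% overlap;
  frequency resolution ~0.029 Hz, adequate for the 0.04 Hz band edge.
  Two-segment fits regress log10 PSD on log10 f over fixed bands
  (0.04-0.5 and 0.5-5 Hz) and intersect the lines analytically; slopes
  closer than 0.2 or an out-of-band intersection flag the record as
  single-power-law.
* **Sway density.** Residence times are computed exactly in C++ (one
  backward/forward scan per sample, all radii in one pass), smoothed by a
  0.5 s zero-phase moving average; alternating extrema are detected on the
  sign of the smoothed differences, and peak/valley pairs with prominence
  below 5% of the curve's range are pruned (plateau ripple and
  smoothing artefacts otherwise register as spurious peaks).
* **Stabilogram diffusion.** Mean-square displacement for all lags up to
  10 s via the FFT autocorrelation identity; short window (0, 1] s, long
  window [2, 10] s; planar diffusion coefficients use the 2-D Brownian
  convention (slope/4), channels slope/2.
* **Gamma fit.** Newton iteration on the shape profile score with the
  closed-form start; moment matching is the non-convergence fallback.
* **Mixed model.** `lme4::lmer` (REML) with random intercepts for subject,
  day, time and the three two-way interactions; boundary estimates report
  as 0. If the REML fit errors, balanced-ANOVA expected-mean-square
  estimates (truncated at zero, three-way interaction pooled into the
  residual) take over, flagged in the output. By default the decomposition
  is fitted for the universal candidates (plus their correlation
  additions); `mixed_all_indices = TRUE` fits every surviving index.
* **Degenerate inputs.** Constant channels, collinear trajectories,
  all-equal intervals and rank-deficient covariances are flagged
  (`degenerate`) rather than propagated; NA values are excluded pairwise
  from moments and tests, and the few trials with sporadic NA among
  retained indices are imputed at the pooled mean (z = 0) for the LDA step
  only.

## Problem sizes used by the test suite

The packaged checks run the full 15 x 3 x 5 x 4 design (900 trials of
4200 samples) for the pipeline-recovery and threshold-robustness studies
(20 seeded replicates), a 6 x 2 x 2 x 3 design for structural end-to-end
tests, and small purpose-built designs for the estimator oracles (e.g.
140 intervals for the Gamma fit, 12-variable problems for the
stepwise-vs-exhaustive comparison). These sizes were chosen to make every
statistical claim testable with comfortable Monte-Carlo margins while the
whole suite stays convenient to run locally.

## Known limitations

* The 73-index battery follows the conventional definitions, but several
  details (exact fractal-dimension variant, sway-density peak rules,
  diffusion windows) vary across the posturography literature; all are
  exposed in `sway_config()` and documented above, and conclusions that
  depend on them should be checked under the alternatives.
* The candidate rule "smallest error-curve prefix under 10%" is inherently
  sensitive near the error floor; on datasets whose curves flatten close
  to 10% the candidate set can change size appreciably between replicates
  even when the final three-way classification is stable.
* Lilliefors' test at n = 60 per subject has limited power against mild
  non-normality; the 70%-of-subjects retention rule inherits that.
* The generator's phenomenological character means mechanistic questions
  (what produces the slow component) are outside its scope by design.
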