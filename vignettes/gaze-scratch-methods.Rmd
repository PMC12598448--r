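---
title: "Methods: simulating and scoring gaze-contingent scratch experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring gaze-contingent scratch experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazescratch)
```

## The paradigm

In a gaze-contingent *scratch* experiment an infant first sees an image of
two salient objects placed in opposite corners (baseline, 5 s). The image is
then covered by a unicolored surface (transition, 3 s). In the contingent
phase every gaze point detected by the eye tracker removes a small square of
the cover at the gaze location, so the infant can "scratch" the picture free;
the phase ends when 20% of the screen is uncovered or after 30 s. Finally
the contingency is silently disrupted: the last still image stays on screen
for 5 s. A trial therefore lasts at most 5 + 3 + 30 + 5 = 43 s. Objects sit
on the falling diagonal (top-left / bottom-right, *drop*) or the rising one
(*rise*), counterbalanced over stimuli and participants.

The scientific question is whether infants *flexibly control* their gaze:
whether they direct it to where informative content can be uncovered, whether
that preference grows within a trial as the contingency is learned, and
whether it survives the disruption.

`gazescratch` re-implements the trial mechanics offline
(`simulate_trial()`), so recorded or simulated gaze can be replayed through
the exact phase schedule, cover bookkeeping, and stop rule, and the analysis
can be exercised end to end on synthetic data with known ground truth.

## AOI geometry and the differential looking score

The screen is partitioned into four corner quadrants by one vertical and one
horizontal split line (`build_aoi_layout()`). The two quadrants on the
condition's diagonal are the *object AOIs*; by default they jointly cover
55.72% of the screen. The split lines are shifted off-center symmetrically:
with relative splits $a = \tfrac12 + d$ in both axes, the diagonal quadrants
cover $a^2 + (1-a)^2 = f$, so $d = \sqrt{(f - 1/2)/2}$ realizes any
$f \ge 1/2$ exactly (for $f < 1/2$ the offsets take opposite signs,
$2(\tfrac14 - d^2) = f$). The *rise* layout is the mirror image of *drop*
across the vertical midline. Rectangles are half-open, so the four quadrants
partition the screen without gaps or double counting.

Looking is scored from fixations, not raw samples. For a phase window the
**differential looking score** is

$$\mathrm{DLS} \;=\; \frac{T_\mathrm{obj} - T_\mathrm{nonobj}}
                          {T_\mathrm{obj} + T_\mathrm{nonobj}} \in [-1, 1],$$

where $T_\mathrm{obj}$ is the summed fixation time in the two object
quadrants and $T_\mathrm{nonobj}$ in the other two; a fixation belongs to
the quadrant containing its centroid, fixations straddling a phase boundary
contribute their within-phase portion to each phase, and a window with no
on-screen looking has an undefined (`NA`) score. Note the calibration: 0
means *equal time per quadrant*. Under spatially uniform looking the
expected DLS is $2f - 1 \approx 0.114$ at $f = 0.5572$ — slightly positive
because the object quadrants are slightly larger. The package verifies this
analytic value by Monte Carlo in its test suite.

Two variants: `split_half_contingent()` splits the *realized* contingent
window (8 s to the realized stop time, not the nominal 30 s) at its midpoint
— a learning signature is a larger second-half DLS. `exploratory_dls()`
rescores the disruption phase after subtracting fixations that landed on
already-uncovered ("visible") object parts from the object looking time, so
only exploratory fixations to still-covered areas support the numerator. The
denominator keeps the visible-part time by default (a config switch,
`exploratory_excludes_denominator`, removes it there too); with the default
the exploratory DLS can only be less than or equal to the standard one.

## Fixation detection

`detect_fixations()` implements a dispersion-duration rule in the
infant-eye-tracking convention: a fixation is a maximal greedy window in
which every valid sample lies within 25 px (Euclidean) of the window's
centroid for **more than** 200 ms (strict). The detector grows windows left
to right, recomputing the centroid as samples join; the first candidate
whose admission would push any member outside the radius closes the window,
with no backtracking — standard I-DT behavior, linear cost in practice.

Choices the convention leaves open, made here and exposed as parameters:

* *dispersion* is distance to the running centroid (matching "mean gaze
  location within 25 pixels"), not pairwise max distance;
* *duration* is strict (`> 200 ms`);
* *blinks*: runs of up to `max_gap_samples = 2` invalid samples (about 17 ms
  at 120 Hz) are tolerated inside a window; longer runs close it. Windows
  start and end on valid samples;
* fixations are detected on the whole trial trace and only then assigned to
  phases, with straddling durations clipped per phase.

The test suite holds the detector to an exhaustive-window oracle that
re-evaluates every candidate window from scratch, on 100 seeded random
traces, requiring exact agreement.

## Exclusion rules and aggregation

Trial level (`apply_trial_exclusions()`), mirroring preregistered criteria:

1. less than 1 s of on-screen looking in the baseline excludes the trial;
2. the trial is kept for the contingent and disruption analyses iff the
   infant looked at least 10 s during the contingent phase **or** scratched
   the 20% stop fraction free. (Read literally, the source criterion's
   wording would exclude exactly the engaged trials; this package implements
   the evident intent — keep if engaged — and flags the reading here.)
3. a disruption phase without a single fixation is additionally excluded.

Subject level (`aggregate_subjects()`): the DLS of valid trials is averaged
per condition, and the subject value is the unweighted mean of the two
condition means, so unequal trial counts cannot bias a subject toward one
diagonal. Undefined trial DLS values drop out of the mean rather than
counting as 0. A subject is included iff both conditions contribute at least
two trials valid for the contingent analysis — the contingent phase carries
the preregistered main hypothesis, which is why its validity is the one
counted; per-phase means still use the trials valid for that phase.

## The Bayesian layer

All headline tests are Bayes factors (BF10, evidence for the alternative
over the null), classified on the conventional scale (anecdotal to extreme
at 3, 10, 30, 100 and their reciprocals; `classify_bf()`).

**`jzs_bf_one_sample()`** — the default-prior one-sample test: under H1 the
standardized effect $\delta$ has a Cauchy prior (scale 0.707, the common
default; the scale is a config knob since the source analyses only state an
"uninformed default prior"). The Bayes factor is the noncentral-$t$ density
of the observed statistic integrated over the prior, divided by the central
density — computed by adaptive quadrature split at the likelihood peak, with
a dense bounded trapezoid fallback where adaptive quadrature fails on
almost-everywhere-underflowing tails. Directed tests truncate and
renormalize the prior (truncating the prior, not the posterior). The result
is deterministic.

**`rank_bf_one_sample()`** — the Bayesian analogue of the Wilcoxon
signed-rank test, for the skewed subject-mean distributions the headline
analyses face. Data enter only through signed ranks, which constrain latent
normal governing values $z_i \sim N(\delta, 1)$; a Gibbs sampler alternates
truncated-normal draws of the latent values (in two interleaved blocks —
each value is bounded only by its rank neighbours, so alternate ranks can be
drawn jointly) with conjugate draws of $\delta$ under the Cauchy prior via
its normal–inverse-gamma mixture. BF10 is the Savage–Dickey ratio at
$\delta = 0$, Rao-Blackwellized over conditional posteriors. Two or more
chains are run (2 × 5000 after 1000 burn-in by default, all seeded) and
split-$\hat R$ is always reported; $\hat R$ above 1.1 flags the result with
a warning, never silently. One caveat by construction: a sample without a
single negative value barely anchors the latent scale, the sampler
random-walks, and such runs are flagged — the BF is then in any case
astronomically large and the classification unaffected.

**`kendall_tau_bf()`** — association with age. The observed tau-b
(tie-corrected, via `stats::cor`, checked against an all-pairs counter in
the tests) is given its asymptotic normal sampling distribution (variance
$2(2n+5)/9n(n-1)$) and a stretched-beta prior on $\tau$ over $[-1, 1]$
(width 1 = uniform); BF10 is the Savage–Dickey ratio at $\tau = 0$ on a
deterministic grid.

**`sequential_monitor()` / `design_simulation()`** — the sequential
preregistration logic: the BF is recomputed as subjects accrue, starting at
the preregistered minimum of 30, stopping at the first crossing of 3 (H1) or
1/3 (H0); crossings before the minimum are never acted on.
`design_simulation()` estimates the operating characteristics (stop
probabilities, mean stopping n) by seeded Monte Carlo.

### Numerical notes and known limitations

* R's noncentral `dt()` carries an absolute error floor (~1e-13) deep in its
  tails. This is irrelevant for two-sided tests and for directed tests in
  the direction of the effect, but a directed BF pointing *opposite* a large
  observed effect (observed $t \approx -7$, BF around 0.02) is accurate only
  to roughly 1%. Such values are decisively in the strong-null region, so no
  classification can change; implementations built on the same base
  function share the limitation.
* Exact numerical parity with GUI statistics packages' MCMC samplers for the
  rank-based tests is out of scope; the package's claims are calibration
  behaviour (null data lean to H0, strong effects to H1, seeded
  reproducibility) and oracle agreement for the deterministic tests.
* The repeated-measures Bayesian ANOVA over the three phases is not
  implemented; the pipeline reports the three post-hoc paired comparisons
  instead.

## The synthetic cohort

`synth_trial()` emulates infant gaze at 120 Hz as alternating fixations and
saccades: log-normal fixation durations (median 300 ms, $\sigma = 0.5$ —
plausible infant values, unconstrained by the source), 50 ms saccades with
linearly interpolated samples, at most 5 px of per-sample jitter, and 10%
of samples lost i.i.d. (tracker dropout, encoded as `valid = FALSE` rows).
Each new fixation targets the union of the two object quadrants with a
phase-dependent probability $p$, placed uniformly within the region (inset
by the jitter radius so jittered samples stay inside the chosen region —
this keeps $p$ exactly interpretable as the object-looking probability);
otherwise it targets the non-object quadrants. Under centroid scoring the
expected DLS is then $2p - 1$, which is what makes the generator a
ground-truth instrument: the pipeline must recover $2p - 1$, and does so
within Monte-Carlo error in the tests for $p \in \{0.3, 0.5, 0.8\}$.

The default probabilities encode the effect pattern the paradigm is built
to detect, at magnitudes matching the group-level scores the design targets:
baseline $p = 0.64$ (expected DLS 0.28), a linear learning ramp 0.56 → 0.62
across the nominal 30-s contingent window (split halves near 0.15 / 0.21),
disruption $p = 0.60$, and a positive age slope of $5\times10^{-4}$ per day
on the disruption preference, over ages drawn uniformly on 180–304 days
(about 6–10 months). The ramp and the disruption probability are mapped on
the *nominal* phase clock; under these parameters a trial almost never
reaches the 20% stop early, so nominal and realized phases coincide. The
transition interval, which no analysis scores, uses the contingent-start
preference so that fixations straddling the 8-s boundary have a continuous
generating law.

What the generator deliberately does **not** model — and hence what passing
tests do not certify about real infant data:

* no between-subject heterogeneity in the targeting probabilities (only the
  age slope): synthetic between-subject SDs are far smaller than empirical
  ones, so group-level Bayes factors on default cohorts are much more
  extreme than any real experiment would produce;
* no disengagement: synthetic infants always provide enough looking time,
  so preregistered exclusions rarely fire on default cohorts (the exclusion
  engine is exercised by constructed fixtures instead);
* no calibration drift, head movement, smooth pursuit, or biomechanically
  realistic saccade kinematics; jitter and i.i.d. dropout stand in for
  measurement noise.

## Problem sizes used by the checks

The packaged checks run the detector-oracle equivalence on 100 seeded 10-s
traces, DLS calibration on 2000 Monte-Carlo fixations, parameter recovery
on cohorts of 10 subjects × 4 trials per probability level and 16 × 6 for
the learning ramp, and sequential-design calibration with 500 simulated
null cohorts of up to 60 subjects; the acceptance script additionally runs
the full default cohort of 45 subjects × 16 trials. These sizes keep
Monte-Carlo error well inside the tested tolerances while the whole suite
runs in minutes on a single CPU.
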