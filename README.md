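# gazescratch

Simulation and analysis of **gaze-contingent "scratch" experiments** with
infants: trials in which an infant's gaze uncovers small squares of a hidden
image, used to measure whether infants flexibly control their eye movements.
The package is aimed at developmental eye-tracking researchers who want to
replay, score, and power such designs offline — on recorded gaze tables or
on synthetic cohorts with known ground truth.

## What it computes

A trial has four phases — baseline (5 s, image visible), transition (3 s,
image covered), contingent (gaze uncovers 25-px cover squares until 20% of
the screen is free or 30 s pass), and disruption (5 s frozen image) — for a
maximum length of 43 s. Objects sit in opposite corners along the falling
(*drop*) or rising (*rise*) diagonal, counterbalanced over 16 object pairs ×
2 conditions = 32 stimuli in two presentation sets.

Looking is scored by the **differential looking score** over four corner
quadrants (AOIs), the two object quadrants jointly covering 55.72% of the
screen by default:

    DLS = (T_obj − T_nonobj) / (T_obj + T_nonobj)   ∈ [−1, 1]

computed from fixations (dispersion–duration rule: samples within 25 px of
the window centroid for more than 200 ms), with preregistered-style trial
and subject exclusion rules, split-half contingent scores (learning), an
exploratory disruption score that discounts fixations on already-uncovered
object parts, and subject-level aggregation (mean of condition means).

The inference layer provides default-prior (JZS) one-sample Bayes factors
(deterministic quadrature), a rank-based (Wilcoxon signed-rank type) Bayes
factor via latent-normal Gibbs sampling with Savage–Dickey density ratios
and split-R-hat reporting, Kendall tau-b association Bayes factors
(stretched-beta prior) for age effects, evidence classification, and
sequential-design monitoring (stop at BF 3 or 1/3 after n = 30) with
Monte-Carlo operating characteristics.

A synthetic-cohort generator emulates infant gaze at 120 Hz (fixation /
saccade alternation, log-normal durations, jitter, dropout) with
phase-dependent object-targeting probabilities `p`, so every stage is
testable against the analytic ground truth `E[DLS] = 2p − 1`.

## Worked example

```r
library(gazescratch)
cfg <- default_config()
cfg$n_subjects <- 8
cfg$trials_per_subject <- 6
cfg$use_rank_tests <- FALSE     # deterministic JZS tests
rpt <- run_pipeline(cfg, seed = 42)
print(rpt)
```

```
== gaze-scratch pipeline report ==
trials: 48 recorded, 0 excluded (rate 0.0%)
subjects: 8 recorded, 8 retained

group DLS (included subjects):
  baseline                 n =  8  M =  0.251  SD = 0.150  SE = 0.053
  contingent               n =  8  M =  0.139  SD = 0.045  SE = 0.016
  disruption               n =  8  M =  0.232  SD = 0.153  SE = 0.054
  contingent_first_half    n =  8  M =  0.102  SD = 0.046  SE = 0.016
  contingent_second_half   n =  8  M =  0.173  SD = 0.122  SE = 0.043
  disruption_exploratory   n =  8  M =  0.229  SD = 0.154  SE = 0.054

tests:
  dls_baseline_gt0                 BF10 = 44.7 (very_strong_h1)
  dls_contingent_gt0               BF10 = 887.7 (extreme_h1)
  dls_disruption_gt0               BF10 = 28.79 (strong_h1)
  split_half_second_gt_first       BF10 = 1.025 (anecdotal_h1)
  ...
```

Reading it: the synthetic cohort was generated with a baseline
object-targeting probability of 0.64, so the group baseline DLS lands near
2·0.64 − 1 = 0.28; all phases show a positive object preference (directed
BF10 well above 3), and the second contingent half exceeds the first
(0.173 vs 0.102) — the learning signature, underpowered at n = 8 (BF ≈ 1).
No synthetic trial fails the looking-time exclusions, so the exclusion rate
is 0%.

A thin command-line front end over the same functions ships in
`inst/cli/gazescratch` (`simulate`, `analyze`, `report`, `seqdesign`).

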