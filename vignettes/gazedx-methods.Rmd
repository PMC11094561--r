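---
title: "Methods: eye-tracking biomarkers and decision-tree integration for early autism diagnosis"
author: "gazedx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eye-tracking biomarkers and decision-tree integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedx)
```

## The problem and the staged model

Specialist autism evaluations are scarce, so young children referred for
evaluation in primary care wait long for a diagnosis. One proposed remedy is
a tiered model: a trained primary-care practitioner (PCP) issues a
best-estimate diagnosis with a certainty rating, an objective eye-tracking
battery supplies biomarkers, and a decision rule either confirms the
diagnosis, rules it out, or refers the child to a specialist.

`gazedx` implements that analysis pipeline in four stages:

1. **Signal processing** (`detect_fixations()`, `detect_saccades()`,
   `drift_accuracy()`, `precision_rms()`): raw gaze/pupil streams are
   reduced to fixation and saccade events plus quality-control indices.
2. **Paradigm metrics** (`nonsocial_preference()`, `gap_overlap_metrics()`,
   `plr_metrics()`, `fixation_and_pupil_summaries()`): six candidate
   biomarkers and auxiliary oculomotor metrics are computed from five
   paradigms — a paired-preference (GeoPref-style) task, a gap-overlap
   disengagement task, a pupillary light reflex (PLR) test, a resting task
   and a passive visual-exploration task.
3. **Screening and composite index** (`screen_biomarkers()`,
   `derive_cutoffs()`, `binarize_and_compose()`, `accuracy_stats()`):
   logistic/ROC screening; per-marker cut points at fixed 95% specificity;
   an any-positive composite with full diagnostic-accuracy statistics.
4. **Decision-tree integration** (`fit_cart()`, `published_tree()`,
   `evaluate_decided()`, `cross_validate()`): classification-tree
   combination of the composite index, biomarker frequency, PCP diagnosis
   and certainty, with three-way terminal decisions
   (diagnose / rule out / refer).

Because no participant-level data are distributable, a seeded synthetic
cohort generator (`simulation_spec()`, `simulate_biomarker_table()`,
`simulate_gaze_stream()`) reproduces the statistical structure the analysis
assumes, with full ground truth, so every stage is testable end to end.

## The six biomarkers

| Metric | Paradigm | Direction counted toward autism |
|---|---|---|
| Nonsocial preference (%) | GeoPref | high |
| No-shift gap effect (%) | gap-overlap | high |
| Resting fixation duration (ms) | resting | high |
| PLR latency (ms) | PLR | low |
| PLR amplitude (%) | PLR | high |
| Exploration fixation duration (ms) | exploration | high |

Directions follow the group means of the study cohort (autism group: more
nonsocial looking, more no-shift trials under overlap, longer fixations,
faster and larger pupil constriction). Auxiliary metrics (overlap−gap RT,
tonic pupil, saccade amplitude/duration) are computed and carried along but
are not part of the composite.

**No-shift gap effect.** The study's main text does not state whether this
is a single-condition percentage or a condition contrast. Its printed range
includes negative values, which only a signed contrast produces, so the
package defines it as *overlap minus gap difference in no-shift trial
percentage*. This reading is prominent in the documentation and is the one
the synthetic generator emulates.

## Signal-processing choices

* **Fixations** use the dispersion-threshold (I-DT) algorithm: maximal
  sample runs whose x-range plus y-range stays within `dispersion_deg`
  (default 1.0°) spanning at least `min_duration_ms` (default 100 ms,
  inclusive). I-DT needs no velocity calibration and is standard for
  clinical-grade trackers in this sampling regime. The scan is greedy and
  deterministic; an exhaustive maximal-run search reproduces it exactly
  (this equivalence is a test).
* **Invalid samples** (blinks, dropped frames): gaps of at most 75 ms are
  bridged by linear interpolation; longer gaps break fixation runs. Both
  constants are arguments.
* **Precision** is the RMS of successive sample-to-sample Euclidean
  distances within fixations (pooled in the squared domain across
  fixations); a centroid-based RMS is available via `method = "centroid"`
  but is not the default. Accuracy is the centroid-to-target displacement
  at drift checks. Coordinates are degrees of visual angle with a
  screen-centred origin.
* **PLR onset**: the pupil trace is smoothed with a *causal* (trailing)
  moving average of 50 ms; velocity is the backward difference; onset is
  the sample *preceding* the first run of 3 consecutive samples with
  velocity below −0.3 mm/s after flash onset. The causal window plus
  backward difference make the detector exact on noiseless traces: the
  smoothed trace cannot move before the signal does, so a ramp whose true
  onset lies on the sample grid is recovered with zero error, and any onset
  is recovered within one sample period. A centred smoother would
  anticipate the decline and bias latency low. All three constants are
  arguments. Baseline is the mean pupil over the 200 ms before the flash;
  amplitude is `100 (baseline − minimum) / baseline`.
* **Gap-overlap RTs**: a shift is the first valid sample inside the target
  AOI after target onset. Shifts faster than 100 ms are anticipatory and
  discard the trial; absence of a qualifying shift within 1000 ms makes the
  trial no-shift. The `[100, 1000]` ms window is standard gap-overlap
  practice; both bounds are arguments.
* **Usable-data gate**: a task contributes metrics only if its valid-sample
  fraction and valid-trial count reach their thresholds; the comparison is
  inclusive at the boundary (a documented tie rule).

## Cut points, the composite, and accuracy statistics

For each marker the cut point is the least extreme value such that the
fraction of nonautism derivation values strictly beyond it is at most 5%
(`derive_cutoff()`); equivalently the `ceiling(0.95 n)`-th order statistic
from the negative side. Exceedance is strict — a value exactly at the
threshold is negative — which favours specificity, consistent with the
design goal of minimising false positives in a heterogeneous referral
population. By construction the achieved in-sample specificity is always at
least the target, and a brute-force threshold search agrees exactly (both
are tests). Cut points are derived on the full sample, as in the source
analysis; a split-sample workflow is available simply by passing pre-derived
rules to `binarize_and_compose()` on held-out children.

The composite is an unweighted union: a child is index-positive if any of
the six markers exceeds its cut point; the biomarker frequency is the
number of exceeded markers (0–6). Missing markers are never imputed and
count as not exceeded.

`accuracy_stats()` reports sensitivity, specificity, PPV and NPV with
**Wilson score** 95% intervals, plus Cohen's κ with the asymptotic interval
`κ ± z √(p₀(1−p₀) / (n(1−pₑ)²))`. Wilson was chosen because it reproduces
all eight published interval bounds for the composite's 79/102 and 34/44
proportions, which exact Clopper–Pearson does not; Clopper–Pearson remains
available via `ci_method = "clopper-pearson"`.

## The decision tree

`fit_cart()` is a greedy binary recursive partitioner over the four
integration features (composite index, frequency, PCP diagnosis,
certainty). Choices:

* **Criterion**: Gini impurity by default (entropy available). With these
  few, mostly binary predictors the two criteria select the same splits in
  simulation.
* **Growth** is *best-first with a total split budget* (`max_splits`,
  default 5): at each step the single best split over all current leaves is
  taken. This gives "growth stopped after m splits" its literal meaning,
  which depth-limited growers cannot express.
* **Acceptance**: both children must hold at least `min_node` cases
  (default 5) and the impurity decrease must reach `cp` (default 0.01)
  times the root impurity, so chance-level features yield a root-only tree.
* **Ties** between equal-gain splits break by the fixed feature order, then
  by the lower threshold: fitting is deterministic.
* **Terminal decisions are explicit configuration**
  (`set_decision_policy()`), defaulting in `published_tree()` to the published
  assignment. The policy is *not* derived from a purity rule, because the
  published tree refers one terminal with 75% nonautism while deciding
  another with 74% nonautism — that choice encodes clinical judgment, not a
  threshold, and the package treats it as data.

`evaluate_decided()` excludes referred cases and scores the diagnose /
rule-out decisions against the reference label. `cross_validate()` uses
stratified folds under a recorded seed and scores held-out cases by
terminal-node posterior probabilities.

## The synthetic cohort generator

The generator's defaults are the study conditions: 102 autism and 44
nonautism children; group-conditional biomarker distributions with the
published means, SDs and ranges (sampled as truncated normals by rejection —
simple and exact for these mild truncations; closed-form truncated moments
are provided for verification); age uniform on 14–48 months; a 71%/29%
male/female split. Where the study reports no value the defaults are chosen
once and documented:

* **PCP accuracy** — sensitivity 0.70 and specificity 0.82, the values
  implied by the published decision-tree node counts (71/102 autism and
  36/44 nonautism children correctly classified by the PCP).
* **Certainty** — P(certain | correct) = 0.75, P(certain | incorrect)
  = 0.35, reflecting the reported facts that 30–40% of clinician autism
  diagnoses lack complete certainty and that correctness rises with
  certainty.
* **Missingness** — 0.2 per paradigm, independent across tasks and
  children, inside the reported 6%–50% per-task unusable range. The
  independence is a modelling choice: per-task usable rates are reported
  but their dependence structure is not.
* **Auxiliary metrics** (overlap−gap RT, tonic pupil, saccade metrics) use
  values plausible for toddlers, flagged in `group_distributions()` as
  assumptions.

Stream rendering (100 Hz default) writes each latent value into the signal
so that a perfect extractor recovers it: dwell fractions into AOI sample
counts, shift latencies into gaze jumps, the PLR into a
baseline–ramp–plateau pupil trace, fixation durations into constant-length
dwell periods. Positional jitter defaults to 0.08° SD — small enough that a
500 ms fixation's dispersion stays within the 1.0° I-DT default (an
optimistic, not hardware-realistic, noise level; the detector itself is
exercised at higher jitter with a proportionally wider dispersion in the
tests). Pupil noise defaults to 0.002 mm.

**Quantization.** Rendering is exact only up to the sample period (10 ms)
and, for the no-shift contrast, the trial count (40 per condition: no-shift
percentages are realizable in steps of 2.5). The recovery tests therefore
assert group-mean recovery within 5% *or* within a stated absolute
quantization floor per marker, whichever is larger — a pure relative bound
is ill-posed for the nonautism no-shift mean, which is a fraction of a
percentage point. The renderer reports its realized (count-quantized)
ground truth alongside the continuous inputs.

**What passing tests do and do not show.** The generator draws the six
markers independently within children, gives missingness no group
structure, and renders stationary noise with no head motion, smooth
pursuit, or stimulus-locked luminance effects. Consequently the synthetic
composite is *more* accurate than the published one (independent markers
make the any-positive union unrealistically sensitive), and agreement of
pipeline outputs with generating parameters validates the implementation —
not the clinical performance claims, which only the study cohort supports.

## Problem sizes and runtime

The default demonstration pipeline simulates 146 children, renders roughly
2.5 million gaze samples, and completes the full
simulate → extract → screen → composite → tree pass in well under two
minutes on one CPU. Distributional-fidelity checks use 10 000 children per
group; permutation-uniformity checks use 1000 label shuffles. These sizes
are the package's own verification choices.

## Known limitations

* The exact detector, thresholds and binocular handling of the original
  acquisition pipeline are not published; all such constants here are
  documented defaults, so absolute metric values from real recordings will
  depend on configuration.
* Per-marker accuracy tables and the usable-data overlap per correlation
  have no published anchors; the package reports the n used alongside every
  estimate instead.
* The published CART point performance on real data (fit AUC 0.92, CV AUC
  0.90) is not reproducible without the study cohort; the package asserts
  structural and qualitative properties on synthetic data only.
* κ for the composite confusion table computes to 0.5048 under the standard
  definition and prints as 0.50, not the published 0.51; every other
  published index and interval reproduces exactly at printed precision.
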