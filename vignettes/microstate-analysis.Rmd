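---
title: "Microstate analysis of neonatal sleep EEG: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of neonatal sleep EEG: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoms)
```

## The model

Microstate analysis treats multichannel EEG as a sequence of brief,
quasi-stable scalp potential topographies. Three assumptions carry the
whole method:

* **Discreteness** — at any instant the scalp field is well approximated
  by one of a small number K of fixed template maps, up to amplitude and
  polarity. Polarity is ignored throughout, because an oscillating source
  configuration reverses the scalp field's sign without changing its
  geometry.
* **Peak sufficiency** — topographic signal-to-noise is highest at the
  local maxima of the global field power (GFP, the spatial standard
  deviation across channels), so templates are estimated from, and fitted
  to, GFP-peak maps only; labels are spread to the remaining samples from
  the nearest peak.
* **Segment structure** — the label sequence consists of maximal runs
  (microstates proper); transitions are counted between consecutive
  distinct runs, which makes self-transitions structurally impossible and
  matches the `1/(1 − P_X)` normalization of the occurrence-driven
  expected transition probability.

For neonatal sleep the scientific questions are whether the same template
set serves both active (AS) and quiet (QS) sleep, how the temporal metrics
(duration, occurrence, coverage) differ between states, whether the
transition syntax is structured beyond occurrence, and how everything
depends on frequency band.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| band-pass | 0.15–45 | Hz | broad-band neonatal EEG; 7th-order zero-phase Butterworth cascade |
| sampling rate | 100 | Hz | after anti-aliased down-sampling |
| GFP peak separation | 10 | ms | one sample safety margin at 100 Hz; no prominence floor by default |
| k-means restarts | 20 | — | polarity-invariant k-means is multimodal; k-means++-style seeding plus restarts |
| k-means tolerance | 1e-6 | rel. EV | convergence on explained variance |
| KL range | 3–15 | — | candidate template counts |
| KL elbow floor (`min_ratio`) | 2 | — | a KL local maximum below this ratio reflects a featureless improvement profile, not an elbow (see below) |
| randomization reps | 5000 | — | syntax test; 500 used in calibration experiments |
| TANOVA permutations | 5000 | — | paired by subject |
| truncated-run rule | exclude | — | boundary-clipped runs leave the duration mean, keep occurrence/coverage |

## Numerical choices

**Filtering.** The band-pass is realized as separate high-pass and
low-pass Butterworth stages, each applied forward and backward (zero
phase, squared magnitude). A 7th-order transfer function at a relative
cutoff of 0.003 (0.15 Hz at 100 Hz) is numerically ill-conditioned, so the
filter is designed and applied as second-order sections derived from the
analytic s-plane pole positions with a per-biquad bilinear transform.
Edges are odd-reflection padded and each biquad starts from its constant
steady state; even so, a 0.15 Hz high-pass has a settling time of several
seconds, so tests that assert pass-band gain do so away from epoch edges.
The closed-form Butterworth magnitude response is the independent test
oracle.

**Clustering.** The assignment criterion is the squared spatial
correlation (equivalently `1 − GD²/2` for zero-mean maps), the template
update the dominant eigenvector of the members' scatter — the closed-form
maximizer of summed squared correlations, which also makes the algorithm
exactly polarity invariant. Restarts use k-means++-style seeding in
correlation geometry. For small problems (≤ 64 maps) every restart's fixed
point is additionally polished by exact single-map and two-map exchange
moves scored with the true eigenvalue objective; Lloyd iterations alone
have fixed points whose basins random initialization essentially never
reaches, and on enumerable instances the polished result attains the
global optimum.

**Model selection.** The Krzanowski–Lai index
`KL(k) = |DIFF(k)/DIFF(k+1)|`, `DIFF(k) = (k−1)^{2/C} W(k−1) − k^{2/C} W(k)`,
is computed on a dispersion grid extended two candidates below the
requested minimum (the one-template dispersion uses the dominant
eigenvector directly) so that local maxima are well defined across the
whole range. A local maximum must beat both neighbours *and* exceed
`min_ratio = 2`: where the improvement profile is flat the index hovers
near 1 and its wiggles are sampling noise, not elbows. Two selection rules
are exposed — first or second local maximum along ascending k — because
"second maximum" phrasing in the literature is ambiguous between the
second local maximum and the second-largest value; neither is asserted as
the only correct reading.

**Backfitting.** Label interpolation between peaks is implemented as
nearest-peak assignment with boundaries at inter-peak midpoints (ties to
the earlier peak): labels are categorical, so literal interpolation is
undefined, and midpoint splitting is the established toolbox behaviour.
Runs touching the epoch edges are flagged truncated and excluded from mean
duration by default (their true length is right- or left-censored), while
still counting toward occurrence and coverage. Occurrence is normalized by
labeled time, not total epoch time, so clipped bad segments do not deflate
it. GEV sums over GFP peaks by default, consistent with peak-based
fitting; an all-samples variant is exposed.

**Syntax.** Group-level chi-square distance compares across-epoch means of
observed and expected transition matrices. The randomization swaps the
observed/expected labels independently per epoch with probability 1/2 — the
epoch is the exchangeability unit. p values count ties as exceedances
(`p = mean(null ≥ observed)`): with strictly-greater counting, degenerate
data whose observed matrix equals its expectation in every epoch would
receive p = 0, a spurious full significance; tie-inclusive counting gives
the correct p ≈ 1 there and differs only on ties elsewhere. A
`(r+1)/(n+1)` conservative variant is available. Randomizations in which a
swapped "observed" transition has zero expected mass score an infinite
distance and count as exceedances.

**TANOVA.** Because templates from polarity-invariant clustering carry
arbitrary signs, subject maps are sign-aligned to their group's dominant
eigenvector before averaging, and the group-mean comparison itself is
polarity invariant. The permutation scheme is paired (within-subject
condition swaps) for the two-state design, label reshuffling otherwise.

**Repeated-measures ANOVA.** Direct sums-of-squares decomposition, each
within-subject effect tested against its own effect-by-subject
interaction; Greenhouse–Geisser epsilon from the covariance of
orthonormally contrasted cell scores; effects with one numerator df skip
the correction (epsilon 1). Coverage always sums to 100% within a
subject-state cell, so a state main effect for coverage cannot exist and
is reported as not applicable. Everything is cross-checked in the test
suite against an independently coded sums-of-squares oracle and against
`aov()` error strata.

## The synthetic-data generator

The generator emulates what the analysis needs to be recoverable, not the
biophysics of a neonatal head:

* K planted zero-mean, unit-GFP template maps, pairwise separated by a
  configurable polarity-invariant global dissimilarity floor (default 0.8);
* segment labels from a first-order Markov chain with zero diagonal
  (uniform, occurrence-driven null, or cyclic/directional variants);
* segment durations from a truncated lognormal (default mean 120 ms,
  floor 30 ms) — strictly positive and right-skewed, the shape real
  microstate duration histograms have — or fixed for exact tests;
* per-segment half-sine GFP envelopes (so GFP peaks sit near segment
  centers, giving the peak detector something to find), optional
  oscillatory carrier for narrow-band scenarios, random polarity per
  segment to exercise the polarity-invariance contract;
* additive 1/f^α background noise (α default 1, matching the
  low-frequency-dominated shape of neonatal EEG spectra), with
  exchangeable spatial correlation, average-referenced, scaled so that
  template-signal RMS over noise RMS equals the planted SNR;
* two states per subject sharing templates but differing in duration law
  and/or syntax, as in a within-subject sleep design.

What it deliberately does **not** contain: volume-conducted dipole
topographies (planted maps are random fields, smoother-than-random scalp
structure is absent), artifacts (ECG, eye movement, electrode pops),
nonstationary arousal dynamics, or inter-subject template variability
beyond noise. Passing recovery tests therefore shows the *pipeline* is
correct and calibrated — it does not validate the microstate model against
real neonatal recordings.

Study-scale experiments in the tests and the acceptance script use cohorts
of 20–30 subjects × 2 states × 60 s at 100 Hz, SNR 5–10, and calibration
batches of 200 null cohorts at 500 randomizations/permutations; these sizes
give stable rates while keeping a full run in the minutes range on one CPU.

## Design decisions on genuinely open points

* **Pooling states.** Per-state template sets are compared template-by-
  template with paired TANOVA; when no template differs at the configured
  alpha the pipeline re-clusters the pooled epochs and carries one template
  set forward. The gate is configuration-driven, mirroring a two-branch
  study design.
* **Template labels.** Group templates are labelled A, B, C, … by
  descending share of attracted GFP-peak maps (a coverage proxy); there is
  no canonical ordering, and any fixed rule makes cross-band/state
  matching reproducible when combined with greedy |correlation| matching
  (`match_templates()`).
* **Per-subject K.** Step-1 clustering uses the same K as step 2 rather
  than per-subject KL selection; with per-subject selection the pooled
  template matrix would mix cardinalities, and there is no established
  benefit.
* **Clip boundaries.** When a keep-mask marks bad segments, retained
  stretches are treated as independent: runs do not span cut points, and
  runs touching a cut are truncated (censored) like epoch edges.
* **Occurrence-driven nulls.** For type-I calibration the null chains use
  uniform occurrence: for the no-self-transition null matrix
  `q_{XY} = P_Y/(1 − P_X)` the stationary law equals `P` only in the
  uniform case, which is therefore the exactly exchangeable instance.
* **Interface.** The pipeline is driven from R (`study_config()` +
  `run_study()`, YAML-round-trippable configuration) rather than a shell
  entry point; an analysis package's natural interface here is its
  functions and scripts.

## Known limitations

* EDF support covers plain 16-bit EDF with a uniform sampling rate across
  signals; EDF+ annotations are not parsed.
* The gamma band's upper edge (45 Hz) coincides with the broad-band
  low-pass cutoff and sits just below the 50 Hz Nyquist at 100 Hz, so
  gamma-band results inherit attenuation from the broad-band stage.
* The 0.15 Hz high-pass needs several seconds to settle; on epochs much
  shorter than ~30 s the edge transients are material.
* Metrics assume the label sequence is the object of interest; no minimum
  duration smoothing or temporal-constraint labeling is applied beyond the
  truncation rule.
* Band "median" frequencies are band midpoints (2.25, 6, 10.5, 19,
  35 Hz), used verbatim in the scaling fits.
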