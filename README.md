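# neoms

Microstate analysis of neonatal sleep EEG in R.

Scalp EEG does not wander continuously between topographies: it dwells in
brief quasi-stable spatial configurations — **microstates** — lasting tens
to hundreds of milliseconds, then switches abruptly to another
configuration. `neoms` implements the complete microstate pipeline for
multichannel sleep EEG in neonates (active sleep, AS, vs quiet sleep, QS),
from raw epochs to group-level inference, together with a seeded
synthetic-cohort generator that makes every stage testable without any
external recording.

It is written for electrophysiologists and methods researchers who want a
scriptable, fully reproducible microstate pipeline: data frames in, tibbles
out, `ggplot2::autoplot()` for every result type, `tidy()`/`glance()` for
fitted objects.

## The method

1. **Preprocessing** — zero-phase Butterworth band-pass (cascade of
   7th-order high-pass and low-pass, each run forward and backward),
   down-sampling, common-average re-referencing.
2. **Global field power.** At each time sample,
   `GFP = sqrt( sum_j (v_j - v̄)² / C )` — the spatial standard deviation
   across the `C` channels. GFP peaks are the moments of highest
   topographic signal-to-noise; their scalp maps are the clustering input.
3. **Template extraction** — a two-step, polarity-invariant *modified
   k-means*: maps are assigned to the template with the largest squared
   spatial correlation (sign ignored), and each template is updated as the
   dominant eigenvector of its members' outer-product sum. Step 1 runs per
   subject; step 2 clusters the pooled individual templates into the group
   set. The number of templates K is chosen with the Krzanowski–Lai
   criterion on the within-cluster dispersion curve.
4. **Backfitting** — each GFP peak takes the best-|correlation| template;
   samples between peaks inherit the nearest peak's label. From the label
   sequence: mean **duration** (ms), **occurrence** (runs/s), **coverage**
   (% of time), and **GEV**, the GFP-weighted fraction of topographic
   variance explained.
5. **Syntax** — observed transition probabilities between templates vs the
   occurrence-driven expectation `P*_{X→Y} = P_X P_Y / (1 − P_X)`, compared
   with the chi-square distance `D = Σ (P_{X→Y} − P*_{X→Y})² / P*_{X→Y}`
   and a 5000-rep randomization test; directional predominance
   `P_{X→Y} − P_{Y→X}` per pair with FDR-corrected one-sample t-tests.
6. **Topography** — global dissimilarity
   `GD² = mean( (u/GFP_u − v/GFP_v)² )` (for zero-mean maps,
   `GD² = 2(1 − r)`), and TANOVA: a permutation test on the GD between
   group-mean maps.
7. **Narrow bands** — the whole pipeline re-run in delta/theta/alpha/beta/
   gamma, with log–log regressions of each metric on the band's median
   frequency.
8. **Inference** — two-way repeated-measures ANOVA (state × template) with
   Greenhouse–Geisser correction and partial eta squared, Bonferroni paired
   post-hocs, Benjamini–Hochberg FDR.

## Worked example

Simulate a small two-state cohort (7 planted templates, 19-channel 10–20
montage, planted QS durations longer than AS) and run the full study:

```r
library(neoms)

cfg <- study_config(
  simulation = list(n_subjects = 5, epoch_length_s = 30, snr = 5),
  clustering = list(k = 7, n_restarts = 10),
  syntax     = list(n_reps = 1000),
  tanova     = list(n_permutations = 500),
  seed = 42)
st <- run_study(cfg)
st
#> <ms_study> k = 7 templates (pooled states), mean GEV 95.84%
#>   syntax AS: D = 0.01138, p = 0.971
#>   syntax QS: D = 0.0248, p = 0.604
#>   ANOVA duration_ms: state F = 275.9 (p = 7.69e-05)
#>   ANOVA occurrence_hz: state F = 198.7 (p = 0.000147)
#>   ANOVA coverage_pct: state F = NA (p = NA)
```

Reading the report: the seven templates explain ~96% of the topographic
variance at GFP peaks (synthetic data are cleaner than scalp EEG); the
planted duration difference between states is picked up by the
repeated-measures ANOVA (`F(1, 4) = 275.9`); the planted syntax is
occurrence-driven, so the randomization test correctly finds no transition
structure (p ≫ 0.05); and the state main effect for coverage is reported
as not applicable, since coverage always totals 100%.

Each piece is an ordinary tibble:

```r
tidy(st$anova$duration_ms)
#> # A tibble: 3 × 9
#>   effect           df1   df2 epsilon df1_gg df2_gg statistic   p_value partial_eta_sq
#> 1 state              1     4   1       1       4     276.    0.0000769          0.986
#> 2 template           6    24   0.436   2.62   10.5     0.981 0.428              0.197
#> 3 state:template     6    24   0.424   2.55   10.2     0.989 0.424              0.198

glance(st$syntax$AS)
#> # A tibble: 1 × 3
#>   distance p_value n_reps
#> 1   0.0114   0.971   1000
```

`autoplot(st$templates)` draws the template topographies,
`autoplot(st$kl)` the model-selection curve, `plot_metrics(st$metrics)` the
duration/occurrence/coverage summary by state.

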