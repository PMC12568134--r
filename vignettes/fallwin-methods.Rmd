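---
title: "Methods: sub-window features, detectors, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sub-window features, detectors, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallwin)
```

## The model and its assumptions

`fallwin` detects falls in tri-axial accelerometer streams by statistical
feature engineering rather than by learned representations. The core
assumptions are:

* a fall is a short event, typically 1–3 s, with a characteristic
  two-phase shape: moderate, growing oscillation while balance is lost,
  a brief free-fall interval where the resultant acceleration collapses
  toward 0 g, then a sharp impact and rest;
* a 3 s analysis window centred on the event captures it fully, and
  splitting the window into two 2 s sub-windows with 1 s overlap lets
  simple per-sub-window statistics separate the pre-impact and impact
  phases;
* acceleration is reported in g, gravity included, at a uniform rate
  (50 Hz is the reference; other rates are converted on ingestion).

The window/sub-window family is parameterised by `window_scheme(n_s, m, o)`:
window length `n_s` seconds, `m` sub-windows, pairwise overlap fraction
`o`. The sub-window length is `L = n_s / (m − (m − 1) o)`; the default
(3, 2, 0.5) gives two 2 s sub-windows. Each sub-window contributes 22
features (7 per-axis statistics × 3 axes + 1 cross-axis range norm), so a
scheme yields a `22 m`-dimensional named vector — 44 for the default.

Two detectors sit behind one contract (`model_spec()`): 1-nearest-
neighbour and an RBF-kernel SVM. Both operate on z-scored features by
default. Scoring uses event-level sensitivity (a fall is found if any
overlapping window is flagged — the OR rule) and window-level specificity,
which matches how a deployed detector is experienced: missed events are
counted per fall, false alarms per decision.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_s` window length | 3 | s | long enough for a whole 1–3 s fall, short enough to exclude unrelated motion |
| `m` sub-windows | 2 | – | pre-impact phase vs impact phase |
| `o` sub-window overlap | 0.5 | fraction | both sub-windows see the window centre, where event placement jitter lands |
| KNN `k` | 1 | – | nearest single example; deterministic and strongest in this family of pipelines |
| SVM `C` | 1 | – | standard box penalty; the kernel, not `C`, is the sensitive choice |
| SVM `gamma` | `1/(f · Var(X))` | – | the "scale" heuristic, computed on the standardized training matrix |
| `standardize` | `TRUE` | – | the bank mixes g-scale means with dimensionless kurtosis; nearest-neighbour distances need a common scale. A flag preserves the literal unscaled reading |
| SMOTE `k` | 5 | – | the classic neighbour count; clamped with a warning when the minority class is tiny |
| streaming `window_s`, `overlap` | 3, 0.3–0.5 | s, fraction | window must match the feature scheme; overlap trades alarm latency and phase coverage against compute |
| `match_tolerance_s` | 3 | s | one window of slack around an annotated fall for event matching, and the exclusion zone for specificity counting |

The event-matching tolerance deserves a note: windows that overlap a
padded fall interval but are not flagged are neither rewarded nor
penalised. They are ambiguous — partially fall, partially background — so
they are excluded from the specificity denominator rather than counted as
true negatives. The padding is configurable.

## The synthetic generator: what it emulates, and what it does not

`synthetic_config()` defines the study conditions under which the whole
pipeline is tested. It emulates:

* gravity as a constant 1 g vector whose orientation is anchored per
  subject (each wearer's habitual pocket orientation) with per-event
  wobble (sd 0.3 on the direction vector). Early versions drew a fresh
  orientation per event; that left subjects distinguishable only by gain
  and offset jitter, and leave-one-subject-out validation showed no
  domain gap at all — contradicting what is consistently observed in
  pocket-worn sensing, where random-fold validation outperforms
  unseen-subject validation. Anchoring orientation per subject restores
  that structure: the distance-based 1-NN detector measurably loses
  accuracy on held-out subjects relative to random folds, while the SVM,
  whose margin is less tied to individual training examples, is much less
  affected;
* the two-phase fall: oscillation ramping to ±0.5 g, a 0.15 s free-fall
  dip, a 0.12 s impact spike of 1.8 g (near smartphone saturation at the
  ±2 g range — impacts are clipped if the subject gain pushes them over),
  then rest at a new orientation. Fall duration is uniform on 1–3 s and
  the impact lands in the second half of the window;
* five ADL subtypes with weights (`walk` 2 Hz gait, `sit_down` a single
  0.9 g spike — the designed hard negative that mimics a soft impact,
  `jump` repeated ~1 g spikes, `lie_still`, `transition` slow
  re-orientation);
* class imbalance (20 falls / 80 ADLs per subject by default), white
  sensor noise (sd 0.05 g), per-subject gain (sd 0.10) and offset
  (sd 0.05 g) jitter, range clipping, and long continuous recordings with
  annotated fall insertions over stitched ADL background.

It does **not** emulate: biomechanically realistic limb dynamics,
gyroscope or orientation channels, non-white sensor noise, drift or
temperature effects, activity transitions with realistic durations and
grammar, or the enormous behavioural diversity of free-living data.
Passing tests on this generator therefore demonstrate that the pipeline's
machinery is correct and that its separability assumptions suffice under
controlled morphology — not that the detector is field-ready. Amplitudes
are order-of-magnitude choices constrained by the two-phase description
above; all are exposed in the config.

Default amplitudes were fixed once from that morphology; the orientation
wobble was calibrated once so the generator exhibits both properties the
study design requires — detectable falls on unseen subjects and a genuine
random-fold/LOSO gap — and none of these values is adjusted per
experiment.

## Numerical choices

* **Sample indexing.** Half-open, 0-based sample intervals everywhere;
  sample *i* is at time *i*/rate, annotations are in seconds.
* **Sub-window rounding.** `L_samp = round(L · rate)`,
  `hop = round((1 − o) · L_samp)`; the last sub-window is anchored to end
  exactly at `round(n_s · rate)`, so rounding error cannot accumulate and
  the union of sub-windows is exactly the window. Schemes whose
  sub-window or hop rounds to zero samples are rejected.
* **Truncation rule.** Single-event traces longer than the window by one
  sample are truncated (some corpora store 151 samples for 3 s at
  50 Hz); longer traces are an error, not silently cut.
* **Sliding windows.** Trailing partial windows are dropped, never
  padded — padding would fabricate data the stream has not produced.
* **Moments.** Population (1/n) moments and non-excess kurtosis, the
  literal reading of the feature definitions; no bias correction. At
  σ = 0 skewness and kurtosis are 0/0 and are defined as 0, which keeps
  all features shift-equivariant.
* **Feature order and names.** Within a sub-window: means, medians, sds,
  skews, kurtoses, maxima, minima (axes x, y, z within each statistic),
  then `SLOP`; sub-windows concatenate in time order. Prefixes `m_`,
  `me_`, `sd_`, `sk_`, `k_`; the suffix digit is the 1-based sub-window
  index. Any fixed order is equivalent for the classifiers; this one is
  documented so feature CSVs are portable.
* **KNN ties.** Equal distances resolve to the smallest training-row
  index; a tied vote (impossible at k = 1) resolves to the nearest tied
  class. This makes predictions fully deterministic.
* **Degenerate ratios.** Metrics with zero denominators report 0 and are
  flagged in an `undefined` column instead of erroring, so parameter
  sweeps survive empty-positive folds.
* **Resampling.** Decimation is plain sample dropping (kept simple and
  exactly invertible in phase; no anti-alias filter) and requires an
  integer ratio; non-integer conversions use per-axis linear
  interpolation on the uniform target grid, which is exact for affine
  signals. Both are exposed; linear is the default since common rate
  pairs (87 → 50 Hz) have non-integer ratios.
* **SMOTE.** Each synthetic row is `p + λ(q − p)`, λ ~ U[0,1], `q` among
  the k = 5 nearest minority neighbours; coincident parents legitimately
  produce a duplicate. Balancing happens strictly inside training folds;
  `audit_fold_plan()` errors if a synthetic row is ever visible to a test
  fold.
* **Shapley estimator.** Permutation sampling with background
  imputation: model-agnostic, unbiased, with per-feature Monte-Carlo
  standard errors; efficiency (Σφ = f(x) − base) holds exactly per
  permutation against the sampled background row, hence up to
  Monte-Carlo error overall. The explained score is the positive-class
  vote fraction (KNN) or the signed decision value (SVM) — stated
  explicitly because attribution magnitudes are only meaningful relative
  to a declared score.
* **Seeds.** Every stochastic stage draws its seed from one root via a
  deterministic integer hash, so a single seed reproduces an entire
  experiment bit-for-bit while stages remain decoupled.

## Problem sizes

The test suite and the acceptance script run the full study at 10
subjects × 100 events (1000 windows, 44 features), 1200 s streaming
recordings (571 decisions at 30% overlap), and 3000–4000 sampled
permutations for the exact-Shapley comparisons; unit and property tests
use smaller fixtures (2–4 subjects) generated in code. These sizes were
chosen as the smallest at which the phenomena of interest — class
imbalance, subject structure, streaming phase mismatch — are stably
expressed.

## Known limitations

* The n-sweep anchors shorter windows at the event start of fixed-length
  recordings; windows longer than the recorded events cannot be swept and
  are skipped.
* Event-level/window-level streaming scoring needs annotated intervals;
  recordings without annotations yield `NA` sensitivity.
* The 1-NN detector stores its full training matrix; for very large
  feature tables an approximate-neighbour backend would be needed.
* SMOTE interpolates in feature space and can place synthetic minority
  points in regions the signal model cannot produce (e.g. sd slightly
  negative is impossible, but a synthetic point between two valid rows is
  always componentwise between them, so bounded features stay in range).
* The generator's hard negatives (`sit_down`) produce single spikes of
  half the fall impact amplitude; real soft falls and hard ADLs overlap
  more, so real-data error rates will be worse than synthetic ones.
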