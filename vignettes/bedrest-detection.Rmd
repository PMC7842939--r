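---
title: "Detecting bedrest in preschool accelerometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bedrest in preschool accelerometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedrestdt)
```

## What the package measures

Waist-worn triaxial accelerometers summarise movement as *counts* per epoch
and axis; at 60-s epochs the Euclidean norm of the three axis counts — the
vector magnitude (VM) — is the working signal. *Bedrest* here means a
sustained period of minimal movement: nighttime sleep plus daytime naps,
deliberately not physiologically staged sleep. The package's job is to
label every worn minute of a multi-day recording as bedrest or wake, after
removing time when the device was off the body, and to summarise the result
the way a paediatric activity study would (bedrest min/day, naps, brief
awakenings).

## The decision-tree detector

`detect_bedrest()` alternates coarse block classification with fine trigger
localisation:

* **Block pass.** The worn segment is cut into blocks of `block_length`
  epochs (final partial block averaged over what it contains). A block mean
  at or below `threshold` counts/min is bedrest-like, above it wake-like.
  The first block fixes the initial state.
* **Start localisation.** From wake, the first bedrest-like block (mean
  strictly below the threshold) is found; within it and its preceding block
  the *last* pair of consecutive epochs both strictly above
  `bedrest_start_trigger` marks the transition — bedrest starts on the next
  epoch. Intuition: the trigger pair is the child's last burst of movement
  before settling.
* **End localisation.** Symmetric: the first wake-like block (mean strictly
  above threshold) is found, and the *first* pair of consecutive epochs both
  strictly above `bedrest_end_trigger` marks the first sustained movement;
  bedrest ends on the epoch before it.
* **Final pass.** After the record is exhausted (epochs after the last
  boundary keep the prevailing state), bedrest periods shorter than
  `min_bedrest_min` are relabeled wake. This pass runs once, at the end.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `block_length` | 36 | epochs (min) | averaging scale of the coarse pass |
| `threshold` | 230 | counts/min | bedrest-like vs wake-like block mean |
| `bedrest_start_trigger` | 305 | counts/min | last-movement pair before bedrest |
| `bedrest_end_trigger` | 1129 | counts/min | first-movement pair after bedrest |
| `min_bedrest_min` | 30 | min | smallest reportable bedrest period |

The four tunables default to the optimum established for preschool
children; `min_bedrest_min = 30` reflects that children are rarely put to
bed for less than half an hour. All are user-settable for other populations.

### Numerical conventions and degenerate cases

These choices are part of the algorithm's contract; the test suite's
independent oracle encodes the same rules.

* Ties at the threshold side with bedrest in the initial-state comparison
  (`mean ≤ threshold`); the block searches are strict (`<`, `>`), so a
  block mean exactly at the threshold is skipped by both searches. Trigger
  comparisons are strict (`> trigger`).
* VM is stored unrounded; integer thresholds are compared against the real
  value.
* When the identified block is the first block, only it is searched (there
  is no preceding block). When no trigger pair exists in the two-block
  window, the boundary falls back to the identified block's first epoch —
  deterministic and conservative.
* Scanning resumes at the epoch after each boundary, and boundaries are
  clamped so a bedrest period always contains at least its start epoch and
  the scan position strictly advances after every bedrest-end; without the
  clamp a trigger pair abutting the scan position could stall the
  alternation.
* Non-wear and excluded epochs split the record: each worn segment is
  processed independently and blocks never span a gap, so an off-body
  device can never be read as bedrest.
* Episode tables use 1-based inclusive `[start_index, end_index]` rows, the
  natural R indexing; durations are `end − start + 1` minutes at 60-s
  epochs.

## The visual-reference heuristic

`score_reference()` automates the rules human raters apply when scoring VM
plots: bedrest-start is the first minute of 10 consecutive minutes at or
below 100 counts/min whose following 20 minutes contain at most 2 minutes
above it; bedrest-end is the minute before a ≥ 500 counts/min minute
confirmed by at least 5 of the next 9 minutes at ≥ 500. The smallest
reportable episodes are 30 min (bedrest) and 10 min (wake). Two decisions
were genuinely open:

* **Minima order.** Short wake gaps (< 10 min) are absorbed into bedrest
  *before* short bedrest (< 30 min) is demoted. The order matters; this one
  mirrors how a rater perceives a consolidated overnight block before
  judging small fragments.
* **Edges.** A confirmation window that runs past the end of the data is
  evaluated over the minutes that exist, so trailing bedrest is not
  discarded; a record shorter than the start rule plus its confirmation
  window scores all wake with a warning.

`merge_raters()` implements the two disagreement resolutions used when two
raters differ: `True1` treats disputed epochs as wake (conservative for
bedrest), `True2` as bedrest. `True1`'s bedrest set is a subset of
`True2`'s by construction, which is also how the acceptance script realises
the overlap-coefficient subset identity.

## Non-wear and quality control

`detect_nonwear()` flags maximal zero-count runs of at least 90 min,
tolerating nonzero spikes of ≤ 2 min when flanked by ≥ 30 min of zeros on
both sides — the published default parameterisation of the zero-run family
of algorithms. "Zero" means exactly zero on the tested signal; a VM of zero
coincides with all-axes zero. The signal is VM by default (consistent with
the detector) with `axis1` selectable.

`validate_recording()` applies the study-selection rules: a valid night has
at least 360 worn minutes (not necessarily contiguous — the rule text does
not demand contiguity, so the weaker reading is used) between 22:00 and
06:59; a valid recording has ≥ 3 valid nights, of which ≥ 2 weeknights and
≥ 1 weekend night; everything after a ≥ 48-h non-wear run is excluded.
"Weekend night" is not standardised; nights *starting* Friday or Saturday
at 22:00 are used, matching the school-week convention. A night is indexed
by the calendar date of its 22:00 start.

## The Sadeh comparator

`sadeh_score()` evaluates the classic linear sleep statistic per epoch:
window mean of counts capped at 300 (11-epoch centred window), the number
of window epochs in the 50–100 band, the standard deviation of the current
and five preceding epochs, and the log of the current count plus one, with
the published coefficients (7.601, −0.065, −1.08, −0.056, −0.703); a
non-negative statistic scores sleep. The coefficients are stored in
`sadeh_params()` because actigraphy software ships several variants;
bit-exact parity with any one commercial implementation is not claimed
(their edge handling is proprietary). Edges truncate the window by default;
zero padding is selectable. The default input is the vertical axis, which
is what the algorithm was built on; VM mode exists only for exploratory
comparisons.

## Agreement statistics

Bedrest is the positive class: sensitivity `TP/(TP+FN)`, specificity
`TN/(TN+FP)`, accuracy `(TP+TN)/n`. Epochs non-worn or excluded in either
sequence are dropped before any metric. A metric with a zero denominator is
`NA`, never 0. `cohen_kappa()` implements weighted kappa (linear weights by
default); for the two-state sequences compared here weighted and unweighted
coincide, and two identical constant sequences — a 0/0 in the formula — are
reported as kappa 1 with a warning, since agreement is total. The overlap
coefficient divides agreed bedrest time by the smaller method total, so a
subset relation yields exactly 1.

## Parameter optimisation

`optimize_dt_params()` wraps a from-scratch Nelder–Mead engine
(`nelder_mead()`) with the standard coefficients ρ = 1, χ = 2, γ = 0.5,
σ = 0.5 and a fixed 100-iteration budget, maximising detection accuracy
against reference labels — pooled over all epochs of the development set by
default (an epoch-weighted criterion), or as the mean of per-recording
accuracies. Design choices:

* The simplex moves in continuous 4-space; each vertex is **rounded to
  integers at evaluation time** (`block_length ≥ 2` enforced), which keeps
  the search smooth while honouring the epoch-granular meaning of the
  parameters and explains how a continuous method yields integer optima.
* The default initial simplex is the published preschool optimum plus four
  single-coordinate +50% perturbations. Seeding the simplex at the shipped
  defaults guarantees the search never reports a vertex worse than them on
  the development data.
* Equal-objective vertices are ordered by lexicographically smaller
  parameter vector, making the whole search deterministic; the best-ever
  *evaluated* point is returned, not merely the final simplex best, and the
  per-iteration trace records a non-decreasing best-so-far accuracy.
* A recording whose detection fails is dropped from the objective with a
  warning, never silently.

## The synthetic generator

`sim_profile()` / `generate_actigraphy()` produce seeded multi-day traces
with ground truth: one night bedrest period per evening (bedtime
20:30 ± 30 min, duration 630 ± 45 min — typical preschool overnight
in-bed time), a daytime nap on half the days (start 13:00 ± 45 min,
duration uniform on 30–90 min, the nap classification band), awakenings at
0.2/h of night bedrest lasting 5–15 min, wake VM log-normal with median
1500 counts/min, bedrest epochs 80% exact zeros with the remainder uniform
on 1–100 counts/min plus rare bursts up to 600 counts/min, and optional
inserted non-wear runs of exact zeros. The wake/bedrest/burst regimes are
chosen to straddle every decision boundary the detectors use (100, 230,
305, 500, 1129 counts/min); naps are kept 30 min clear of nights and
awakenings 30 min clear of bedrest edges so the planted episode structure
is unambiguous. A target VM is decomposed onto the three axes along a
random positive-octant direction and rounded to integer counts, with VM
recomputed from the rounded axes so the axis/VM invariant is exact.

What the generator does *not* emulate: gradual sleep-onset "wind-down"
ramps, correlated movement bursts, device artefacts, or between-child
heterogeneity in activity level. Passing the synthetic-recovery checks
therefore shows the detector recovers planted structure under the intended
count regimes — it does not certify field performance on real recordings,
which is what the original validation against visually scored data
established.

## Problem sizes used by the checks

The test suite cross-validates the detector against an independent naive
forward-scan oracle on 1,000 random traces of up to 2,000 epochs with
randomised parameters; synthetic recovery uses ten 7-day traces
(10,080 epochs each) at the default profile and requires mean epoch
accuracy ≥ 0.95; the optimiser checks use a 4-D quadratic (convergence to
1e−3 within 200 iterations) and a five-recording, 2-day-per-recording
development set over the full 100-iteration budget. These sizes make the
whole suite run in a couple of minutes on one core while still exercising
every code path; nothing about the algorithms limits them to these sizes.

## Known limitations

* The detector identifies bedrest, not sleep; quiet wakefulness in bed is
  bedrest by definition here.
* Naps shorter than `min_bedrest_min` are invisible by design; lower the
  minimum for populations with very short naps.
* Block misalignment can shave minutes off short naps (a 30-min nap split
  across two 36-min blocks may fail to pull either mean under the
  threshold); this is inherent to the block-average design.
* The quality-control weekend definition and the non-contiguous reading of
  the 6-h wear rule are documented conventions, not universals; both are
  isolated in `validate_recording()` / `is_valid_night()`.
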