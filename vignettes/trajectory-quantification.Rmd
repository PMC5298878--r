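---
title: "Quantifying medially directed cardiomyocyte movement: methods and design"
author: "cardiotrax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying medially directed cardiomyocyte movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotrax)
```

## The problem

During cardiac fusion in the zebrafish embryo, the two bilateral sheets
of cardiomyocyte precursors in the anterior lateral plate mesoderm
(ALPM) move toward the embryonic midline and merge into a ring, the
precursor of the heart tube. Timelapse confocal imaging with a
myocardial reporter yields per-cell tracks over ~2 hours at a 4-minute
cadence; the scientific questions are kinematic: do mutant cells move
more slowly, less straight, or in the wrong direction? `cardiotrax`
answers these from track tables alone — image segmentation and track
linking are upstream and out of scope.

## The analysis model

### Frame of reference

Raw tracks contain stage and imaging drift. Each embryo carries one
reference-landmark track (the notochord tip, the most consistent
anatomical landmark available in these recordings); the landmark's
cumulative displacement since the first timepoint is subtracted from
every cell position at the matching timepoint. This removes *exactly*
any displacement field shared by the cells and the landmark. The
landmark itself retracts slightly posteriorly over the recording; by
convention the landmark defines the frame, so this biological motion is
not modelled out separately — a deliberate inheritance of the original
measurement convention, and the reason corrected anterior-posterior
velocities carry a small positive offset.

Correction operates on positions anchored at the first timepoint rather
than on per-step velocities. For complete tracks the two are identical;
the anchored form is well defined even if a future extension admits
gaps.

### Medial coordinate

The midline is declared metadata (`midline_x`), an anatomical landmark,
never estimated from the tracks. The medial coordinate is

\[ x_m = \begin{cases} x - \text{midline}_x & \text{left side} \\
\text{midline}_x - x & \text{right side} \end{cases} \]

so movement toward the midline increases \(x_m\) for cells on either
side. All downstream kinematics are invariant under reflecting an
embryo about its midline with the side labels swapped, which the test
suite checks as a property.

### Per-cell metrics

All metrics are computed in the 2D \((x_m, y)\) plane (these cells move
negligibly along z) over each complete track, with net quantities taken
between the first and last timepoint, without smoothing or windowing:
speed (path length / time), efficiency index (displacement / path
length), axis velocities \(v_{ML} = \Delta x_m / T\) and
\(v_{AP} = \Delta y / T\), and net direction. The field's customary
direction formula, arctan(|Δy| / Δx), is ambiguous when Δx < 0: a
single-argument arctangent cannot distinguish medial from lateral
movement. We therefore use the quadrant-aware two-argument form,
`atan2(|Δy|, Δxm)`, giving angles in [0°, 180°] with 0° purely medial
and 180° purely lateral — the only reading under which laterally moving
cells occupy a distinct angular sector of the rose plot. Because the AP
displacement enters as an absolute value, every metric except the sign
of \(v_{AP}\) is invariant under an AP sign flip, and direction < 90°
is equivalent to \(v_{ML} > 0\).

Degenerate inputs: a track of zero duration is an error; a track that
never moves has speed 0 and *missing* (not zero) efficiency and
direction, so cohort means are not dragged toward zero by tracking
artifacts; the count of such tracks is reported.

### Aggregation and comparison

Cohort-level means are computed per cell across all embryos, and
per-embryo means of means are exposed alongside, because both views are
standard: the per-cell view matches "average velocity of individual
cells", the per-embryo view treats the embryo as the biological
replicate. The direction histogram uses 10 equal bins over [0°, 180°],
right-open except the last bin which is closed so that both 0° and 180°
count. "No medial movement" is operationalized as \(v_{ML} \le 0\)
(threshold configurable). Group contrasts use the unpaired two-tailed
Student's t-test in its classic pooled-variance form — that is what the
plain name denotes — with Welch's form switchable
(`var_equal = FALSE`); no multiple-testing correction is applied, and
embryo is not modelled as a random effect, matching the analysis the
package reproduces.

### Bilateral-domain gap

Convergence of the two ALPM domains is summarized per embryo and stage
by sampling the distance between the medial edges of the left and right
domains at three anterior-posterior points 200 µm apart (linear
interpolation along the supplied edge curves) and taking the **maximum**
as the representative gap. The placement of the three points along the
AP axis is not fixed by the original procedure; we centre them on the
midpoint of the edges' common span by default and offer anterior
anchoring as an option. The statistic is invariant to mirror reflection
and monotone under pointwise widening of the gap, both tested as
properties. Per-stage cohort comparisons reuse the same t-test; stages
with fewer than two embryos in a group are skipped with a warning.

## The synthetic-data generator

The generator exists so that the whole pipeline can be validated by
parameter recovery: it produces data with *known* kinematics in the
exact format the pipeline consumes.

Each embryo is a biased random walk of two bilateral cell populations.
Per step, a cell's displacement is the sum of

- deterministic drift: `medial_drift · dt` toward the midline and
  `ap_drift · dt` along AP;
- an embryo-coherent increment, drawn once per embryo per timestep in
  the (medial, AP) frame and applied mirrored to the two sides, with
  variance `coherent_fraction · noise_sigma²` per component — the
  simplest mechanism that reproduces coherent collective movement
  without neighbor exchange (with `coherent_fraction = 1` the
  medial-lateral rank order of cells on a side is exactly preserved);
- independent per-cell Gaussian noise with the remaining variance
  `(1 − coherent_fraction) · noise_sigma²`.

A reference-landmark track retracts posteriorly at
`reference_retraction` µm/min, and an `imaging_drift` vector is added to
*all* objects including the landmark — this is precisely the component
drift correction must (and does, exactly) remove.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `dt` | 4 min | imaging cadence of the emulated recordings |
| `n_timepoints` | 31 (120 min) | inside the 2–3 h recording window |
| `medial_drift` | 0.19 µm/min | wild-type cohort mean ML velocity |
| `noise_sigma` | 0.3 µm/step | unconstrained by any printed number; chosen so per-cell speeds land in the ~0.2 µm/min range typical of these cells |
| `coherent_fraction` | 0.5 | a convention: half the step variance is collective |
| `z_noise_sigma` | 0.05 µm/step | near-zero z movement |
| `initial_gap` | 150 µm | bilateral separation typical at the 16-somite stage |
| `reference_retraction` | 0.05 µm/min | "slight" posterior retraction |
| `imaging_drift` | (0.1, 0.1) µm/min | nonzero so correction is exercised by default |

`noise_sigma` and `coherent_fraction` are flagged as conventions: no
printed number constrains them, and none of the calibration below
depends on them (the medial-velocity estimator is unbiased for
`medial_drift` regardless of noise).

### Cohort presets and calibration

The `wt` preset has 8 embryos × 21 cells (11 left + 10 right) = 168
cells, with per-embryo drifts spread symmetrically over 0.15–0.23
µm/min — every embryo medial, cell-weighted mean exactly 0.19 µm/min.
The `ref_mutant` preset has 6 embryos and 137 cells (five of 23, one of
22): two "mild" embryos at the wild-type cohort drift and four "severe"
embryos sharing one drift value solved in closed form from the
calibration constraint

\[ d_{severe} = \frac{N\,\bar v_{mut} - n_{mild}\,v_{wt}}{n_{severe}}
 = \frac{137 \cdot 0.016 - 46 \cdot 0.19}{91} \approx -0.072\ \mu
 \text{m/min}, \]

i.e. slightly lateral — "near or below zero". A single shared severe
value is the simplest model honouring that description. Note the
per-embryo cell counts: the published totals (168 cells over 8 embryos,
137 over 6) imply ~21–23 analysed cells per embryo, which we read as the
complete-track survivors drawn from the two most medial cell columns of
both sides; the generator accepts arbitrary per-side counts outside the
presets.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: complete
bilateral tracks, coherent collective drift toward (or away from) the
midline, a shared imaging-drift field, a slowly retracting landmark, and
cohort composition. It does **not** emulate cell divisions, track gaps,
neighbor mechanics, chemotactic gradients, or any image-level artifact.
Passing recovery tests therefore shows the *pipeline arithmetic* is
correct under the stated motion model — not that the motion model is a
complete account of real cardiomyocyte behaviour.

## Numerical choices

- AP tertile bands use initial y only; rank r of n maps to band
  `round(2(r−1)/(n−1))`, ties broken by track id, so 9 cells split
  3/3/3, 2 cells take top and bottom, and a single cell is labelled
  middle.
- Histogram bins are right-open except the last ([162°, 180°]).
- Gap interpolation is linear with ordered-tie collapsing; a sample
  point outside an edge's span is a coverage error, never extrapolated.
- Determinism: every stochastic component derives from one integer seed
  plus a stable per-embryo hash; identical (preset, seed) gives
  byte-identical track files. The simulator restores the caller's RNG
  state.
- Zero pooled variance with equal means is a degenerate-input error for
  the t-test rather than t = 0.

## Problem sizes

Validation runs the full calibrated cohorts (168 + 137 cells, 31
timepoints) across five seeds for recovery checks — a few seconds of
computation — and smaller randomized embryos (6–10 cells, 11–16
timepoints) for property sweeps. Recovery is asserted within three
standard errors of the seed-to-seed spread.

## Known limitations

- Translation-only drift correction via a single landmark; no rigid or
  affine registration of point clouds.
- Track-level summaries only: no instantaneous-velocity series, MSD, or
  persistence-time fitting.
- The gap statistic consumes annotated edge coordinates; it does not
  segment domains from images.
- Incomplete tracks are discarded, not imputed; with many gaps the
  complete-track filter can bias which cells are analysed.
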