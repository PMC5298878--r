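# cardiotrax

Quantification of directed collective cell migration from timelapse
cell-track tables, built around the cellular analysis of **cardiac
fusion**: the medial movement of the two bilateral cardiomyocyte
populations of the zebrafish anterior lateral plate mesoderm (ALPM)
toward the embryonic midline, where they merge to form the heart tube.
The package is for developmental biologists who track cells in timelapse
confocal data (e.g. Imaris exports) and want reproducible, testable
kinematics instead of spreadsheet arithmetic.

## What it computes

Given long-format tracks (one row per cell per timepoint, with a
reference-landmark track per embryo), the pipeline:

1. **Filters to complete tracks** — only cells with a position at every
   timepoint are analysed.
2. **Drift-corrects** — the reference landmark's (notochord tip)
   cumulative displacement is subtracted from every cell position,
   removing stage/imaging drift exactly.
3. **Aligns the two sides** — each cell's medial coordinate is
   `xm = x − midline_x` (left) or `midline_x − x` (right), so movement
   toward the midline increases `xm` on both sides; cells are also
   banded into anterior/middle/posterior tertiles.
4. **Computes per-cell kinematics** over the track's full XY trajectory:

   - speed = distance / time, where distance is the polygonal path length
   - efficiency index = displacement / distance ∈ [0, 1]
   - axis velocities `v_ML = Δxm / T`, `v_AP = Δy / T` (µm/min)
   - net direction = atan2(|Δy|, Δxm) ∈ [0°, 180°]
     (0° = purely medial, 180° = purely lateral)

5. **Aggregates and compares** — per-embryo means, the fraction of cells
   with no medial movement (`v_ML ≤ 0`), a 10-bin direction histogram
   (rose plot) over [0°, 180°], and unpaired two-tailed Student's
   t-tests (pooled variance) between cohorts, at per-cell and per-embryo
   level.
6. **Measures bilateral convergence** — from medial-edge curves of the
   two ALPM domains, the gap at three AP points 200 µm apart, taking the
   maximum as the embryo's representative gap, compared per stage across
   cohorts.

A calibrated biased-random-walk simulator generates synthetic wild-type
and mutant cohorts (8 embryos / 168 cells and 6 embryos / 137 cells,
with 2 mild and 4 severe mutant embryos) whose cell-weighted mean
medial-lateral velocities equal 0.19 and 0.016 µm/min; it is used to
validate the whole pipeline by parameter recovery.

## Worked example

```r
library(cardiotrax)

wt  <- simulate_cohort(make_preset("wt", seed = 1))
mut <- simulate_cohort(make_preset("ref_mutant", seed = 1))
both <- track_table(rbind(as.data.frame(wt), as.data.frame(mut)),
                    midline_x = 0, dt = 4)
res <- analyze_tracks(both)
res
#> <trajectory_analysis> 305 cells, 14 embryo(s), group(s): mutant, wt
#>   mutant: mean speed 0.157 um/min, mean ML velocity 0.016 um/min, non-medial 0.66
#>   wt: mean speed 0.212 um/min, mean ML velocity 0.191 um/min, non-medial 0.00
#>   ML velocity (per cell): t = -17.094, p = 2.45e-46

res$histograms$mutant
#> <direction_histogram> 10 bins over [0, 180] deg (group: mutant)
#>    [0,18)   [18,36)   [36,54)   [54,72)   [72,90)  [90,108) [108,126) [126,144)
#>        42         4         0         0         0         0         0        29
#> [144,162) [162,180]
#>        61         1

plot(res$histograms$mutant)   # rose plot
```

The wild-type cohort moves medially at 0.191 µm/min with essentially
every cell directed toward the midline; the mutant cohort's mean medial
velocity collapses to 0.016 µm/min, two thirds of its cells show no
medial movement, and the rose plot is bimodal — the mild embryos' cells
still point medially (0–36°) while the severe embryos' cells point away
from the midline (>126°). The per-cell medial-lateral velocities differ
between cohorts at t = −17.1 (pooled df = 303).

Shell front end for the same steps:

```sh
Rscript inst/cli/cardiotrax.R simulate --preset wt --seed 1 --outdir out/
Rscript inst/cli/cardiotrax.R analyze --tracks out/tracks_wt.csv --outdir out/
Rscript inst/cli/cardiotrax.R gap --edges edges.csv --outdir out/
```

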