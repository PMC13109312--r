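---
title: "Kernel row detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel row detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelrows)
```

This vignette is the package's account of the science behind `detect_rows()`:
the geometric model it assumes, what every tunable parameter means, what the
synthetic data generator does and does not emulate, and the design decisions
taken where the method left genuine latitude.

## The problem and the model

A corn ear carries kernels in rows that wind along the cob. In a single
photograph only one side is visible, rows curve with the spiral arrangement
and converge at the tapered ends, and a kernel localizer adds position error
and misses kernels. `detect_rows()` reconstructs the visible-side rows from
the kernel centre points alone under three structural assumptions:

* **A dominant axis.** The point cloud is elongated along the cob axis, so
  the leading principal component identifies it. After alignment, `x` is
  axial and `y` transverse.
* **A quasi-grid middle.** Near the middle of the ear, rows run almost
  parallel to the axis, so compressing `x` by a large factor `t` turns each
  row into a tight transverse band that ordinary K-means separates. The
  silhouette coefficient then selects the row count: for each candidate
  count `c` we keep the best of several seeded K-means fits and pick
  `c* = argmax S(c)`.
* **Slowly turning rows.** Away from the middle, a row may curve, but the
  angle between successive inter-kernel steps is small — on real ears the
  large majority of such angles are below 10 degrees. The greedy search
  exploits this: a candidate point is admitted to the row whose running
  direction it deviates from least, provided the deviation is at most
  `2 θ_T`.

Everything downstream (partial rows, outliers, the phenotype) follows from
these three assumptions; ears that violate them (heavily diseased, strongly
deformed, or imaged so that rows overlap) are outside the method's scope.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `t` | 1000 | — | axial squeeze factor; `x` contributes to distances as `1/t²` |
| `alpha` | 0.09 | fraction of `L` | half-width of the clustered middle segment (total width `2αL`) |
| `theta_T` | 10 | degrees | base angle threshold of the three correction regimes |
| `c_min`, `c_max` | 2, 10 | rows | silhouette search range (visible side) |
| `kmeans_restarts` | 10 | — | k-means++ restarts per candidate count |
| `rng_seed` | 1 | — | master seed for all K-means randomness |
| `partial_split_min_silhouette` | 0.75 | — | separation needed to declare two partial rows |

`t = 1000` sits on the plateau where squeezed distances have effectively
converged to `|Δy|`: increasing `t` further changes the distance of a point
pair by a term that decays as `1/t²`, so silhouette curves for
`t = 1000, 3000, 10000` are indistinguishable (the acceptance suite checks
agreement within `10⁻³`). `alpha = 0.09` balances two failure modes: a
narrower segment has too few points per row for stable clustering, a wider
one reaches into the curved, tapering ends where rows converge and the
silhouette degrades monotonically. `theta_T = 10°` mirrors the empirical
inter-kernel angle distribution of intact rows; the halved-angle regime in
`(θ_T, 2θ_T]` accepts a kernel whose step angle is plausibly inflated by
localization error while letting the row direction turn only half way,
which damps error propagation along the trace. The search range 2–10 covers
the visible side of ears with the usual whole-ear prior of 12–20 rows; the
reported `rows_per_ear` is therefore a *unilateral* count.

## The synthetic generator as study conditions

`simulate_ear()` places rows on a cylinder (radius 100 px, length 800 px by
default) at equal azimuth spacing, advances the azimuth by `twist_rate`
degrees per pixel of axial advance (0 = linear arrangement), projects the
half-cylinder facing the camera (`visible_window = 180°`, half-open so that
a row sitting exactly on one silhouette edge is counted once), applies an
elliptical end taper to the projected transverse coordinate, and adds
isotropic Gaussian jitter and i.i.d. Bernoulli dropout. Ground truth labels
every emitted kernel with its row; rows with fewer than two emitted kernels
are dropped from the truth phenotype, mirroring the unilateral reporting
convention.

The validation batteries in the test suite and `scripts/acceptance.R` use
`simulate_battery()` defaults chosen once from geometry:

* whole-ear rows in {10, 12, 14, 16}, i.e. 5–8 visible rows;
* 15–25 kernels per row;
* `twist_rate` uniform on [0, 0.025] deg/px — up to 20° of total twist
  across the ear, spanning linear to moderately spiral arrangements while
  keeping ground-truth inter-kernel step angles far below 10°;
* taper strength 0.3;
* jitter at 5% of the *minimum* transverse gap between adjacent visible
  rows at the ear centre (the tightest spacing occurs near the silhouette
  edges where `sin` flattens);
* dropout 0 for the row-count battery, 0.1 for the assignment battery.

Problem sizes are 100 ears for the row-count and dropout batteries, 50 for
the sensitivity sweep, and 20 for the rotation and angle batteries, with
one K-means-seeded detection per ear.

What the generator does *not* emulate: kernel shape and size (points only),
perspective distortion, disease or pest damage, multiple ears per image,
and localizer error that is structured rather than isotropic (e.g.
systematic bias along the axis). Passing the synthetic batteries therefore
demonstrates the geometric core — pose normalization, row-count selection,
curve tracing, partial-row logic — not robustness to every failure mode of
a real localizer.

## Numerical and design choices

**Middle-segment width.** The segment is the closed interval
`[centre − αL, centre + αL]`; closed endpoints avoid dropping kernels on
exact boundary ties.

**PCA sign and rotation range.** The rotation angle is constrained to
`(−90°, 90°]`, fixing the eigenvector sign ambiguity; a residual 180° flip
is immaterial because the pipeline is left/right symmetric and rows are
reported sorted by transverse position.

**K-means.** Initialization is k-means++ on the squeezed coordinates,
refined by Hartigan–Wong, best of `kmeans_restarts` restarts by total
within-cluster sum of squares, with a per-candidate-count seed derived from
`rng_seed` (and never from `t` or `alpha`, so sweep cells are comparable).
Silhouette ties across counts resolve to the smallest count (parsimony:
fewer spurious rows). Points in singleton clusters take silhouette 0, the
standard convention for an otherwise undefined `a(i)`.

**Candidate ordering and row assignment.** Within one directional pass,
unlabeled points are visited by increasing axial distance from the segment
edge (ties by lower `y`, then input order), which makes every row's
boundary advance monotonically. Each candidate is scored against *all* row
frontiers and assigned to the admissible row with the smallest angle — not
to the first admissible row in an arbitrary enumeration — so the result is
independent of row order (the suite asserts this under label shuffling).
Direction vectors are re-normalized after every update; the angle test
itself is scale-free.

**Corrections never move points.** The halved-angle regime updates only the
row's direction state; reported coordinates are always the input ones.

**Partial rows.** The residue is squeeze-clustered with 2-means. A naive
"two rows if `S(2) > 0`" rule is vacuous — splitting *any* non-degenerate
point set in two yields a positive silhouette (about 0.5–0.6 for a single
contiguous band), so it would always report two partial rows and would cut
a single curved partial row in half. Two safeguards fix this, both fixed
before the batteries were evaluated and both geometric rather than tuned:
(i) two partial rows require a strongly separated split,
`S(2) > 0.75`, midway between the ~0.6 of a split band and the ~0.9+ of two
genuinely distinct bands (`partial_split_min_silhouette = 0` restores the
naive rule); (ii) a split whose two clusters occupy disjoint axial ranges
on the *same side* of the ear centre is vetoed — that signature identifies
one curved row cut along its length, whereas genuine pairs of partial rows
sit at opposite ends or, when they share an end, both run to the tip and
overlap axially. Residues of fewer than 3 points yield no partial row, and
recovered rows with fewer than 2 members return to the outliers.

**R² convention.** `count_metrics()` defaults to the denominator
`Σ(C̄ᵍ − Cᵖᵢ)²` used by this pipeline's evaluation protocol and exposes the
textbook `Σ(Cᵍᵢ − C̄ᵍ)²` behind `r2 = "conventional"`; both equal 1 on
perfect predictions.

**Row matching.** Precision/recall/F1 require a row correspondence; the
package computes the exact maximum-overlap one-to-one assignment on the
contingency table via a bitmask dynamic program (exact for up to 20 rows on
the smaller side, far beyond any real ear) and is verified against
exhaustive enumeration in the tests. Note that F1 under this matching is
symmetric in which labeling is called "predicted": swapping exchanges FP
and FN while TP is unchanged, so only precision and recall trade places.

**Degenerate inputs.** Fewer than `c_min + 1` points, all-coincident
points, or a middle segment too thin to cluster raise typed errors naming
the stage; a single-cluster silhouette and zero-vector angles are typed
errors as well rather than silent NaNs.

## Known limitations

* Rows are reported for one visible side; no attempt is made to infer the
  whole-ear row count from a single view.
* A truth row reduced to exactly 2 visible kernels cannot be recovered:
  the minimum-residue rule (3 points) classifies its kernels as outliers,
  giving an off-by-one row count on such ears. This is the dominant
  residual error mode in the clean battery.
* `theta_T` is fixed, not adaptive; ears whose genuine curvature exceeds
  `2 θ_T` per step (strong spirals sampled sparsely) will shed kernels into
  the outlier set.
* The silhouette criterion can occasionally prefer splitting a long
  twist-spread row over separating the two tightly spaced rows at a
  silhouette edge; this is a model-selection ambiguity inherent to the
  squeezed representation.
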