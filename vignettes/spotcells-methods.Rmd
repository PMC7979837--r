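---
title: "Methods: cell geometry, neighbour detection and local variability in spotcells"
author: "spotcells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell geometry, neighbour detection and local variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spotcells` analyses single-molecule FISH experiments in blastoderm-stage
embryos after spot detection and segmentation have been done: its inputs are
tables of 3D spot coordinates in micrometres (a dense membrane-channel spot
cloud labelled with cell ids, and per-gene transcript spots), and its
outputs are per-cell counts, an immediate-neighbour graph, and per-cell
local-variability scores. This vignette explains the models and the
numerical choices.

## Cell polygons

A cell's shape is taken to be the **convex hull** of its membrane spots.
Blastoderm cells are columnar, near-convex prisms, and convexity buys exact
geometric predicates: point containment is a conjunction of face half-space
inequalities, and the distance between two cells is a convex programme.
Non-convex (e.g. strongly interdigitated) cells would be clipped to their
convex envelope; this is a known limitation, acceptable for the columnar
epithelium this package targets, and alpha-shape reconstruction is
deliberately out of scope.

The hull is built by an incremental visibility/horizon algorithm over
double-precision micrometre coordinates. Cells with fewer than four
non-coplanar spots (within tolerance) cannot span a 3D body; they are
reported as *degenerate* and excluded rather than fabricated, and downstream
scoring treats them as isolated.

Numerical choices:

* coplanarity/containment tolerance: **1e-9 μm** absolute — far below any
  microscope's localisation precision, far above double-precision noise at
  embryo coordinates (hundreds of μm);
* points are inserted farthest-first, which avoids degenerate horizons on
  structured inputs; a candidate face whose vertices are (near-)collinear is
  rejected and the inserting point skipped — such a point adds no volume
  beyond tolerance;
* face normals are oriented against a strictly interior reference point (the
  initial simplex centroid), making orientation independent of insertion
  order; volume and solid centroid follow from signed tetrahedra.

## Immediate-neighbour detection

The contact rule mirrors expand-and-intersect: every polygon expanded in 3D
by r, intersections then link exactly the directly neighbouring cells. The
default **r = 0.6 μm is roughly 10% of a blastoderm cell diameter**; a
fractional form (`expansionFraction`, resolved against the median cell
diameter of the data set) is available for tissues at other scales.

Expansion is interpreted as the **Minkowski sum with a ball of radius r**,
not as a vertex displacement: pushing mesh vertices outward under-expands
near face interiors and depends on the triangulation, whereas for convex
bodies the Minkowski form has an exact algebraic equivalent —

> expanded polygons intersect ⇔ d(P_i, P_j) < 2r,

with d the minimum distance between the unexpanded hulls. That distance is
computed by minimising ‖p − q‖ over convex combinations of the two vertex
sets, a small strictly-convex quadratic programme (quadprog) after a ridge
of 1e-9·max‖v‖² — the induced distance error is orders of magnitude below
the 2r decision scale. Ties at exactly 2r are a measure-zero event and are
resolved as *non-adjacent* (strict `<`) for determinism. The test suite
checks this rule against an independent certificate oracle: sampled
Minkowski boundary pairs certify intersection, support-function separating
directions certify disjointness.

Candidate pairs are pre-filtered by centroid distance ≤ sum of circumradii
+ 2r — a provably conservative bound, so pruning can never drop a true
neighbour — and most survivors are resolved by bounding-box lower bounds or
vertex-pair upper bounds before the exact QP runs. This keeps the default
2000-cell embryo's neighbour stage near a second instead of O(n²) hull
distances.

The **radius method** (`0 < ‖c_i − c_j‖ ≤ R`, inclusive) is kept as the
simple alternative; duplicate centroids connect (and are logged), and R = 0
yields an edgeless graph.

## Spot-to-cell assignment

A transcript spot inside exactly one hull belongs to that cell. Because
hulls are built from jittered spot clouds they may overlap slightly; a spot
inside several hulls is assigned to the **nearest polygon centroid** and
flagged ambiguous — deterministic and order-independent. Spots inside no
hull stay unassigned (in real embryos these are mostly basal transcripts
below the membrane-ingression limit, which cannot be attributed with
certainty); unassigned and ambiguous fractions are reported.

## Local variability statistics

For focal count x with neighbour counts n_1…n_k (neighbour group = focal ∪
neighbours):

* **Fano factor** = population variance / mean of the group. Variance and
  mean are population measures (divide-by-n); the sample (n−1) form is
  exposed as an option. An all-zero group returns 0 rather than NaN — a
  deliberate, heatmap-friendly convention, flagged by the all-zero group
  mean in the output.
* **NV** = mean_j |x − n_j| / X_max, X_max the per-gene maximum count over
  the analysed cells. NV is invariant under adding a constant to the focal
  cell and all its neighbours: it reports *numerically* large local
  differences on the scale of the gene's maximal expression.
* **PV** = mean_j |x − n_j| / max(group). The group maximum includes the
  focal cell — required for the boundary case of a single transcript among
  empty neighbours, which must score exactly 1 (otherwise the normaliser
  would be zero). PV falls as the same absolute difference rides on a
  larger baseline.
* **PV filter**: raw PV is kept only when the group mean count is ≥ 1
  (inclusive); otherwise the filtered score is 0. The group for the filter
  also includes the focal cell, consistent with the Fano group.

Isolated cells (no neighbours, including degenerate-geometry cells) score 0
on all three measures and are flagged rather than dropped, keeping the
score table rectangular. Both NV and PV are bounded in [0, 1]; the bounds
are attained and are enforced by exhaustive/randomised enumeration in the
tests.

Count histograms use bins [(k−1)·w+1, k·w] (with the default width 5:
"1-5", "6-10", …) and exclude zeros by default, since for patterned genes
the zero class is dominated by cells outside the expression domain.

## The synthetic embryo

The generator emulates the *detected-spot level* of a cellular blastoderm —
the actual input of the pipeline — not images (no voxels, PSFs or optical
noise). Cells are hexagonal prisms on a regular lattice:

* ~**2000 cells**, centre spacing (flat-to-flat diameter) **6 μm**, depth
  **9.6 μm** (a 48-slice stack at 200 nm), i.e. the scale of a real
  segmented embryo;
* **40 membrane spots per cell** (~80,000 per embryo): the 12 prism corner
  vertices (a tricellular-junction analogue that makes the spot cloud span
  the full cell volume, as a dense real membrane stain does), plus random
  points on the lateral faces and the apical/basal rims, all displaced by
  isotropic Gaussian jitter of sd **0.1 μm** (a free simulation choice —
  no quantitative membrane-localisation noise model is available — exposed
  as a parameter);
* per-gene counts with means from AP-axis profiles — a seven-stripe
  Gaussian-bump pattern and logistic-edged broad domains with graded
  borders, peak means 60–80 mRNA/cell — and **negative-binomial noise with
  variance 3× the mean** by default (Poisson optional): patterned genes in
  fixed embryos are overdispersed;
* mRNA spots: exactly the true count per cell, uniform inside the prism
  inset by **0.5 μm** from every face. The inset exists so that exact count
  recovery is a well-posed end-to-end invariant: hulls built from jittered
  membrane spots can locally erode ~3–4σ (σ = 0.1 μm) inside the true
  prism, so the inset is set at 5σ a priori to dominate that erosion.

The lattice itself is kept regular — all positional noise lives in the
membrane-spot jitter — so the prisms remain an exact, non-overlapping
partition: true adjacency (lattice edges; interior degree exactly 6) and
true counts stay well-defined ground truth. Two-channel data for
concordance checks are generated by independent binomial thinning (p = 0.5)
of a parent count, mimicking interleaved probe sets reporting the same
molecules.

What passing tests on this generator shows — and does not: geometry,
assignment and scoring are exact on near-convex, monolayer, well-separated
cells with unbiased spot noise. Real embryos add segmentation errors,
non-convex membranes, spot under/over-detection, basal ambiguity and depth-
dependent signal loss; none of these are modelled, so the generator
validates the *code*, not the upstream microscopy.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; the pipeline fans one master seed out
to per-stage seeds by fixed offsets, so stages can be re-run in isolation.
Two runs with the same seed produce byte-identical CSVs (the manifest
records an md5 per output file).

The test suite exercises unit geometry on analytic fixtures (cubes, balls,
19-cell lattices), property checks on 100-pair random-polytope batches and
300-centroid brute-force comparisons, and the full default embryo (2000
cells, ~80,000 membrane spots, ~150,000 transcripts) for adjacency
recovery, exact count recovery and determinism — sizes chosen to match the
study conditions while keeping a complete run in minutes on one CPU.

## Known limitations

* Convex cells only; strongly non-convex shapes are clipped.
* Contact detection assumes a sensible expansion r: much larger values
  bridge second-ring cells, much smaller ones miss true contacts (the edge
  set is monotone in r, so the sensitivity is easy to probe).
* NV requires the population maximum; comparing NV across genotypes with
  different maxima requires care.
* The statistics describe *local* variability; no inference (promoter
  models, significance tests between genotypes) is attached to them here.
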