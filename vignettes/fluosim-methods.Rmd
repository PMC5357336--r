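---
title: "Simulating fluorescence cell micrographs with pixel-exact ground truth"
author: "fluosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating fluorescence cell micrographs with pixel-exact ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluosim)
```

## Why simulate micrographs

Cell segmentation pipelines are conventionally validated against expert
hand annotations. Hand delineation is slow, and it carries inter- and
intra-observer variability that contaminates the validation itself —
especially where cells touch, overlap or overlay. A simulator that renders
realistic fluorescent cells *and knows every pixel's provenance* sidesteps
the problem: the ground truth is exact by construction, and scene
parameters that are confounded in real data (cell density, degree of
overlap, noise level) can be varied one at a time.

`fluosim` builds such scenes from three components learned from, or
emulating, annotated cell patches: a statistical shape model for outlines,
an intensity-weighted elastic warp that transfers real cell textures onto
generated outlines, and an overlap-bounded placement procedure. On top of
the simulator sit the two objective image measurements used to compare
simulated and real data, and a reference segmentation harness so that the
effect of, say, increasing overlap on segmentation accuracy can be
quantified directly.

## Cell shapes: a PCA shape model with a size floor

Annotated masks are converted to contours of `N` arc-length-equidistant
points (default `N = 100`; the boundary is traced at the 0.5 iso-level of
the mask so polygon area matches pixel area). Contours are centered,
rotated to their principal axes, and put into point-to-point
correspondence by an exhaustive search over all `N` cyclic shifts and both
traversal orientations, scored by summed squared distance after the
optimal rotation; the reference is the first contour on the first pass and
the running mean, Procrustes-style, on the second. Scale is *not*
normalized away: absolute size matters downstream for placement and
texture transfer.

PCA on the aligned `2N`-vectors gives the mean shape $x_m$, orthonormal
eigenmodes $P$ and per-mode variances $\lambda_j$. New shapes are

$$x = x_m + P b, \qquad b_j \sim \mathcal N(0, \lambda_j)
\text{ clamped to } \pm 3\sqrt{\lambda_j},$$

with a candidate rejected and redrawn if its polygon self-intersects or
falls below the minimum-size floor `r_min` (mean distance of contour
points from their centroid, in pixels). The floor prevents degenerate,
implausibly small cells; it is the package's operationalization of the
coefficient-space size constraint, whose literal form involves a
pseudo-inverse acting on a centered mean and is not well defined — the
raw coefficient test $\lVert b - P^{+} x_m \rVert > r_{min}$ remains
available via `constraint = "coefficient"`. Because coefficients are
clamped (not redrawn), their asymptotic variance is the censored-normal
second moment $0.995\,\lambda_j$; the test suite checks recovery against
that analytic value.

The number of modes defaults to the smallest set explaining 98% of the
training variance.

## Textures: intensity-weighted elastic warping

The texture of an annotated cell is treated as an elastic tissue spanned
between fixation points on the target outline. Three point classes carry
three energy terms with weights `w_fix`, `w_border`, `w_bulk`:

* **fixation points** — every 4th contour point (configurable), pinned to
  the matching target contour point by a linear spring;
* **border points** — the mask's boundary pixels, chained along the traced
  boundary with springs between consecutive points;
* **bulk points** — interior mask pixels with 8-connected springs whose
  stiffness is $\log(1+I(p)) \cdot \log(1+I(n))$, so bright texture
  resists deformation more than dim texture (`bulk_force()` evaluates this
  printed gradient term exactly).

Design choices a maintainer should know about:

* **Rest configuration.** Border and bulk springs are at rest in the
  *source* configuration (`rest = "natural"`), so an untransformed patch
  is an exact equilibrium and the identity warp reproduces its input
  bit-for-bit. Literal zero-rest-length springs (`rest = "zero"`) are kept
  as an option, but they contract the boundary even when source and target
  coincide, which contradicts the intended identity behavior.
* **Descent direction.** The bulk term above is the energy *gradient*;
  relaxation descends along its negative (attractive springs). Descending
  along the printed sign literally would make every neighborhood repulsive
  and the energy unbounded below.
* **Bulk reaction on the border.** Border points also receive the
  reaction of adjacent bulk springs. Without it the interior equilibrium
  is scale-invariant in `w_bulk` and the weight would have no observable
  effect; with it, raising `w_bulk` measurably reduces the stretching of
  bright regions (verified as a monotone trend in the tests).
* **Step rule.** Points are visited in a seeded random order; the summed
  force moves each point a distance capped at `step_cap` (0.5 px). The
  default learning rate is per-point stiffness preconditioning
  (`eta = "auto"`, factor `omega = 0.8`), which is ordinary gradient
  descent under a diagonal rescaling and converges orders of magnitude
  faster on stiff spring networks than a single global rate; a numeric
  `eta` reproduces the plain rule. Iteration stops when the largest
  per-sweep displacement drops below `tol` (1e-3 px) or after `max_iters`
  (5000); sustained energy increase over ten consecutive sweeps aborts
  with an error.
* **Weights.** Defaults `w_fix = 20`, `w_border = 4`, `w_bulk = 0.02`
  were chosen so that a uniform-intensity disk warped to a 1.5x disk
  reproduces the analytic similarity map to within ~1.5% mean radial
  error; they must be re-tuned per cell and texture type (the config
  exposes one triple per run).

After relaxation every point splats its source intensity to the nearest
pixel of the target's bounding box (multiple deposits average); in-mask
pixels without deposits are filled by inverse-distance-weighted
interpolation from the 8 nearest deposited pixels. Output intensities are
therefore convex combinations of source intensities and never leave the
source range. Texture patches are drawn uniformly from the pool filtered
to within ±50% of the target's polygon area, which avoids the known
failure mode of stretching a small patch onto a much larger shape.

## Placement under a Jaccard bound

A layout assigns `N_c` cells to `N_cluster` clusters with centers drawn
uniformly inside the frame (with a margin so cells stay fully inside).
The first cell of a cluster sits at its center; each later cell starts at
the center and moves outward along a random direction in 1 px increments
until its Jaccard overlap with *every* already placed cell in the scene is
at most `J_max` (`J_max = 0` demands pixel-disjoint masks; the bound is
checked scene-wide, not only within the cluster, so the audit invariant is
global). If a direction exits the frame before the bound is met, a new
direction is drawn (32 retries, then the layout is declared infeasible).
One deliberate deviation from a strict first-cell-at-center rule: when
another cluster's cells already occupy the center, the first cell moves
like any other, keeping the overlap bound absolute.

The four overlap degrees used throughout are presets of this machinery,
all with a single cluster: isolated (`J_max = 0` plus a 2 px minimum
gap), touching (`J_max = 0`, abutting allowed), overlapping
(`J_max = 0.15`) and overlaying (`J_max = 0.40`). The two positive bounds
are not quantified in the source material and are config-exposed; in a
realistic-overlap study `J_max` would be measured from expert annotations
of real data and passed in.

## Scene composition and ground truth

Pipeline order: Perlin gradient-noise background (octave-summed, amplitude
halving per octave, rescaled to `[offset, offset + amplitude]`), cell
intensities added at their placed offsets (fluorescence is additive in
overlap regions; a `maximum` mode exists for comparison; background cells
are deliberately not blurred), Gaussian sensor noise, clipping to the bit
depth (8-bit default) and rounding to integer gray levels. The fraction
of clipped pixels is recorded and warned about above 1%.

The label map carries the topmost cell id on overlap pixels, but the full
per-cell masks, contours, cluster ids and source-patch ids are kept, so
overlaps are exactly recoverable. Every image derives its
cell-generation, placement and composition seeds from the master seed by
a counter-based rule recorded in the manifest; an overlap series built
from one master seed therefore contains *identical cells* at every
degree, differing only in arrangement — which is what makes paired
comparisons across degrees exact.

## Objective measurements

Two per-cell measurements, each averaged with equal cell weight
(a pixel under two cells contributes to both):

* mean in-cell intensity — mean over cells of the mean intensity inside
  the cell mask;
* SMD (summed mean difference) — per-cell mean absolute deviation from
  the cell's own mean,
  $\mathrm{SMD} = \frac{1}{N_C}\sum_c \frac{1}{N_c}\sum_{p \in c}
  \lvert I(p) - A_c \rvert$ — a texture/edge-strength proxy.

SMD is invariant to adding a constant to the image and scales linearly
with multiplicative rescaling; both laws, and a brute-force pixel-loop
equivalence, are tested. Dataset summaries average per image first, then
over images (the alternative — pooling all cells — is not used, and the
choice is visible in `summarize_dataset()`).

With additive composition, mean in-cell intensity necessarily rises with
the overlap degree; isolated and touching are an exact statistical tie
(identical cells, zero overlap in both), so the trend test compares
paired per-image differences at 99.5% one-sided confidence rather than
asserting a strict inequality at the tie.

## The reference segmentation harness

The harness reproduces a conventional pipeline: DoG band-pass
(`sigma_low`, `sigma_high`), k-means on the filtered intensity
(quantile-seeded, hence deterministic) with the brightest cluster(s) as
foreground, then marker-based watershed on the relief
`w * edge + (1 - w) * inverted distance transform`, with markers from
distance-transform maxima (*hybrid*) or from supplied seed points such as
nuclei centroids (*seeded*; seeds landing outside the foreground snap to
the nearest foreground pixel). Components below `a_min` pixels are
removed. The standard operators are EBImage's; the harness contributes the
wiring, the scoring and the optimizer.

Scoring uses the combined Jaccard: predicted and ground-truth cells are
matched one-to-one greedily by descending pairwise Jaccard and the matched
sum is divided by `max(n_pred, n_gt)`, so both false splits and false
merges are penalized; the matching rule is isolated in one function so a
Hungarian variant is a one-line swap. Parameters are optimized by cyclic
coordinate descent over config-exposed grids (each parameter swept to its
grid argmax holding the others fixed, cycling until a full cycle improves
by ≤ 1e-4), and evaluation uses seeded k-fold cross-validation (default
3 folds): optimize on the training split, score the held-out split, every
image tested exactly once.

## What the procedural fixtures do and do not show

All tests and the acceptance script run on procedural patches: disks,
ellipses and band-limited radially perturbed blobs (guaranteed simple
polygons) carrying uniform, radial-gradient or speckled textures. These
exercise every contract of the pipeline — shape statistics, warp
fidelity, overlap bounds, trend directions — but they are smoother and
cleaner than real stains: no debris, no shading fields, no
out-of-focus blur, and shape variability far below that of, say,
spreading macrophages. Passing on fixtures therefore demonstrates
correctness of the machinery, not photo-realism for a given cell type;
realism on real data depends on the annotated patch pool supplied for
training, and high-quality input patches remain mandatory.

## Problem sizes and numerical choices

The always-run suites use sizes chosen to exercise the statistics without
waste: shape recovery trains on 200 blobs and audits 10,000 samples
(5,000 in the acceptance script); the warp oracle uses a radius-16 disk
scaled 1.5x; the placement audit replays 100 seeded layouts across
`J_max` ∈ {0, 0.15, 0.4}; the overlap series is 4 degrees × 12 images of
128² px with 6 cells each; the cross-validated harness runs on the first
10 images per degree with reduced grids (σ ∈ {1, 1.5, 2} × {3, 4, 5},
k ∈ {2, 3}, w ∈ {0, 0.2, 0.4}, σ_ws ∈ {1, 2}, a_min ∈ {20, 50, 100}),
3 folds and 2 coordinate-descent cycles. Degenerate inputs are refused
early with named errors (multi-component masks, collinear contours, empty
masks, infeasible layouts, label overflow past 16-bit with advice to use
32-bit mode).

## Known limitations

Single channel per run (no coupled nucleus/cytoplasm scenes); no optical
model (PSF, depth of field) and no illumination/shading artifacts; no
physical cell-cell adhesion — placement is purely overlap-bounded; very
high shape-variability populations are better served by clustering the
training patches and fitting one shape model per cluster.
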