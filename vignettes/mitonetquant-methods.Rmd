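---
title: "Quantifying mitochondrial network morphology: models, parameters and validation"
author: "MitoNetQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial network morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoNetQuant)
```

# The measurement problem

Mitochondria in muscle and neuronal cells form tubular networks whose
morphology — coverage, particle size, fragmentation, interconnectedness —
reports on the balance of fission and fusion. A single-channel micrograph
of an outer-membrane GFP reporter contains that information, but extracting
it reproducibly requires a fixed, parameterized pipeline rather than visual
scoring. MitoNetQuant implements such a pipeline: enhance, binarize,
skeletonize, dissect the skeleton into a branch graph, and measure. This
vignette explains each model choice, every tunable parameter, what the
synthetic validation does and does not establish, and the package's known
limitations.

# Pipeline stages and their assumptions

## Local contrast enhancement

`enhanceImage()` applies CLAHE, a median filter, and an unsharp mask, in
that order. CLAHE equalizes histograms within a `claheTiles` x
`claheTiles` grid (default 8), clipping each tile histogram at a
`claheClip` fraction (default 0.01) to bound noise amplification; a 1x1
grid degenerates to global histogram equalization, as does any frame
smaller than twice the tile count (with a warning). The median filter
(radius `medianRadiusPx`, default 1 px) suppresses impulse noise without
blurring tube edges. The unsharp mask is defined explicitly as
`out = in + unsharpAmount * (in - Gaussian(in, unsharpRadiusPx))`, default
amount 0.6 at sigma 2 px, clipped to the bit-depth range. The defaults are
package choices made once for ~0.1 um pixels and tubules a few pixels
wide; all are recorded in the parameter fingerprint carried by every
output row, so a batch processed with drifting settings is mechanically
detectable.

The assumption behind this stage is that mitochondrial signal is locally
bright and curvilinear on a darker, possibly uneven background; the stage
normalizes illumination so that a single global threshold per cell is
meaningful.

## Binarization

`binarizeImage()` thresholds with Otsu's criterion by default, computed
per ROI on integer intensity levels by exhaustive search: the threshold
`t` maximizes the between-class variance of the split `{x < t}` /
`{x >= t}`, ties broken to the lowest level, and foreground is `x >= t`.
Operating on integer levels makes the threshold exactly reproducible and
directly comparable to an independent exhaustive search, and makes the
mask invariant to affine intensity rescaling up to quantization. A
zero-variance ROI has no threshold; it yields an empty mask and a warning
rather than an arbitrary cut. Connected foreground components smaller than
`minObjectPx` (default 4 px, 8-connectivity) are removed as specks — at
the default calibration, 4 px is 0.04 square microns, well below any
resolvable mitochondrion.

## Skeletonization

`skeletonize()` reduces the mask to a 1-px backbone by Zhang-Suen parallel
thinning followed by a sequential cleanup that deletes pixels whose
Yokoi/Hilditch connectivity number is 1 and that have at least two
neighbours. The cleanup matters: parallel thinning leaves staircase-corner
pixels that a naive neighbour count would tag as junctions on every curved
tubule. Two guards keep the topology contract: any residual fully-
foreground 2x2 block is reduced via the same connectivity test, and a mask
component that thinning deletes entirely (an isolated 2x2 block is the
canonical case) is restored as its single most central pixel, so component
counts are always preserved.

Thinning algorithms have a directional bias: a mask and its 90-degree
rotation can yield skeletons differing by a few pixels. Object, junction
and endpoint counts are invariant on tubular structures (asserted in the
test suite); total skeleton length agrees across rotations to well under
2%, and branch counts can differ by one when a marginal loop forms in one
orientation only. Cell-level conclusions are unaffected.

## Tagged and labelled skeletons; the branch graph

`tagAndLabel()` assigns per-pixel roles from the 8-neighbour count —
endpoint (0 or 1 neighbours), slab (2), junction (3+) — and labels objects
by 8-connected components in raster-scan order. An isolated pixel has zero
neighbours; the package tags it as an endpoint (the endpoint rule is
"at most one neighbour") and it becomes a degenerate one-node object with
no branches.

`buildSkeletonGraph()` merges 8-adjacent junction pixels into a single
junction node at their centroid — a Y- or X-crossing of wide tubes thins
into a small cluster of junction-tagged pixels that is one biological
junction, not several. Two further rules handle thinning artifacts and
topology:

* **Split junctions.** Thinning can split one crossing into two junction
  clusters a pixel or two apart. Junction-junction branches with at most
  `mergeGapPx` (default 2) intermediate pixels are contracted into one
  node. Contracting a connector cannot change the cycle count.
* **Pure loops.** A closed curve with no junctions or endpoints is one
  object with a single self-edge; the edge needs a node, so an "anchor"
  node is placed at the raster-first pixel. Anchor nodes are excluded from
  junction and endpoint counts.

Branches are traced through slab pixels from node to node; their metric
length sums Euclidean step lengths (1 for orthogonal, sqrt(2) for diagonal
moves, scaled by the pixel size), and paths attached to a multi-pixel
junction cluster extend to the cluster centroid so that, e.g., the four
arms of a symmetric plus-cross of two 21-px lines each measure exactly
10 pixel units.

## Spur pruning

On noisy images the Otsu boundary is ragged, and thinning converts
boundary bumps into 1-2 px terminal twigs, each fabricating a junction.
`pruneSpurs()` removes junction-to-endpoint branches shorter than
`pruneSpursPx` (default 3 px) and re-thins. Measured on synthetic frames
at signal-to-noise ratio above 5, unpruned skeletons over-count junctions
by roughly 10-15% while pruning at 3 px brings the aggregate error to
about 1%; thresholds of 5 px and above start consuming genuine short
branches. Pruning is exposed in the run configuration (0 disables it,
restoring raw neighbour-count behaviour) and participates in the parameter
fingerprint.

## Per-object and per-cell measurement

"Mitochondrial length" per object is the total skeleton length of the
object. Total length is additive, robust to exactly where the junction
node lands, and reduces to the intuitive rod length for unbranched
objects; a `lengthMode = "longest-branch"` switch reports the maximal
branch instead. Object area is the pixel count of the 8-connected mask
component containing the object's skeleton, scaled by the squared pixel
size. A "network" is an object whose skeleton contains at least one merged
junction node (i.e. a point with 3 or more incident branches); junction
counts per network measure complexity. Object number is normalized per
100 square microns of cell area — a round unit at the scale of a worm
muscle cell; the normalization is recorded in the column name
(`objects_per_100um2`). For a polygonal ROI, the cell area counts only
in-polygon pixels. With zero objects all means are written as missing
values, never 0 — a cell with no detected mitochondria must not drag group
means toward zero silently.

# The synthetic ground-truth generator

`simulateImage()` emulates the reporter signal the pipeline is built for:
bright curvilinear tubules on a dark background. Centerlines are smoothed
random walks with a fixed 1-px step and turning angle bounded at 30
degrees per step; each object draws from its own RNG substream of the
frame seed, so enlarging `nObjects` leaves earlier objects bit-identical.
Walks avoid the frame border, keep `minSeparationPx` (default 5 px) away
from other objects (enforced by rejection against a dilated occupancy
mask), and keep 7 px away from their own course more than 12 steps back —
tubules do not hairpin at sub-PSF gaps, and allowing that would create
blur-bridged contacts that corrupt the junction ground truth. Side
branches sprout at interior anchor points with probability
`branchingProb`, at 60-120 degrees from the local trunk direction,
creating degree-3 junctions. Anchors keep at least 12 steps of trunk on
either side and branches are drawn at 12 steps minimum, so every
ground-truth junction protrudes resolvably (more than two tube widths)
beyond the merged tube zone; a junction whose third arm is shorter than
the tube width is unresolvable at these optics and would make the ground
truth meaningless.

Rendering stamps disks of the tube width (default 3 px) along each
polyline, convolves with a Gaussian PSF (default sigma 1 px — the Airy
sigma of a 1.4-NA oil objective at ~0.1 um pixels), and adds Poisson shot
noise (gain 1) plus Gaussian read noise (sd 4) on a background of 20
(8-bit scale). The frame records its realized SNR, defined as the blurred
peak amplitude over the noise sd at background (~13 at defaults). Default
scene composition — 256 px frames at 0.1 um/px, 20 tubules of mean length
4 um (sd 1.5), branching probability 0.3 — yields 3-6% coverage; sparse
relative to densely packed muscle, chosen so that ground-truth identity
of every object is unambiguous under the stated separation.

`simulateConditionPair()` renders the two biological extremes at matched
signal content: few long branched tubules (fused) versus many short
unbranched ones (fragmented), iteratively rescaling the fragmented length
scale until true coverages agree within 5% relative.

What passing the synthetic validation shows: the pipeline recovers known
topology and geometry through realistic blur and mixed noise, and orders
fused versus fragmented conditions correctly at matched coverage. What it
does not show: robustness to structured background the generator omits —
worm autofluorescence, muscle-fiber striations, out-of-focus light beyond
a single Gaussian PSF, or densely overlapping networks whose ground truth
is itself ambiguous. Results on real tissue still warrant visual spot
checks of the skeleton overlays (`writeOverlayPng`).

# Numerical choices and degenerate inputs

* Coordinates are row-major with the origin at the top-left; manifest
  rectangles are 0-based half-open, polygon rasterization uses the
  even-odd rule with boundary pixels included.
* Object labels and node numbering follow raster-scan order of each
  structure's first pixel; branch tracing starts from the raster-first
  end; ties in junction attachment resolve to the raster-first junction
  pixel. Output is therefore byte-stable: identical input and
  configuration reproduce an identical CSV.
* Multi-page TIFFs quantify page 1 with a warning (single best-focus
  planes are the intended input). Calibration is user-supplied
  (`pixelSizeUm`), defaulting to 1 um/px with a warning, since TIFFs
  rarely carry trustworthy pixel sizes.
* Empty masks skeletonize to empty skeletons; zero-area ROIs error;
  a batch continues past per-ROI failures and reports them, with a
  non-zero exit at the CLI.
* The acceptance and test simulations use 256-px frames and 100-frame
  batches — sizes at which the full suite completes in minutes on a
  single core while every statistical check retains adequate resolution.

# Known limitations

* Junction counts on noisy data are accurate in aggregate (about 1% at
  the default SNR) but individual frames can be off by one or two; studies
  comparing junction counts should compare distributions, not single
  cells.
* Thinning bias makes branch counts and skeleton length weakly
  orientation-dependent (under 2% in length); counts of objects,
  junctions and endpoints are orientation-invariant on tubular
  structures.
* Coverage inherits a small positive bias (~1.5 percentage points at
  defaults) because the PSF widens tubes before thresholding; comparisons
  across conditions imaged identically are unaffected.
* The pipeline is 2D: it quantifies single planes, not z-stacks, and
  crossing tubules in projection merge into one object.
* No background subtraction or deconvolution is performed; strongly
  uneven backgrounds should be corrected upstream.
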