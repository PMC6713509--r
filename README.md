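# MitoNetQuant

Per-cell morphometry of mitochondrial networks in single-channel
fluorescence micrographs.

Mitochondria shift between fused, interconnected networks and fragmented
collections of short rods — a balance that changes with age, stress and
genetic perturbation of the fission/fusion machinery. Imaging an
outer-membrane reporter (e.g. a TOMM-20::GFP fusion) in *C. elegans* muscle
or neurons shows these states clearly, but comparing genotypes and ages
requires turning each cell image into numbers. MitoNetQuant does that: from
a calibrated grayscale TIFF and a set of per-cell regions of interest it
produces one CSV row per cell with the attributes that discriminate the
fused and fragmented states.

## The pipeline

Each cell image passes through:

1. **Crop** — rectangular or polygonal ROIs cut from large acquisitions
   (`cropRoi`, `batchCrop`); polygon crops carry a validity mask so
   coverage is computed over in-cell pixels only.
2. **Enhance** — contrast-limited adaptive histogram equalization (CLAHE),
   a median filter, and an unsharp mask
   (`out = in + amount * (in - Gaussian(in, radius))`), in that order
   (`enhanceImage`).
3. **Binarize** — per-ROI Otsu threshold (exhaustive search over integer
   intensity levels; foreground is `x >= t`) or a fixed level, then removal
   of foreground specks below `minObjectPx` (`binarizeImage`).
4. **Skeletonize** — topology-preserving thinning to a 1-px backbone
   (Zhang-Suen with a connectivity-number cleanup; `skeletonize`).
5. **Tag, label, graph** — every skeleton pixel is tagged by its
   8-neighbour count (0-1: endpoint, 2: slab, 3+: junction), objects are
   labelled by 8-connected components, 8-adjacent junction pixels merge
   into single junction nodes, and branches are traced with metric lengths
   (orthogonal step = pixel size, diagonal = sqrt(2) x pixel size)
   (`tagAndLabel`, `buildSkeletonGraph`, optional `pruneSpurs`).
6. **Measure** — per-object length, area, branch/junction/endpoint counts
   and the network flag; per-cell coverage, object density, means, and
   network complexity (`measureObjects`, `summarizeCell`,
   `writeMetricsCsv`).

The per-cell attributes, in CSV column order: `roi_id`, `source_id`,
`cell_area_um2`, `mito_coverage_pct` (percent of the cell area covered by
thresholded signal), `object_count`, `objects_per_100um2` (object number
normalized per 100 square microns), `mean_object_length_um` (total skeleton
length per object by default; `--length-mode longest-branch` switches),
`mean_object_area_um2`, `network_count` (objects with at least one merged
junction node), `junction_count_total`, `mean_junctions_per_network`,
`branch_count_total`, `threshold_used`, `params_fingerprint` (hash of every
analysis parameter — rows from different settings refuse to share a CSV
unless explicitly allowed).

Fragmentation reads as higher `objects_per_100um2` with lower
`mean_object_length_um`; fusion as fewer, longer objects with more
networks and junction points.

A built-in generator (`simulateImage`, `simulateConditionPair`) renders
ground-truthed synthetic micrographs — random-walk tubules with controlled
branching, width, Gaussian PSF and Poisson-Gaussian noise — so the whole
pipeline is validated without microscope data.

## Worked example

Simulate one matched fused/fragmented pair at equal mitochondrial content
and quantify both frames:

```r
library(MitoNetQuant)
pair <- simulateConditionPair(simParams(seed = 42L), fusedN = 5L, fragmentedN = 50L)
cfg  <- runConfig(pixelSizeUm = 0.1)
rbind(quantifyOne(pair$fused$image, cfg),
      quantifyOne(pair$fragmented$image, cfg))
```

```
           roi_id mito_coverage_pct object_count objects_per_100um2 mean_object_length_um network_count junction_count_total
1 sim_seed3034655             7.985            5             0.7629                23.312             5                   11
2 sim_seed4041928             8.846           50             7.6294                 1.845             1                    1
```

Both frames hold a similar amount of signal (~8% coverage), but the fused
frame resolves into 5 long branched networks (mean length 23.3 um, 11
junction points; ground truth is 11), while the fragmented frame contains
50 short rods (mean 1.8 um) at 10x the object density — the quantitative
signature separating the fused and fragmented states.

The same analysis from a shell, via the bundled CLI:

```sh
inst/scripts/mitonetquant simulate --preset pair --seed 42 --out frames/
inst/scripts/mitonetquant batch --cropped-dir frames/ --out metrics.csv --pixel-size 0.1
inst/scripts/mitonetquant crop --manifest rois.json --out-dir crops/ --pixel-size 0.065
```

ROIs arrive as a JSON manifest (schema in `?readRoiManifest`); ImageJ
`.roi`/RoiSet files are not read directly — export their bounding
rectangles into the manifest.

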