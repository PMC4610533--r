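---
title: "Segmenting white blood cells in stained smears: the model behind leukoSeg"
author: "leukoSeg maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting white blood cells in stained smears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukoSeg)
```

## The problem

A differential blood count requires locating every leukocyte (white blood
cell, WBC) in a Wright-stained smear micrograph. The stain renders nuclei
dark purple, cytoplasm a lighter lilac, red blood cells (RBCs) reddish and
the plasma background pale. Three things make automatic segmentation hard:
illumination differs between microscopes and sessions; the cytoplasm tint
of leukemic marrow cells is close to the nucleus tint; and cells adhere,
so a single foreground component can contain two to six cells.

leukoSeg addresses all three with a four-phase pipeline whose key idea is
to obtain two kinds of *seeds* before any splitting is attempted: the
nucleus groups ("inside seeds", one per cell) and the whole-cell regions
("outside seeds"). Adhesion is then resolved by watershed flooding of the
cell regions from the nucleus groups.

## Phase I: nucleus seeds from illumination-invariant color ratios

All color features are ratios, so a global multiplicative illumination
change cancels:

* the rg chromaticities $r = R/(R{+}G{+}B)$, $g = G/(R{+}G{+}B)$,
  $b = 1 - r - g$;
* the HSI saturation $S = 1 - 3\min(R,G,B)/(R{+}G{+}B)$.

Nuclei combine the highest saturation with the lowest green chromaticity
of any structure in the field. Both planes are min–max rescaled to the
byte range ($I_s$, $I_g$) and the enhancement $I_E = I_s / I_g$ (zero
where $I_g = 0$) is thresholded by Otsu's method, keeping the bright
side. Two numerical guards surround the threshold:

* **Tail winsorisation.** $I_E$ is a ratio; a handful of pixels with a
  near-zero denominator would otherwise occupy the top of the byte range
  and crush every real class into one histogram bin. Values above the
  0.995 quantile of the positive part (`ratioClipQuantile`) are clipped.
* **Raw-ratio floor.** Otsu assumes the histogram is bimodal in the right
  place; when nuclei cover only a fraction of a percent of the field the
  maximal between-class split can land between background and RBCs
  instead. The mask is therefore intersected with $S/g > 1$ computed on
  the *unnormalized* planes — a scene-independent stain property:
  saturation exceeds green chromaticity only on strongly stained nucleus
  pixels. On a field with no leukocyte at all this floor empties the mask
  instead of promoting the red cells.

The thresholded mask is repaired by a closing-then-opening with a small
disk (`seRadius - 1`) — raw pixel noise otherwise inflates chain-code
perimeters about two-fold, which matters later — and components below
`minNucleusArea` (S1 = 100 px) are removed as platelets and debris.

Segmented neutrophil nuclei come in up to five lobes. Lobe pairs whose
areas lie strictly inside `coreAreaRange` (100–950 px) and whose minimum
boundary-to-boundary Euclidean distance is below `maxCoreGap` (55 px) are
joined by filling the axis-aligned rectangle spanned by their centroids,
padded by `centroidPad` (5 px) and clamped to the image; the closest pair
is connected first and the search iterates to a fixed point. The pixels
added here are remembered: a seed containing them is known to be *one*
nucleus group.

## Phase II: whole-cell regions from two complementary strategies

**Strategy 1 — cyan channel + mean shift.** The CMYK cyan fraction
$C = (1 - R' - K)/(1 - K)$, $K = 1 - \max(R', G', B')$ is high on nuclei,
moderate on cytoplasm and essentially zero on RBCs and background. The
byte-scaled plane is smoothed by mean-shift filtering in the joint
$(x, y, \text{intensity})$ space with a flat kernel: each pixel's estimate
moves to the mean of the samples within Chebyshev spatial distance
$h_s = 3$ and intensity distance $h_r = 3$, for at most four iterations or
until the intensity shift drops below 0.5. The filter is a contraction of
the intensity range and cannot blur across steps wider than $h_r$.

**Strategy 2 — b/g enhancement.** Cell pixels (nucleus and cytoplasm)
have a larger blue-to-green chromaticity ratio than RBCs and background;
$I_{en} = b/g$ (zero where $g = 0$) is winsorised and byte-scaled.

Both planes are cut by the same *area-anchored adaptive threshold*: the
whole-cell area is assumed to be $N$ times the nucleus area ($N = 3$ for
peripheral blood, $1.5$ for bone marrow, where nuclei dominate the cell),
so the RBC-plus-background budget is $S_{image} - N \cdot S_{nucleus}$
with $S_{nucleus}$ the total inside-seed area. The threshold is the
smallest gray level whose cumulative histogram count reaches that budget;
the cell mask is strictly above it. This rule is rank-based, hence
invariant to any monotone rescaling of the plane, and monotone in both
$N$ and the nucleus area.

The two masks are unioned (a cell seen by only one strategy survives),
denoised at `minCellArea` (S2 = 350 px), hole-filled (a nucleus darker
than its cytoplasm can punch a hole in the cyan mask, and watershed seeds
must lie inside the region), and smoothed by the same close-open repair.

## Phase III: nucleus-marked watershed

A component of the cell mask is *adhesive* when any of three signals
fires:

1. its area exceeds `adhesionMinArea` (S3 = 3500 px, just above the
   largest single cell) **or** its roundness (compactness
   $P^2 / 4\pi A$, ~1 for a disk) exceeds `adhesionRoundness` (R = 3);
2. it contains two or more nucleus seeds (one cell carries one nucleus);
3. its single nucleus seed is itself adhesive: roundness above
   `nucleusAdhesionRoundness` (1.4) *and* area above the single-core
   bound — the signature of two merged nuclei. Seeds assembled by the
   centroid connection are exempt, and so are seeds no larger than one
   core: both are known single-nucleus configurations.

The defaults in signal 1 combine the two printed bounds with *or* rather
than *and*: the compactness of two overlapping disks is at most 2
(tangency) and decreases with overlap, so a conjunctive rule could never
fire on the canonical two-cell clump, while a disjunctive false positive
is harmless — a convex component with a single marker passes through both
watershed passes unchanged. Both the rule and the comparator are
parameters (`adhesionRule`, `adhesionComparator`) for users who want the
conjunctive reading.

If nothing is adhesive the components are returned as cells. Otherwise
the mask is flooded from the nucleus-group markers over the negated
Euclidean distance-to-background relief (`watershedSurface` can switch to
the distance-to-seed relief; basins coincide for disk-like cells). The
flood is a deterministic priority queue: lowest relief first, ties broken
by insertion order, so ridge pixels are assigned reproducibly and the
basins partition the mask exactly.

Basins still adhesive after this pass — typically because their nuclei
merged into one seed — go through a second, adaptive split:

* the basin's nucleus group is *corroded* through the superlevel sets of
  its distance map until it falls apart into at least two cores; merged
  nuclei overlap only slightly, so their waist is deep and the cores are
  reliable markers;
* failing that, local-extremum regions
  $\{d \ge \texttt{extremumRadius}\}$ ($R_s = 7$ px) of the basin itself
  are used;
* failing that, the basin is corroded the same way; if it vanishes before
  splitting it is returned unsplit.

Corrosion by distance-map superlevels is exact disk erosion: the split
window between a clump's waist saddle and its lobe peaks can be only two
or three levels wide, and the city-block approximation of iterated
3×3 erosion can skip it entirely. In every path a marker must look like a
core — at least 25 px and at least a tenth of the largest core at the
same depth — because thresholded masks shed small boundary fragments
under corrosion, and a fragment marker would carve a spurious cell.

## Phase IV: post-processing

The nucleus mask is intersected with the cell labels, so each nucleus
inherits its cell's label and a nucleus straddling a ridge is split with
the cells. Components without a single nucleus pixel — stain debris,
RBC clumps picked up by Phase II — are removed (equivalently: the cell
mask is reconstructed from the nucleus marker). Labels are compacted and
per-cell features (area, chain-code perimeter with $\sqrt2$-weighted
diagonals, bounding box, roundness, centroid) are reported.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `minNucleusArea` (S1) | 100 | px | nucleus-mask denoising |
| `minCellArea` (S2) | 350 | px | cell-mask denoising |
| `centroidPad` (T2) | 5 | px | lobe-connection rectangle padding |
| `maxCoreGap` (l11) | 55 | px | max lobe gap for connection |
| `coreAreaRange` (s11, s12) | 100–950 | px | single-lobe area window |
| `adhesionMinArea` (S3) | 3500 | px | adhesive-cluster area bound |
| `adhesionRoundness` (R) | 3.0 | — | adhesive-cluster roundness bound |
| `nucleusAdhesionRoundness` | 1.4 | — | merged-nucleus roundness bound |
| `extremumRadius` (Rs) | 7 | px | local-extremum level, pass 2 |
| `spatialBandwidth` (hs) | 3 | px | mean-shift window half-side |
| `rangeBandwidth` (hr) | 3 | byte | mean-shift intensity bandwidth |
| `areaRatio` (N) | 3 / 1.5 | — | cell/nucleus area ratio by smear type |
| `resizeFactor` | 0.2 | — | working-scale factor |
| `seRadius` | 3 | px | structuring-element radius |
| `ratioClipQuantile` | 0.995 | — | ratio-plane winsorisation |

All pixel-valued defaults are calibrated at the working resolution
obtained by scaling full-resolution 100x oil-immersion captures
(~2080×1542) by 0.2. Images already at working scale should be processed
with `resizeFactor = 1`. The resize itself is area-averaging; final labels
are mapped back by nearest-neighbour upsampling.

## The synthetic smear generator

`makeSmear()` renders scenes with pixel-exact ground truth directly at
working scale: a pale background, reddish anucleate RBC disks, WBCs as
lilac cytoplasm ellipses (axis ratio 0.85–1) containing dark purple
nucleus disks — one per cell, or several lobes with small gaps for
segmented neutrophils — then a global multiplicative illumination factor
and additive Gaussian noise (sd 4, a mild sensor-noise level chosen so
that tests exercise the algorithm, not a denoiser). Default palettes
satisfy the stain orderings the method relies on (they are asserted by
the test suite): nucleus highest in saturation and lowest in green
chromaticity; cyan decreasing nucleus → cytoplasm → RBC/background; cell
pixels highest in b/g. The marrow palette narrows the nucleus/cytoplasm
contrast, and the marrow geometry uses $N = 1.5$.

Geometry choices that define the simulated study conditions:

* isolated cell radii 14–30 px (areas ≈ 600–2800 px) and nucleus radius
  $r/\sqrt N$, inside the published per-type ranges at working scale;
* cells that are not cluster mates keep at least 55 px of boundary
  clearance — smear fields chosen for differential counting are sparse,
  and the lobe-pairing geometry presumes that nuclei of distinct cells
  sit farther apart than `maxCoreGap`;
* adhesive clusters are built from 24–32 px cells (monocyte/blast-sized),
  placed at center distances of 0.48–0.84 times the radius sum, so a
  two-cell clump genuinely overlaps without full occlusion and its union
  exceeds S3;
* cluster-mate nuclei are pushed apart until they no longer touch —
  unless `mergedNuclei = TRUE`, which instead slides the closest pair's
  nuclei together until they overlap, the configuration that forces the
  second watershed pass.

What the generator does **not** emulate: chromatin texture, out-of-focus
blur, uneven (spatially varying) illumination, WBC–RBC adhesion, stain
precipitate. Passing tests therefore demonstrate the pipeline's logic —
seed extraction, thresholding rules, adhesion separation — under
controlled conditions, not clinical-grade performance on real smears.

## Worked example

```{r example}
scene <- makeSmear(imageSize = c(300, 400), nWbc = 4, nRbc = 50,
                   overlapFraction = 0.5, seed = 42)
params <- segmentationParams("peripheral", resizeFactor = 1)
result <- segmentImage(scene, params)
result
evaluateSegmentation(result, scene)
```

## Numerical conventions and degenerate inputs

* Histograms bin intensities by `round()` into 0–255; Otsu ties resolve
  to the smallest maximizer (across an empty inter-mode gap the
  between-class variance is flat, so the cut lands at the gap's lower
  edge); a constant plane warns and yields an empty foreground.
* The adaptive threshold clamps its budget to the image area; a budget
  below zero (requested cell area larger than the image) warns and
  returns 0.
* Zero-sum (black) pixels are achromatic: chromaticity (1/3, 1/3, 1/3),
  saturation 0.
* A marker overhanging its mask is clipped before reconstruction or
  flooding rather than raising an error.
* Chain-code perimeter of an isolated pixel is 1 by convention; labels
  that watershed ridge-cutting made non-4-connected have the perimeters
  of their pieces summed.
* Matching for evaluation requires IoU strictly above the threshold
  (perfect overlap always matches): a cell covered half-and-half by two
  predictions is broken, not correctly segmented.
* `makeSmear` is bit-reproducible for a fixed seed and restores the
  caller's RNG state.

## Problem sizes used by the validation suite

The bundled tests and the acceptance script generate all inputs
programmatically: 300×400 px scenes with 3–6 cells for end-to-end batches
(50 images), 360×420 px scenes of 2–6 overlapping cells for the adhesion
suites (100 scenes each), 20 scene pairs for the illumination contrast,
and 16×16 / up-to-24×24 random planes for the exact oracle-equivalence
checks of the mean-shift and watershed kernels.

## Known limitations

* Corrosion-based second-pass splitting needs a waist; near-total
  occlusion of one cell by another (center distance below either radius)
  is unsplittable by shape and survives as one cell.
* The area-anchored threshold inherits any error in the nucleus-area
  estimate; gross Phase I failure propagates to the cell masks.
* Multi-lobed nuclei inside adhesive clusters can be connected across
  cells by the centroid rectangle when their lobes fall in the pairing
  window; the second pass usually recovers the count, but this is the
  dominant residual error mode in the synthetic batches.
* Parameters are calibrated for the 0.2x working scale; other
  magnifications require rescaling the pixel-valued thresholds.
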