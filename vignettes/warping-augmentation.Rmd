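---
title: "Mask-guided warping augmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-guided warping augmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endowarp)
```

## The procedure and its assumptions

`endowarp` deforms an image and its segmentation mask *jointly* so that
the deformed pair remains a valid training example. The deformation is a
piecewise affine homeomorphism of the image rectangle, anchored on the
tissue itself:

1. **Keypoints.** Interior keypoints are the pixel-area centroids of the
   mask's regions (cells and guttae alike — guttae keep their region ids
   and are deformed like cells). Border keypoints are a fixed lattice of
   32 points at fractions 0, 1/8, ..., 1 of each image edge. Dense fixed
   edge points keep every triangle of the mesh inside the rectangle, so
   no output pixel ever samples outside the input (no black-triangle
   artefacts).
2. **Shifts.** Each interior keypoint moves by
   `(δx, δy) = (R₁, R₂) · d_min / s`, `Rᵢ ~ U(−1, 1)` independently per
   axis and per keypoint. `d_min` is the minimum pairwise keypoint
   distance under the per-axis-min metric `d(a, b) = min(|xₐ − x_b|,
   |yₐ − y_b|)`; the strain `s > 0` divides it, so larger `s` means
   smaller shifts. Border keypoints never move.
3. **Mesh and map.** The shifted set K′ is Delaunay-triangulated
   (`interp::tri.mesh`) and the same index triples are imposed on K,
   which makes the per-triangle affine correspondence well defined; each
   affine is solved exactly from its three vertex pairs. A draw is valid
   only if every triangle keeps strictly positive signed area on *both*
   sides — the certificate that the map is bijective on the rectangle.
4. **Resampling.** Output pixels are pulled back through the inverse
   affine of their containing triangle: bilinear interpolation for
   intensities, nearest-neighbour for labels (labels are never blended,
   so the warped mask cannot invent ids).
5. **Plausibility control.** A draw is rejected and redrawn (default
   budget 20) if the mesh folds over or the warped mask loses a region
   or fragments one into more 4-connected components than it had. This
   replaces manual curation of plausible deformations with an automated,
   reproducible rule.
6. **Refinement.** Warped masks are repaired by marker-based watershed:
   each region is eroded into a marker (disc radius 2 by default; a
   region that would vanish is restored as one pixel nearest its
   centroid, so region count is always preserved), and markers flood an
   elevation surface with Meyer's priority-flood algorithm under
   8-connectivity.

The assumptions are mild: masks partition the image into connected
regions of nontrivial area; cells are roughly convex so their centroid
is a sensible anchor; and boundary evidence in the image (dark borders
or strong gradients) exists for watershed to snap to.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `s` / `s_range` | `[2, 3]` | — | inverse deformation strength; 2 = strong, 3 = mild |
| `retry_budget` | 20 | draws | redraws before a pair is rejected |
| `connectivity_side` | `"target"` | — | which point set defines the triangulation |
| `mask_warp` | `"labels"` | — | warp label ids, or the thin boundary raster |
| `marker_erosion_radius` | 2 | px | marker conservatism for watershed |
| `elevation_mode` | `"gradient"` | — | Sobel magnitude, or `1 − intensity` |
| `min_region_area` | 5 | px | refined regions below this merge into their largest neighbour |

The `[2, 3]` strain default is the documented operating range of the
method on endothelial mosaics; values below ~1 produce deformations
that the rejection rule discards with increasing frequency.

**Choosing the elevation.** The Sobel gradient default is the robust
choice for real micrographs, where absolute intensity is confounded by
illumination gradients and glare. On renders whose borders are uniformly
dark — including this package's synthetic mosaics — `1 − intensity` is
the better topography: a dark band produces *two* gradient ridges (one
per flank), and flooding can settle one pixel off the band's centre,
while inverted intensity has a single ridge exactly on the border. On
clean synthetic mosaics, inverted-intensity refinement restores the
ground truth to interior Dice above 0.99; the gradient mode lands near
0.93 for this band-offset reason, not because the flooding misbehaves.

## The degenerate-distance policy

The per-axis-min metric makes `d(a, b) = 0` whenever two keypoints share
an x or a y coordinate. The border lattice is axis-aligned, so over all
of K the minimum is *identically* zero; even among interior centroids,
which are rounded to integer pixels, two of them almost always share a
row or column on a 96 × 96 patch (a birthday-paradox effect). The
implemented policy is therefore: compute `d_min` over interior–interior
pairs only, and floor it at 1 px when it falls below 1, with a logged
message. The floor — not the raw minimum — is what scales shifts in
practice, so typical keypoint displacements are `≤ 1/s` px and warps
are deliberately subtle. We implement the metric as printed rather than
substituting a Chebyshev or Euclidean distance, which would change the
method; the policy is the smallest intervention that keeps the shift
magnitude defined and nonzero.

## Triangle correspondence

Triangulating K and K′ independently need not give the same
connectivity, which would leave the per-triangle map undefined. The
package triangulates the *shifted* set K′ (re-triangulation of the
modified points) and imposes those triples on K, then additionally
requires positive areas on the source side. The alternative —
connectivity from K — is available as `connectivity_side = "source"`;
all package properties (vertex exactness, bijectivity certificate,
identity limit) hold for either choice.

## The synthetic generator

`generate_mosaic()` emulates a specular-microscopy endothelial patch:
a Voronoi partition of `n_cells` seed points (endothelial tessellations
are near-Voronoi, and the partition provides ground-truth labels for
free), dark intercellular borders (two-sided interface band, optionally
dilated), a `guttae_fraction` share of regions rendered as dark filled
blobs, a smooth multiplicative illumination plane in a random direction,
additive Gaussian noise, then Gaussian blur. Intensities are quantized
to the 8-bit grid so that disk round trips are exact at both 8- and
16-bit depths. Seed points keep a soft minimum separation so no cell
degenerates to a sliver, and regions are post-processed to be single
4-connected components (border carving can pinch a cell at triple
junctions).

What the generator does **not** emulate: specular glare, out-of-focus
field curvature, instrument calibration error, the intensity texture of
real endothelial cytoplasm, or realistic gutta morphology (real guttae
bulge across cell boundaries). Tests passing on these mosaics certify
the geometry, resampling, rejection and refinement machinery — not
segmentation difficulty on clinical images.

## Numerical choices and degenerate inputs

- Centroids round half-to-even to integer pixels; duplicates after
  rounding are merged with a warning, and a centroid colliding with a
  border-lattice point is dropped with a warning.
- Border-lattice positions are `round(f · (size − 1))`. On even-sized
  images the half-edge point falls at x.5, so the lattice is flip-
  symmetric only to within 1 px; on odd sizes the symmetry is exact.
- Triangles are normalized to positive signed area; map validity uses
  an area floor of 1e−9. Vertex correspondences are reproduced to
  ≤ 1e−9 px and forward-then-inverse round trips return within 1e−6 px.
- Identity maps reproduce the input bit-exactly: inverse-mapped sample
  coordinates within 1e−6 of a pixel centre snap onto it.
- Watershed flooding breaks elevation ties first-in-first-out, which is
  deterministic but marker-shape-dependent on the flat plateaus of
  quantized images; `refine_mask()` therefore iterates the
  marker → flood step to a fixed point (2–4 passes in practice, capped
  at 25), which makes refinement exactly idempotent.
- Cocircular point sets admit several Delaunay triangulations; any
  valid one is accepted and all downstream properties are
  triangulation-choice-independent.
- A mask supplied as a 0/255 boundary raster is converted to labels by
  4-connected labeling of the non-boundary pixels; frame-touching
  components larger than half the image are treated as background, and
  components under 4 px (interstitial slivers inside wide junction
  bands) are absorbed into the boundary.
- Empty masks, collinear keypoints, non-positive strain and mismatched
  dimensions are rejected with messages naming the offending input.

## Problem sizes in the test suite

The suite exercises 96 × 96 mosaics of 15–40 cells (the patch geometry
the method targets): 1000 shift fields for the bound check, 50 maps for
the bijectivity round trip on a 32 × 32 grid, 100 accepted augmentations
for region preservation, 50 paired seeds for the strain-ordering sign
test, and 20 random 15-point sets for the brute-force empty-circumcircle
check. The full suite and the acceptance script each run in well under a
minute on one CPU.

## Known limitations

- With the 1 px degenerate-distance floor, warps are subtle by
  construction; users wanting visibly strong deformations must lower
  `s` below 1 and accept higher rejection rates.
- The automated plausibility rule (fold-over + region preservation)
  is necessary but not sufficient for clinical realism; it cannot
  judge texture plausibility.
- Refinement assumes boundary evidence in the image near the warped
  boundary; on very blurred inputs watershed lines follow noise.
- `evaluate_pairs()` compares binary boundary rasters; instance-level
  metrics (per-cell IoU matching) are out of scope.
- AUROC-style score-based metrics require a model's continuous output
  and are deliberately not provided.
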