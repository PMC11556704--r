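# endowarp

Mask-guided warping augmentation for cell-mosaic microscopy images.

## The problem

Segmenting the corneal endothelium — the single layer of near-hexagonal
cells imaged by specular microscopy — is limited by the scarcity of
expert-annotated masks. Generic augmentations (flips, rotations) do not
model how a cellular mosaic actually varies between patients; guttae in
Fuchs dystrophy make things worse. `endowarp` implements an
anatomy-aware alternative: deform an image *and its segmentation mask
jointly* through a piecewise affine warp anchored on the cells
themselves, then repair the warped mask with marker-based watershed so
its boundaries stay thin, closed and aligned with the image.

It is aimed at anyone building segmentation training sets for
cell-mosaic tissue (corneal endothelium, retinal pigment epithelium,
similar epithelial sheets) who has images with label or boundary masks
and wants more of them.

## Method

For an image *I* with label mask *M*:

1. **Keypoints.** K = cell centroids of *M* (interior points) plus a
   fixed 32-point lattice on the image border (corners, edge centers,
   quarters, eighths) that pins the warp to the frame.
2. **Random shifts.** Each interior keypoint moves by
   `(δx, δy) = (R₁, R₂) · d_min / s`, with `R₁, R₂ ~ U(−1, 1)` and
   `d_min = min over pairs of min(|Δx|, |Δy|)` (interior pairs, floored
   at 1 px when degenerate). The strain `s` inversely controls
   deformation: `s = 2` strong, `s = 3` mild.
3. **Warp.** The shifted set K′ is Delaunay-triangulated; the same
   connectivity is imposed on K so every triangle carries an exact
   affine map `f`. Output pixels are pulled back through `f⁻¹` —
   bilinear for intensities, nearest-neighbour for labels. Maps that
   fold a triangle (breaking bijectivity) or lose a mask region are
   rejected and redrawn.
4. **Refinement.** Each warped region is eroded into a marker; markers
   flood an elevation map (Sobel gradient, or inverted intensity) by
   Meyer's watershed until a fixed point, giving thin closed boundaries
   with the region count preserved.

A synthetic endothelium generator (Voronoi mosaic with dark borders,
optional guttae, illumination gradient, blur, noise) provides ground
truth for testing, and Dice / accuracy / mean-IoU utilities evaluate
mask agreement.

## Worked example

```r
library(endowarp)

pair <- generate_mosaic(mosaic_spec(96, 96, n_cells = 20,
                                    guttae_fraction = 0.15, seed = 42))
pair
#> <labeled_pair> 96 x 96, 20 regions, 3120 boundary px

res <- warp_pair(pair, s = 2, seed = 7)
#> degenerate d_min (0 px): floored at 1 px
res
#> <warp_result> s = 2, d_min = 1, 0 retries, max|d| = 0.497 px

refined <- refine_mask(res$pair$image, res$pair$label_mask)
cc <- confusion(boundary_from_labels(refined), pair$boundary_mask)
sprintf("Dice %.3f  accuracy %.3f  mIoU %.3f", dice(cc), accuracy(cc), miou(cc))
#> "Dice 0.857  accuracy 0.913  mIoU 0.816"
```

The generated mosaic has 20 regions, three of them guttae. The warp at
`s = 2` used the 1 px degenerate-distance floor (integer centroids
almost always share a row or column under the per-axis-min metric, so
the raw minimum is 0 — see the vignette), was accepted on the first
draw, and moved keypoints by up to 0.497 px = d_min/s. The metrics
compare the refined warped boundary against the *original* boundary:
they are below 1 exactly because the augmentation changed the mask —
plausibly, since all 20 regions survive connected.

Batch use mirrors this via a manifest:

```r
report <- augment_dataset(manifest, "out/", augment_config(
  s_range = c(2, 3), n_outputs_per_input = 2, seed = 1))
```

which writes warped image/mask pairs plus a JSON sidecar per output
(strain, seed, d_min, keypoints, shifts) for exact replay with
`replay_sidecar()`. The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/endowarp.R generate --out data/ --n 4 --cells 20
Rscript inst/cli/endowarp.R augment data/manifest.csv --out aug/ --seed 1
Rscript inst/cli/endowarp.R evaluate aug/ truth/ --out metrics.csv
Rscript inst/cli/endowarp.R demo --out demo/
```

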