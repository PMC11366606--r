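---
title: "Methods: wheat point-cloud phenotyping from reconstruction to traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wheat point-cloud phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wheatpheno turns a colored point cloud of a potted wheat plant — the kind of
cloud a multi-view stereo (SFM-MVS) reconstruction produces — into phenotypic
traits: plant height, crown area, convex-hull volume, surface area, and
per-leaf midrib length and maximum width. This vignette explains the model
behind each stage, the tunable parameters and why their defaults are what
they are, what the built-in scene simulator does and does not emulate, and
the numerical choices that matter.

## The processing model

A raw reconstruction differs from the real scene in scale (photogrammetric
units are arbitrary) and orientation (the frame is tilted), and it contains a
pot, soil, ground, a scale marker and stray noise points besides the plant.
The pipeline undoes these in a fixed order:

1. **Scale restoration.** A sticker of known physical width $W_{real}$
   (3 cm by default) is visible in the scene. Its width in cloud units,
   $W_{virtual}$, is the mean of three repeated measurements, and every
   coordinate is multiplied by $S = W_{real} / W_{virtual}$.
2. **Frame levelling.** The ground plane is found by RANSAC (point-triple
   hypotheses, inlier count within `dist_thresh`, least-squares refinement on
   the inliers). The cloud is rotated so the plane normal $n_1$ maps onto the
   vertical reference $n_2 = (0,0,1)$ — a Rodrigues rotation about
   $n_1 \times n_2$ by $\arccos(n_1 \cdot n_2)$ — and translated so the
   ground inliers average $z = 0$.
3. **Plant isolation.** Euclidean clustering of the whole scene is wasteful
   (over 90% of points are scenery), so a centroid cut-off shrinks the
   problem first: with $z_{ground}$ the ground centroid and $z_{plant}$ the
   centroid of green points, everything below
   $z_{thr} = z_{ground} + \alpha\,(z_{plant} - z_{ground})$, $0 \le \alpha
   \le 1$, is dropped; the survivors are clustered by fixed-radius
   connectivity (two points connect when closer than `eps`), the cluster
   nearest the plant-color centroid is kept and mapped back to full
   resolution, and it is then cleaned by the color filter (keep points with
   $G-R > 5$ and $G-B > 30$, strictly) and statistical outlier removal.
4. **Stem–leaf segmentation.** Region growing on per-point normals and
   curvature (surface variation $\lambda_0 / (\lambda_0+\lambda_1+\lambda_2)$
   of the k-NN covariance): regions start at the unvisited point of least
   curvature; a neighbour joins when its normal is within `angle_thresh` of
   the normal of the point it was reached from, and continues the front only
   when its own curvature is below `curv_thresh`. Regions are classified as
   stem (strongly linear and near-vertical) or leaf.
5. **Traits.** Height is the z-range. Crown area is the product of the
   projected hull diameter and the perpendicular extent (a rotation-invariant
   reading of "maximum horizontal distance times perpendicular distance"; an
   axis-aligned variant is available via `crown_area(mode = "aabb")` — the
   two genuinely differ, e.g. for a 4 × 1 rectangle at 45°). Convex volume
   comes from a quickhull over the plant points. Surface area is the facet
   sum of a ball-pivoting mesh over MST-oriented normals. Leaf traits come
   from PCA alignment, local polynomial (loess) midrib fitting at `stations`
   x-positions, arc length of the fitted polyline, and the maximum slab
   extent perpendicular to the local midrib tangent.

```{r}
library(wheatpheno)
scene <- generate_scene(stage_preset("seedling", seed = 1,
                                     true_scale = 0.7, tilt_deg = 10))
restored <- restore_scale_and_frame(scene$cloud, seed = 1)
plant <- extract_plant(restored$cloud, seed = 1)
seg <- region_growing(plant$cloud, estimate_local_geometry(plant$cloud, 6),
                      k = 24, angle_thresh = 10, curv_thresh = 0.1,
                      min_region = 10)
phenotype_plant(plant$cloud, seg)
```

## Parameters that matter

| parameter | default | units | role and rationale |
|---|---|---|---|
| `real_width` | 3 | cm | physical marker width |
| `dist_thresh` | 0.2 | cm | RANSAC inlier band; generous against coordinate noise of a few hundredths of a cm |
| `ransac_iters` | 1000 | — | triple hypotheses; ground is ~30% of the scene, so failure odds are negligible |
| `alpha` | 0.3 | — | cut-off interpolation; low enough to stay below the stem base in pots filled nearly to the rim, high enough to clear the ground and platform |
| `eps` | 1 | cm | clustering hop on the 0.5 cm voxel working copy |
| `min_size` | 50 | points | suppresses outlier clumps |
| `gr_thresh`, `gb_thresh` | 5, 30 | 8-bit counts | green margins separating wheat tissue from soil/pot |
| `sor_k`, `sor_ratio` | 10, 3.0 | — | statistical filter; deliberately conservative because it runs last, after clustering and color filtering have removed gross noise — a small neighbourhood and a wide band preserve tapering leaf tips, whose sparsity is geometric, not noise |
| `voxel` (working copy) | 0.5 | cm | centroid/cut-off estimation only; full resolution is restored afterwards |
| `surface_voxel`, `leaf_voxel` | 0.2 | cm | uniformity for meshing and midrib fitting while keeping ~mm width resolution |
| `k` (geometry) | 30 | points | normal/curvature neighbourhood on dense clouds |
| `angle_thresh` | 8 | degrees | smoothness bound for region growing |
| `curv_thresh` | 0.05 | — | growth-front promotion bound |
| `min_region` | 100 | points | minimum organ size |
| `stations`, `span`, `degree` | 30, 0.3, 2 | — | midrib loess: degree-2 local fits with tricube weights over 30% of points, evaluated at 30 stations |

Region-growing thresholds are resolution-dependent; like the original
formulation, they need adjustment per cloud. For the ~1 mm spacing of the
simulated scenes the settings that separate seedling leaves cleanly are
smaller and looser than the defaults: geometry `k = 6` (neighbourhoods stay
local near the stem–blade junction), growing `k = 24` (the front can bridge
sparse junctions), `angle_thresh = 10`, `curv_thresh = 0.1`,
`min_region = 10`.

## The scene simulator and its ground truth

`generate_scene()` builds the canonical upright scene first and records the
truth before any distortion, so every downstream comparison is exact:

* **Plant.** One to ten tillers (vertical cylinders, radius 0.25 cm) with
  leaves attached at the stem surface. A leaf is a ribbon swept along a
  planar cubic Bézier midrib; a single `droop` parameter in [0, 1] bends it
  from a straight blade rising at 75° to an arch whose tip tangent plunges at
  −75° (the tip never falls below its attachment). The control polygon is
  rescaled so the midrib arc length equals the designed length exactly; the
  width tapers as $w(t) = w_{max}\,4t(1-t)$, clipped to $0.35\,w_{max}$ near
  the base. Base, tip and apex midrib points are always included as exact
  samples, so the designed height equals the generated z-range exactly.
* **Scenery.** A truncated-cone pot (18 cm tall, filled with soil to 17 cm —
  pots for full-cycle wheat are tall, and this keeps the α = 0.3 cut-off
  below the stem base at every stage), a planar ground patch, and a 5 × 3 cm
  white marker patch tangent to the pot wall (the 3 cm side is the width the
  scale restoration measures).
* **Colors.** Clipped Gaussians per class (plant (60, 140, 60) ± 12; soil
  (120, 100, 80); pot (150, 60, 50); ground (110, 105, 95); marker
  (250, 250, 250)). Plant samples are constrained to satisfy both green
  margins and scenery samples to violate at least one, so the color contract
  of the filter holds by construction while the distributions still overlap
  enough to exercise it.
* **Densities.** 100 points/cm² on plant surfaces (1 mm spacing — the
  resolution close-range MVS dense clouds actually reach; coarser sampling
  under-resolves the ~1.5 mm basal strips of seedling blades), half that on
  stems, 250 on the high-contrast marker, 8–25 on scenery.
* **Distortion.** The whole scene is multiplied by `true_scale`, rotated by
  `tilt_deg` about a horizontal axis, perturbed with isotropic Gaussian noise
  (`noise_sd`, raw units), and salted with uniform far outliers in a box
  three times the scene extent.

Six stage presets (seedling … grain filling) draw tiller counts, stem
heights and leaf sizes from increasing, non-overlapping ranges; a shared
uniform draw per seed makes designed heights monotone across stages for a
fixed seed, and leaf attachment/length caps guarantee no apex overtops the
tallest stem, so the drawn stem height *is* the designed plant height.
Cultivar profiles modulate architecture (`loose_many_tillers`: two extra
tillers, droopier, wider azimuth spread; `compact_few_tillers`: one fewer,
slightly shorter). All preset ranges are simulator choices, not field
measurements.

What the simulator does **not** emulate — and what passing tests therefore do
not show about real data: reconstruction holes and occlusion (every surface
is fully sampled), leaf curl and twist (ribbons are flat across their width),
spikes/ears, non-uniform reconstruction density, color bleeding between
organs, and scenes with several plants per pot.

## Numerical choices

* **Marker width.** The minor-PCA-axis extent is estimated as
  $(q_{95} - q_{05})/0.90$ of the projections (mean of three bootstrap
  repeats). For a uniform strip this is unbiased, and unlike the raw min–max
  range it is immune to the upward bias of boundary noise — with a strongly
  shrunk scene the raw extent would overestimate the marker by several
  percent and corrupt every height downstream. White-ish far outliers are
  excluded by keeping only the largest Euclidean cluster of the white-point
  selection.
* **Eq. for the rotation.** The normalized cross product of the two normals
  is an axis, not a matrix; the implementation uses the Rodrigues rotation
  about that axis. Antiparallel normals fall back to a π rotation about
  (1, 0, 0).
* **Ground at zero.** After rotation the cloud is translated so ground
  inliers average z = 0; height itself uses the cloud's own z-range, so any
  residual offset cancels.
* **Strict color margins.** Points exactly on G−R = 5 or G−B = 30 are
  removed (the thresholds are removal boundaries).
* **Ties and determinism.** Region growing breaks curvature ties by lowest
  point index; RANSAC and the bootstrap take seeds; clustering labels follow
  first appearance; reruns of the pipeline with one config are reproducible.
* **Degenerate inputs.** Collinear and coplanar clouds are rejected with
  distinct errors by the hull; crown area degrades gracefully to L × 0 for
  collinear projections; loess widens its span once before failing.

## Validation design and problem sizes

The built-in experiments mirror the published evaluation layout: 72 plants
(six stages × three cultivar profiles × four replicates, designed heights
10–60 cm) processed end to end under coordinate noise of 0.02 cm, 1% far
outliers, random global scale in [0.3, 3] and tilt up to 15°; and 160
standalone leaves (lengths 5–35 cm, widths 0.8–2.0 cm) measured by midrib
fitting. Agreement is scored with the same three statistics the workflow
reports for real plants:

$$R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},
\qquad
\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (y_i - \hat y_i)^2},
\qquad
\mathrm{RRMSE} = \frac{\mathrm{RMSE}}{\bar y} \times 100\%.$$

`scripts/acceptance.R` reruns exactly this experiment from scratch and the
test suite asserts the resulting statistics; the vignette quotes no numbers
that those runs do not compute. Growth-dynamics summaries use the classical
equal-variance one-way ANOVA with pairwise two-group comparisons, starred
`*` at p ≤ 0.05 and `**` at p ≤ 0.01, uncorrected by default (a Bonferroni
flag exists) — matching the reporting style of cultivar-comparison figures
in this literature.

## Known limitations

* Region growing under-segments dense, mutually occluding canopies
  (tillering–booting); the unclassified fraction is reported instead of being
  patched by manual editing.
* Points at the stem–blade junction are ambiguous even in principle; a small
  basal fraction of each blade may end up unclassified or in a stem region.
* Leaf width is a chord (straight-line) extent, not a geodesic width, so
  strongly curled leaves would be underestimated — curled ribbons are not
  generated, and real curl is one reason synthetic accuracy should be read
  as an upper bound.
* Ball pivoting needs reasonably uniform sampling; the fixed voxel +
  spacing-scaled radii work for these scenes, but holes in real
  reconstructions can leave open boundaries and underestimate area.
* The "maximum surface distance" reading of leaf length is implemented as
  the arc length of the fitted midrib, which is the measurable quantity the
  procedure actually produces.
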