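# wheatpheno

Automated phenotyping of potted wheat plants from colored 3D point clouds.

Multi-view image sequences of a wheat plant, reconstructed with SFM-MVS
photogrammetry, yield a dense colored point cloud — but one in an arbitrary
metric scale, in a tilted frame, and cluttered with the pot, soil, ground,
and stray noise points. `wheatpheno` is an R implementation of the full
workflow that turns such a cloud into phenotypic traits, for plant
scientists and breeders monitoring wheat architecture across the growth
cycle (seedling through grain filling):

1. **Scale restoration** from a marker sticker of known width:
   `S = W_real / W_virtual`, with `W_virtual` the mean of repeated
   measurements of the sticker in the cloud.
2. **Frame levelling**: RANSAC ground-plane detection and a Rodrigues
   rotation taking the plane normal `n1` onto `n2 = (0, 0, 1)`, with the
   ground translated to `z = 0`.
3. **Plant isolation** by centroid-assisted Euclidean clustering: points
   below the cut-off `z_thr = z_ground + α (z_plant − z_ground)` are
   discarded, the survivors are clustered by fixed-radius connectivity, and
   the cluster at the plant-color centroid is kept — then cleaned by the
   green-margin color filter (`G − R > 5`, `G − B > 30`) and statistical
   outlier removal (mean k-NN distance beyond `μ + c·σ`).
4. **Stem–leaf segmentation** by region growing on per-point normals and
   surface-variation curvature.
5. **Trait extraction**: plant height `H = z_max − z_min`; crown area
   `C = L_max × W_max` (projected hull diameter × perpendicular extent);
   convex-hull volume; ball-pivoting mesh surface area; and per-leaf midrib
   length (arc length of a local-polynomial fit) and maximum width.

Accuracy is quantified as `R² = 1 − Σ(yᵢ−ŷᵢ)²/Σ(yᵢ−ȳ)²`,
`RMSE = √(Σ(yᵢ−ŷᵢ)²/n)` and `RRMSE = 100·RMSE/ȳ`, and growth dynamics are
compared across cultivars with one-way ANOVA (`*` p ≤ 0.05, `**` p ≤ 0.01).

Because the workflow needs ground truth to validate against, the package
includes a first-class scene simulator: parametric wheat plants (tillers,
Bézier-midrib ribbon leaves with exact designed lengths and widths) in a
soil-filled pot on a planar ground with a 3 cm marker sticker, distorted by
a global scale, a frame tilt, Gaussian noise and far outliers, with exact
per-point labels recorded before distortion.

## Worked example

```r
library(wheatpheno)

scene    <- generate_scene(stage_preset("seedling", seed = 1,
                                        true_scale = 0.7, tilt_deg = 10))
restored <- restore_scale_and_frame(scene$cloud, seed = 1)
plant    <- extract_plant(restored$cloud, seed = 1)
seg      <- region_growing(plant$cloud,
                           estimate_local_geometry(plant$cloud, 15),
                           k = 24, angle_thresh = 15, curv_thresh = 0.15,
                           min_region = 60)
restored$scale
phenotype_plant(plant$cloud, seg)
```

```
#> <scale_estimate> W_virtual = 2.103, W_real = 3, S = 1.42663
#> <plant_phenotypes>
#> # A tibble: 1 × 7
#>   n_points plant_height l_max w_max crown_area convex_volume surface_area
#>      <int>        <dbl> <dbl> <dbl>      <dbl>         <dbl>        <dbl>
#> 1     1529         10.8  10.6  5.68       60.3          122.         23.1
#> leaves:
#> # A tibble: 4 × 4
#>   leaf_region n_points leaf_length leaf_width
#>         <int>    <int>       <dbl>      <dbl>
#> 1           1      178        6.21      0.312
#> 2           2      268        7.42      0.481
#> 3           3      152        6.19      0.226
#> 4           4       71       NA        NA
#> failures: 1
```

The scene (46,291 points) was shrunk to 0.7× and tilted 10°; the pipeline
measures the 3 cm sticker at 2.103 cloud units and rescales by `S = 1.427`
(0.7 × 1.427 ≈ 1), then isolates the 1,529-point plant. The designed plant
height for this seed is 10.797 cm; the extracted value is 10.8 cm. Plant-level traits are computed on the full isolated cloud;
leaf lengths run a little short of their designed values (7.3–7.8 cm)
because region growing cannot claim the ambiguous stem–blade junction — the
same truncation the original workflow patched by manual editing. Standalone
leaves measured directly (no segmentation step) recover length and width to
about 0.08 cm and 0.03 cm RMSE; see the methods vignette
(`vignettes/wheat-phenotyping-methods.Rmd`) for the full validation design.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/wheatpheno pipeline --simulate seedling --seed 7 -o run7
```

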