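# coquina

Quantitative analysis of the 3D orientation fabric of fossil shell
concentrations from serial-section data.

Dense shell beds record their own depositional history: aligned apertures,
imbricated shells and preferred orientations point to currents or mass
flows, while isotropic fabrics point to quiet settling. For a lithified bed
the orientations of thousands of mm-scale shells are only accessible by
serial grinding: cut a reference block, grind it away at a fixed interval,
segment the shells across the section stack, and reduce each reconstructed
specimen to landmarks — A on the aperture margin, B on the opposite margin
(|A−B| = maximum diameter), and for planispiral shells a third point C
spanning the sagittal plane.

`coquina` implements the whole chain in R:

- **synthetic shell beds** with controlled fabrics (`fabric_config()`,
  `generate_scene()`) standing in for unpublished segmentation data, so
  every stage is testable against ground truth;
- **virtual sectioning** at a grinding interval with analytic
  cross-sections (`slice_scene()`), specimen reconstruction by
  cross-section connectivity (`reconstruct_specimens()`), landmark
  placement (`extract_landmarks()`, `landmark_table()`), and the
  slice-count eligibility rules (≥ 6 slices for the lineation A:B, ≥ 3 for
  the sagittal plane A-B-C, ≥ 2 for gastropods; `eligibility_filter()`);
- **orientation geometry**: lineation trend/plunge with directed aperture
  azimuth, sagittal-plane dip/dip-direction and pole
  (`measure_orientations()`), stratigraphic overturn correction
  (`correct_overturn()`);
- **directional statistics**: rose diagrams in 20° classes with vector
  mean and maximum class (`rose_histogram()`), lower-hemisphere
  equal-area/equal-angle projection and its exact inverse
  (`project_lower_hemisphere()`, `unproject()`,
  `plane_to_pole_and_great_circle()`), Fisher mean with the α95 cone of
  confidence and the preferred-orientation percentage 100·R/n
  (`fisher_statistics()`), where

  κ̂ = (n−1)/(n−R),  cos α = 1 − (n−R)/R · [(1/p)^(1/(n−1)) − 1];

- **abundance extrapolation** from the block footprint to the bed's mapped
  extension, x = count / footprint · extension
  (`extrapolate_abundance()`);
- an end-to-end pipeline writing scene JSON, landmark and orientation CSVs,
  a statistics JSON and SVG figures (`run_pipeline()`), plus a thin CLI at
  `inst/scripts/coquina.R` with subcommands `simulate`, `slice`, `measure`,
  `stats`, `extrapolate`, `run-all`.

## Worked example

Generate a spaced shell bed with sagittal planes imbricated 14° toward 155°
(pole 335°/76°, Fisher κ = 30), grind it at 2 mm across the bedding,
reconstruct, and measure the fabric:

```r
library(coquina)

cfg <- fabric_config(n_ammonoids = 120, n_gastropods = 8, pole_kappa = 30,
                     packing = "matrix_supported", min_spacing_mm = 28)
scene <- generate_scene(cfg, block_dims_mm = c(450, 450, 45), seed = 1)
scene
#> <scene> 128 shells (120 ammonoids, 8 gastropods) in 450 x 450 x 45 mm block, seed 1

stack <- slice_scene(scene, interval_mm = 2, axis = "y")
stack
#> <slice_stack> 226 slices at 2 mm, 561 cross-sections

specimens <- reconstruct_specimens(stack)
orient <- measure_orientations(landmark_table(specimens, stack))

poles <- subset(orient, plane_eligible)
fisher_statistics(poles$pole_trend_deg, poles$pole_plunge_deg)
#> <fisher_stats> n = 106
#>   mean 336.8/77.2  R = 101.893  kappa = 25.57
#>   preferred orientation 96.1%  cone of confidence (95%) 2.77 deg
```

The 106 specimens that crossed at least three sections recover the imposed
fabric: the mean sagittal-plane pole 336.8°/77.2° is within about a degree
of the true 335°/76° (a mean plane dipping ~13° toward ~157°), the
recovered concentration (κ̂ = 25.6) is close to the generating κ = 30, and
the 95% cone of confidence about the mean is 2.8° wide. The preferred
orientation of 96% reflects the deliberately concentrated validation
fabric; the package default (κ = 3) produces the mid-60s percentages
typical of real current-aligned beds.

```r
extrapolate_abundance(3253, 0.150 * 0.140, 5e6)
#> <abundance_estimate> 3253 specimens / 0.021 m^2 block x 5e+06 m^2 extension = 7.745e+11
```

Scaling the 3,253 shells counted in the 0.021 m² block footprint to a 5 km²
bed gives 7.745 × 10¹¹ shells — the formula is evaluated exactly, and the
report always carries the inputs next to the result.

The methods vignette (`vignettes/shell-fabric-methods.Rmd`) documents the
model idealisations, the coordinate and plotting conventions, the
eligibility rules, the statistical definitions and the known limitations
(notably that connectivity-based segmentation requires spaced shells,
unlike the manual segmentation of a shell-supported bed).

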