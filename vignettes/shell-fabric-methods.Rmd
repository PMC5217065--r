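---
title: "Quantifying shell-bed orientation fabrics from virtual serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shell-bed orientation fabrics from virtual serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coquina)
```

## The problem

Dense fossil shell concentrations (coquinas) record how their shells came to
rest: a current leaves aligned apertures and imbricated shells, a gravity
flow leaves a different fabric, and quiet settling leaves none. For a
lithified bed the only way at the full 3D orientation of thousands of small
shells is destructive serial grinding: the block is ground away at a fixed
interval, each exposed face is imaged, specimens are segmented and
reconstructed across faces, and each reconstructed shell is reduced to a few
landmarks from which its orientation is measured. `coquina` implements that
entire chain as code, together with a synthetic shell-bed generator that
plays the role of the (unpublished) segmentation data, so every stage can be
validated against a known ground truth.

The pipeline has five stages:

1. **Synthetic shell bed** (`generate_scene()`): planispiral shells
   (ammonoids) and helical shells (gastropods) with controlled sizes,
   positions and orientation fabrics.
2. **Virtual sectioning** (`slice_scene()`): analytic cross-sections on
   parallel planes at the grinding interval.
3. **Reconstruction and landmarks** (`reconstruct_specimens()`,
   `extract_landmarks()`): specimens from cross-section connectivity,
   then landmarks A (aperture margin), B (opposite margin), C (third
   sagittal-plane point, ammonoids only).
4. **Orientation geometry** (`measure_orientations()`): lineation A:B
   (trend/plunge, aperture azimuth, maximum diameter) and the imaginary
   sagittal plane A-B-C (dip, dip direction, pole), with an optional
   stratigraphic overturn correction (`correct_overturn()`).
5. **Fabric statistics** (`fabric_report()`): rose diagrams, lower-hemisphere
   stereographic projections, Fisher mean with cone of confidence, preferred
   orientation, and abundance extrapolation.

## Conventions

Right-handed frame with x = East, y = North, z = up; bedding horizontal.
Azimuths are degrees clockwise from North; plunge and dip are degrees below
horizontal. Angles are degrees in every interface; lengths are mm; areas for
the extrapolation are m². A line is reported as an axis: the trend of its
downward end, with horizontal axes normalised to trends in [0, 180). The
aperture direction is kept separately as a *directed* azimuth (the
horizontal projection of the vector from B to A). A plane's pole is its
downward normal, with pole trend = dip direction + 180° (mod 360) and pole
plunge = 90° − dip; for vertical planes the dip-direction tie is broken into
[0, 180).

## The synthetic shell bed

A scientist needs the generator to emulate the study conditions it stands in
for, so the defaults are fixed at those conditions:

| parameter | default | meaning |
|---|---|---|
| `n_ammonoids`, `n_gastropods` | 3253, 211 | counted abundances (≈ 15:1) |
| `ammonoid_size` | log-normal(log 8, 0.5) on [1.5, 27.7] mm | observed diameter range; only the range is known, so a truncated log-normal supplies the interior |
| `gastropod_size` | log-normal(log 6, 0.35) on [2.8, 11.3] mm | observed length range |
| `pole_mean_trend_plunge` | (335, 76) | pole of a sagittal plane dipping 14° toward 155° |
| `pole_kappa` | 3 | Fisher concentration; gives a preferred orientation (100·R/n) in the mid-60s percent, the magnitude reported for such beds |
| `aperture_mode_azimuths` | (155, 335) | bimodal NNW/SSE aperture fabric, modes 180° apart |
| `aperture_sd_deg` | 30 | wrapped-normal spread; chosen so the 20° rose classes peak at 13–16% |
| `whorl_fraction` | 0.25 | tube width as fraction of diameter — a free parameter, not constrained by landmarks |
| `packing` | shell-supported | shells may interpenetrate, as in the real bed |

An ammonoid is idealised as a solid disc — the convex hull of the annular
shell, outer diameter equal to the maximum diameter, thickness equal to the
whorl width — with the aperture marked on its rim in the sagittal plane; a
gastropod as a solid cone from apex (B) to aperture (A). This is exactly the
level of detail the landmark scheme can see; whorl expansion, ontogenetic
shape change and fragmentation are deliberately not modelled.

The block default is the reference block in bed coordinates:
150 × 140 × 45 mm with the 45 mm bed thickness vertical and the 140 mm axis
the horizontal grinding direction. Grinding a bed *across* the bedding is
what makes gently imbricated discs span many slices (roughly
diameter/interval); stacking horizontal slices through the same fabric would
leave most shells in one or two slices and starve every downstream filter.
`slice_scene(axis =)` exposes both geometries.

Scenes are reproducible bit-for-bit from `(config, seed)`; `write_scene()`
serialises to JSON at 17 significant digits so a round trip is exact.

## Virtual sectioning and reconstruction

Slices are idealised as planes (not slabs) at z = k·interval along the
grinding axis, k = 0, 1, …, floor(extent/interval) — both block surfaces
count, so a 140 mm extent at 2 mm gives 71 planes. Each shell crossing a
plane contributes one convex outline, computed analytically: an interior
point of the cut is found on the segment joining the solid's two extreme
points along the grinding axis, and the boundary is located by radial
bisection (64 directions, 40 iterations ≈ 10⁻¹⁰ mm precision) of the
solid's exact membership test. No rasterisation is involved and outline
vertices lie exactly on the shell surface.

Cross-sections on consecutive slices are joined into specimens by largest
positive 2D overlap area (Sutherland–Hodgman clipping of the convex
outlines; ties toward the lowest index). Where nothing overlaps, a proximity
fallback joins to the nearest outline within twice the interval: a shell
thinner than the interval lying nearly bed-parallel, or an inclined cone
near its apex, genuinely produces consecutive sections with a small
plan-view gap that a human segmenter would still join. Grouping accuracy is
measurable because each cross-section retains its source shell id; on
spaced scenes the grouping reproduces the ground-truth ids exactly.

**Limitation — dense beds.** At the real bed's packing density shells
touch and interpenetrate, and connectivity-based segmentation fuses them
into multi-shell blobs whose landmark orientations are meaningless; the
manual segmentation this stage emulates resolved such contacts by eye.
Validation scenes therefore use `packing = "matrix_supported"` with a
minimum spacing above the largest diameter. Fabric *statistics* from the
package are trustworthy in the spaced regime; the dense regime exercises
only counting.

### Landmarks

A is the outline vertex closest to the generator's aperture marker
(validation mode) or, blind, the vertex farthest from the cloud centroid —
a documented best-effort heuristic, since blind aperture recognition needs
anatomy the idealised disc does not have. B maximises distance from A; C
(ammonoids) maximises distance from the line A–B.

Raw extreme vertices sit on the shell's *outer surface*, up to half a whorl
width off the sagittal mid-plane, which would bias the A-B-C plane by up to
atan(t/2R) ≈ 14° at default proportions. By default the three landmarks are
therefore projected onto the total-least-squares plane of the whole outline
cloud (vertices resampled to uniform arc length and weighted by the arc
length they represent), emulating the operator's placement of landmarks on
the sagittal plane itself. `extract_landmarks(snap_sagittal = FALSE)`
returns the raw surface vertices instead: their positions converge to the
true margin points as the interval shrinks, at the cost of the tube-width
bias in the plane.

Even the fitted plane carries a per-shell error floor of several degrees at
a 2 mm interval: the boundary-of-cuts point cloud of a thick disc is
intrinsically asymmetric about the mid-plane. The error direction varies
from shell to shell, so ensemble fabric means are unbiased — a 300-shell
validation scene recovers its configured mean sagittal plane to within
about 1° — but single-specimen orientations should be read with that floor
in mind. This mirrors the practical accuracy of the physical protocol.

### Eligibility

Ammonoids reconstructed from at least 6 slices enter the lineation A:B
analysis; at least 3 slices the sagittal-plane analysis; gastropods cut at
least twice enter the gastropod analysis. All specimens stay in the total
count. The aperture rose uses the lineation-eligible sample, since the
aperture direction is an attribute of the lineation A:B.

## Fabric statistics

**Rose diagrams** (`rose_histogram()`): half-open bins `[lo, hi)` anchored
at 0°, default width 20°; axial mode folds θ and θ+180° together. The
summary reports the circular vector mean, the mean resultant length, and
the maximum class (interval and percentage) — the class that plots at the
circumference under the radius convention used here and in the field.
Because a bimodal fabric with modes 180° apart largely cancels as directed
vectors, reports carry both the directed and the axial (angle-doubled)
vector mean.

**Fisher statistics** (`fisher_statistics()`): axes are flipped into the
hemisphere of the dominant eigenvector of the orientation tensor (so the
result is exactly invariant under 180° flips of any subset and unbiased for
fabrics straddling the horizon); then R = |Σvᵢ|, mean direction = R's
direction, κ̂ = (n−1)/(n−R), and the cone of confidence about the mean at
significance p:

cos α = 1 − (n−R)/R · [(1/p)^(1/(n−1)) − 1],

with p = 0.05 by default. The **preferred orientation** is 100·R/n — 100
would indicate perfectly parallel orientation. Note that for *axes* the
isotropic baseline of this statistic is about 50 (folded uniform axes have
E|cos| = ½), not 0; values in the 60s–80s therefore indicate a real fabric,
and the simulated isotropic null in the test suite sits at 50 ± 5.

**Stereographic projection** (`project_lower_hemisphere()`): equal-area
(Schmidt) by default, r = √2·sin((90°−plunge)/2), which maps the hemisphere
onto the unit disc with horizontal lines on the primitive circle;
equal-angle (Wulff), r = tan((90°−plunge)/2), by flag. `unproject()` is the
exact inverse; `plane_to_pole_and_great_circle()` returns a plane's pole
and its great-circle trace as a polyline. Equal-area is the conventional
choice when point densities are read off the net, which is how fabric plots
are interpreted.

**Overturn correction** (`correct_overturn()`): a bed overturned about a
fold axis is restored by the half-turn rotation R = 2uu′ − I about the
horizontal axis u. Applying it twice is the identity. An undirected plane
whose dip direction is perpendicular to the axis maps to itself (only its
facing flips); directed azimuths map to 2·axis − azimuth. The orientation
data analysed here come from a right-way-up section, so the correction is
provided as a tool rather than applied by default.

**Abundance extrapolation** (`extrapolate_abundance()`): specimens per m²
of bedding-plane footprint of the block, times the bed's mapped extension:
x = count / footprint · extension, computed exactly with no rounding. With
the counted 3,253 ammonoids, the 0.150 × 0.140 m = 0.021 m² footprint and
the 5 km² = 5 × 10⁶ m² extension, the formula yields 7.745 × 10¹¹
ammonoids (and 5.02 × 10¹⁰ gastropods). Published summaries of such beds
sometimes quote totals around three orders of magnitude smaller than this
formula gives at these inputs; the report therefore always prints the
inputs next to the result so the arithmetic is auditable.

## Numerical choices

- Degeneracy tolerances: |A−B| < 10⁻⁶ mm or triangle area < 10⁻⁶ mm² is an
  error (collinear C is dropped with a flag).
- Vertical-plane dip-direction tie broken into [0, 180); horizontal-axis
  trend normalised into [0, 180).
- Outline resolution: 64 vertices by default; convergence studies in the
  test suite use 192–256 where vertex spacing would otherwise floor the
  measurement before the slice interval does.
- Scene determinism: one seed drives sizes, orientations, apertures and
  placement in a fixed draw order; the RNG state of the caller is restored.
- Problem sizes: validation uses 300-shell scenes (≈ 240 plane-eligible,
  ≈ 80 lineation-eligible at 2 mm), 500 replicate samples of n = 50 for
  cone-of-confidence coverage, and 10⁴ random lines for projection
  round-trips — large enough that stochastic checks are stable at the
  tolerances asserted, and small enough to run routinely.

## What passing tests do and do not show

The generator emulates counts, size ranges, a Fisher pole fabric, a bimodal
aperture fabric and block geometry. It does not emulate shell fragmentation,
ontogenetic shape change, touching-shell contacts at shell-supported
density, sediment infill or diagenetic deformation. Passing the validation
suite therefore shows that the *measurement chain* — sectioning,
reconstruction, landmarking, directional statistics — is correct and
unbiased under the stated geometry, not that any particular fossil bed
satisfies the idealisation. Applying the statistics stages to real landmark
tables (`read_landmarks()` accepts the documented CSV schema) involves no
synthetic component.
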