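# skelemorph

3D skeletal morphometry for micro-CT/MRI phenotyping of mouse models of
achondroplasia and related chondrodysplasias.

Preclinical models of achondroplasia (activating *Fgfr3* mutations) are
usually phenotyped with 2D distances on radiographs. That misses what the
disease actually does to a skeleton in 3D: long bones bow (so straight
lengths underestimate the deficit), the growth plate changes volume and
topography, the foramen magnum narrows as a curved 3D aperture, and the
spine curves. `skelemorph` implements the 3D measurements for each of
these, the statistics of a two-genotype (WT vs Ach), two-age (3 and 6
week) study design, and — since studies of this kind rarely deposit raw
scans — a family of analytic phantoms with closed-form ground truth that
validates the entire measurement chain.

## What it computes

| Domain | Measurement | Model |
|---|---|---|
| Long bones | curved 3D length | polyline through seed points; optional automatic medial centerline of a tubular mask |
| Trabecular bone | BV/TV, Tb.Th, Tb.N | voxel counting in a growth-plate-referenced VOI (0.1 mm offset, 0.5 mm extent, threshold 40); maximal-inscribed-sphere local thickness; plate-model Tb.N = (BV/TV)/Tb.Th |
| Growth plate | volume, thickness (mean, histogram, topographic map), volume/thickness area surrogate | two-surface model on the split isosurface |
| Craniofacial | skull bone volume, brain volume, foramen circumference / diameters / area | largest-component voxel counting; slice-area x 0.5 mm MRI stacks; longest boundary rim loop + (pi/4)·Dt·Ds |
| Spine | kyphosis index, body length, pedicle length, curved L4–L6 length | KI = chord / max perpendicular deviation; landmark and seed distances |
| Statistics | Welch t (unrounded df), Holm–Šídák step-down, χ² goodness of fit, mean ± SEM, significance stars | strict open star bands, `*` 0.01<p<0.05 … `****` p<0.0001 |

All coordinates are voxel-centre world mm; axis 1 of every volume is the
longitudinal (scan) axis. I/O: NIfTI-1 and multi-page TIFF volumes
(TIFF requires explicit spacing — never a silent 1.0), ASCII STL/PLY
meshes, CSV study tables, JSON landmarks, YAML pipeline configs.

## Worked example

```r
library(skelemorph)

# A helical "bowed tibia" phantom: tube of radius 0.3 mm around a helix
# (R = 3 mm, 1 mm/rad, one turn), voxelized at 50 um.
ph <- phantom_curved_tube(helix_radius = 3, pitch = 1, theta_max = 2*pi,
                          tube_radius = 0.3, spacing = 0.05, seed = 7)
c(seed_polyline   = curved_length(ph$seeds),
  auto_centerline = curved_length(centerline_from_mask(ph$mask)),
  analytic        = 2*pi*sqrt(10))
#>   seed_polyline auto_centerline        analytic
#>        19.86843        19.86291        19.86918

# Trabecular triple on a 0.1 mm plate / 0.4 mm period lattice at 10 um:
pl <- phantom_plate_lattice(thickness = 0.1, period = 0.4, spacing = 0.01)
trabecular_metrics(threshold_mask(pl$volume, 40), voi = pl$voi)
#> <trabecular_result>
#>   BV/TV  0.2500
#>   Tb.Th  0.1000 mm
#>   Tb.N   2.5000 1/mm
#>   BV 0.1080 mm^3 / TV 0.4320 mm^3

# A synthetic two-age study with a -2 SD growth-plate effect at 3 weeks only:
st <- generate_study(n_per_group = 10, effects = list(gp_volume = c(-2, 0)),
                     baseline = 12, seed = 42)
summarize_groups(st)
#> <group_comparison> WT vs Ach, mean +/- SEM, Welch t
#>  measurement_name age_weeks         mean_wt        mean_ach      p_value stars
#>         gp_volume         3 12.55 +/- 0.264 9.837 +/- 0.516 0.0003967858   ***
#>         gp_volume         6 11.82 +/- 0.366 11.64 +/- 0.353 0.7187681394    ns
```

The curved length is recovered to 0.03% by the seed polyline and the
automatic centerline alike; the trabecular triple is exact on the
voxel-aligned lattice; and the study summary shows the 3-week-only
significance pattern with its Welch p-values and star codes.

Batch runs are driven by a YAML config (`run_pipeline("config.yaml")`,
or the thin CLI at `inst/cli/skelemorph.R` with subcommands `phantom`,
`length`, `trab`, `gp`, `skull`, `brain`, `foramen`, `spine`, `stats`,
`run`); every run writes a parameter manifest next to its results, and
per-sample failures are recorded without aborting the batch.

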