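# tibiaslope

Automated, slice-wise measurement of medial, lateral, and coronal tibial
slopes from 3D knee MRI of the proximal tibia.

## The problem

The posterior tibial slope — the inferior-posterior inclination of the
tibial plateau relative to a line perpendicular to a proximal tibial
reference axis — is a knee-morphometry quantity implicated in ACL injury
risk, osteoarthritis, and arthroplasty planning. It differs between the
medial (MTS) and lateral (LTS) plateau compartments and varies across each
plateau, so single-slice manual measurements are both observer-dependent
and incomplete, and reference axes built from the tibial shaft depend on
how much distal bone the scan includes. This package is for
musculoskeletal-imaging researchers who want reproducible, whole-plateau
slope profiles from MRI, plus the frontal-plane analogue (CTS).

## The method

For a segmented proximal tibia (automatic Otsu segmentation is built in, or
supply your own mask):

1. the transverse **plane 1** is placed through the most anterior point of
   the tibial tuberosity;
2. per plane, the slice holding the longest chord of the tibia in plane 1
   is the **reference slice** (SRS sagittally, CRS coronally); the chord is
   *line 1*, a parallel chord 10 mm distal is *line 2*, and the midpoints
   of the two define the **reference axis** (SRA / CRA);
3. in every slice, the cortical contour is traced at sub-voxel resolution
   and the two points of greatest positive curvature on the superior rim —
   **nodes A and B** — mark the anterior/posterior (or medial/lateral)
   plateau borders;
4. the slice's slope is the angle between line AB and the perpendicular to
   the reference axis through A, reported **positive when B is inferior**;
5. slice positions are normalized by the plateau extent on their side of
   the reference slice, and slices whose contour dips below line AB form
   the articular **concavity zone** of each compartment.

Because the axis uses only structures proximal to (and including) the
tuberosity, the measurement is independent of scan length — the package's
validation shows < 0.1° shift after removing 20 mm of distal shaft.

Patient MRIs are not redistributable, so validation runs on a synthetic
proximal-tibia phantom (shaft, flaring metaphysis, planar facets with known
slopes, optional articular dish, anterior tuberosity crest) with analytic
ground truth and the target acquisition geometry: 1.6 mm slices with a
0.8 mm gap (2.4 mm centres), 0.5 mm in-plane.

## Worked example

```r
library(tibiaslope)

ph <- generate_phantom(phantom_spec(lateral_slope_deg = 7,
                                    medial_slope_deg = 9,
                                    coronal_slope_deg = 2))
m <- measure_profiles(ph$volume)       # segments, then measures both planes
summarize_subject(m, subject_id = "phantom-01")
#>   compartment  n mean_deg sd_deg zone_lo zone_hi zone_n zone_mean_deg
#> 1     lateral 11     7.03  0.703      NA      NA      0            NA
#> 2      medial  8     9.05  0.598      NA      NA      0            NA
#> 3     coronal 78     2.13  0.730      NA      NA      0            NA
```

The compartment means recover the phantom's ground-truth slopes (7, 9, 2°)
to within a few tenths of a degree; the zone columns are `NA` because this
phantom has flat (undished) facets, so no concavity zone exists.
`tidy(m)` returns the per-slice samples (slice, normalized distance, signed
slope, node coordinates), `autoplot(m)` draws the normalized slope
profiles, and `write_report()` emits `samples.csv` + `summary.json`.

Cohort-level statistics, shown on the bundled nine-subject example cohort:

```r
cohort_stats(example_cohort())
#>   n lts_mean mts_mean cts_mean cor_cts_mts cor_cts_lts highlighted_fraction
#> 1 9     5.43     7.64    0.844      -0.448      -0.484                0.667
```

`highlighted_fraction` is the share of subjects with mean MTS < 8° and mean
LTS < 5.5° (strict inequalities): 6 of these 9 subjects, i.e. 66.7%.

A thin command-line front end ships in `inst/cli/tibiaslope`
(`measure`, `phantom`, `cohort` subcommands).

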