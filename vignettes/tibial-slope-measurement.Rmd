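---
title: "Slice-wise measurement of tibial slopes: method and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise measurement of tibial slopes: method and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tibiaslope)
```

## The measurement problem

The posterior tibial slope (PTS) is the sagittal-plane inferior-posterior
inclination of the tibial plateau relative to a line perpendicular to a
proximal tibial reference axis. It differs between the medial (MTS) and
lateral (LTS) compartments, varies across each plateau, and is implicated in
anterior cruciate ligament injury risk, knee osteoarthritis and arthroplasty
planning. Manual 2D measurements are observer-dependent, and long-axis
reference constructions are sensitive to how much distal tibia the scan
happens to include. This package implements an automated, slice-wise
measurement from 3D knee MRI whose reference axis uses only the proximal
tibia, plus the frontal-plane analogue (the coronal tibial slope, CTS).

## The procedure

1. **Tuberosity point and plane 1.** The most anterior bone voxel within a
   band 10--40 mm inferior to the most superior tibial voxel is taken as the
   tip of the tibial tuberosity; the transverse plane through it is
   *plane 1*. The band exists because the anterior rim of the plateau can be
   more anterior than the tuberosity on some anatomies; its bounds are
   configuration keys. Ties are resolved deterministically: most anterior,
   then most inferior, then smallest medial-lateral offset from the mask's
   ML centroid. (The centroid reference, rather than an absolute ML
   coordinate, keeps the rule translation-equivariant.)
2. **Reference slice and axis, per plane.** Within plane 1, the sagittal
   slice holding the longest anterior-posterior chord of the tibia is the
   sagittal reference slice (SRS), and that chord is line 1. Line 2 is the
   parallel chord 10 mm distal, clipped to the bone contour. The sagittal
   reference axis (SRA) joins the midpoints of lines 1 and 2 and is
   normalised to point superiorly. The coronal reference slice and axis
   (CRS/CRA) are built identically from the longest medial-lateral chord.
   Because everything is anchored to plane 1, truncating distal shaft does
   not move the axis -- the motivating property over long-axis methods.
3. **Rim nodes by curvature.** Each slice's cortical contour is traced at
   sub-voxel resolution, resampled uniformly in arc length, smoothed with a
   periodic Gaussian (`curvature_sigma_mm`, default 2 mm), and its signed
   planar curvature computed. The two vertices of maximal positive curvature
   in the anterior and posterior halves (sagittal; medial/lateral halves for
   coronal) of the contour's superior portion are the plateau rim nodes A
   and B.
4. **Signed slope.** The slope of a slice is the angle between line AB and
   the line through A perpendicular to the reference axis, positive when B
   lies inferior to that perpendicular -- the clinical sign convention in
   both planes.
5. **Normalisation and concavity zones.** Each slice's distance from the
   reference slice is normalised by the extent of bone on its side, so
   profiles are comparable within and between subjects. Contour vertices
   between A and B that fall more than `concavity_depth_min_mm` below line
   AB mark the articular dish; the largest contiguous run of such slices
   (tolerating one interrupted slice) defines the compartment's concavity
   zone, and slopes are additionally summarised inside it.

## Image model and conventions

Volumes live in a canonical frame: array axes run anterior, medial,
superior, with coordinates in mm at voxel centres. Left knees are mirrored
about the sagittal midplane at load time so that "medial" always means +y;
laterality is a required input because it cannot be inferred reliably from a
cropped proximal-tibia scan. Segmentation is a global Otsu threshold
followed by largest-connected-component selection (which discards femoral or
fibular fragments) and slice-wise hole filling. Holes are filled in sagittal
sections: filling transverse sections would also fill surface depressions
such as the articular dish, which a transverse cut encloses with bone.

The "cortex contour" consumed by the landmarking stage is a sub-voxel
iso-contour (marching squares). When the intensity volume is available the
contour is traced on the intensities at the segmentation threshold rather
than on the binary mask: with partial-volume data this localises the cortex
well below voxel quantisation. Traced rings are then smoothed with a
sub-voxel Gaussian (0.6 of the geometric-mean in-plane spacing) to remove
the axis-aligned/diagonal segment signature of marching squares, which
otherwise inflates perimeters by a few percent and corrupts curvature.

## The curvature operator

Published descriptions of curvature-based rim landmarking rarely pin down
the operator; Gaussian curvature proper is undefined for plane curves, so
this package interprets the idea as signed planar curvature at a Gaussian
smoothing scale. Two discretisations were considered:

* the coordinate formula $\kappa = (u'v'' - v'u'')/(u'^2+v'^2)^{3/2}$ with
  periodic finite differences on the smoothed contour;
* the arc-length derivative of the smoothed tangent angle,
  $\kappa = d\theta/ds$, with periodic central differences.

The package uses the tangent-angle form. Coordinate smoothing shrinks a
circle of radius $r$ by the factor $e^{-\sigma^2/2r^2}$, so the coordinate
formula inflates its curvature by about $\sigma^2/r^2$ (2% for $r = 5$ mm at
$\sigma = 1$ mm) -- right at the edge of the accuracy the validation battery
demands. The tangent angle is scale-free, so the tangent-angle estimator is
exact for circles at any smoothing scale, and its discrete closed-contour
integral telescopes to exactly $2\pi$, giving turning-number conservation by
construction. Both properties are asserted in the test suite.

Node search guards (all configuration keys) reject a slice rather than
guess: the best curvature peak must exceed `kappa_min` (0.05/mm); two
near-equal peaks more than `flat_peak_sep_mm` apart within one half mean a
featureless arc (a circular section has no rim) and reject the slice; the
two rim nodes must be at least `min_node_sep_mm` (12 mm) apart, since node
pairs on a sliver section that barely grazes the plateau edge reflect local
corner rounding, not the articular surface; and slices whose contour top
lies more than `plateau_band_mm` (15 mm) below the most superior bone point
carry no plateau surface at all (for example sections through the
tuberosity crest anterior of the plateau) and are skipped. Skipped slices
are logged with reasons in the measurement object.

A known, accepted bias follows from taking the node at the curvature
maximum: on a smoothed corner whose two arms are asymmetric (a tilted facet
meeting a flaring metaphyseal wall) the maximum sits slightly around the
corner, a fraction of a millimetre inferior to the geometric rim. On the
phantom grid this produces compartment-mean biases of two to three tenths
of a degree, and it slightly reduces apparent dish depth; both effects are
quantified by the validation battery and stay well inside its bands.

## The synthetic phantom

Patient MRIs cannot be redistributed, so validation runs on a parametric
proximal tibia with analytic ground truth: a vertical circular shaft
(radius 15 mm) flaring over its top 20 mm into a plateau whose
cross-section is an ellipse extended 4 mm anteriorly and 10 mm posteriorly
(AP extents 19/25 mm, ML half-width 35 mm -- the posterior condyles
overhang, as in real anatomy); two planar plateau facets with configurable
sagittal slopes, blended smoothly over a 4 mm half-width at the ML midline,
plus a uniform coronal tilt; an optional spherical-cap dish per facet with
configurable depth and normalized span; and an anterior tuberosity modelled
as the summit of an anterior crest of constant 5.2 mm prominence below its
summit. The crest shape matters: anatomically the tuberosity continues into
the anterior tibial border, and a bump that faded within 10 mm of plane 1
would shift the line-1 and line-2 midpoints differently and tilt the
reference axis by several degrees on a perfectly straight shaft. With a
constant-prominence crest the two chords are congruent and the recovered
axis is vertical to well under half a degree.

Voxels default to 0.5 mm in-plane with 2.4 mm slice centres (1.6 mm slices
with a 0.8 mm gap, the acquisition protocol this method targets). Intensity
is 1000 for bone on 0 background with linear partial-volume sampling at the
boundary and additive Gaussian noise (default SD 50, seeded); the noise
stream is a single per-volume RNG stream so phantoms are bit-reproducible.
Expected compartment slopes are the in-plane facet angles, which is what a
slice-wise measurement estimates; for coronal tilts up to 2 degrees these
differ from the facet-plane dihedral angles by under 0.1 degree. When the
two sagittal slopes differ the plateau is not a plane and the per-slice
coronal reading varies linearly with the slice's AP position; the phantom's
near-symmetric AP footprint makes the compartment mean converge to the
prescribed tilt.

What the phantom does not emulate: soft tissue, bias fields, cartilage,
multi-bone fields of view beyond simple disconnected fragments, and real
cortical texture. Passing the battery therefore demonstrates the geometry
pipeline -- segmentation boundary handling, reference construction,
landmarking, sign conventions, normalisation -- under controlled conditions,
not robustness to clinical image quality.

## Validation battery and problem sizes

The package's acceptance checks, all recomputed at run time
(`scripts/acceptance.R`, also mirrored in the test suite):

* the bundled nine-subject example cohort yields a 66.7% highlighted-zone
  fraction under the strict thresholds MTS < 8 and LTS < 5.5 degrees;
* slope recovery on a 96-phantom grid (lateral 0/4/7/12, medial 0/5/9/15,
  coronal 0/2 degrees, three seeds): at least 90% of compartment means
  within 1 degree of truth and per-compartment bias within 0.5 degrees;
* curvature oracles: circle curvature within 2% for radii 5--20 mm, ellipse
  apex curvature within 5%, total turning within 5% of $2\pi$;
* sign conventions, including antisymmetry under reflection of node B;
* scan-length independence: removing 20 mm of distal shaft moves compartment
  means by under 0.5 degrees;
* a lateral dish spanning 40--60% of the lateral extent is recovered as a
  concavity zone within 0.05 of those bounds, and flat phantoms yield none
  (the dish phantom uses 1 mm ML sampling so the zone boundary is resolved
  finer than the +-5% band);
* line 2 sits exactly 10 mm distal to line 1, and a cylinder sheared 5
  degrees in the sagittal plane recovers a 5.0 +- 0.2 degree axis tilt.

These sizes keep the full battery at a few minutes on one CPU while leaving
each check statistically meaningful; a single two-plane measurement of one
phantom (roughly 140 usable slices) takes a couple of seconds.

## Degenerate inputs and numerical choices

Empty masks, constant volumes, volumes too short for the tuberosity band or
for line 2, coincident nodes, and single-slice plateaus raise informative
errors; empty slices and slices without reliable rim nodes are skipped and
logged. Chord-length ties in reference-slice selection go to the slice
nearer the plane-1 centroid, then to the smaller index. Compartments with
fewer than two valid slices are reported as absent (`NA`), never as zero.
Sample SDs use the $n-1$ denominator. Concavity zones are reported for the
medial and lateral compartments; a coronal zone is not defined because a
single normalized-distance interval cannot span the anterior and posterior
sides simultaneously (coronal samples still carry per-slice concave-node
counts). Zone bounds are kept at full precision internally and rounded only
for display.

## A worked phantom example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(lateral_slope_deg = 7,
                                    medial_slope_deg = 9,
                                    coronal_slope_deg = 2))
m <- measure_profiles(ph$volume)
glance(m)[, c("lts", "mts", "cts")]
autoplot(m)
```

On this phantom the recovered means land within a few tenths of a degree of
(7, 9, 2). The `autoplot()` method reproduces the normalized slope-profile
view (slope against normalized distance per compartment, concavity zones
shaded).

## Limitations

The method measures cortical bone geometry, not the cartilage surface; its
landmarks inherit the smoothing-scale bias discussed above; the tuberosity
operationalisation (search band plus tie-breaks) is a construction of this
package, since "the most anterior point of the tuberosity" is not otherwise
computable; and the bundled cohort table is a nine-subject example for the
classification demonstration, not a normative reference.
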