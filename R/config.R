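#' Measurement configuration
#'
#' Tunable parameters of the slope-measurement pipeline, with defaults used
#' throughout the package. All lengths are millimetres.
#'
#' @param tuberosity_band_mm Length-2 numeric: the search band for the most
#'   anterior tuberosity point, expressed as distances inferior to the most
#'   superior tibial voxel. The band excludes the anterior plateau rim (which
#'   can protrude further anteriorly than the tuberosity on some anatomies)
#'   and the distal shaft.
#' @param axis_offset_mm Distance between reference line 1 (in the transverse
#'   plane through the tuberosity) and the parallel line 2 used to construct
#'   the reference axis. The protocol value is 10 mm.
#' @param curvature_sigma_mm Arc-length scale of the periodic Gaussian used to
#'   smooth contours before curvature estimation.
#' @param superior_fraction Fraction of a contour's vertical extent, measured
#'   down from its top, inside which plateau rim nodes are searched. Keeps the
#'   tuberosity and distal cortex from capturing the curvature maximum.
#' @param kappa_min Minimum signed curvature (1/mm) for a vertex to qualify as
#'   a rim node; slices whose best candidate falls below this are skipped.
#' @param flat_peak_tol Relative tolerance of the flat-maximum guard: a slice
#'   is rejected when its two best curvature peaks within one contour half
#'   differ by less than this fraction while lying more than
#'   `flat_peak_sep_mm` apart (an ambiguous, featureless rim).
#' @param flat_peak_sep_mm Arc-length separation beyond which two near-equal
#'   curvature peaks trigger the flat-maximum guard.
#' @param concavity_depth_min_mm Minimum perpendicular depth below the rim
#'   node line for a contour vertex to count as part of the articular
#'   concavity; suppresses discretisation noise.
#' @param min_node_sep_mm Minimum distance between the two rim nodes of a
#'   slice. Sections that barely graze the plateau edge produce node pairs a
#'   few millimetres apart whose connecting line reflects local corner
#'   rounding rather than the articular surface; such slices are skipped.
#' @param plateau_band_mm Slices whose contour top lies more than this far
#'   below the most superior point of the bone are considered not to carry
#'   plateau surface (e.g. sections through the tuberosity crest only) and
#'   are skipped.
#' @param resample_mm Uniform arc-length spacing to which traced contours are
#'   resampled before smoothing and curvature estimation.
#' @param zone_gap_slices Number of consecutive non-concave slices tolerated
#'   inside a concavity zone before it is considered interrupted.
#'
#' @return A named list of class `slope_config`.
#' @examples
#' cfg <- slope_config(curvature_sigma_mm = 1.5)
#' cfg$axis_offset_mm
#' @export
slope_config <- function(tuberosity_band_mm = c(10, 40),
                         axis_offset_mm = 10,
                         curvature_sigma_mm = 2.0,
                         superior_fraction = 0.30,
                         kappa_min = 0.05,
                         flat_peak_tol = 0.05,
                         flat_peak_sep_mm = 5,
                         concavity_depth_min_mm = 0.1,
                         min_node_sep_mm = 12,
                         plateau_band_mm = 15,
                         resample_mm = 0.4,
                         zone_gap_slices = 1) {
  stopifnot(length(tuberosity_band_mm) == 2, tuberosity_band_mm[1] >= 0,
            tuberosity_band_mm[2] > tuberosity_band_mm[1],
            axis_offset_mm > 0, curvature_sigma_mm > 0,
            superior_fraction > 0, superior_fraction < 1,
            kappa_min >= 0, concavity_depth_min_mm >= 0, resample_mm > 0)
  structure(list(
    tuberosity_band_mm = as.numeric(tuberosity_band_mm),
    axis_offset_mm = axis_offset_mm,
    curvature_sigma_mm = curvature_sigma_mm,
    superior_fraction = superior_fraction,
    kappa_min = kappa_min,
    flat_peak_tol = flat_peak_tol,
    flat_peak_sep_mm = flat_peak_sep_mm,
    concavity_depth_min_mm = concavity_depth_min_mm,
    min_node_sep_mm = min_node_sep_mm,
    plateau_band_mm = plateau_band_mm,
    resample_mm = resample_mm,
    zone_gap_slices = zone_gap_slices
  ), class = "slope_config")
}
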