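#' Most anterior point of the tibial tuberosity
#'
#' Searches the mask for the most anterior bone voxel inside a band of
#' superior-inferior coordinates 10-40 mm (configurable) inferior to the
#' most superior tibial voxel. The band excludes the anterior plateau rim,
#' which can protrude further anteriorly than the tuberosity, and the distal
#' shaft. Ties are broken deterministically: most anterior, then most
#' inferior, then smallest medial-lateral offset from the mask's ML
#' centroid (the centroid reference keeps the rule translation-equivariant).
#'
#' @param mask A [binary_mask] covering the proximal tibia.
#' @param config A [slope_config()]; uses `tuberosity_band_mm`.
#' @return Numeric `(x, y, z)` voxel-centre coordinates in mm.
#' @export
find_tuberosity_point <- function(mask, config = slope_config()) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$grid)) abort("Mask is empty.")
  idx <- which(mask$grid, arr.ind = TRUE)
  xs <- mask$origin[1] + (idx[, 1] - 1) * mask$spacing[1]
  ys <- mask$origin[2] + (idx[, 2] - 1) * mask$spacing[2]
  zs <- mask$origin[3] + (idx[, 3] - 1) * mask$spacing[3]
  ztop <- max(zs)
  band <- zs <= ztop - config$tuberosity_band_mm[1] &
    zs >= ztop - config$tuberosity_band_mm[2]
  if (!any(band))
    abort(paste0("No bone inside the tuberosity search band; the volume's ",
                 "superior-inferior extent is too short."))
  ycen <- mean(ys)
  xs <- xs[band]; ys <- ys[band]; zs <- zs[band]
  cand <- which(xs == max(xs))
  cand <- cand[zs[cand] == min(zs[cand])]
  cand <- cand[which.min(abs(ys[cand] - ycen))]
  c(x = xs[cand], y = ys[cand], z = zs[cand])
}

#' Transverse plane through a point
#'
#' @param point `(x, y, z)` mm, typically from [find_tuberosity_point()].
#' @return A `transverse_plane` (list with `z0`, mm).
#' @export
make_plane1 <- function(point) {
  stopifnot(length(point) == 3, all(is.finite(point)))
  structure(list(z0 = unname(point[3])), class = "transverse_plane")
}

# u-extent of the intersections of a contour with the horizontal line v = v0
# returns c(lo, hi) or NULL when the line misses the contour
chord_at <- function(contour, v0) {
  ring <- contour_ring(contour)
  n <- nrow(ring)
  j <- c(2:n, 1)
  v1 <- ring[, 2]; v2 <- ring[j, 2]
  cross <- (v1 - v0) * (v2 - v0) <= 0 & v1 != v2
  if (!any(cross)) return(NULL)
  t <- (v0 - v1[cross]) / (v2[cross] - v1[cross])
  us <- ring[cross, 1] + t * (ring[j, 1][cross] - ring[cross, 1])
  if (length(us) < 2) return(NULL)
  range(us)
}

#' Select the reference slice by the longest chord in plane 1
#'
#' For each candidate slice, measures the chord of the tibia cross-section
#' cut by the transverse plane (anterior-posterior chord across sagittal
#' slices, medial-lateral chord across coronal slices) on the sub-voxel
#' contour, and returns the slice holding the longest chord together with
#' that chord (reference line 1). Chord-length ties go to the slice nearer
#' the plane-1 cross-section centroid, then to the smaller index.
#'
#' @param mask A [binary_mask].
#' @param plane1 A [make_plane1()] result.
#' @param direction `"AP"` (sagittal candidates, the sagittal reference
#'   slice) or `"ML"` (coronal candidates, the coronal reference slice).
#' @param config A [slope_config()].
#' @param contours Optional pre-traced list of contours indexed by slice,
#'   as produced internally by [measure_profiles()]; traced on demand when
#'   missing.
#' @return List with `slice_index`, `line1` (list: `u` endpoints, `v0`,
#'   `chord_mm`), and `chords` (per-candidate tibble).
#' @export
select_reference_slice <- function(mask, plane1, direction = c("AP", "ML"),
                                   config = slope_config(), contours = NULL) {
  direction <- match.arg(direction)
  plane <- if (direction == "AP") "sagittal" else "coronal"
  normal <- if (direction == "AP") 2L else 1L
  z0 <- plane1$z0
  nslices <- dim(mask$grid)[normal]
  if (is.null(contours))
    contours <- lapply(seq_len(nslices), function(j)
      trace_contour(mask, j, plane, resample_mm = config$resample_mm))
  chords <- purrr::map_dfr(seq_len(nslices), function(j) {
    ct <- contours[[j]]
    if (is.null(ct)) return(tibble(slice_index = j, chord_mm = NA_real_))
    ch <- chord_at(ct, z0)
    tibble(slice_index = j,
           chord_mm = if (is.null(ch)) NA_real_ else diff(ch),
           u_lo = if (is.null(ch)) NA_real_ else ch[1],
           u_hi = if (is.null(ch)) NA_real_ else ch[2])
  })
  ok <- which(!is.na(chords$chord_mm))
  if (!length(ok))
    abort("No slice intersects the tibia at the plane-1 level.")
  best <- ok[chords$chord_mm[ok] == max(chords$chord_mm[ok])]
  if (length(best) > 1) {
    # tie: slice nearer the plane-1 cross-section centroid along this axis
    k <- which.min(abs(axis_coords(mask, 3) - z0))
    sl <- mask$grid[, , k]
    idx <- which(sl, arr.ind = TRUE)
    cen <- if (nrow(idx)) mean(mask$origin[normal] +
                                 (idx[, normal] - 1) * mask$spacing[normal])
           else NA_real_
    pos <- mask$origin[normal] + (best - 1) * mask$spacing[normal]
    if (is.finite(cen)) best <- best[abs(pos - cen) == min(abs(pos - cen))]
    best <- min(best)
  }
  ch <- chord_at(contours[[best]], z0)
  list(slice_index = best,
       line1 = list(u = ch, v0 = z0, chord_mm = diff(ch)),
       chords = chords)
}

#' Build the reference axis from the reference-slice chords
#'
#' Draws reference line 2 parallel to line 1 and `offset_mm` inferior,
#' clipped to the anterior and posterior (or medial and lateral) tibia
#' borders of the reference-slice contour, and connects the midpoints of
#' the two lines. The result is a unit direction with positive superior
#' component: the sagittal or coronal reference axis.
#'
#' @param contour The reference slice's [contour2d].
#' @param line1 Line-1 description from [select_reference_slice()].
#' @param offset_mm Line separation; the protocol value is 10 mm.
#' @return A `reference_axis`: list with `origin` (midpoint of line 1,
#'   in-slice mm), `direction` (unit 2-vector), `line1`, `line2`, `plane`,
#'   `reference_slice_index`.
#' @export
build_reference_axis <- function(contour, line1, offset_mm = 10) {
  stopifnot(inherits(contour, "contour2d"), offset_mm > 0)
  v2 <- line1$v0 - offset_mm
  ch2 <- chord_at(contour, v2)
  if (is.null(ch2))
    abort(sprintf(paste0("The reference slice does not extend %g mm below ",
                         "line 1; acquire a longer scan or reduce the axis ",
                         "offset."), offset_mm))
  mid1 <- c(mean(line1$u), line1$v0)
  mid2 <- c(mean(ch2), v2)
  d <- mid1 - mid2
  len <- sqrt(sum(d^2))
  if (len == 0) abort("Degenerate reference axis (coincident midpoints).")
  d <- d / len
  if (d[2] < 0) d <- -d
  structure(list(origin = mid1, direction = d,
                 line1 = line1,
                 line2 = list(u = ch2, v0 = v2, chord_mm = diff(ch2)),
                 plane = attr(contour, "plane"),
                 reference_slice_index = attr(contour, "slice_index")),
            class = "reference_axis")
}
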