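#' Signed slope of a node pair relative to a reference axis
#'
#' The slope is the angle between the line through the two rim nodes and the
#' line through `node_a` perpendicular to the reference axis. The sign
#' follows the clinical convention: positive when `node_b` (the posterior
#' node in sagittal slices, the lateral node in coronal slices) falls on the
#' inferior side of that perpendicular.
#'
#' @param node_a,node_b In-slice `(u, v)` coordinates in mm.
#' @param axis A [build_reference_axis()] result, or a unit 2-vector giving
#'   the in-slice axis direction.
#' @return Signed slope in degrees, in (-90, 90).
#' @examples
#' up <- c(0, 1)
#' slope_angle(c(0, 0), c(10, -1.763), up)   # ~ +10
#' @export
slope_angle <- function(node_a, node_b, axis) {
  d <- if (inherits(axis, "reference_axis")) axis$direction else as.numeric(axis)
  d <- d / sqrt(sum(d^2))
  w <- node_b - node_a
  if (all(w == 0)) abort("Coincident nodes: slope undefined.")
  p <- c(d[2], -d[1])                       # in-slice perpendicular to the axis
  wp <- sum(w * p)
  if (abs(wp) < 1e-12)
    abort("Node line is parallel to the reference axis; slope undefined.")
  atan2(-sum(w * d), abs(wp)) * 180 / pi
}

#' Normalized slice distance from the reference slice
#'
#' @param slice_mm Physical coordinate (mm) of the slice along the plane
#'   normal.
#' @param reference_mm Coordinate of the reference slice.
#' @param max_extent_mm Distance from the reference slice to the farthest
#'   slice containing tibia on the same side; must be positive.
#' @return `|slice - reference| / max_extent`, clamped to `[0, 1]`.
#' @export
normalized_distance <- function(slice_mm, reference_mm, max_extent_mm) {
  if (!is.finite(max_extent_mm) || max_extent_mm <= 0)
    abort("`max_extent_mm` must be positive (single-slice plateau?).")
  pmin(pmax(abs(slice_mm - reference_mm) / max_extent_mm, 0), 1)
}

#' Measure slope profiles across both anatomical planes
#'
#' Runs the full pipeline on one subject: tuberosity point, transverse
#' plane 1, reference slice and axis per plane, per-slice curvature
#' landmarks, signed slopes, normalized distances, and concavity zones.
#' Sagittal slices are split into the medial and lateral compartments by
#' their side of the sagittal reference slice (the reference slice itself
#' belongs to neither); coronal slices form the `"coronal"` compartment and
#' are normalized against the anterior or posterior extent on their side of
#' the coronal reference slice. Slices without a reliable rim-node pair are
#' skipped and logged in the result.
#'
#' @param volume An [image_volume] in the canonical frame (see
#'   [load_volume()]).
#' @param mask Optional [binary_mask]; computed with [segment_tibia()] when
#'   missing.
#' @param config A [slope_config()].
#' @param planes `"both"` (default), `"sagittal"`, or `"coronal"`.
#' @return A `slope_measurement` object: list with tibbles `samples` (one
#'   row per measured slice), `zones` (concavity-zone bounds per
#'   compartment), `skipped` (slice, plane, reason), the two
#'   `reference_axis` objects, and the configuration. `tidy()`, `glance()`
#'   and `autoplot()` methods are provided.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' m <- measure_profiles(ph$volume, ph$mask, planes = "sagittal")
#' glance(m)
#' @export
measure_profiles <- function(volume, mask = NULL, config = slope_config(),
                             planes = c("both", "sagittal", "coronal")) {
  stopifnot(inherits(volume, "image_volume"))
  planes <- match.arg(planes)
  if (is.null(mask)) mask <- segment_tibia(volume)
  stopifnot(inherits(mask, "binary_mask"))
  if (!identical(dim(mask$grid), dim(volume$grid)))
    abort("Mask and volume have different grid shapes.")

  tub <- find_tuberosity_point(mask, config)
  plane1 <- make_plane1(tub)
  zs <- axis_coords(mask, 3)
  z_top <- max(zs[apply(mask$grid, 3, any)])

  # with partial-volume intensities, iso-contours at the segmentation
  # threshold localise the cortex beyond the mask's half-voxel quantisation
  level <- attr(mask, "threshold")
  intensity <- if (!is.null(level)) volume$grid

  do_plane <- function(plane) {
    normal <- if (plane == "sagittal") 2L else 1L
    direction <- if (plane == "sagittal") "AP" else "ML"
    nsl <- dim(mask$grid)[normal]
    contours <- lapply(seq_len(nsl), function(j)
      trace_contour(mask, j, plane, resample_mm = config$resample_mm,
                    intensity = intensity, level = level %||% 0.5))
    ref <- select_reference_slice(mask, plane1, direction, config, contours)
    axis <- build_reference_axis(contours[[ref$slice_index]], ref$line1,
                                 offset_mm = config$axis_offset_mm)
    pos <- axis_coords(mask, normal)
    ref_mm <- pos[ref$slice_index]
    # farthest slice containing any bone, per side of the reference slice
    has_bone <- apply(mask$grid, normal, any)
    ext_pos <- max(c(pos[has_bone] - ref_mm, 0))
    ext_neg <- max(c(ref_mm - pos[has_bone], 0))
    rows <- list(); skipped <- list()
    for (j in seq_len(nsl)) {
      if (j == ref$slice_index) next
      ct <- contours[[j]]
      if (is.null(ct)) {
        if (has_bone[j])
          skipped[[length(skipped) + 1]] <-
            tibble(plane = plane, slice_index = j, reason = "no usable contour")
        next
      }
      if (max(contour_ring(ct)[, 2]) < z_top - config$plateau_band_mm) {
        skipped[[length(skipped) + 1]] <-
          tibble(plane = plane, slice_index = j,
                 reason = "section below the plateau band")
        next
      }
      # internally traced contours are uniformly resampled by construction;
      # residual spacing deviation from corner contraction is benign
      prof <- suppressWarnings(
        contour_curvature(ct, sigma_mm = config$curvature_sigma_mm))
      nodes <- find_plateau_nodes(ct, prof, plane, config)
      if (is.null(nodes)) {
        skipped[[length(skipped) + 1]] <-
          tibble(plane = plane, slice_index = j, reason = "no reliable rim nodes")
        next
      }
      conc <- concavity_nodes(ct, nodes, config$concavity_depth_min_mm)
      side_mm <- pos[j] - ref_mm
      ext <- if (side_mm > 0) ext_pos else ext_neg
      if (ext <= 0) next
      compartment <- if (plane == "sagittal") {
        if (side_mm > 0) "medial" else "lateral"
      } else "coronal"
      side <- if (plane == "sagittal") {
        if (side_mm > 0) "medial" else "lateral"
      } else if (side_mm > 0) "anterior" else "posterior"
      rows[[length(rows) + 1]] <- tibble(
        plane = plane, compartment = compartment, side = side,
        slice_index = j, distance_mm = abs(side_mm),
        normalized_distance = normalized_distance(pos[j], ref_mm, ext),
        slope_deg = slope_angle(nodes$node_a, nodes$node_b, axis),
        node_a_u = nodes$node_a[1], node_a_v = nodes$node_a[2],
        node_b_u = nodes$node_b[1], node_b_v = nodes$node_b[2],
        n_concavity_nodes = nrow(conc$vertices),
        concavity_depth_mm = conc$max_depth)
    }
    list(samples = bind_rows(rows), skipped = bind_rows(skipped), axis = axis)
  }

  res <- list()
  if (planes %in% c("both", "sagittal")) res$sagittal <- do_plane("sagittal")
  if (planes %in% c("both", "coronal")) res$coronal <- do_plane("coronal")

  samples <- bind_rows(purrr::map(res, "samples"))
  skipped <- bind_rows(purrr::map(res, "skipped"))
  zones <- bind_rows(purrr::map(c("lateral", "medial"), function(comp)
    concavity_zone_bounds(samples, comp, config$zone_gap_slices)))
  samples$in_concavity_zone <- FALSE
  if (nrow(zones) && nrow(samples)) {
    for (r in seq_len(nrow(zones))) {
      hit <- samples$compartment == zones$compartment[r] &
        samples$normalized_distance >= zones$lo[r] &
        samples$normalized_distance <= zones$hi[r]
      samples$in_concavity_zone <- samples$in_concavity_zone | hit
    }
  }
  if (nrow(samples))
    samples <- arrange(samples, .data$plane, .data$compartment,
                       .data$normalized_distance)
  structure(list(samples = samples, zones = zones, skipped = skipped,
                 axes = purrr::map(res, "axis"),
                 tuberosity = tub, plane1 = plane1,
                 laterality = volume$laterality, config = config),
            class = "slope_measurement")
}

#' Concavity-zone bounds for one compartment
#'
#' The concavity zone is the largest contiguous run of slices (tolerating
#' `gap_slices` interruptions) whose plateau contour dips below the rim-node
#' line, expressed as a normalized-distance interval.
#'
#' @param samples Slope-sample tibble (from [measure_profiles()]), needing
#'   columns `compartment`, `normalized_distance`, `n_concavity_nodes`.
#' @param compartment `"lateral"` or `"medial"`.
#' @param gap_slices Number of consecutive non-concave slices tolerated
#'   inside a run.
#' @return One-row tibble (`compartment`, `lo`, `hi`, `n_slices`), or a
#'   0-row tibble when no slice is concave.
#' @export
concavity_zone_bounds <- function(samples, compartment, gap_slices = 1) {
  empty <- tibble(compartment = character(), lo = numeric(),
                  hi = numeric(), n_slices = integer())
  s <- samples[samples$compartment == compartment, , drop = FALSE]
  if (!nrow(s)) return(empty)
  s <- s[order(s$normalized_distance), , drop = FALSE]
  conc <- which(s$n_concavity_nodes > 0)
  if (!length(conc)) return(empty)
  run_id <- cumsum(c(1, diff(conc) > gap_slices + 1))
  runs <- split(conc, run_id)
  best <- runs[[which.max(lengths(runs))]]
  tibble(compartment = compartment,
         lo = min(s$normalized_distance[best]),
         hi = max(s$normalized_distance[best]),
         n_slices = length(best))
}
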