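#' In-slice contours
#'
#' A `contour2d` is a closed, simple, counter-clockwise polyline of in-slice
#' coordinates in mm: `u` along the slice's horizontal anatomical axis
#' (anterior for sagittal slices, medial for coronal) and `v` along the
#' superior axis. The first vertex is repeated as the last. Vertices are
#' uniformly spaced in arc length, which the curvature stage relies on.
#'
#' @param vertices Two-column numeric matrix of `(u, v)` mm; open or closed
#'   (a repeated last vertex is detected and normalised).
#' @param slice_index Integer slice index the contour came from.
#' @param plane `"sagittal"`, `"coronal"` or `"axial"`.
#' @return A `contour2d` object.
#' @export
contour2d <- function(vertices, slice_index = NA_integer_,
                      plane = c("sagittal", "coronal", "axial")) {
  plane <- match.arg(plane)
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  if (isTRUE(all.equal(vertices[1, ], vertices[nrow(vertices), ],
                       check.attributes = FALSE)))
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  if (nrow(vertices) < 8)
    abort("A contour needs at least 8 distinct vertices.")
  if (shoelace_area(vertices) < 0)
    vertices <- vertices[nrow(vertices):1, , drop = FALSE]
  structure(rbind(vertices, vertices[1, ]),
            slice_index = as.integer(slice_index), plane = plane,
            class = c("contour2d", "matrix", "array"))
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("<contour2d> %d vertices, %s slice %s, perimeter %.2f mm\n",
              nrow(x) - 1L, attr(x, "plane"), attr(x, "slice_index"),
              contour_perimeter(x)))
  invisible(x)
}

# ring of unique vertices (closure row dropped), plain matrix
contour_ring <- function(contour) {
  v <- unclass(contour)
  v[-nrow(v), , drop = FALSE]
}

#' Signed area (shoelace) and perimeter of a contour
#'
#' Positive area means counter-clockwise orientation in the `(u, v)` frame.
#'
#' @param contour A [contour2d] or a two-column vertex matrix.
#' @return Signed area in mm^2 / perimeter in mm.
#' @export
contour_area <- function(contour) {
  v <- if (inherits(contour, "contour2d")) contour_ring(contour) else as.matrix(contour)
  shoelace_area(v)
}

#' @rdname contour_area
#' @export
contour_perimeter <- function(contour) {
  v <- if (inherits(contour, "contour2d")) contour_ring(contour) else as.matrix(contour)
  sum(sqrt(rowSums((v - v[c(2:nrow(v), 1), ])^2)))
}

shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# periodic Gaussian smoothing of a uniformly sampled ring
smooth_ring <- function(ring, sigma_mm, h) {
  n <- nrow(ring)
  K <- min(ceiling(4 * sigma_mm / h), (n - 1L) %/% 2L)
  if (K < 1) return(ring)
  w <- exp(-((-K:K) * h)^2 / (2 * sigma_mm^2))
  w <- w / sum(w)
  cbind(as.numeric(stats::filter(ring[, 1], w, circular = TRUE)),
        as.numeric(stats::filter(ring[, 2], w, circular = TRUE)))
}

# resample a closed ring to n points uniform in arc length
resample_ring <- function(v, spacing_mm) {
  closed <- rbind(v, v[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  per <- s[length(s)]
  n <- max(8L, as.integer(round(per / spacing_mm)))
  si <- seq(0, per, length.out = n + 1L)[-(n + 1L)]
  cbind(approx(s, closed[, 1], xout = si)$y,
        approx(s, closed[, 2], xout = si)$y)
}

#' Trace the outer bone contour of one slice
#'
#' Extracts the requested slice of a binary mask, keeps its largest
#' foreground component, fills holes, and traces the outer boundary as a
#' sub-voxel iso-contour at the 0.5 level (marching squares), resampled to
#' uniform arc-length spacing. Sub-voxel contours are used because
#' voxel-staircase boundaries corrupt curvature estimation.
#'
#' @param mask A [binary_mask].
#' @param slice_index Index of the slice along the plane's normal axis
#'   (medial axis for sagittal slices, anterior axis for coronal).
#' @param plane `"sagittal"` or `"coronal"` (or `"axial"`).
#' @param resample_mm Target vertex spacing; see [slope_config()].
#' @param intensity Optional 3D intensity array with the mask's geometry
#'   (e.g. the source volume restricted to the neighbourhood of the mask).
#'   When given, the boundary is traced as the iso-contour of the intensity
#'   at `level` instead of the binary 0.5 level; with partial-volume data
#'   this localises the cortex with sub-voxel accuracy well beyond the
#'   half-voxel quantisation of a binary mask.
#' @param level Iso-level for the intensity contour, typically the
#'   segmentation threshold.
#' @return A [contour2d], or `NULL` when the slice holds no usable
#'   foreground (the caller is expected to skip such slices).
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' tc <- trace_contour(ph$mask, slice_index = 16, plane = "sagittal")
#' @export
trace_contour <- function(mask, slice_index,
                          plane = c("sagittal", "coronal", "axial"),
                          resample_mm = 0.4, intensity = NULL, level = 0.5) {
  stopifnot(inherits(mask, "binary_mask"))
  plane <- match.arg(plane)
  ax <- list(sagittal = c(1L, 3L), coronal = c(2L, 3L), axial = c(1L, 2L))[[plane]]
  normal <- setdiff(1:3, ax)
  if (slice_index < 1 || slice_index > dim(mask$grid)[normal]) return(NULL)
  take_slice <- function(g) switch(plane,
                                   sagittal = g[, slice_index, ],
                                   coronal = g[slice_index, , ],
                                   axial = g[, , slice_index])
  sl <- take_slice(mask$grid)
  if (!any(sl)) return(NULL)
  lab <- EBImage::bwlabel(sl * 1L)
  nl <- max(lab)
  if (nl > 1L) {
    counts <- tabulate(lab[lab > 0], nbins = nl)
    best <- which(counts == max(counts))
    if (length(best) > 1) {                  # tie: inferior-most centroid
      vc <- vapply(best, function(b) mean(which(lab == b, arr.ind = TRUE)[, 2]),
                   numeric(1))
      best <- best[which.min(vc)]
    }
    sl <- lab == best
  }
  sl <- EBImage::fillHull(sl * 1L) > 0
  if (is.null(intensity)) {
    field <- sl * 1
    lev <- 0.5
  } else {
    stopifnot(identical(dim(intensity), dim(mask$grid)))
    field <- take_slice(intensity)
    # suppress structures other than the selected component without touching
    # the iso-level line, which runs close to the component's voxel boundary
    guard <- EBImage::dilate(sl * 1L, EBImage::makeBrush(5, "box")) > 0
    field[!guard] <- 0
    lev <- level
  }
  u <- axis_coords(mask, ax[1])
  v <- axis_coords(mask, ax[2])
  # pad with background so boundary objects still close
  du <- mask$spacing[ax[1]]; dv <- mask$spacing[ax[2]]
  up <- c(u[1] - du, u, u[length(u)] + du)
  vp <- c(v[1] - dv, v, v[length(v)] + dv)
  m <- matrix(0, length(up), length(vp))
  m[2:(length(u) + 1), 2:(length(v) + 1)] <- field
  cl <- contourLines(up, vp, m, levels = lev)
  if (!length(cl)) return(NULL)
  areas <- vapply(cl, function(cc) abs(shoelace_area(cbind(cc$x, cc$y))),
                  numeric(1))
  cc <- cl[[which.max(areas)]]
  poly <- cbind(cc$x, cc$y)
  if (!isTRUE(all.equal(poly[1, ], poly[nrow(poly), ])))
    poly <- rbind(poly, poly[1, ])
  ring <- poly[-nrow(poly), , drop = FALSE]
  per <- sum(sqrt(rowSums((ring - ring[c(2:nrow(ring), 1), ])^2)))
  if (nrow(ring) < 4 || per < 8 * resample_mm) return(NULL)
  ring <- resample_ring(ring, resample_mm)
  # de-staircase: marching squares on voxel grids emits only axis-aligned and
  # diagonal segments, inflating perimeters by a few percent and corrupting
  # local geometry; a sub-voxel Gaussian in arc length removes the raster
  # signature while moving the boundary by far less than a voxel
  ring <- smooth_ring(ring, 0.6 * sqrt(du * dv), resample_mm)
  contour2d(ring, slice_index = slice_index, plane = plane)
}
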