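#' Image volumes and binary masks
#'
#' `image_volume()` wraps a 3D intensity array together with its physical
#' voxel spacing and laterality in the package's canonical anatomical frame;
#' `binary_mask()` does the same for a logical array. In the canonical frame
#' the three array axes run, in order, anterior (+x), medial (+y) and
#' superior (+z), with physical coordinates in millimetres at voxel centres.
#' Left knees are mirrored about the sagittal midplane when loaded, so
#' "medial" always means increasing +y regardless of side.
#'
#' @param grid 3D numeric (volume) or logical (mask) array, axes ordered
#'   anterior / medial / superior.
#' @param spacing Positive length-3 numeric, voxel centre-to-centre distances
#'   in mm along the three axes. For a sagittally acquired series the second
#'   component is slice thickness plus inter-slice gap.
#' @param laterality `"left"` or `"right"`.
#' @param origin Physical coordinate (mm) of the first voxel centre,
#'   length-3 numeric.
#' @return An object of class `image_volume` or `binary_mask`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 2.4, 0.5))
#' dim(v$grid)
#' @export
image_volume <- function(grid, spacing, laterality = "right",
                         origin = c(0, 0, 0)) {
  check_geometry(grid, spacing, origin)
  laterality <- match.arg(laterality, c("left", "right"))
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), laterality = laterality),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
binary_mask <- function(grid, spacing, laterality = "right",
                        origin = c(0, 0, 0)) {
  check_geometry(grid, spacing, origin)
  laterality <- match.arg(laterality, c("left", "right"))
  grid <- grid != 0
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), laterality = laterality),
            class = "binary_mask")
}

check_geometry <- function(grid, spacing, origin) {
  if (length(dim(grid)) != 3L)
    abort("`grid` must be a 3D array.")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three positive finite numbers (mm).")
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort("`origin` must be three finite numbers (mm).")
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, %s knee\n",
              paste(dim(x$grid), collapse = " x "),
              paste(format(x$spacing), collapse = " x "), x$laterality))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$grid), collapse = " x "), sum(x$grid),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Physical coordinates of voxel centres along one axis
#' @noRd
axis_coords <- function(x, axis) {
  x$origin[axis] + (seq_len(dim(x$grid)[axis]) - 1) * x$spacing[axis]
}

#' Mask with the geometry of a volume
#' @noRd
mask_like <- function(volume, grid) {
  binary_mask(grid, spacing = volume$spacing, laterality = volume$laterality,
              origin = volume$origin)
}

#' Mirror a volume or mask about the sagittal midplane (medial-lateral flip)
#' @noRd
mirror_ml <- function(x) {
  n <- dim(x$grid)[2]
  x$grid <- x$grid[, n:1, , drop = FALSE]
  # keep voxel-centre coordinates identical up to reversal of direction:
  # the first voxel centre stays at the old last centre's mirrored position
  x$origin[2] <- -(x$origin[2] + (n - 1) * x$spacing[2])
  x
}
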