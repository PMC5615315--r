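#' Segment the tibia by automatic thresholding
#'
#' Applies Otsu's threshold to the volume histogram, keeps the largest
#' connected component of the bone mask (which discards femur or fibula
#' fragments and bright specks), and fills holes slice by slice.
#'
#' @param volume An [image_volume]. Bone must be distinguishable from
#'   background by a global threshold.
#' @return A [binary_mask].
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' m <- segment_tibia(ph$volume)
#' @export
segment_tibia <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  g <- volume$grid
  rng <- range(g)
  if (diff(rng) <= 0)
    abort("Volume is constant; automatic thresholding found no bone.")
  scaled <- (g - rng[1]) / diff(rng)
  flat <- scaled
  dim(flat) <- c(dim(g)[1], dim(g)[2] * dim(g)[3])   # one global histogram
  thr <- EBImage::otsu(flat, range = c(0, 1), levels = 256)
  fg <- scaled > thr
  if (!any(fg))
    abort("Automatic threshold produced an empty mask.")
  fg <- largest_component_3d(fg)
  # fill internal (marrow) holes slice-wise in sagittal sections; filling in
  # axial sections would also fill surface depressions such as the articular
  # dish, which are enclosed by bone in a transverse cut
  for (j in seq_len(dim(fg)[2])) {
    sl <- fg[, j, ]
    if (any(sl)) fg[, j, ] <- EBImage::fillHull(sl * 1L) > 0
  }
  out <- mask_like(volume, fg)
  attr(out, "threshold") <- rng[1] + thr * diff(rng)
  out
}

#' Largest 26-connected foreground component of a 3D logical array
#'
#' Per-slice 2D labelling merged across adjacent slices with union-find.
#' Ties on voxel count are broken by the more inferior component centroid.
#' @noRd
largest_component_3d <- function(fg) {
  nz <- dim(fg)[3]
  labs <- vector("list", nz)
  offs <- integer(nz)
  nlab <- 0L
  for (k in seq_len(nz)) {
    l <- EBImage::bwlabel(fg[, , k] * 1L)
    offs[k] <- nlab
    mx <- as.integer(max(l))
    l[l > 0] <- l[l > 0] + nlab
    nlab <- nlab + mx
    labs[[k]] <- l
  }
  if (nlab == 0L) return(fg)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (k in seq_len(nz - 1L)) {
    a <- labs[[k]]; b <- labs[[k + 1L]]
    touch <- a > 0 & b > 0
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (r in seq_len(nrow(pairs))) union(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  counts <- numeric(nlab)
  zsum <- numeric(nlab)
  for (k in seq_len(nz)) {
    l <- labs[[k]]
    pos <- l > 0
    if (!any(pos)) next
    t <- tabulate(roots[l[pos]], nbins = nlab)
    counts <- counts + t
    zsum <- zsum + t * k
  }
  best <- which(counts == max(counts))
  if (length(best) > 1)                       # tie: inferior-most centroid
    best <- best[which.min(zsum[best] / counts[best])]
  keep <- array(FALSE, dim(fg))
  for (k in seq_len(nz)) {
    l <- labs[[k]]
    sel <- l > 0
    sel[sel] <- roots[l[l > 0]] == best
    keep[, , k] <- sel
  }
  keep
}

#' Cortical shell of a bone mask
#'
#' Returns the mask minus its one-voxel slice-wise erosion: a one-voxel
#' shell on the cortical boundary, the voxel-level counterpart of the
#' threshold-mask Boolean subtraction that isolates the bone contour.
#' Slices whose object is thinner than two voxels cannot be eroded and are
#' returned unchanged (with a warning when that is true of every slice).
#'
#' @param mask A [binary_mask].
#' @param plane Plane whose slices are eroded independently: `"sagittal"`
#'   (default, the acquisition plane), `"coronal"`, or `"axial"`.
#' @return A [binary_mask] containing the shell.
#' @export
cortical_shell <- function(mask, plane = c("sagittal", "coronal", "axial")) {
  stopifnot(inherits(mask, "binary_mask"))
  plane <- match.arg(plane)
  if (!any(mask$grid)) abort("Mask is empty.")
  ax <- switch(plane, sagittal = 2L, coronal = 1L, axial = 3L)
  perm <- switch(plane, sagittal = c(1, 3, 2), coronal = c(2, 3, 1),
                 axial = c(1, 2, 3))
  g <- aperm(mask$grid, perm)
  brush <- EBImage::makeBrush(3, "box")
  eroded <- array(FALSE, dim(g))
  for (k in seq_len(dim(g)[3])) {
    sl <- g[, , k]
    if (!any(sl)) next
    # pad so objects touching the volume edge still erode there
    p <- matrix(0L, nrow(sl) + 2, ncol(sl) + 2)
    p[2:(nrow(sl) + 1), 2:(ncol(sl) + 1)] <- sl * 1L
    e <- EBImage::erode(p, brush) > 0
    eroded[, , k] <- e[2:(nrow(sl) + 1), 2:(ncol(sl) + 1)]
  }
  if (!any(eroded))
    warn("Mask is thinner than 2 voxels in every slice; returning it unchanged.")
  shell <- g & !eroded
  shell <- aperm(shell, order(perm))
  mask_like(mask, shell)
}
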