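#' Signed curvature along a contour
#'
#' Smooths the closed contour with a periodic Gaussian kernel in arc length
#' and estimates signed planar curvature as the arc-length derivative of the
#' smoothed tangent angle (periodic central differences). For a
#' counter-clockwise contour the sign is positive where the boundary is
#' locally convex. The tangent-angle formulation is exact for circles (no
#' curvature inflation from the smoothing-induced radius shrinkage) and
#' conserves total turning: the discrete integral of curvature over any
#' closed simple contour telescopes to exactly 2*pi.
#'
#' @param contour A [contour2d] with uniformly spaced vertices (as produced
#'   by [trace_contour()] or [contour2d()] on resampled input).
#' @param sigma_mm Gaussian smoothing scale in mm of arc length.
#' @return A `curvature_profile`: list with `kappa` (1/mm, aligned with the
#'   contour vertices, closure vertex included), `sigma_mm`, `spacing_mm`
#'   and the smoothed vertex coordinates `smoothed`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)[-201]
#' circ <- contour2d(cbind(10 * cos(th), 10 * sin(th)))
#' mean(contour_curvature(circ, sigma_mm = 1)$kappa)  # ~ 0.1
#' @export
contour_curvature <- function(contour, sigma_mm = 2.0) {
  stopifnot(inherits(contour, "contour2d"), sigma_mm > 0)
  ring <- contour_ring(contour)
  n <- nrow(ring)
  if (n < 8) abort("A contour needs at least 8 distinct vertices.")
  seg <- sqrt(rowSums((ring[c(2:n, 1), ] - ring)^2))
  h <- mean(seg)
  if (max(abs(seg - h)) > 0.5 * h)
    warn("Contour vertices are not uniformly spaced; curvature may be biased.")
  K <- min(ceiling(4 * sigma_mm / h), (n - 1L) %/% 2L)
  if (K >= 1) {
    w <- exp(-((-K:K) * h)^2 / (2 * sigma_mm^2))
    w <- w / sum(w)
    su <- as.numeric(stats::filter(ring[, 1], w, circular = TRUE))
    sv <- as.numeric(stats::filter(ring[, 2], w, circular = TRUE))
  } else {
    su <- ring[, 1]; sv <- ring[, 2]
  }
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  theta <- atan2(sv[ip] - sv[im], su[ip] - su[im])
  dtheta <- theta[ip] - theta
  dtheta <- atan2(sin(dtheta), cos(dtheta))   # wrap to (-pi, pi]
  kappa <- (dtheta + dtheta[im]) / (2 * h)
  structure(list(kappa = c(kappa, kappa[1]), sigma_mm = sigma_mm,
                 spacing_mm = h, smoothed = cbind(su, sv)),
            class = "curvature_profile")
}

#' Locate the plateau rim nodes of one slice
#'
#' Restricts the contour to its superior portion (the top
#' `superior_fraction` of the vertical extent, so the tuberosity and distal
#' cortex cannot capture the maximum), splits that region into two halves at
#' its horizontal midpoint, and returns the vertex of maximal positive
#' curvature in each half: the anterior/posterior plateau rim for sagittal
#' slices, the medial/lateral rim for coronal slices. Slices with no
#' convincing rim are rejected rather than guessed: the best candidate must
#' exceed `kappa_min`, and near-equal curvature peaks far apart within one
#' half (a featureless arc, e.g. a circular cross-section) trigger the
#' flat-maximum guard.
#'
#' @param contour A [contour2d].
#' @param profile Matching [contour_curvature()] result.
#' @param plane `"sagittal"` or `"coronal"`.
#' @param config A [slope_config()].
#' @return A `plateau_nodes` list (`node_a`, `node_b`, vertex indices, slice
#'   index, plane), or `NULL` when no reliable node pair exists. `node_a` is
#'   the anterior (sagittal) or medial (coronal) rim node.
#' @export
find_plateau_nodes <- function(contour, profile,
                               plane = c("sagittal", "coronal"),
                               config = slope_config()) {
  plane <- match.arg(plane)
  stopifnot(inherits(profile, "curvature_profile"))
  ring <- contour_ring(contour)
  n <- nrow(ring)
  kappa <- profile$kappa[seq_len(n)]
  h <- profile$spacing_mm
  v <- ring[, 2]
  vmin <- min(v); vmax <- max(v)
  sup <- v > vmax - config$superior_fraction * (vmax - vmin)
  if (!any(sup)) return(NULL)
  u <- ring[, 1]
  umid <- (min(u[sup]) + max(u[sup])) / 2
  pick <- function(idx) {
    if (!length(idx)) return(NULL)
    k <- kappa[idx]
    best <- idx[which.max(k)]
    if (kappa[best] < config$kappa_min) return(NULL)
    # flat-maximum guard: a rival peak of similar height far away means the
    # "corner" is not localised
    arc <- pmin(abs(idx - best), n - abs(idx - best)) * h
    rival <- k[arc > config$flat_peak_sep_mm]
    if (length(rival) &&
        max(rival) > (1 - config$flat_peak_tol) * kappa[best]) return(NULL)
    best
  }
  ia <- pick(which(sup & u > umid))
  ib <- pick(which(sup & u <= umid))
  if (is.null(ia) || is.null(ib)) return(NULL)
  if (sqrt(sum((ring[ia, ] - ring[ib, ])^2)) < config$min_node_sep_mm)
    return(NULL)
  structure(list(node_a = ring[ia, ], node_b = ring[ib, ],
                 index_a = ia, index_b = ib,
                 slice_index = attr(contour, "slice_index"), plane = plane),
            class = "plateau_nodes")
}

#' Contour vertices inside the articular concavity
#'
#' Walks the superior arc of the contour between the two rim nodes and
#' returns the vertices whose perpendicular distance below the node-to-node
#' line exceeds `depth_min_mm` (the articular "dish"). An empty result means
#' the plateau is flat in this slice.
#'
#' @param contour A [contour2d].
#' @param nodes Matching [find_plateau_nodes()] result.
#' @param depth_min_mm Minimum depth below the rim line; see
#'   [slope_config()].
#' @return List with `vertices` (matrix, possibly 0-row), `depths` (mm) and
#'   `max_depth` (mm, 0 when empty).
#' @export
concavity_nodes <- function(contour, nodes, depth_min_mm = 0.1) {
  stopifnot(inherits(nodes, "plateau_nodes"))
  ring <- contour_ring(contour)
  n <- nrow(ring)
  arc1 <- arc_indices(nodes$index_a, nodes$index_b, n)
  arc2 <- arc_indices(nodes$index_b, nodes$index_a, n)
  # the superior arc is the plateau surface
  arc <- if (mean(ring[arc1, 2]) >= mean(ring[arc2, 2])) arc1 else arc2
  arc <- setdiff(arc, c(nodes$index_a, nodes$index_b))
  if (!length(arc))
    return(list(vertices = ring[0, , drop = FALSE], depths = numeric(0),
                max_depth = 0))
  ab <- nodes$node_b - nodes$node_a
  nrm <- c(ab[2], -ab[1]) / sqrt(sum(ab^2))
  if (nrm[2] > 0) nrm <- -nrm                 # make it point inferior
  depths <- as.numeric((ring[arc, , drop = FALSE] -
                          matrix(nodes$node_a, length(arc), 2,
                                 byrow = TRUE)) %*% nrm)
  keep <- depths > depth_min_mm
  list(vertices = ring[arc[keep], , drop = FALSE], depths = depths[keep],
       max_depth = if (any(keep)) max(depths[keep]) else 0)
}

# indices strictly following i up to and including j, walking forward
arc_indices <- function(i, j, n) {
  if (j >= i) seq(i, j) else c(seq(i, n), seq_len(j))
}
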