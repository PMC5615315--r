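#' Specification of a synthetic proximal-tibia phantom
#'
#' A parametric proximal tibia used as the package's validation substrate:
#' a vertical shaft that flares into a metaphysis carrying two planar
#' (optionally dished) plateau facets, plus an anterior tuberosity modelled
#' as the summit of an anterior crest of constant prominence (the tuberosity
#' anatomically continues into the anterior tibial border, which is what
#' keeps the chord-midpoint reference axis parallel to the shaft).
#'
#' Slopes follow the measurement sign convention: a positive sagittal slope
#' tilts the facet posteriorly-inferiorly; a positive coronal slope puts the
#' lateral rim inferior to the medial rim. The default voxel grid mimics the
#' acquisition protocol the method targets: sagittal slices with 1.6 mm
#' thickness and 0.8 mm gap (2.4 mm centre-to-centre) and 0.5 mm in-plane
#' resolution.
#'
#' @param lateral_slope_deg,medial_slope_deg Signed sagittal facet slopes in
#'   degrees. Must satisfy `abs(slope) < 45`.
#' @param coronal_slope_deg Signed coronal tilt of the plateau in degrees.
#' @param dish_depth_mm Length-2 numeric `(lateral, medial)`: maximal depth
#'   of the spherical-cap articular dish on each facet; 0 disables it.
#' @param dish_span Length-2 list or 2x2 matrix of normalized-distance
#'   intervals (rows `(lo, hi)` for lateral then medial) over which each dish
#'   spans its side's medial-lateral extent.
#' @param tuberosity_height_mm Anterior prominence of the crest beyond the
#'   shaft cortex.
#' @param tuberosity_offset_mm Distance below the plateau reference plane at
#'   which the crest reaches full prominence (its summit region).
#' @param shaft_length_mm Height of the plateau reference plane above the
#'   distal cut; must be at least 50 so the 10 mm axis offset and distal
#'   truncation experiments stay inside the volume.
#' @param spacing Voxel spacing (anterior, medial, superior) in mm.
#' @param laterality `"left"` or `"right"`; left phantoms are anatomically
#'   mirrored when written to disk.
#' @param noise_sd SD of additive Gaussian intensity noise (bone = 1000,
#'   background = 0).
#' @param seed Integer seed for the phantom's noise stream.
#' @return A list of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(lateral_slope_deg = 7, medial_slope_deg = 9)
#' @export
phantom_spec <- function(lateral_slope_deg = 7,
                         medial_slope_deg = 9,
                         coronal_slope_deg = 0,
                         dish_depth_mm = c(0, 0),
                         dish_span = rbind(c(0.40, 0.60), c(0.45, 0.70)),
                         tuberosity_height_mm = 5.2,
                         tuberosity_offset_mm = 25,
                         shaft_length_mm = 70,
                         spacing = c(0.5, 2.4, 0.5),
                         laterality = "right",
                         noise_sd = 50,
                         seed = 1L) {
  for (s in c(lateral_slope_deg, medial_slope_deg, coronal_slope_deg))
    if (!is.finite(s) || abs(s) >= 45)
      abort("Facet slopes must be finite and |slope| < 45 degrees.")
  if (shaft_length_mm < 50)
    abort("`shaft_length_mm` must be >= 50 mm.")
  if (any(spacing <= 0)) abort("`spacing` must be positive.")
  dish_span <- if (is.matrix(dish_span)) dish_span else
    rbind(dish_span[[1]], dish_span[[2]])
  if (any(dish_span < 0) || any(dish_span > 1) ||
      any(dish_span[, 2] <= dish_span[, 1]))
    abort("`dish_span` intervals must satisfy 0 <= lo < hi <= 1.")
  if (length(dish_depth_mm) == 1) dish_depth_mm <- rep(dish_depth_mm, 2)
  if (any(dish_depth_mm < 0)) abort("`dish_depth_mm` must be >= 0.")
  structure(list(
    lateral_slope_deg = lateral_slope_deg,
    medial_slope_deg = medial_slope_deg,
    coronal_slope_deg = coronal_slope_deg,
    dish_depth_mm = dish_depth_mm,
    dish_span = dish_span,
    tuberosity_height_mm = tuberosity_height_mm,
    tuberosity_offset_mm = tuberosity_offset_mm,
    shaft_length_mm = shaft_length_mm,
    spacing = as.numeric(spacing),
    laterality = match.arg(laterality, c("left", "right")),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# quintic smoothstep, C2, on [0, 1]
smootherstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^3 * (t * (6 * t - 15) + 10)
}

# fixed anatomy of the phantom (mm); facet geometry comes from phantom_spec()
PHANTOM_SHAPE <- list(
  shaft_radius = 15,      # circular shaft cross-section
  anterior_gain = 4,      # anterior extent grows 15 -> 19 at the plateau
  posterior_gain = 10,    # posterior extent grows 15 -> 25
  ml_gain = 20,           # ML half-width grows 15 -> 35
  flare_height = 20,      # metaphyseal flare occupies the top 20 mm
  crest_sigma_y = 8,      # ML spread of the anterior crest
  crest_decay_z = 4,      # fade of the crest above its summit
  ridge_blend = 4         # half-width of the facet blend at the ML midline
)

#' Generate a synthetic proximal-tibia volume with ground truth
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (an [image_volume], canonical
#'   frame), `mask` (noise-free occupancy as a [binary_mask]) and
#'   `ground_truth` (a list holding the analytic expected slope per
#'   compartment in degrees, facet plane coefficients, the plateau ML
#'   half-width, tuberosity crest geometry, and dish parameters).
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' ph$ground_truth$expected[["lateral"]]
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- PHANTOM_SHAPE
  zc <- spec$shaft_length_mm              # plateau reference plane height
  h <- spec$tuberosity_height_mm
  z_tub <- zc - spec$tuberosity_offset_mm
  bl <- sh$ridge_blend
  tl <- tan(spec$lateral_slope_deg * pi / 180)
  tm <- tan(spec$medial_slope_deg * pi / 180)
  tc <- tan(spec$coronal_slope_deg * pi / 180)
  b_plateau <- sh$shaft_radius + sh$ml_gain

  xmax_top <- sh$shaft_radius + sh$anterior_gain
  x <- seq(-(sh$shaft_radius + sh$posterior_gain + 3),
           max(xmax_top, sh$shaft_radius + h) + 3, by = spec$spacing[1])
  y <- seq(-(b_plateau + 3), b_plateau + 3, by = spec$spacing[2])
  zmax <- zc + max(abs(c(tl, tm))) * max(abs(x)) + abs(tc) * max(abs(y)) + 3
  z <- seq(-1, zmax, by = spec$spacing[3])

  # facet top surface z_top(x, y): per-side planar slopes blended smoothly
  # across the ML midline, a uniform coronal tilt, minus optional dishes
  w <- smootherstep((y + bl) / (2 * bl))          # 0 lateral -> 1 medial
  tan_sag <- tl + (tm - tl) * w
  ztop <- zc + outer(x, tan_sag) + matrix(tc * y, length(x), length(y),
                                          byrow = TRUE)
  dish <- list()
  for (side in 1:2) {                             # 1 = lateral, 2 = medial
    d <- spec$dish_depth_mm[side]
    if (d <= 0) next
    sgn <- if (side == 1) -1 else 1
    span <- spec$dish_span[side, ]
    yc <- sgn * mean(span) * b_plateau
    rho <- diff(span) / 2 * b_plateau
    xc <- (sh$anterior_gain - sh$posterior_gain) / 2   # plateau centroid
    R <- (rho^2 + d^2) / (2 * d)
    r2 <- outer((x - xc)^2, (y - yc)^2, `+`)
    delta <- ifelse(r2 < rho^2, sqrt(pmax(R^2 - r2, 0)) - (R - d), 0)
    ztop <- ztop - delta
    dish[[if (side == 1) "lateral" else "medial"]] <-
      list(depth = d, span = span, center = c(xc, yc), rim_radius = rho)
  }

  # per-z cross-section: posteriorly-shifted ellipse plus the anterior crest.
  # Intensities use linear boundary sampling (voxel coverage along the
  # anterior-posterior and superior-inferior boundaries) so that grayscale
  # iso-contours localise the surface at sub-voxel precision, as partial
  # volume does in MRI; ground-truth occupancy uses the voxel-centre rule.
  nx <- length(x); ny <- length(y); nz <- length(z)
  occ <- array(FALSE, c(nx, ny, nz))
  cov <- array(0, c(nx, ny, nz))
  crest_y <- exp(-y^2 / (2 * sh$crest_sigma_y^2))
  dx <- spec$spacing[1]; dz <- spec$spacing[3]
  xlo_mat <- matrix(x - dx / 2, nx, ny)
  xhi_mat <- matrix(x + dx / 2, nx, ny)
  for (k in seq_len(nz)) {
    zk <- z[k]
    if (zk + dz / 2 <= 0) next
    s <- smootherstep((zk - (zc - sh$flare_height)) / sh$flare_height)
    a_ant <- sh$shaft_radius + sh$anterior_gain * s
    a_post <- sh$shaft_radius + sh$posterior_gain * s
    b <- sh$shaft_radius + sh$ml_gain * s
    x0 <- (a_ant - a_post) / 2
    a <- (a_ant + a_post) / 2
    half <- a * sqrt(pmax(1 - (y / b)^2, 0))
    crest <- h * crest_y * (if (zk <= z_tub) 1 else
                              exp(-((zk - z_tub) / sh$crest_decay_z)^2 / 2))
    lo <- ifelse(half > 0, x0 - half, Inf)
    hi <- ifelse(half > 0, x0 + half + crest, -Inf)
    lo_m <- matrix(lo, nx, ny, byrow = TRUE)
    hi_m <- matrix(hi, nx, ny, byrow = TRUE)
    cov_x <- pmin(pmax((pmin(xhi_mat, hi_m) - pmax(xlo_mat, lo_m)) / dx, 0), 1)
    cov_z <- pmin(pmax((ztop - (zk - dz / 2)) / dz, 0), 1) *
      pmin(pmax((zk + dz / 2) / dz, 0), 1)
    cov[, , k] <- cov_x * cov_z
    if (zk >= 0)
      occ[, , k] <- outer(x, lo, `>=`) & outer(x, hi, `<=`) & (zk <= ztop)
  }

  grid <- 1000 * cov
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec$seed)
    grid <- grid + array(rnorm(length(grid), 0, spec$noise_sd), dim(grid))
  }

  origin <- c(x[1], y[1], z[1])
  volume <- image_volume(grid, spec$spacing, spec$laterality, origin)
  mask <- binary_mask(occ, spec$spacing, spec$laterality, origin)
  gt <- list(
    expected = c(lateral = spec$lateral_slope_deg,
                 medial = spec$medial_slope_deg,
                 coronal = spec$coronal_slope_deg),
    facet_tangents = c(lateral = tl, medial = tm, coronal = tc),
    plateau_half_width_mm = b_plateau,
    plateau_z_mm = zc,
    crest = list(height_mm = h, apex_x_mm = sh$shaft_radius + h,
                 summit_z_mm = z_tub, sigma_y_mm = sh$crest_sigma_y),
    dish = dish,
    spec = spec
  )
  list(volume = volume, mask = mask, ground_truth = gt)
}

#' The default phantom validation grid
#'
#' Crossing of lateral slopes \{0, 4, 7, 12\}°, medial slopes
#' \{0, 5, 9, 15\}°, coronal slopes \{0, 2\}° and noise seeds, at 0.5 mm
#' in-plane / 2.4 mm slice spacing: 96 phantoms for the default three seeds.
#'
#' @param lateral,medial,coronal Slope levels (degrees) to cross.
#' @param seeds Integer noise seeds.
#' @param noise_sd Intensity noise SD passed to each [phantom_spec()].
#' @return A tibble with one row per phantom and a list-column `spec`.
#' @examples
#' nrow(phantom_grid())              # 96
#' nrow(phantom_grid(seeds = 1))     # 32
#' @export
phantom_grid <- function(lateral = c(0, 4, 7, 12),
                         medial = c(0, 5, 9, 15),
                         coronal = c(0, 2),
                         seeds = 1:3,
                         noise_sd = 50) {
  g <- expand.grid(lateral_slope_deg = lateral, medial_slope_deg = medial,
                   coronal_slope_deg = coronal, seed = as.integer(seeds),
                   KEEP.OUT.ATTRS = FALSE)
  g$spec <- purrr::pmap(g, function(lateral_slope_deg, medial_slope_deg,
                                    coronal_slope_deg, seed) {
    phantom_spec(lateral_slope_deg = lateral_slope_deg,
                 medial_slope_deg = medial_slope_deg,
                 coronal_slope_deg = coronal_slope_deg,
                 seed = seed, noise_sd = noise_sd)
  })
  as_tibble(g)
}

#' Write a phantom validation suite to disk
#'
#' Generates each phantom of a [phantom_grid()] and writes a NIfTI volume and
#' a JSON ground-truth file per phantom.
#'
#' @param out_dir Output directory (created if needed).
#' @param grid A [phantom_grid()] tibble; defaults to the full 96-phantom
#'   grid.
#' @return Tibble of the files written, invisibly.
#' @export
phantom_suite <- function(out_dir, grid = phantom_grid()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort(sprintf("Cannot create output directory '%s'.", out_dir))
  files <- purrr::pmap(grid, function(lateral_slope_deg, medial_slope_deg,
                                      coronal_slope_deg, seed, spec) {
    stem <- sprintf("phantom_L%g_M%g_C%g_s%d", lateral_slope_deg,
                    medial_slope_deg, coronal_slope_deg, seed)
    ph <- generate_phantom(spec)
    nii <- file.path(out_dir, paste0(stem, ".nii.gz"))
    js <- file.path(out_dir, paste0(stem, ".json"))
    write_volume(ph$volume, nii)
    gt <- ph$ground_truth
    gt$expected <- as.list(gt$expected)
    gt$facet_tangents <- as.list(gt$facet_tangents)
    gt$spec <- unclass(gt$spec)
    gt$spec$dish_span <- as.vector(t(gt$spec$dish_span))
    jsonlite::write_json(gt, js, auto_unbox = TRUE, digits = NA)
    tibble(volume = nii, ground_truth = js)
  })
  invisible(bind_rows(files))
}
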