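# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# the reference phantom used across files: protocol spacing, typical slopes
ref_phantom <- function() {
  fixture("ref_phantom", function() {
    ph <- generate_phantom(phantom_spec(lateral_slope_deg = 7,
                                        medial_slope_deg = 9,
                                        coronal_slope_deg = 2,
                                        noise_sd = 50, seed = 7L))
    ph$seg <- segment_tibia(ph$volume)
    ph
  })
}

ref_measurement <- function() {
  fixture("ref_measurement", function() {
    ph <- ref_phantom()
    suppressWarnings(measure_profiles(ph$volume, ph$seg))
  })
}

# analytic closed contours ---------------------------------------------------

circle_contour <- function(r, spacing = 0.4, center = c(0, 0)) {
  n <- max(16, round(2 * pi * r / spacing))
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour2d(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

ellipse_contour <- function(a, b, spacing = 0.4) {
  th <- seq(0, 2 * pi, length.out = 4096)[-4096]
  ring <- cbind(a * cos(th), b * sin(th))
  contour2d(tibiaslope:::resample_ring(ring, spacing))
}

# axis-aligned rectangle with rounded corners, optionally rotated; returns
# the contour and the four corner-arc apex coordinates
rounded_rect_contour <- function(width, height, radius, spacing = 0.4,
                                 rot_deg = 0) {
  w2 <- width / 2 - radius
  h2 <- height / 2 - radius
  arc <- function(cx, cy, th0) {
    th <- seq(th0, th0 + pi / 2, length.out = 32)
    cbind(cx + radius * cos(th), cy + radius * sin(th))
  }
  ring <- rbind(arc(w2, h2, 0), arc(-w2, h2, pi / 2),
                arc(-w2, -h2, pi), arc(w2, -h2, 3 * pi / 2))
  # corner apexes: arc centres displaced by radius along the 45-degree rays
  cen <- rbind(c(w2, h2), c(-w2, h2), c(-w2, -h2), c(w2, -h2))
  ray <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)) / sqrt(2)
  apex <- cen + radius * ray
  if (rot_deg != 0) {
    a <- rot_deg * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    ring <- ring %*% t(R)
    apex <- apex %*% t(R)
  }
  list(contour = contour2d(tibiaslope:::resample_ring(ring, spacing)),
       apex = apex)
}

# upright or sheared cylinder mask (radius 15 mm, height 70 mm); the shear
# tilts the axis in the sagittal plane by `shear_deg`
cylinder_mask <- function(shear_deg = 0, spacing = c(0.5, 2.4, 0.5),
                          radius = 15, height = 70) {
  tphi <- tan(shear_deg * pi / 180)
  x <- seq(-radius - 2, radius + 2 + tphi * height, by = spacing[1])
  y <- seq(-16.8, 16.8, by = spacing[2])
  z <- seq(-1, height + 1, by = spacing[3])
  occ <- array(FALSE, c(length(x), length(y), length(z)))
  for (k in seq_along(z)) {
    zk <- z[k]
    if (zk < 0 || zk > height) next
    xc <- tphi * zk
    occ[, , k] <- outer((x - xc)^2, y^2, `+`) <= radius^2
  }
  binary_mask(occ, spacing, origin = c(x[1], y[1], z[1]))
}
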