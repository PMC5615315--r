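test_that("the tuberosity point matches the ground-truth oracle", {
  ph <- ref_phantom()
  cfg <- slope_config()
  got <- find_tuberosity_point(ph$seg, cfg)
  # oracle: argmax of the anterior coordinate over the true occupancy within
  # the search band, same tie-breaks (most inferior, then most central)
  occ <- ph$mask
  idx <- which(occ$grid, arr.ind = TRUE)
  xs <- occ$origin[1] + (idx[, 1] - 1) * occ$spacing[1]
  ys <- occ$origin[2] + (idx[, 2] - 1) * occ$spacing[2]
  zs <- occ$origin[3] + (idx[, 3] - 1) * occ$spacing[3]
  band <- zs <= max(zs) - cfg$tuberosity_band_mm[1] &
    zs >= max(zs) - cfg$tuberosity_band_mm[2]
  cand <- which(band & xs == max(xs[band]))
  cand <- cand[zs[cand] == min(zs[cand])]
  cand <- cand[which.min(abs(ys[cand] - mean(ys)))]
  oracle <- c(xs[cand], ys[cand], zs[cand])
  expect_lt(max(abs(got - oracle) / occ$spacing), 1 + 1e-9)  # within 1 voxel
  # the crest is centred on the sagittal midline
  expect_lt(abs(got[2]), occ$spacing[2] + 1e-9)
})

test_that("tuberosity search is translation-equivariant and tie-breaks are fixed", {
  m <- cylinder_mask(0)
  p0 <- find_tuberosity_point(m)
  # no bump: anterior-most surface point; the inferior-most slice in the
  # band wins the tie
  zs <- m$origin[3] + (seq_len(dim(m$grid)[3]) - 1) * m$spacing[3]
  ztop <- max(zs[apply(m$grid, 3, any)])
  expect_equal(unname(p0[3]), ztop - 40, tolerance = m$spacing[3])
  expect_equal(unname(p0[2]), 0, tolerance = 1e-9)
  m2 <- m
  m2$origin[1] <- m2$origin[1] + 5          # translate 5 mm anteriorly
  p1 <- find_tuberosity_point(m2)
  expect_equal(unname(p1 - p0), c(5, 0, 0), tolerance = 1e-12)
  # volume too short for the band
  short <- binary_mask(m$grid[, , 1:10], m$spacing, origin = m$origin)
  expect_error(find_tuberosity_point(short), "band")
  expect_error(find_tuberosity_point(binary_mask(array(FALSE, c(3, 3, 3)),
                                                 c(1, 1, 1))), "empty")
})

test_that("plane 1 passes through the tuberosity point", {
  expect_equal(make_plane1(c(1, 2, 42))$z0, 42)
  expect_equal(make_plane1(c(-5, 7, 42))$z0, make_plane1(c(0, 0, 42))$z0)
  ph <- ref_phantom()
  p <- find_tuberosity_point(ph$seg)
  pl <- make_plane1(p)
  k <- which.min(abs(ph$seg$origin[3] +
                       (seq_len(dim(ph$seg$grid)[3]) - 1) * ph$seg$spacing[3] -
                       pl$z0))
  expect_true(any(ph$seg$grid[, , k]))
})

test_that("the reference slice holds the longest chord", {
  # ellipsoidal cylinder: AP semi-axis 25 mm, centred at a known ML slice
  sp <- c(0.5, 2.4, 0.5)
  x <- seq(-27, 27, sp[1]); y <- seq(-16.8, 16.8, sp[2]); z <- seq(-1, 60, sp[3])
  occ <- array(FALSE, c(length(x), length(y), length(z)))
  for (k in seq_along(z)) {
    if (z[k] < 0 || z[k] > 58) next
    occ[, , k] <- outer((x / 25)^2, (y / 14)^2, `+`) <= 1
  }
  m <- binary_mask(occ, sp, origin = c(x[1], y[1], z[1]))
  ref <- select_reference_slice(m, make_plane1(c(0, 0, 18)), "AP")
  ycen <- which(abs(y) < 1e-9)
  expect_equal(ref$slice_index, ycen)
  expect_equal(ref$line1$chord_mm, 50, tolerance = sp[1])
  # single-slice mask: that slice is returned
  one <- binary_mask(occ[, ycen, , drop = FALSE] &
                       array(TRUE, c(length(x), 1, length(z))),
                     sp, origin = c(x[1], 0, z[1]))
  expect_equal(select_reference_slice(one, make_plane1(c(0, 0, 18)),
                                      "AP")$slice_index, 1)
})

test_that("the reference axis is vertical for an upright cylinder", {
  m <- cylinder_mask(0)
  ref <- select_reference_slice(m, make_plane1(find_tuberosity_point(m)), "AP")
  ct <- trace_contour(m, ref$slice_index, "sagittal")
  axis <- build_reference_axis(ct, ref$line1)
  expect_equal(axis$direction, c(0, 1), tolerance = 1e-6)
  expect_equal(axis$line1$v0 - axis$line2$v0, 10)   # exactly 10 mm apart
})

test_that("a 5-degree sagittal shear tilts the axis by 5 degrees", {
  m <- cylinder_mask(5)
  ref <- select_reference_slice(m, make_plane1(find_tuberosity_point(m)), "AP")
  ct <- trace_contour(m, ref$slice_index, "sagittal")
  axis <- build_reference_axis(ct, ref$line1)
  tilt <- atan2(axis$direction[1], axis$direction[2]) * 180 / pi
  expect_equal(tilt, 5, tolerance = 0.2)
  # axis construction fails gracefully when the slice is too short
  stub <- binary_mask(m$grid[, , 140:143], m$spacing,
                      origin = c(m$origin[1:2], m$origin[3] + 139 * m$spacing[3]))
  ct2 <- trace_contour(stub, ref$slice_index, "sagittal")
  z0 <- stub$origin[3] + 3 * stub$spacing[3]
  expect_error(build_reference_axis(ct2, list(u = c(-10, 10), v0 = z0)),
               "does not extend")
})

test_that("axis direction always points superiorly and ignores translation", {
  ph <- ref_phantom()
  m <- ref_measurement()
  for (ax in m$axes) {
    expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)
    expect_gt(ax$direction[2], 0)
  }
  base_axis <- function(mask) {
    ref <- select_reference_slice(mask,
                                  make_plane1(find_tuberosity_point(mask)), "AP")
    ct <- trace_contour(mask, ref$slice_index, "sagittal")
    build_reference_axis(ct, ref$line1)
  }
  shifted <- ph$seg
  shifted$origin <- shifted$origin + c(8, -4.8, 0)
  expect_equal(base_axis(shifted)$direction, base_axis(ph$seg)$direction,
               tolerance = 1e-6)
})
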