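test_that("slope_angle matches closed forms and sign conventions", {
  up <- c(0, 1)
  expect_equal(slope_angle(c(0, 0), c(10, -1.763), up), 10, tolerance = 0.01)
  expect_equal(slope_angle(c(0, 0), c(10, 0), up), 0)
  expect_equal(slope_angle(c(0, 0), c(10, 1.763), up), -10, tolerance = 0.01)
  # antisymmetry under superior/inferior reflection of node B about A
  for (dv in c(-3, -1, 0.5, 2))
    expect_equal(slope_angle(c(2, 1), c(12, 1 + dv), up),
                 -slope_angle(c(2, 1), c(12, 1 - dv), up))
  # tilting the axis changes the reading accordingly
  # an anteriorly tilted axis tips its perpendicular down toward anterior,
  # so a horizontal node line reads as negative (B above the perpendicular)
  tilted <- c(sin(0.1), cos(0.1))
  expect_equal(slope_angle(c(0, 0), c(10, 0), tilted),
               -0.1 * 180 / pi, tolerance = 1e-6)
  expect_error(slope_angle(c(1, 1), c(1, 1), up), "Coincident")
})

test_that("normalized distances follow the reference-slice convention", {
  expect_equal(normalized_distance(30, 30, 30), 0)
  expect_equal(normalized_distance(60, 30, 30), 1)
  expect_equal(normalized_distance(42, 30, 30), 0.4)
  expect_equal(normalized_distance(100, 30, 30), 1)   # clamped
  expect_error(normalized_distance(42, 30, 0), "positive")
})

test_that("phantom slopes are recovered in both planes", {
  m <- ref_measurement()
  g <- glance(m)
  expect_equal(g$lts, 7, tolerance = 1)
  expect_equal(g$mts, 9, tolerance = 1)
  expect_equal(g$cts, 2, tolerance = 1)
  expect_true(all(m$samples$normalized_distance >= 0 &
                    m$samples$normalized_distance <= 1))
  expect_true(all(m$samples$slope_deg > -90 & m$samples$slope_deg < 90))
  expect_setequal(unique(m$samples$compartment),
                  c("lateral", "medial", "coronal"))
})

test_that("a zero-slope phantom measures flat in every compartment", {
  ph <- generate_phantom(phantom_spec(0, 0, 0, noise_sd = 50, seed = 3L))
  m <- suppressWarnings(measure_profiles(ph$volume, segment_tibia(ph$volume)))
  g <- glance(m)
  expect_lt(abs(g$lts), 0.5)
  expect_lt(abs(g$mts), 0.5)
  expect_lt(abs(g$cts), 0.5)
})

test_that("mirrored left knees measure identically with labels preserved", {
  ph <- ref_phantom()
  g0 <- glance(ref_measurement())
  left <- ph$volume
  left$laterality <- "left"
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(left, tmp)
  back <- load_volume(tmp, "left")
  m2 <- suppressWarnings(measure_profiles(back, segment_tibia(back)))
  g2 <- glance(m2)
  expect_equal(g2$lts, g0$lts, tolerance = 0.2)
  expect_equal(g2$mts, g0$mts, tolerance = 0.2)
  expect_equal(g2$cts, g0$cts, tolerance = 0.2)
})

test_that("posterior-inferior facets always give positive slopes", {
  # positive ground-truth slopes in both planes, two geometries
  for (spec in list(phantom_spec(5, 8, 2, noise_sd = 50, seed = 4L),
                    phantom_spec(12, 15, 2, noise_sd = 50, seed = 5L))) {
    ph <- generate_phantom(spec)
    m <- suppressWarnings(measure_profiles(ph$volume, segment_tibia(ph$volume)))
    sm <- summarize_subject(m)
    expect_true(all(sm$mean_deg > 0))
  }
})

test_that("concavity zones recover the dish and tolerate single-slice gaps", {
  sp <- phantom_spec(7, 9, 0, dish_depth_mm = c(2, 0),
                     dish_span = rbind(c(0.40, 0.60), c(0.45, 0.70)),
                     spacing = c(0.5, 1.0, 0.5), noise_sd = 50, seed = 6L)
  ph <- generate_phantom(sp)
  m <- suppressWarnings(measure_profiles(ph$volume, segment_tibia(ph$volume),
                                         planes = "sagittal"))
  z <- m$zones[m$zones$compartment == "lateral", ]
  expect_equal(nrow(z), 1)
  expect_lt(abs(z$lo - 0.40), 0.05)
  expect_lt(abs(z$hi - 0.60), 0.05)
  # rim nodes sit on the rounded corner shoulder, so the node line lies a
  # fraction of a millimetre inferior to the facet plane and the apparent
  # depth is slightly reduced; the analytic-contour test covers the exact case
  expect_gt(max(m$samples$concavity_depth_mm), 1.4)
  expect_lt(max(m$samples$concavity_depth_mm), 2.3)
  expect_false("medial" %in% m$zones$compartment)    # flat facet: no zone
  # gap tolerance: a single interrupting slice does not split the zone
  fake <- tibble::tibble(
    compartment = "lateral",
    normalized_distance = seq(0.1, 0.9, by = 0.1),
    n_concavity_nodes = c(0, 0, 3, 4, 0, 5, 2, 0, 0))
  zb <- concavity_zone_bounds(fake, "lateral", gap_slices = 1)
  expect_equal(c(zb$lo, zb$hi), c(0.3, 0.7))
  zb0 <- concavity_zone_bounds(fake, "lateral", gap_slices = 0)
  expect_equal(c(zb0$lo, zb0$hi), c(0.3, 0.4))   # equal runs: first wins
  expect_equal(nrow(concavity_zone_bounds(fake[0, ], "lateral")), 0)
})

test_that("subject summaries follow sample-SD and zone-filter semantics", {
  m <- ref_measurement()
  base <- summarize_subject(m)
  fake <- m
  fake$samples <- tibble::tibble(
    plane = "sagittal", compartment = "lateral",
    slope_deg = c(3, 4, 5, 10, 0),
    in_concavity_zone = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    n_concavity_nodes = 0, normalized_distance = seq(0.1, 0.5, 0.1),
    concavity_depth_mm = 0)
  fake$zones <- m$zones[0, ]
  sm <- summarize_subject(fake)
  expect_equal(sm$mean_deg, mean(c(3, 4, 5, 10, 0)))
  expect_equal(sm$zone_mean_deg, 10)               # only in-zone samples
  fake3 <- fake; fake3$samples <- fake$samples[1:3, ]
  sm3 <- summarize_subject(fake3)
  expect_equal(sm3$mean_deg, 4)
  expect_equal(sm3$sd_deg, 1)                      # sample SD, n - 1
  fake1 <- fake; fake1$samples <- fake$samples[1, ]
  sm1 <- summarize_subject(fake1)
  expect_equal(sm1$mean_deg, 3)
  expect_true(is.na(sm1$sd_deg))                   # SD absent, not zero
  expect_true(all(base$sd_deg >= 0, na.rm = TRUE))
})

test_that("the highlighted-zone classification uses strict thresholds", {
  expect_equal(classify_highlighted_zone(example_cohort()), 6 / 9,
               tolerance = 1e-12)
  all0 <- data.frame(lts = numeric(9), mts = numeric(9))
  expect_equal(classify_highlighted_zone(all0), 1)
  edge <- data.frame(lts = 5.5, mts = 0)
  expect_equal(classify_highlighted_zone(edge), 0)  # strict inequality
  edge2 <- data.frame(lts = 0, mts = 8)
  expect_equal(classify_highlighted_zone(edge2), 0)
  expect_error(classify_highlighted_zone(all0[0, ]), "Empty")
})

test_that("cohort statistics report correlations for three or more subjects", {
  st <- cohort_stats(example_cohort())
  expect_equal(st$n, 9)
  expect_equal(st$highlighted_fraction, 6 / 9)
  expect_true(is.finite(st$cor_cts_mts) && abs(st$cor_cts_mts) <= 1)
  co <- example_cohort()
  expect_equal(st$cor_cts_lts, cor(co$cts, co$lts))
  two <- cohort_stats(co[1:2, ])
  expect_true(is.na(two$cor_cts_mts))
})

test_that("tidy, glance and autoplot expose the measurement", {
  m <- ref_measurement()
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(m$samples))
  g <- glance(m)
  expect_equal(nrow(g), 1)
  p <- ggplot2::autoplot(m)
  expect_s3_class(p, "ggplot")
})
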