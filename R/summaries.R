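#' Subject-level slope summary
#'
#' Mean and sample SD (n - 1 denominator) of the signed slope per
#' compartment, over all valid slices and over the slices inside the
#' compartment's concavity zone, together with the zone bounds. Compartments
#' with fewer than two valid slices are reported as absent (`NA`), not zero.
#'
#' @param measurement A [measure_profiles()] result.
#' @param subject_id,sex Optional metadata carried into reports.
#' @return A tibble of class `subject_summary`, one row per compartment with
#'   columns `compartment`, `n`, `mean_deg`, `sd_deg`, `zone_lo`, `zone_hi`,
#'   `zone_n`, `zone_mean_deg`, `zone_sd_deg`.
#' @export
summarize_subject <- function(measurement, subject_id = NULL, sex = NULL) {
  stopifnot(inherits(measurement, "slope_measurement"))
  s <- measurement$samples
  z <- measurement$zones
  comps <- intersect(c("lateral", "medial", "coronal"),
                     unique(s$compartment))
  rows <- purrr::map_dfr(comps, function(comp) {
    x <- s$slope_deg[s$compartment == comp]
    zi <- s$slope_deg[s$compartment == comp & s$in_concavity_zone]
    zb <- z[z$compartment == comp, , drop = FALSE]
    measurable <- length(x) >= 2
    tibble(
      compartment = comp,
      n = length(x),
      mean_deg = if (measurable || length(x) == 1) mean(x) else NA_real_,
      sd_deg = if (length(x) >= 2) sd(x) else NA_real_,
      zone_lo = if (nrow(zb)) zb$lo else NA_real_,
      zone_hi = if (nrow(zb)) zb$hi else NA_real_,
      zone_n = length(zi),
      zone_mean_deg = if (length(zi)) mean(zi) else NA_real_,
      zone_sd_deg = if (length(zi) >= 2) sd(zi) else NA_real_)
  })
  structure(rows, subject_id = subject_id, sex = sex,
            class = c("subject_summary", class(rows)))
}

#' Cohort statistics across subjects
#'
#' Compartment means across a cohort, Pearson correlation of the coronal
#' mean with the medial and lateral means (reported once at least three
#' subjects are available), and the highlighted-zone fraction of
#' [classify_highlighted_zone()].
#'
#' @param cohort Data frame with one row per subject and numeric columns
#'   `lts`, `mts` and (optionally) `cts`: the subject-average lateral,
#'   medial, and coronal slopes in degrees.
#' @return A one-row tibble with cohort means, correlations and the
#'   highlighted-zone fraction.
#' @examples
#' cohort_stats(example_cohort())
#' @export
cohort_stats <- function(cohort) {
  stopifnot(is.data.frame(cohort), all(c("lts", "mts") %in% names(cohort)))
  if (!nrow(cohort)) abort("Empty cohort.")
  has_cts <- "cts" %in% names(cohort)
  n <- nrow(cohort)
  tibble(
    n = n,
    lts_mean = mean(cohort$lts), mts_mean = mean(cohort$mts),
    cts_mean = if (has_cts) mean(cohort$cts) else NA_real_,
    cor_cts_mts = if (has_cts && n >= 3) cor(cohort$cts, cohort$mts) else NA_real_,
    cor_cts_lts = if (has_cts && n >= 3) cor(cohort$cts, cohort$lts) else NA_real_,
    highlighted_fraction = classify_highlighted_zone(cohort))
}

#' Fraction of subjects in the low-slope highlighted zone
#'
#' Classifies each subject by whether both average slopes fall in the lower
#' left quarter of the medial-vs-lateral slope plane: mean medial slope
#' strictly below `mts_max` and mean lateral slope strictly below `lts_max`.
#'
#' @param cohort Data frame with numeric columns `lts` and `mts` (degrees),
#'   one row per subject.
#' @param mts_max,lts_max Strict upper thresholds in degrees; defaults 8 and
#'   5.5.
#' @return Fraction of subjects inside the zone, in `[0, 1]`.
#' @examples
#' classify_highlighted_zone(example_cohort())  # 2/3
#' @export
classify_highlighted_zone <- function(cohort, mts_max = 8, lts_max = 5.5) {
  stopifnot(is.data.frame(cohort), all(c("lts", "mts") %in% names(cohort)))
  if (!nrow(cohort)) abort("Empty cohort.")
  if (any(!is.finite(cohort$lts)) || any(!is.finite(cohort$mts)))
    abort("Cohort contains non-finite slope averages.")
  mean(cohort$mts < mts_max & cohort$lts < lts_max)
}

#' Bundled example cohort
#'
#' Subject-average tibial slopes for a nine-subject MRI morphometry cohort
#' (six female, three male), as measured by a slice-wise curvature-based
#' protocol: average lateral and medial slopes, their concavity-zone
#' averages, and the coronal average, with SDs in degrees. Used in examples
#' and as the worked input for [classify_highlighted_zone()].
#'
#' @return A tibble with one row per subject.
#' @examples
#' classify_highlighted_zone(example_cohort())
#' @export
example_cohort <- function() {
  tibble(
    subject = paste0("S", 1:9),
    sex = c("F", "F", "F", "F", "F", "F", "M", "M", "M"),
    lts = c(14.8, 5.4, 3.2, 8.7, 8.1, 3.4, -0.2, 3.3, 2.2),
    lts_sd = c(3.5, 1.1, 1.6, 3.1, 4.8, 0.3, 0.9, 2.2, 1.5),
    lts_zone = c(18.5, 5.5, 4.4, 9.5, 7.2, 3.3, -0.2, 3.9, 3.1),
    lts_zone_sd = c(2.2, 0.2, 1.3, 1.8, 1.5, 0.3, 1.2, 1.0, 1.0),
    mts = c(13.2, 5.7, 7.6, 10.1, 15.6, 5.9, 2.3, 3.3, 5.1),
    mts_sd = c(1.5, 2.1, 1.4, 1.6, 0.6, 0.8, 0.7, 1.1, 1.5),
    mts_zone = c(13.5, 4.4, 8.1, 11.0, 15.7, 5.3, 2.8, 3.6, 5.2),
    mts_zone_sd = c(3.2, 3.9, 1.8, 3.6, 1.7, 0.5, 1.1, 1.2, 1.6),
    cts = c(0.4, 0.4, 0.4, 0.4, 0.4, 2.4, 2.4, 0.4, 0.4),
    cts_sd = c(0.2, 0.2, 0.2, 0.2, 0.2, 1.6, 2.8, 0.2, 0.2))
}
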