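#' Tidy a slope measurement
#'
#' Returns the per-slice slope samples as a tibble: one row per measured
#' slice with plane, compartment, normalized distance, signed slope and node
#' coordinates.
#'
#' @param x A [measure_profiles()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy slope_measurement
#' @export
tidy.slope_measurement <- function(x, ...) {
  as_tibble(x$samples)
}

#' One-row overview of a slope measurement
#'
#' @param x A [measure_profiles()] result.
#' @param ... Unused.
#' @return A one-row tibble with compartment means/SDs (`lts`, `mts`,
#'   `cts`), concavity-zone means and bounds, and bookkeeping counts.
#' @export
glance.slope_measurement <- function(x, ...) {
  sm <- summarize_subject(x)
  g <- function(comp, col) {
    v <- sm[[col]][sm$compartment == comp]
    if (length(v)) v else NA_real_
  }
  tibble(
    lts = g("lateral", "mean_deg"), lts_sd = g("lateral", "sd_deg"),
    mts = g("medial", "mean_deg"), mts_sd = g("medial", "sd_deg"),
    cts = g("coronal", "mean_deg"), cts_sd = g("coronal", "sd_deg"),
    lts_zone = g("lateral", "zone_mean_deg"),
    mts_zone = g("medial", "zone_mean_deg"),
    lat_zone_lo = g("lateral", "zone_lo"), lat_zone_hi = g("lateral", "zone_hi"),
    med_zone_lo = g("medial", "zone_lo"), med_zone_hi = g("medial", "zone_hi"),
    n_samples = nrow(x$samples), n_skipped = nrow(x$skipped))
}

#' Plot slope profiles
#'
#' Signed slope against normalized distance from the reference slice, one
#' line per compartment, with concavity zones shaded.
#'
#' @param object A [measure_profiles()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot slope_measurement
#' @export
autoplot.slope_measurement <- function(object, ...) {
  s <- object$samples
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$normalized_distance,
                                       y = .data$slope_deg,
                                       colour = .data$compartment))
  if (nrow(object$zones))
    p <- p + ggplot2::geom_rect(
      data = object$zones, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                   ymin = -Inf, ymax = Inf, fill = .data$compartment),
      alpha = 0.12)
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "normalized distance from reference slice",
                  y = "tibial slope (deg)",
                  colour = "compartment", fill = "concavity zone") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.slope_measurement
#' @param measurement A [measure_profiles()] result.
#' @export
plot_slope_profiles <- function(measurement, ...) {
  autoplot.slope_measurement(measurement, ...)
}
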