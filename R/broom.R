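#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy and summarize cardiac indices
#'
#' `tidy()` returns the per-cycle table; `glance()` one row of
#' across-cycle means (EDV, ESV, SV, EF, HR, CO) plus the cycle count.
#'
#' @param x A `cardiac_indices` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cardiac_indices <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.cardiac_indices
#' @export
glance.cardiac_indices <- function(x, ...) {
  tibble::tibble(
    n_cycles = nrow(x),
    edv_ml = mean(x$edv_ml), esv_ml = mean(x$esv_ml),
    sv_ml = mean(x$sv_ml), ef_pct = mean(x$ef_pct),
    hr_bpm = mean(x$hr_bpm), co_lpm = mean(x$co_lpm)
  )
}

#' Tidy and summarize a Bland-Altman analysis
#'
#' `tidy()` returns the per-pair (average, difference) table; `glance()`
#' the mean difference, limits of agreement and within-limits fraction.
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bland_altman <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$pairs),
    mean_difference = x$mean_difference,
    sd_difference = x$sd_difference,
    loa_lower = x$loa_lower, loa_upper = x$loa_upper,
    within_limits_fraction = x$within_limits_fraction
  )
}

db_raster_df <- function(db, x, z) {
  tibble::tibble(
    x_mm = rep(x, each = length(z)) * 1e3,
    z_mm = rep(z, times = length(x)) * 1e3,
    db = as.vector(db)
  )
}

#' Plot methods for images, fields and analyses
#'
#' `autoplot()` methods return ggplot objects: greyscale B-mode and
#' M-mode images on millimetre axes (depth increasing downwards), field
#' maps as dB heat maps, volume waveforms as time series and
#' Bland-Altman scatter plots with the mean-difference and limit lines.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name autoplot-echopatch
NULL

#' @rdname autoplot-echopatch
#' @export
autoplot.bmode_image <- function(object, ...) {
  d <- db_raster_df(object$intensity_db, object$grid$x, object$grid$z)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_mm, .data$z_mm,
                                  fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(object$floor_db, 0),
                                 name = "dB") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)")
}

#' @rdname autoplot-echopatch
#' @export
autoplot.mmode_image <- function(object, ...) {
  d <- tibble::tibble(
    t_s = rep(object$times, each = length(object$z)),
    z_mm = rep(object$z * 1e3, times = length(object$times)),
    db = as.vector(object$intensity_db)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$t_s, .data$z_mm,
                                  fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "dB") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "depth (mm)")
}

#' @rdname autoplot-echopatch
#' @export
autoplot.field_map <- function(object, ...) {
  db <- 20 * log10(pmax(object$rms_pressure / max(object$rms_pressure),
                        1e-3))
  d <- db_raster_df(db, object$x, object$z)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_mm, .data$z_mm,
                                  fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "RMS (dB)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)")
}

#' @rdname autoplot-echopatch
#' @export
autoplot.volume_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$volume_ml)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "LV volume (ml)")
}

#' @rdname autoplot-echopatch
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$average, .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_difference) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "average", y = "difference")
}

#' @importFrom rlang .data
NULL
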