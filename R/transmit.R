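#' Excitation pulse description
#'
#' A Gaussian-modulated cosine at the array centre frequency whose
#' Gaussian spectral envelope has the stated -6 dB fractional bandwidth.
#' The temporal envelope standard deviation follows from
#' `sigma_f = bw * fc / (2 sqrt(2 ln 2))` and `sigma_t = 1 / (2 pi sigma_f)`;
#' the waveform is truncated at +/- 4 sigma_t.
#'
#' @param centre_frequency Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth in (0, 2).
#' @return Object of class `pulse`.
#' @export
pulse <- function(centre_frequency = 3e6, fractional_bandwidth = 0.55) {
  if (centre_frequency <= 0) {
    rlang::abort("`centre_frequency` must be positive.",
                 class = "echopatch_transmit_error")
  }
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2) {
    rlang::abort("`fractional_bandwidth` must lie in (0, 2).",
                 class = "echopatch_transmit_error")
  }
  sigma_f <- fractional_bandwidth * centre_frequency / (2 * sqrt(2 * log(2)))
  structure(
    list(
      centre_frequency = centre_frequency,
      fractional_bandwidth = fractional_bandwidth,
      sigma_t = 1 / (2 * pi * sigma_f)
    ),
    class = "pulse"
  )
}

#' Evaluate a pulse waveform
#'
#' @param p A `pulse`.
#' @param t Times in seconds (0 = envelope peak).
#' @return Pressure waveform values (unit peak envelope).
#' @export
pulse_waveform <- function(p, t) {
  stopifnot(inherits(p, "pulse"))
  w <- exp(-0.5 * (t / p$sigma_t)^2) * cos(2 * pi * p$centre_frequency * t)
  w[abs(t) > 4 * p$sigma_t] <- 0
  w
}

#' Half support of a pulse in seconds
#' @param p A `pulse`.
#' @export
pulse_support <- function(p) 4 * p$sigma_t

#' Equally spaced steering-angle set
#'
#' Endpoint-inclusive set of `n` angles. The wearable imager's wide-beam
#' compounding uses 97 angles spanning -37.5 to +37.5 degrees; the exact
#' step is 75 / 96 = 0.78125 degrees (printed as 0.78).
#'
#' @param min_deg,max_deg Span endpoints in degrees.
#' @param n Number of angles (>= 1).
#' @return Numeric vector of degrees, with attribute `step_deg`.
#' @export
angle_set <- function(min_deg = -37.5, max_deg = 37.5, n = 97L) {
  if (n < 1) {
    rlang::abort("`n` must be >= 1.", class = "echopatch_transmit_error")
  }
  if (min_deg > max_deg) {
    rlang::abort("`min_deg` must not exceed `max_deg`.",
                 class = "echopatch_transmit_error")
  }
  ang <- if (n == 1) (min_deg + max_deg) / 2 else
    seq(min_deg, max_deg, length.out = n)
  attr(ang, "step_deg") <- if (n > 1) (max_deg - min_deg) / (n - 1) else 0
  ang
}

new_transmit_event <- function(kind, array, delays, angle = NA_real_,
                               focal_point = NULL, virtual_source = NULL,
                               apodization = NULL) {
  delays <- delays - min(delays)
  if (is.null(apodization)) apodization <- rep(1, array$n_elements)
  structure(
    list(
      kind = kind, steer_angle = angle, focal_point = focal_point,
      virtual_source = virtual_source, delays = delays,
      apodization = apodization, n_elements = array$n_elements
    ),
    class = "transmit_event"
  )
}

#' @export
print.transmit_event <- function(x, ...) {
  cat(sprintf("<transmit_event> %s, %d elements, delay spread %.1f ns\n",
              x$kind, x$n_elements, diff(range(x$delays)) * 1e9))
  invisible(x)
}

#' Plane-wave transmit delays
#'
#' `delay_i = (x_i sin(theta) + z_i cos(theta)) / c`, shifted so the
#' minimum delay is zero. True (possibly curved) element positions are
#' used, so the law also holds for conformal arrays.
#'
#' @param array An `array_geometry`.
#' @param angle Steering angle in degrees (|angle| < 90).
#' @param c Speed of sound in m/s.
#' @return A `transmit_event` of kind `"plane"`.
#' @export
plane_delays <- function(array, angle, c = 1540) {
  if (abs(angle) >= 90) {
    rlang::abort("Plane-wave steering angle must satisfy |angle| < 90 deg.",
                 class = "echopatch_transmit_error")
  }
  th <- angle * pi / 180
  d <- (array$positions[, 1] * sin(th) + array$positions[, 3] * cos(th)) / c
  new_transmit_event("plane", array, d, angle = angle)
}

#' Mono-focus transmit delays
#'
#' `delay_i = (max_j d_j - d_i) / c` with `d_i = |focus - r_i|`, so that
#' the wavefronts from all elements coincide at the focal point.
#'
#' @param array An `array_geometry`.
#' @param focus Focal point, 3-vector in metres (z > 0), or a scalar depth.
#' @param c Speed of sound in m/s.
#' @return A `transmit_event` of kind `"focus"`.
#' @export
focus_delays <- function(array, focus = 60e-3, c = 1540) {
  if (length(focus) == 1) focus <- c(0, 0, focus)
  if (focus[3] <= 0) {
    rlang::abort("Focal depth must be positive.",
                 class = "echopatch_transmit_error")
  }
  d <- sqrt(colSums((t(array$positions) - focus)^2))
  if (any(d < 1e-9)) {
    rlang::abort("Focus coincides with an element position.",
                 class = "echopatch_transmit_error")
  }
  new_transmit_event("focus", array, (max(d) - d) / c,
                     focal_point = focus)
}

#' Wide-beam (diverging-wave) transmit delays
#'
#' The diverging wavefront is generated by a virtual point source behind
#' the aperture at `v = (-z_v sin(theta), 0, -z_v cos(theta))`;
#' `delay_i = (|r_i - v| - min_j |r_j - v|) / c`. As `z_v` grows the law
#' converges to the plane-wave law at the same angle.
#'
#' @param array An `array_geometry`.
#' @param angle Steering angle in degrees.
#' @param virtual_depth Distance of the virtual source behind the aperture
#'   centre, metres (> 0).
#' @param c Speed of sound in m/s.
#' @return A `transmit_event` of kind `"widebeam"`.
#' @export
widebeam_delays <- function(array, angle, virtual_depth, c = 1540) {
  if (virtual_depth <= 0) {
    rlang::abort("`virtual_depth` must be positive.",
                 class = "echopatch_transmit_error")
  }
  th <- angle * pi / 180
  v <- c(-virtual_depth * sin(th), 0, -virtual_depth * cos(th))
  d <- sqrt(colSums((t(array$positions) - v)^2))
  new_transmit_event("widebeam", array, (d - min(d)) / c, angle = angle,
                     virtual_source = v)
}

#' Default virtual-source depth for a compounding span
#'
#' Chosen so the geometric cone of the 0-degree diverging wave covers the
#' full steered sector: `z_v = (aperture / 2) / tan(span / 2)`.
#'
#' @param array An `array_geometry`.
#' @param span_deg Full angular span in degrees.
#' @export
default_virtual_depth <- function(array, span_deg = 75) {
  (aperture_width(array) / 2) / tan(span_deg / 2 * pi / 180)
}

#' Transmit sequence container
#'
#' @param events List of `transmit_event`s (non-empty, same array size).
#' @param pulse A `pulse`.
#' @return Object of class `transmit_sequence`.
#' @export
transmit_sequence <- function(events, pulse = echopatch::pulse()) {
  if (length(events) == 0) {
    rlang::abort("A transmit sequence must contain at least one event.",
                 class = "echopatch_transmit_error")
  }
  n <- unique(vapply(events, function(e) e$n_elements, integer(1)))
  if (length(n) != 1) {
    rlang::abort("All events must reference the same array.",
                 class = "echopatch_transmit_error")
  }
  structure(list(events = events, pulse = pulse),
            class = "transmit_sequence")
}

#' @export
print.transmit_sequence <- function(x, ...) {
  kinds <- table(vapply(x$events, function(e) e$kind, character(1)))
  cat(sprintf("<transmit_sequence> %d events (%s)\n", length(x$events),
              paste(names(kinds), kinds, sep = ":", collapse = ", ")))
  invisible(x)
}

#' @export
length.transmit_sequence <- function(x) length(x$events)

#' Wide-beam coherent-compounding sequence
#'
#' One diverging-wave event per angle of an endpoint-inclusive angle set.
#' Defaults reproduce the wearable imager's sequence: 97 angles over a
#' 75-degree span (-37.5 to +37.5 degrees).
#'
#' @param array An `array_geometry`.
#' @param span_deg Full span in degrees.
#' @param n_angles Number of angles.
#' @param virtual_depth Virtual-source depth (m); default
#'   [default_virtual_depth()].
#' @param pulse A `pulse`.
#' @param c Speed of sound in m/s.
#' @return A `transmit_sequence` of wide-beam events.
#' @export
compounding_sequence <- function(array, span_deg = 75, n_angles = 97L,
                                 virtual_depth = NULL,
                                 pulse = echopatch::pulse(), c = 1540) {
  if (is.null(virtual_depth)) {
    virtual_depth <- if (span_deg > 0) {
      default_virtual_depth(array, span_deg)
    } else {
      10 * aperture_width(array)
    }
  }
  angles <- angle_set(-span_deg / 2, span_deg / 2, n_angles)
  events <- lapply(angles, function(a) {
    widebeam_delays(array, a, virtual_depth, c)
  })
  transmit_sequence(events, pulse)
}

#' Single-event helper sequences
#'
#' `plane_sequence()` wraps one or more plane-wave events;
#' `focus_sequence()` wraps a single mono-focus event (default focal
#' depth 60 mm).
#'
#' @param array An `array_geometry`.
#' @param angles Steering angles in degrees.
#' @param focus Focal point or depth (m).
#' @param pulse A `pulse`.
#' @param c Speed of sound in m/s.
#' @return A `transmit_sequence`.
#' @export
plane_sequence <- function(array, angles = 0, pulse = echopatch::pulse(),
                           c = 1540) {
  transmit_sequence(lapply(angles, function(a) plane_delays(array, a, c)),
                    pulse)
}

#' @rdname plane_sequence
#' @export
focus_sequence <- function(array, focus = 60e-3,
                           pulse = echopatch::pulse(), c = 1540) {
  transmit_sequence(list(focus_delays(array, focus, c)), pulse)
}
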