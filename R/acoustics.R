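#' Root mean square
#'
#' `sqrt((x1^2 + ... + xn^2) / n)`, the quantity mapped over the grid by
#' [simulate_field()].
#'
#' @param x Non-empty numeric vector.
#' @return Non-negative scalar.
#' @export
rms <- function(x) {
  if (length(x) == 0) {
    rlang::abort("`x` must be non-empty.", class = "echopatch_acoustics_error")
  }
  sqrt(mean(x^2))
}

#' Point-scatterer phantom
#'
#' A phantom is a tibble of point scatterers (`x`, `y`, `z` in metres,
#' `amplitude` dimensionless reflectivity) plus optional labelled regions
#' used as ground truth by the quality metrics.
#'
#' @param scatterers Data frame with columns `x`, `y`, `z`, `amplitude`
#'   (missing `y` defaults to 0, missing `amplitude` to 1).
#' @param regions Optional tibble of labelled shapes (kept as metadata).
#' @param seed Optional integer recorded for provenance.
#' @return Object of class `phantom` (a tibble subclass).
#' @export
phantom <- function(scatterers, regions = NULL, seed = NULL) {
  s <- tibble::as_tibble(scatterers)
  if (!"y" %in% names(s)) s$y <- 0
  if (!"amplitude" %in% names(s)) s$amplitude <- 1
  s <- s[, c("x", "y", "z", "amplitude")]
  if (nrow(s) > 0) {
    if (any(!is.finite(as.matrix(s)))) {
      rlang::abort("Scatterer coordinates and amplitudes must be finite.",
                   class = "echopatch_acoustics_error")
    }
    if (any(s$z <= 0)) {
      rlang::abort("All scatterers must lie at z > 0 (inside the tissue).",
                   class = "echopatch_acoustics_error")
    }
  }
  structure(s, class = c("phantom", class(tibble::tibble())),
            regions = regions, seed = seed)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d scatterers\n", nrow(x)))
  NextMethod()
}

scatterer_matrix <- function(ph) {
  if (nrow(ph) == 0) {
    matrix(numeric(0), 0, 3)
  } else {
    cbind(ph$x, ph$y, ph$z)
  }
}

#' Rectangular simulation grid for field maps
#'
#' @param x_range,z_range Lateral/axial extents in metres (`z > 0`).
#' @param dx,dz Grid spacings in metres.
#' @param y Elevational plane (default 0).
#' @return List with coordinate vectors `x`, `z` and scalar `y`.
#' @export
field_grid <- function(x_range = c(-8e-3, 8e-3), z_range = c(1e-3, 140e-3),
                       dx = 0.5e-3, dz = 0.5e-3, y = 0) {
  if (min(z_range) <= 0) {
    rlang::abort("Field grids must lie at z > 0.",
                 class = "echopatch_acoustics_error")
  }
  list(x = seq(x_range[1], x_range[2], by = dx),
       z = seq(z_range[1], z_range[2], by = dz), y = y)
}

#' Simulated transmitted-pressure RMS field
#'
#' For each grid point the time-domain pressure is the superposition of
#' the per-element delayed pulse replicas with 1/r spherical spreading and
#' far-field rectangular-aperture directivity (element width acting
#' laterally, element length elevationally). The map reports the root
#' mean square of that waveform over a common time record; for a
#' multi-event sequence the squared sums of all events are pooled before
#' the square root, so the compound field is the overall effect of all
#' transmissions.
#'
#' @param array An `array_geometry`.
#' @param sequence A `transmit_sequence` or a single `transmit_event`.
#' @param grid A [field_grid()].
#' @param pulse A `pulse` (defaults to the sequence's pulse).
#' @param c Speed of sound, m/s.
#' @param fs Time sampling rate for the RMS record, Hz.
#' @return Object of class `field_map`: `x`, `z`, and `rms_pressure`
#'   (length(z) x length(x) matrix, arbitrary linear units).
#' @export
simulate_field <- function(array, sequence, grid = field_grid(),
                           pulse = NULL, c = 1540, fs = 20e6) {
  if (inherits(sequence, "transmit_event")) {
    sequence <- transmit_sequence(list(sequence),
                                  if (is.null(pulse)) echopatch::pulse()
                                  else pulse)
  }
  stopifnot(inherits(sequence, "transmit_sequence"))
  p <- if (is.null(pulse)) sequence$pulse else pulse
  if (min(grid$z) <= 0) {
    rlang::abort("Field grids must lie at z > 0.",
                 class = "echopatch_acoustics_error")
  }
  pts <- expand.grid(z = grid$z, x = grid$x) # z fastest -> column-major fill
  n_pts <- nrow(pts)
  py <- rep(grid$y, n_pts)
  sumsq <- numeric(n_pts)
  n_rec <- 0
  for (ev in sequence$events) {
    sumsq <- sumsq + cpp_field_event(
      array$positions, array$normals, ev$delays, ev$apodization,
      pts$x, py, pts$z, p$centre_frequency, p$sigma_t, c, fs,
      array$element_width, array$element_length
    )
    # common record: longest arrival plus pulse support
    t_end <- max(ev$delays) +
      sqrt(max(grid$x^2 + grid$y^2) + max(grid$z)^2) / c + 2 * pulse_support(p)
    n_rec <- max(n_rec, ceiling(t_end * fs))
  }
  structure(
    list(x = grid$x, z = grid$z,
         rms_pressure = matrix(sqrt(sumsq / n_rec),
                               nrow = length(grid$z), ncol = length(grid$x))),
    class = "field_map"
  )
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %d x %d points, peak RMS %.3g\n",
              length(x$z), length(x$x), max(x$rms_pressure)))
  invisible(x)
}

#' Simulate pulse-echo RF channel data
#'
#' Born single-scattering model. For each event, element and scatterer the
#' echo arrives at `t = t_tx + |scatterer - r_e| / c`, where `t_tx` is the
#' first arrival of the transmitted wavefront at the scatterer
#' (`min_e(delay_e + |p - r_e| / c)`); the amplitude is
#' reflectivity x (1/r_tx)(1/r_rx) x transmit and receive directivity.
#' Echoes are accumulated linearly over scatterers; optional white
#' Gaussian noise of the stated RMS is added with an explicit seed.
#'
#' @param phantom A [phantom()].
#' @param array An `array_geometry`.
#' @param sequence A `transmit_sequence`.
#' @param fs Sampling rate, Hz (must be >= 4 x centre frequency).
#' @param duration Record length in seconds; default covers the deepest
#'   scatterer round trip plus margins.
#' @param noise_rms Additive Gaussian noise RMS (0 = off).
#' @param seed Integer seed for the noise (required when `noise_rms > 0`).
#' @param c Speed of sound, m/s.
#' @return Object of class `channel_data`: `samples` array
#'   (time x element x event), `fs`, `t0`, `c`, `array`, `sequence`.
#' @export
simulate_channel_data <- function(phantom, array, sequence, fs = 20e6,
                                  duration = NULL, noise_rms = 0,
                                  seed = NULL, c = 1540) {
  stopifnot(inherits(array, "array_geometry"),
            inherits(sequence, "transmit_sequence"))
  p <- sequence$pulse
  if (fs < 4 * p$centre_frequency) {
    rlang::abort("`fs` must be at least 4x the pulse centre frequency.",
                 class = "echopatch_acoustics_error")
  }
  if (is.null(duration)) {
    zmax <- if (nrow(phantom) > 0) max(phantom$z) else 10e-3
    max_delay <- max(vapply(sequence$events,
                            function(e) max(e$delays), numeric(1)))
    duration <- max_delay + 2 * (zmax + 5e-3) / c + 2 * pulse_support(p)
  }
  # round up to an FFT-friendly length (Hilbert transforms downstream)
  n_samples <- stats::nextn(as.integer(ceiling(duration * fs)), c(2, 3, 5))
  sc <- scatterer_matrix(phantom)
  amps <- if (nrow(phantom) > 0) phantom$amplitude else numeric(0)
  n_ev <- length(sequence$events)
  samples <- array(0, dim = c(n_samples, array$n_elements, n_ev))
  for (k in seq_len(n_ev)) {
    ev <- sequence$events[[k]]
    samples[, , k] <- cpp_channel_event(
      array$positions, array$normals, ev$delays, ev$apodization,
      sc, amps, p$centre_frequency, p$sigma_t, c, fs, 0, n_samples,
      array$element_width, array$element_length
    )
  }
  if (noise_rms > 0) {
    if (is.null(seed)) {
      rlang::abort("Provide an explicit `seed` when `noise_rms > 0`.",
                   class = "echopatch_acoustics_error")
    }
    set.seed(seed)
    samples <- samples + stats::rnorm(length(samples), sd = noise_rms)
  }
  structure(
    list(samples = samples, fs = fs, t0 = 0, c = c,
         array = array, sequence = sequence, noise_rms = noise_rms,
         seed = seed),
    class = "channel_data"
  )
}

#' @export
print.channel_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "<channel_data> %d samples x %d elements x %d events @ %.3g MHz\n",
    d[1], d[2], d[3], x$fs / 1e6
  ))
  invisible(x)
}

#' Analytic signal of a real trace
#'
#' FFT-based Hilbert construction; the modulus is the signal envelope.
#' Matrices are processed column-wise.
#'
#' @param x Real numeric vector or matrix (one trace per column).
#' @return Complex vector or matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  if (is.matrix(x)) {
    stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  } else {
    stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  }
}
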