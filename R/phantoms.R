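#' Wire phantoms
#'
#' Monofilament wires are far below the imaging resolution and are
#' modelled as ideal point scatterers of unit reflectivity. Two presets
#' mirror common characterization layouts: `"nine-wire-row"` places nine
#' wires at 0, +/-1, +/-2, +/-3 and +/-4 cm laterally at 50 mm depth;
#' `"depth-ladder"` places on-axis wires every 10 mm from 10 to 140 mm.
#'
#' @param layout `"nine-wire-row"`, `"depth-ladder"`, or a data frame with
#'   columns `x`, `z` (metres; optional `reflectivity`).
#' @return A [phantom()].
#' @export
wire_phantom <- function(layout = "nine-wire-row") {
  if (is.character(layout)) {
    layout <- switch(
      layout,
      "nine-wire-row" = tibble::tibble(
        x = c(0, 1, -1, 2, -2, 3, -3, 4, -4) * 1e-2, z = 50e-3
      ),
      "depth-ladder" = tibble::tibble(x = 0, z = seq(10, 140, 10) * 1e-3),
      rlang::abort(sprintf("Unknown wire layout preset '%s'.", layout),
                   class = "echopatch_phantom_error")
    )
  }
  layout <- tibble::as_tibble(layout)
  if (nrow(layout) == 0) {
    return(phantom(tibble::tibble(x = numeric(0), y = numeric(0),
                                  z = numeric(0), amplitude = numeric(0))))
  }
  if (any(layout$z <= 0)) {
    rlang::abort("Wires must lie at z > 0.",
                 class = "echopatch_phantom_error")
  }
  if (anyDuplicated(layout[, c("x", "z")])) {
    rlang::abort("Wire positions must be unique.",
                 class = "echopatch_phantom_error")
  }
  refl <- if ("reflectivity" %in% names(layout)) layout$reflectivity else 1
  phantom(tibble::tibble(x = layout$x, y = 0, z = layout$z,
                         amplitude = refl))
}

# Nominal mid-depth resolution cell used to express speckle density
# (lateral ~1 mm x axial ~0.5 mm for the 3 MHz default aperture).
resolution_cell_area <- function() 1.0e-3 * 0.5e-3

#' Speckle phantom with cylindrical contrast inclusions
#'
#' Uniformly random scatterer positions (seeded) fill the field of view
#' with fully developed speckle; scatterer reflectivities are Gaussian
#' with standard deviation scaled by `10^(contrast_db / 20)` inside each
#' inclusion and 1 outside. Inclusion definitions are retained as ground
#' truth for contrast metrics.
#'
#' @param inclusions Data frame with columns `x`, `z`, `radius` (metres)
#'   and `contrast_db`; inclusions must not overlap.
#' @param x_range,z_range Field extents in metres.
#' @param density Scatterers per nominal resolution cell (>= 10 for fully
#'   developed speckle; default 20).
#' @param seed Integer seed (required, for reproducibility).
#' @return A [phantom()] with a `regions` attribute holding the inclusion
#'   table.
#' @export
inclusion_phantom <- function(inclusions, x_range = c(-8e-3, 8e-3),
                              z_range = c(20e-3, 40e-3), density = 20,
                              seed = 1L) {
  inc <- tibble::as_tibble(inclusions)
  stopifnot(all(c("x", "z", "radius", "contrast_db") %in% names(inc)))
  if (any(inc$radius <= 0)) {
    rlang::abort("Inclusion radii must be positive.",
                 class = "echopatch_phantom_error")
  }
  if (nrow(inc) > 1) {
    for (i in seq_len(nrow(inc) - 1)) {
      for (j in (i + 1):nrow(inc)) {
        d <- sqrt((inc$x[i] - inc$x[j])^2 + (inc$z[i] - inc$z[j])^2)
        if (d < inc$radius[i] + inc$radius[j]) {
          rlang::abort("Inclusions must not overlap.",
                       class = "echopatch_phantom_error")
        }
      }
    }
  }
  area <- diff(range(x_range)) * diff(range(z_range))
  n <- as.integer(round(density * area / resolution_cell_area()))
  set.seed(seed)
  x <- stats::runif(n, x_range[1], x_range[2])
  z <- stats::runif(n, z_range[1], z_range[2])
  scale <- rep(1, n)
  for (i in seq_len(nrow(inc))) {
    ins <- (x - inc$x[i])^2 + (z - inc$z[i])^2 < inc$radius[i]^2
    scale[ins] <- 10^(inc$contrast_db[i] / 20)
  }
  amp <- stats::rnorm(n) * scale
  phantom(tibble::tibble(x = x, y = 0, z = z, amplitude = amp),
          regions = inc, seed = seed)
}

# Smooth periodic LV volume waveform: contraction over 30% of the cycle,
# end-systolic plateau 10%, filling 30%, end-diastolic diastasis 30%.
lv_volume_phase <- function(phase, edv, esv) {
  phase <- phase %% 1
  v <- numeric(length(phase))
  sv <- edv - esv
  a <- phase < 0.30
  v[a] <- esv + sv * (1 + cos(pi * phase[a] / 0.30)) / 2
  b <- phase >= 0.30 & phase < 0.40
  v[b] <- esv
  d <- phase >= 0.40 & phase < 0.70
  v[d] <- esv + sv * (1 - cos(pi * (phase[d] - 0.40) / 0.30)) / 2
  e <- phase >= 0.70
  v[e] <- edv
  v
}

#' Beating left-ventricle phantom
#'
#' Generates a periodic stack of binary cavity masks emulating
#' segmentation output on an apical long-axis section of the left
#' ventricle, together with the exact ground-truth volume per frame. The
#' cavity is a prolate spheroid with a fixed 2:1 long-to-short axis ratio
#' whose volume `(4/3) pi a b^2` follows a smooth two-phase cycle between
#' the end-diastolic and end-systolic volumes (systolic contraction over
#' about a third of the cycle, then filling and a diastasis plateau).
#'
#' @param edv,esv End-diastolic / end-systolic volume in ml (esv < edv).
#' @param heart_rate Beats per minute.
#' @param frame_rate Frames per second (must exceed 2 x heart_rate / 60).
#' @param n_cycles Number of cardiac cycles.
#' @param pixel_mm Mask pixel size in millimetres.
#' @param n_pixels Mask side length in pixels (square masks).
#' @param seed Integer recorded for provenance (generation is
#'   deterministic).
#' @return List with `masks` (frame x row x col binary array), `truth`
#'   (tibble `time_s`, `volume_ml`), `frame_dt` (s), `pixel_mm`, `spec`.
#' @export
beating_lv <- function(edv = 120, esv = 50, heart_rate = 75,
                       frame_rate = 30, n_cycles = 4, pixel_mm = 0.5,
                       n_pixels = 224L, seed = 1L) {
  if (!(esv > 0 && esv < edv)) {
    rlang::abort("Require 0 < esv < edv.", class = "echopatch_phantom_error")
  }
  if (heart_rate <= 0) {
    rlang::abort("`heart_rate` must be positive.",
                 class = "echopatch_phantom_error")
  }
  if (frame_rate < 2 * heart_rate / 60) {
    rlang::abort("`frame_rate` undersamples the cycle (temporal aliasing).",
                 class = "echopatch_phantom_error")
  }
  period <- 60 / heart_rate
  n_frames <- as.integer(round(n_cycles * period * frame_rate))
  t <- (seq_len(n_frames) - 1) / frame_rate
  vol <- lv_volume_phase(t / period, edv, esv)
  # prolate spheroid, a = 2 b: V = (4/3) pi a b^2 = (8/3) pi b^3
  b_mm <- (3 * vol * 1e3 / (8 * pi))^(1 / 3) # ml -> mm^3
  a_mm <- 2 * b_mm
  ctr <- (n_pixels + 1) / 2
  rr <- (seq_len(n_pixels) - ctr) * pixel_mm # long axis along rows
  cc <- (seq_len(n_pixels) - ctr) * pixel_mm
  masks <- array(0L, dim = c(n_frames, n_pixels, n_pixels))
  for (k in seq_len(n_frames)) {
    m <- outer(rr^2 / a_mm[k]^2, cc^2 / b_mm[k]^2, `+`) <= 1
    masks[k, , ] <- m * 1L
  }
  list(
    masks = masks,
    truth = tibble::tibble(time_s = t, volume_ml = vol),
    frame_dt = 1 / frame_rate, pixel_mm = pixel_mm,
    spec = list(edv = edv, esv = esv, heart_rate = heart_rate,
                frame_rate = frame_rate, n_cycles = n_cycles, seed = seed)
  )
}
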