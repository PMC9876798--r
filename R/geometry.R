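#' Construct a flat linear transducer array
#'
#' Builds the geometry of a 1-D linear array centred on the lateral (x)
#' axis. The default arguments describe a wearable 3 MHz cardiac imager
#' aperture: 32 elements, 0.4 mm pitch, 0.3 mm element width, 2.3 mm
#' elevational element length and 55% fractional (-6 dB) bandwidth.
#'
#' Coordinate convention throughout the package: x lateral, y elevational,
#' z axial positive into tissue, origin at the aperture centre, SI units.
#'
#' @param n_elements Number of elements (>= 1).
#' @param pitch Element centre-to-centre spacing in metres.
#' @param element_width Lateral element width in metres (must be < pitch).
#' @param element_length Elevational element length in metres.
#' @param centre_frequency Centre frequency in Hz.
#' @param fractional_bandwidth Fractional -6 dB bandwidth (dimensionless).
#' @return An object of class `array_geometry`: a list with the scalar
#'   parameters plus `positions` and `normals` (`n_elements` x 3 matrices).
#' @examples
#' arr <- linear_array()
#' aperture_width(arr) # 12.4 mm
#' @export
linear_array <- function(n_elements = 32L, pitch = 0.4e-3,
                         element_width = 0.3e-3, element_length = 2.3e-3,
                         centre_frequency = 3e6,
                         fractional_bandwidth = 0.55) {
  if (n_elements < 1) {
    abort_geometry("`n_elements` must be >= 1.")
  }
  if (!(pitch > element_width && element_width > 0)) {
    abort_geometry("Require `pitch` > `element_width` > 0.")
  }
  if (element_length <= 0 || centre_frequency <= 0) {
    abort_geometry("Element length and centre frequency must be positive.")
  }
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2) {
    abort_geometry("`fractional_bandwidth` must lie in (0, 2).")
  }
  n <- as.integer(n_elements)
  x <- (seq_len(n) - 1 - (n - 1) / 2) * pitch
  positions <- cbind(x = x, y = 0, z = 0)
  normals <- cbind(x = 0, y = 0, z = rep(1, n))
  structure(
    list(
      n_elements = n, pitch = pitch, element_width = element_width,
      element_length = element_length, centre_frequency = centre_frequency,
      fractional_bandwidth = fractional_bandwidth,
      positions = positions, normals = normals, flat = TRUE
    ),
    class = "array_geometry"
  )
}

abort_geometry <- function(msg) {
  rlang::abort(msg, class = "echopatch_geometry_error")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "<array_geometry> %d elements, pitch %.3g mm, fc %.3g MHz, %s\n",
    x$n_elements, x$pitch * 1e3, x$centre_frequency / 1e6,
    if (isTRUE(x$flat)) "flat" else "curved"
  ))
  invisible(x)
}

#' @export
as_tibble.array_geometry <- function(x, ...) {
  tibble::tibble(
    element = seq_len(x$n_elements),
    x = x$positions[, 1], y = x$positions[, 2], z = x$positions[, 3],
    nx = x$normals[, 1], ny = x$normals[, 2], nz = x$normals[, 3]
  )
}

#' Aperture width of a linear array
#'
#' @param array An `array_geometry`.
#' @return Width `(n_elements - 1) * pitch` in metres.
#' @export
aperture_width <- function(array) {
  (array$n_elements - 1) * array$pitch
}

#' Pitch expressed in ultrasonic wavelengths
#'
#' With the default cardiac-imager parameters (0.4 mm pitch, 3 MHz,
#' c = 1540 m/s) the pitch is 0.78 wavelengths, small enough to keep
#' grating lobes out of the steered sector.
#'
#' @param pitch Pitch in metres.
#' @param fc Centre frequency in Hz.
#' @param c Speed of sound in m/s (default 1540, soft tissue).
#' @return `pitch * fc / c` (dimensionless).
#' @examples
#' pitch_in_wavelengths(0.4e-3, 3e6) # ~0.78
#' @export
pitch_in_wavelengths <- function(pitch, fc, c = 1540) {
  if (any(c(pitch, fc, c) <= 0)) {
    abort_geometry("`pitch`, `fc` and `c` must all be positive.")
  }
  pitch * fc / c
}

#' Orthogonal (Mills-cross) array from a flat linear array
#'
#' Two identical linear apertures sharing a centre, the second rotated 90
#' degrees about the axial (z) axis, giving two perpendicular imaging
#' planes without rotating the probe.
#'
#' @param base A flat `array_geometry`.
#' @return An object of class `orthogonal_array` with fields `axis_a` and
#'   `axis_b`.
#' @export
orthogonal_array <- function(base) {
  stopifnot(inherits(base, "array_geometry"))
  if (!isTRUE(base$flat)) {
    abort_geometry("The base of an orthogonal array must be flat.")
  }
  axis_b <- base
  # rotate 90 deg about z: (x, y) -> (-y, x)
  axis_b$positions <- cbind(
    x = -base$positions[, 2], y = base$positions[, 1],
    z = base$positions[, 3]
  )
  axis_b$normals <- cbind(
    x = -base$normals[, 2], y = base$normals[, 1], z = base$normals[, 3]
  )
  structure(list(axis_a = base, axis_b = axis_b), class = "orthogonal_array")
}

#' @export
print.orthogonal_array <- function(x, ...) {
  cat(sprintf(
    "<orthogonal_array> 2 x %d elements (Mills cross)\n",
    x$axis_a$n_elements
  ))
  invisible(x)
}

#' Surface profiles for conformal arrays
#'
#' A surface profile describes the out-of-plane displacement of the skin
#' surface the array conforms to, as a function of arc length along the
#' aperture. `surface_flat()` is the identity; `surface_cylinder()` models
#' skin over a convex cylindrical body of the given radius (edge elements
#' recede from the tissue); `surface_sampled()` takes measured
#' (arc length, displacement) pairs, e.g. from a 3-D scan of the chest.
#'
#' @param radius Cylinder radius in metres (must exceed the aperture
#'   half-width when applied).
#' @param s Strictly increasing arc lengths in metres (sampled profile).
#' @param h Out-of-plane displacements in metres at `s` (positive towards
#'   the tissue, i.e. +z).
#' @return An object of class `surface_profile`.
#' @export
surface_flat <- function() {
  structure(list(kind = "flat"), class = "surface_profile")
}

#' @rdname surface_flat
#' @export
surface_cylinder <- function(radius) {
  if (radius <= 0) abort_geometry("Cylinder radius must be positive.")
  structure(list(kind = "cylinder", radius = radius),
            class = "surface_profile")
}

#' @rdname surface_flat
#' @export
surface_sampled <- function(s, h) {
  if (length(s) != length(h) || length(s) < 2) {
    abort_geometry("`s` and `h` must be equal-length vectors (>= 2).")
  }
  if (any(diff(s) <= 0)) {
    abort_geometry("Arc length `s` must be strictly increasing.")
  }
  structure(list(kind = "sampled", s = as.numeric(s), h = as.numeric(h)),
            class = "surface_profile")
}

#' Map a flat array onto a measured surface profile
#'
#' Re-positions the elements of a flat array along a curved surface so
#' that the arc length between adjacent elements is preserved (equal to
#' the pitch) and the element normals follow the local surface normal.
#' This supplies the true element positions used to correct phase
#' distortion in transmit and receive beamforming on a deformed aperture.
#' Positions are re-centred so the aperture centroid stays at the origin.
#'
#' @param array A flat `array_geometry`.
#' @param profile A `surface_profile`. A flat profile returns the array
#'   unchanged.
#' @return An `array_geometry` with curved positions/normals
#'   (`flat = FALSE` unless the profile is flat).
#' @export
apply_surface <- function(array, profile) {
  stopifnot(inherits(array, "array_geometry"),
            inherits(profile, "surface_profile"))
  if (profile$kind == "flat") {
    return(array)
  }
  n <- array$n_elements
  s_elem <- (seq_len(n) - 1 - (n - 1) / 2) * array$pitch

  if (profile$kind == "cylinder") {
    r <- profile$radius
    if (r <= aperture_width(array) / 2) {
      abort_geometry("Cylinder radius must exceed the aperture half-width.")
    }
    theta <- s_elem / r
    pos <- cbind(x = r * sin(theta), y = 0, z = r * cos(theta) - r)
    nrm <- cbind(x = sin(theta), y = 0, z = cos(theta))
  } else {
    if (min(profile$s) > min(s_elem) || max(profile$s) < max(s_elem)) {
      abort_geometry("Surface profile does not span the aperture.")
    }
    # integrate dx = sqrt(ds^2 - dh^2) on a fine arc-length grid
    sg <- seq(min(s_elem), max(s_elem), length.out = 4096)
    hg <- stats::approx(profile$s, profile$h, xout = sg)$y
    dh <- diff(hg)
    ds <- diff(sg)
    dx <- sqrt(pmax(ds^2 - dh^2, 0))
    xg <- c(0, cumsum(dx))
    xg <- xg - stats::approx(sg, xg, xout = 0)$y
    x_e <- stats::approx(sg, xg, xout = s_elem)$y
    z_e <- stats::approx(sg, hg, xout = s_elem)$y
    # tangent in the x-z plane -> normal with positive z component
    tx <- stats::approx(sg[-1] - ds / 2, dx / ds, xout = s_elem, rule = 2)$y
    tz <- stats::approx(sg[-1] - ds / 2, dh / ds, xout = s_elem, rule = 2)$y
    tn <- sqrt(tx^2 + tz^2)
    nrm <- cbind(x = -tz / tn, y = 0, z = tx / tn)
    pos <- cbind(x = x_e, y = 0, z = z_e)
  }
  pos <- sweep(pos, 2, colMeans(pos))
  colnames(pos) <- colnames(nrm) <- c("x", "y", "z")
  out <- array
  out$positions <- pos
  out$normals <- nrm
  out$flat <- FALSE
  out
}

#' Read or write a surface profile as CSV
#'
#' Two-column files hold `s_mm,h_mm` (arc length and out-of-plane
#' displacement in millimetres); values are converted to metres on read.
#'
#' @param path File path.
#' @param profile A sampled `surface_profile` (for writing).
#' @return `read_surface_csv()` returns a sampled `surface_profile`.
#' @export
read_surface_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("s_mm", "h_mm") %in% names(d))) {
    abort_geometry("Surface CSV must have columns `s_mm` and `h_mm`.")
  }
  surface_sampled(d$s_mm * 1e-3, d$h_mm * 1e-3)
}

#' @rdname read_surface_csv
#' @export
write_surface_csv <- function(profile, path) {
  stopifnot(inherits(profile, "surface_profile"),
            profile$kind == "sampled")
  utils::write.csv(
    data.frame(s_mm = profile$s * 1e3, h_mm = profile$h * 1e3),
    path, row.names = FALSE
  )
  invisible(path)
}
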