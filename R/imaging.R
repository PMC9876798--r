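#' Cartesian pixel grid with the standard spacing convention
#'
#' Pixel spacings follow the display convention
#' `dy = imaging depth / (N_vertical - 1)` and
#' `dx = imaging width / (N_lateral - 1)`, i.e. pixels span the extents
#' inclusively. The grid may be windowed away from the probe with
#' `z_min` / `x_centre`; `depth` and `width` are then the imaged extents.
#'
#' @param depth Axial extent in metres.
#' @param width Lateral extent in metres.
#' @param n_axial,n_lateral Pixel counts (>= 2).
#' @param z_min Top of the window (m, default 0).
#' @param x_centre Lateral centre of the window (m, default 0).
#' @return Object of class `pixel_grid` with coordinate vectors `x`, `z`
#'   and spacings `dx`, `dz`.
#' @export
pixel_grid <- function(depth, width, n_axial, n_lateral, z_min = 0,
                       x_centre = 0) {
  sp <- pixel_spacing(depth, width, n_axial, n_lateral)
  structure(
    list(
      depth = depth, width = width,
      n_axial = as.integer(n_axial), n_lateral = as.integer(n_lateral),
      dz = sp[["dy"]], dx = sp[["dx"]],
      z = z_min + seq(0, depth, length.out = n_axial),
      x = x_centre + seq(-width / 2, width / 2, length.out = n_lateral)
    ),
    class = "pixel_grid"
  )
}

#' Pixel spacing from image extents and pixel counts
#'
#' `dy = depth / (N_vertical - 1)`; `dx = width / (N_lateral - 1)`.
#'
#' @param depth,width Imaged extents in metres.
#' @param n_vertical,n_lateral Pixel counts (>= 2).
#' @return Named vector `c(dy = , dx = )` in metres.
#' @export
pixel_spacing <- function(depth, width, n_vertical, n_lateral) {
  if (n_vertical < 2 || n_lateral < 2) {
    rlang::abort("Pixel counts must be >= 2 per axis.",
                 class = "echopatch_imaging_error")
  }
  if (depth <= 0 || width <= 0) {
    rlang::abort("Image extents must be positive.",
                 class = "echopatch_imaging_error")
  }
  c(dy = depth / (n_vertical - 1), dx = width / (n_lateral - 1))
}

rx_window <- function(n, apodization = c("hann", "uniform")) {
  apodization <- match.arg(apodization)
  if (apodization == "uniform" || n == 1) {
    rep(1, n)
  } else {
    0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  }
}

grid_points <- function(grid) {
  # z varies fastest so matrices fill column-major as [z, x]
  list(x = rep(grid$x, each = length(grid$z)),
       z = rep(grid$z, times = length(grid$x)))
}

new_beamformed_frame <- function(values, grid, coverage = NULL,
                                 events = NA) {
  structure(list(values = values, grid = grid, coverage = coverage,
                 events = events),
            class = "beamformed_frame")
}

#' @export
print.beamformed_frame <- function(x, ...) {
  cat(sprintf("<beamformed_frame> %d x %d pixels\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Delay-and-sum receive beamforming
#'
#' Delay-and-sum of one transmit event onto a pixel grid. Each channel is
#' converted to its analytic signal before summation; per pixel, each
#' element in the receive aperture contributes its sample at
#' `t_tx(p) + |p - r_e| / c` (linear interpolation in time), where
#' `t_tx(p)` is the first arrival of the transmitted wavefront. Supplying
#' the true curved `element_positions` of a conformal array corrects the
#' phase distortion that nominal flat positions would cause.
#'
#' @param channel A `channel_data`.
#' @param grid A `pixel_grid`.
#' @param event Event index (default 1).
#' @param f_number Receive f-number of the angle-based dynamic aperture
#'   (acceptance `|tan theta| <= 1/(2 f#)`, Hann tapered; sector pixels
#'   outside every element's cone fall back to the full aperture). The
#'   default 0 selects phased-array mode: full aperture with the fixed
#'   `apodization` window.
#' @param apodization Fixed receive window used when `f_number = 0`:
#'   `"hann"` (default) or `"uniform"`.
#' @param element_positions Optional n x 3 matrix overriding the element
#'   positions assumed during beamforming (defaults to the positions of
#'   the array stored with the channel data).
#' @param .analytic Internal: precomputed analytic-signal matrix for this
#'   event (used by [beamform_compound()] to share one FFT pass).
#' @return A `beamformed_frame` of complex pixel values with a coverage
#'   matrix counting contributing elements per pixel.
#' @export
das_beamform <- function(channel, grid, event = 1L, f_number = 0,
                         apodization = c("hann", "uniform"),
                         element_positions = NULL, .analytic = NULL) {
  stopifnot(inherits(channel, "channel_data"), inherits(grid, "pixel_grid"))
  if (event < 1 || event > dim(channel$samples)[3]) {
    rlang::abort("`event` is out of range.",
                 class = "echopatch_imaging_error")
  }
  elem <- if (is.null(element_positions)) {
    channel$array$positions
  } else {
    element_positions
  }
  an <- if (is.null(.analytic)) {
    rf <- channel$samples[, , event, drop = TRUE]
    if (is.null(dim(rf))) rf <- matrix(rf, ncol = 1)
    analytic_signal(rf)
  } else {
    .analytic
  }
  ev <- channel$sequence$events[[event]]
  pts <- grid_points(grid)
  out <- cpp_das_event(Re(an), Im(an), elem, ev$delays, pts$x, pts$z,
                       channel$c, channel$fs, channel$t0, f_number,
                       rx_window(nrow(elem), apodization))
  vals <- matrix(complex(real = out$re, imaginary = out$im),
                 nrow = length(grid$z), ncol = length(grid$x))
  cov <- matrix(out$coverage, nrow = length(grid$z), ncol = length(grid$x))
  new_beamformed_frame(vals, grid, coverage = cov, events = event)
}

#' Coherent compounding of beamformed frames
#'
#' Pre-envelope (complex) weighted sum of frames on identical grids;
#' uniform weights by default.
#'
#' @param frames List of `beamformed_frame`s.
#' @param weights Optional numeric weights, one per frame.
#' @return A `beamformed_frame`.
#' @export
compound <- function(frames, weights = NULL) {
  if (length(frames) == 0) {
    rlang::abort("`frames` must be non-empty.",
                 class = "echopatch_imaging_error")
  }
  g <- frames[[1]]$grid
  same <- vapply(frames, function(f) {
    identical(f$grid$x, g$x) && identical(f$grid$z, g$z)
  }, logical(1))
  if (!all(same)) {
    rlang::abort("All frames must share the same pixel grid.",
                 class = "echopatch_imaging_error")
  }
  if (is.null(weights)) weights <- rep(1, length(frames))
  acc <- Reduce(`+`, Map(function(f, w) w * f$values, frames, weights))
  cov <- Reduce(`+`, lapply(frames, function(f) {
    if (is.null(f$coverage)) 0 else f$coverage
  }))
  new_beamformed_frame(acc, g, coverage = cov,
                       events = length(frames))
}

#' Beamform and coherently compound all events of a record
#'
#' @inheritParams das_beamform
#' @param weights Optional per-event compounding weights.
#' @return A `beamformed_frame`.
#' @export
beamform_compound <- function(channel, grid, f_number = 0,
                              apodization = c("hann", "uniform"),
                              element_positions = NULL, weights = NULL) {
  d <- dim(channel$samples)
  elem <- if (is.null(element_positions)) {
    channel$array$positions
  } else {
    element_positions
  }
  if (is.null(weights)) weights <- rep(1, d[3])
  # Hilbert all traces in one FFT pass, then one compounding kernel call
  an_all <- analytic_signal(matrix(channel$samples, nrow = d[1]))
  delays <- vapply(channel$sequence$events, function(e) e$delays,
                   numeric(d[2]))
  pts <- grid_points(grid)
  out <- cpp_das_compound(Re(an_all), Im(an_all), elem,
                          matrix(delays, nrow = d[2]), weights,
                          pts$x, pts$z, channel$c, channel$fs,
                          channel$t0, f_number,
                          rx_window(d[2], apodization))
  vals <- matrix(complex(real = out$re, imaginary = out$im),
                 nrow = length(grid$z), ncol = length(grid$x))
  cov <- matrix(out$coverage, nrow = length(grid$z), ncol = length(grid$x))
  new_beamformed_frame(vals, grid, coverage = cov, events = d[3])
}

#' Envelope detection and logarithmic compression
#'
#' The image intensity is the magnitude of the complex (analytic)
#' beamformed value, normalized to the frame maximum and compressed as
#' `I_new = 20 log10(I_old)` so the maximum maps to 0 dB, then clipped at
#' the display floor.
#'
#' @param frame A `beamformed_frame` (not identically zero).
#' @param floor_db Display floor in dB (default -60).
#' @return Object of class `bmode_image` with matrix `intensity_db`.
#' @export
envelope_logcompress <- function(frame, floor_db = -60) {
  stopifnot(inherits(frame, "beamformed_frame"))
  env <- Mod(frame$values)
  m <- max(env)
  if (m == 0) {
    rlang::abort("Cannot normalize an all-zero frame.",
                 class = "echopatch_imaging_error")
  }
  db <- 20 * log10(pmax(env / m, 10^((floor_db - 20) / 20)))
  db[db < floor_db] <- floor_db
  structure(
    list(intensity_db = db, grid = frame$grid, floor_db = floor_db),
    class = "bmode_image"
  )
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d pixels, floor %g dB\n",
              nrow(x$intensity_db), ncol(x$intensity_db), x$floor_db))
  invisible(x)
}

#' Linear-intensity view of a B-mode image
#'
#' Inverts the log compression: `10^(dB / 20)` (max 1).
#'
#' @param bmode A `bmode_image`.
#' @return Matrix of linear intensities.
#' @export
linear_intensity <- function(bmode) {
  10^(bmode$intensity_db / 20)
}

#' Sector scan conversion
#'
#' Converts beam x range sector data (polar) onto a Cartesian pixel grid
#' with bilinear interpolation, upsampling both directions by an integer
#' factor (default 5). Pixels outside the sector are set to the floor and
#' masked.
#'
#' @param sector Matrix of intensities, rows = range samples, columns =
#'   beams.
#' @param angles_deg Strictly monotone beam angles in degrees.
#' @param ranges Range sample positions in metres (uniform).
#' @param upsample Integer upsampling factor for both axes.
#' @param floor Value assigned outside the sector (default min of input).
#' @return List with `values` (matrix), `x`, `z`, `mask` (TRUE inside
#'   the sector).
#' @export
scan_convert <- function(sector, angles_deg, ranges, upsample = 5L,
                         floor = min(sector)) {
  if (length(angles_deg) != ncol(sector) || length(ranges) != nrow(sector)) {
    rlang::abort("`angles_deg`/`ranges` must match the sector dimensions.",
                 class = "echopatch_imaging_error")
  }
  d <- diff(angles_deg)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0))) {
    rlang::abort("Beam angles must be strictly monotone.",
                 class = "echopatch_imaging_error")
  }
  if (all(d < 0)) {
    angles_deg <- rev(angles_deg)
    sector <- sector[, rev(seq_len(ncol(sector))), drop = FALSE]
  }
  th <- angles_deg * pi / 180
  r_max <- max(ranges)
  x_ext <- if (length(th) > 1) r_max * max(abs(sin(th))) else 0
  nx <- max(2L, as.integer(ncol(sector) * upsample))
  nz <- max(2L, as.integer(nrow(sector) * upsample))
  x <- if (x_ext > 0) seq(-x_ext, x_ext, length.out = nx) else rep(0, 1)
  z <- seq(min(ranges) * min(cos(th)), r_max, length.out = nz)
  px <- rep(x, each = length(z))
  pz <- rep(z, times = length(x))
  r <- sqrt(px^2 + pz^2)
  a <- atan2(px, pz)
  # fractional indices into the polar raster
  fi_r <- (r - ranges[1]) / (ranges[2] - ranges[1])
  fi_a <- if (length(th) > 1) {
    stats::approx(th, seq_along(th) - 1, xout = a, rule = 1)$y
  } else {
    ifelse(abs(a - th[1]) < 1e-9, 0, NA_real_)
  }
  eps <- 1e-9
  inside <- !is.na(fi_a) & fi_r >= -eps & fi_r <= nrow(sector) - 1 + eps
  fi_r <- pmin(pmax(fi_r, 0), nrow(sector) - 1)
  vals <- rep(floor, length(px))
  if (any(inside)) {
    i0 <- pmin(floor(fi_r[inside]), nrow(sector) - 2)
    j0 <- pmin(floor(fi_a[inside]), max(ncol(sector) - 2, 0))
    wr <- fi_r[inside] - i0
    wa <- fi_a[inside] - j0
    idx <- function(i, j) sector[cbind(i + 1, j + 1)]
    if (ncol(sector) > 1) {
      vals[inside] <-
        (1 - wr) * (1 - wa) * idx(i0, j0) +
        wr * (1 - wa) * idx(i0 + 1, j0) +
        (1 - wr) * wa * idx(i0, j0 + 1) +
        wr * wa * idx(i0 + 1, j0 + 1)
    } else {
      vals[inside] <- (1 - wr) * idx(i0, 0) + wr * idx(i0 + 1, 0)
    }
  }
  list(values = matrix(vals, nrow = length(z), ncol = length(x)),
       x = x, z = z,
       mask = matrix(inside, nrow = length(z), ncol = length(x)))
}

#' Extract an M-mode image from a B-mode time series
#'
#' Stacks the axial intensity profile at the grid column nearest to the
#' requested scanline position, one column per frame.
#'
#' @param frames Time-ordered list (>= 2) of `bmode_image`s on a common
#'   grid.
#' @param x Scanline lateral position in metres (must fall inside the
#'   grid).
#' @param frame_dt Frame interval in seconds.
#' @return Object of class `mmode_image`: matrix `intensity_db`
#'   (depth x frame), `z`, `times`, `x`.
#' @export
extract_mmode <- function(frames, x = 0, frame_dt = 1 / 30) {
  if (length(frames) < 2) {
    rlang::abort("At least two frames are required for M-mode.",
                 class = "echopatch_imaging_error")
  }
  g <- frames[[1]]$grid
  if (x < min(g$x) || x > max(g$x)) {
    rlang::abort("Scanline position lies outside the image grid.",
                 class = "echopatch_imaging_error")
  }
  j <- which.min(abs(g$x - x))
  cols <- vapply(frames, function(f) f$intensity_db[, j],
                 numeric(length(g$z)))
  structure(
    list(intensity_db = cols, z = g$z,
         times = (seq_along(frames) - 1) * frame_dt, x = g$x[j],
         frame_dt = frame_dt, floor_db = frames[[1]]$floor_db),
    class = "mmode_image"
  )
}

#' @export
print.mmode_image <- function(x, ...) {
  cat(sprintf("<mmode_image> %d depths x %d frames at x = %.1f mm\n",
              nrow(x$intensity_db), ncol(x$intensity_db), x$x * 1e3))
  invisible(x)
}
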