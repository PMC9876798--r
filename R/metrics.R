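#' Full width at half maximum of a sampled profile
#'
#' Width of the main lobe at half the peak value, with sub-sample
#' half-max crossings located by linear interpolation between the
#' straddling samples. The profile must have a single main lobe whose
#' peak is interior and above both edges; profiles with two equal maxima
#' or whose peak sits on a boundary are rejected.
#'
#' @param profile Sampled non-negative values.
#' @param spacing Sample spacing (metres, or any unit).
#' @return FWHM in the units of `spacing`.
#' @export
fwhm <- function(profile, spacing) {
  n <- length(profile)
  if (n < 3) {
    rlang::abort("Profile too short.", class = "echopatch_metrics_error")
  }
  pk <- max(profile)
  at_pk <- which(profile == pk)
  if (any(diff(at_pk) > 1)) {
    rlang::abort("Profile has multiple equal maxima (not unimodal).",
                 class = "echopatch_metrics_error")
  }
  i <- at_pk[1]
  i2 <- at_pk[length(at_pk)]
  if (i == 1 || i2 == n) {
    rlang::abort("Peak lies on the profile boundary.",
                 class = "echopatch_metrics_error")
  }
  half <- pk / 2
  # walk outwards from the peak to the first half-max crossings
  li <- i
  while (li > 1 && profile[li - 1] >= half) li <- li - 1
  if (li == 1 && profile[1] >= half) {
    rlang::abort("No half-maximum crossing on the left.",
                 class = "echopatch_metrics_error")
  }
  left <- (li - 1) - (profile[li] - half) / (profile[li] - profile[li - 1])
  ri <- i2
  while (ri < n && profile[ri + 1] >= half) ri <- ri + 1
  if (ri == n && profile[n] >= half) {
    rlang::abort("No half-maximum crossing on the right.",
                 class = "echopatch_metrics_error")
  }
  right <- (ri - 1) + (profile[ri] - half) / (profile[ri] - profile[ri + 1])
  (right - left) * spacing
}

# Bilinear interpolation of a [z, x] matrix at query points; NA -> 0
# outside the grid.
interp_image <- function(m, zvec, xvec, zq, xq) {
  fi <- (zq - zvec[1]) / (zvec[2] - zvec[1])
  fj <- (xq - xvec[1]) / (xvec[2] - xvec[1])
  ok <- fi >= 0 & fi <= length(zvec) - 1 & fj >= 0 & fj <= length(xvec) - 1
  out <- numeric(length(zq))
  if (!any(ok)) return(out)
  i0 <- pmin(floor(fi[ok]), length(zvec) - 2)
  j0 <- pmin(floor(fj[ok]), length(xvec) - 2)
  wi <- fi[ok] - i0
  wj <- fj[ok] - j0
  out[ok] <-
    (1 - wi) * (1 - wj) * m[cbind(i0 + 1, j0 + 1)] +
    wi * (1 - wj) * m[cbind(i0 + 2, j0 + 1)] +
    (1 - wi) * wj * m[cbind(i0 + 1, j0 + 2)] +
    wi * wj * m[cbind(i0 + 2, j0 + 2)]
  out
}

#' Per-wire axial and lateral resolution from a B-mode image
#'
#' For each wire of the ground-truth phantom, locates the image peak
#' within `window` of the true position and measures the FWHM of the
#' linear-scale point-spread-function profiles through that peak. For a
#' sector imager the point spread is oriented along the beam: the axial
#' profile is taken along the range direction (aperture centre towards
#' the peak) and the lateral profile along the cross-range direction
#' perpendicular to it; on axis these reduce to the vertical and
#' horizontal image cuts. Wires with no local maximum within 2 mm of the
#' truth are flagged as missing.
#'
#' @param bmode A `bmode_image`.
#' @param truth A [phantom()] of point targets.
#' @param window Half-width of the search/profile window in metres.
#' @return Tibble: `x_mm`, `z_mm` (truth), `peak_x_mm`, `peak_z_mm`,
#'   `axial_fwhm_mm`, `lateral_fwhm_mm`, `detected`.
#' @export
resolution_set <- function(bmode, truth, window = 5e-3) {
  stopifnot(inherits(bmode, "bmode_image"))
  lin <- linear_intensity(bmode)
  g <- bmode$grid
  step <- min(g$dz, g$dx)
  s <- seq(-window, window, by = step)
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    x0 <- truth$x[i]
    z0 <- truth$z[i]
    jx <- which(abs(g$x - x0) <= window)
    jz <- which(abs(g$z - z0) <= window)
    out <- tibble::tibble(
      x_mm = x0 * 1e3, z_mm = z0 * 1e3, peak_x_mm = NA_real_,
      peak_z_mm = NA_real_, axial_fwhm_mm = NA_real_,
      lateral_fwhm_mm = NA_real_, detected = FALSE
    )
    if (length(jx) < 3 || length(jz) < 3) return(out)
    sub <- lin[jz, jx, drop = FALSE]
    pk <- arrayInd(which.max(sub), dim(sub))
    pz <- g$z[jz[pk[1]]]
    px <- g$x[jx[pk[2]]]
    if (abs(pz - z0) > 2e-3 || abs(px - x0) > 2e-3) return(out)
    # beam (range) direction through the peak, from the aperture centre
    phi <- atan2(px, pz)
    prof_ax <- interp_image(lin, g$z, g$x, pz + s * cos(phi),
                            px + s * sin(phi))
    prof_la <- interp_image(lin, g$z, g$x, pz - s * sin(phi),
                            px + s * cos(phi))
    ax <- try(fwhm(prof_ax, step), silent = TRUE)
    la <- try(fwhm(prof_la, step), silent = TRUE)
    out$peak_x_mm <- px * 1e3
    out$peak_z_mm <- pz * 1e3
    out$axial_fwhm_mm <- if (inherits(ax, "try-error")) NA_real_ else ax * 1e3
    out$lateral_fwhm_mm <- if (inherits(la, "try-error")) NA_real_ else la * 1e3
    out$detected <- TRUE
    out
  })
}

#' Elevational resolution by scatterer offset sweep
#'
#' The elevational point spread is probed by sweeping a single point
#' scatterer across elevational offsets y at fixed depth, imaging each,
#' and recording the image peak amplitude versus offset; the FWHM of that
#' amplitude profile is the elevational resolution. (A bench equivalent
#' rotates the probe against a wire; the sweep probes the same elevational
#' beam profile without hardware.)
#'
#' @param array An `array_geometry`.
#' @param sequence A `transmit_sequence` (a single 0-degree wide-beam or
#'   plane event is typical; the elevational profile is transmit-strategy
#'   insensitive).
#' @param depth Scatterer depth in metres.
#' @param y_max Maximum |y| offset of the sweep in metres.
#' @param n_offsets Number of sweep points (odd keeps y = 0 sampled).
#' @param fs Sampling rate, Hz.
#' @return List: `profile` tibble (`y_mm`, `peak_amplitude`) and
#'   `fwhm_mm`.
#' @export
elevational_resolution <- function(array, sequence, depth = 50e-3,
                                   y_max = 8e-3, n_offsets = 17L,
                                   fs = 20e6) {
  ys <- seq(-y_max, y_max, length.out = n_offsets)
  grid <- pixel_grid(6e-3, 4e-3, 61L, 21L, z_min = depth - 3e-3)
  amp <- vapply(ys, function(y0) {
    ph <- phantom(tibble::tibble(x = 0, y = y0, z = depth, amplitude = 1))
    ch <- simulate_channel_data(ph, array, sequence, fs = fs)
    fr <- beamform_compound(ch, grid)
    max(Mod(fr$values))
  }, numeric(1))
  list(
    profile = tibble::tibble(y_mm = ys * 1e3, peak_amplitude = amp),
    fwhm_mm = fwhm(amp, diff(ys[1:2])) * 1e3
  )
}

#' Distance-measurement accuracy
#'
#' `accuracy = 1 - |computed / truth - 1|`.
#'
#' @param computed Measured distance (same units as `truth`).
#' @param truth Ground-truth distance (> 0).
#' @return Fraction (1 = perfect).
#' @export
location_accuracy <- function(computed, truth) {
  if (any(truth <= 0)) {
    rlang::abort("Ground-truth distances must be positive.",
                 class = "echopatch_metrics_error")
  }
  1 - abs(computed / truth - 1)
}

#' Dynamic range from grey value versus contrast
#'
#' Least-squares line `grey = m * contrast + b` through the supplied
#' (contrast, mean grey) points; the dynamic range is the contrast span
#' between the extrapolated grey values 255 and 0, which equals `255 / m`.
#'
#' @param contrasts_db Inclusion contrasts in dB (>= 2 points).
#' @param mean_grey Mean 8-bit grey values in `[0, 255]`.
#' @return List: `dynamic_range_db`, `contrast_at_255`, `contrast_at_0`,
#'   `slope`, `intercept`.
#' @examples
#' dynamic_range(c(-15, 15), c(38.7, 159.8))$dynamic_range_db # 63.2
#' @export
dynamic_range <- function(contrasts_db, mean_grey) {
  if (length(contrasts_db) != length(mean_grey) || length(contrasts_db) < 2) {
    rlang::abort("Need >= 2 paired (contrast, grey) points.",
                 class = "echopatch_metrics_error")
  }
  fit <- stats::lm(mean_grey ~ contrasts_db)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || m <= 0) {
    rlang::abort("Grey values must increase with contrast (slope > 0).",
                 class = "echopatch_metrics_error")
  }
  list(
    dynamic_range_db = 255 / m,
    contrast_at_255 = (255 - b) / m,
    contrast_at_0 = (0 - b) / m,
    slope = m, intercept = b
  )
}

#' Contrast-to-noise ratio
#'
#' `CNR = |mu_in - mu_out| / sqrt(sigma_in^2 + sigma_out^2)` over two
#' disjoint regions of interest, computed on linear (pre-compression)
#' intensities.
#'
#' @param image Numeric matrix of linear intensities.
#' @param roi_in,roi_out Logical masks (same dimensions as `image`) or
#'   index vectors; must be non-empty and disjoint.
#' @return Non-negative scalar.
#' @export
cnr <- function(image, roi_in, roi_out) {
  ii <- if (is.logical(roi_in)) which(roi_in) else as.integer(roi_in)
  io <- if (is.logical(roi_out)) which(roi_out) else as.integer(roi_out)
  if (length(ii) == 0 || length(io) == 0) {
    rlang::abort("ROIs must be non-empty.", class = "echopatch_metrics_error")
  }
  if (length(intersect(ii, io)) > 0) {
    rlang::abort("ROIs must be disjoint.", class = "echopatch_metrics_error")
  }
  vi <- image[ii]
  vo <- image[io]
  s2 <- stats::var(vi) + stats::var(vo)
  if (!is.finite(s2) || s2 == 0) {
    rlang::abort("Joint ROI variance is zero.",
                 class = "echopatch_metrics_error")
  }
  abs(mean(vi) - mean(vo)) / sqrt(s2)
}

#' Signal-to-noise ratio versus depth
#'
#' For each target point, `SNR = 20 log10(peak linear amplitude within a
#' small window around the target / RMS of the noise region)`.
#'
#' @param bmode A `bmode_image`.
#' @param signal_points Data frame with target columns `x`, `z` (metres).
#' @param noise_roi Logical mask over the image marking a target-free
#'   region.
#' @param window Half-width of the peak search window (m).
#' @return Tibble: `x_mm`, `z_mm`, `snr_db`.
#' @export
snr_depth <- function(bmode, signal_points, noise_roi, window = 3e-3) {
  lin <- linear_intensity(bmode)
  if (!any(noise_roi)) {
    rlang::abort("Noise ROI is empty.", class = "echopatch_metrics_error")
  }
  noise <- rms(lin[noise_roi])
  g <- bmode$grid
  purrr::map_dfr(seq_len(nrow(signal_points)), function(i) {
    jx <- which(abs(g$x - signal_points$x[i]) <= window)
    jz <- which(abs(g$z - signal_points$z[i]) <= window)
    tibble::tibble(
      x_mm = signal_points$x[i] * 1e3, z_mm = signal_points$z[i] * 1e3,
      snr_db = 20 * log10(max(lin[jz, jx]) / noise)
    )
  })
}

#' Penetration depth by the 6-dB rule
#'
#' The deepest wire whose image peak exceeds the local background mean by
#' at least `margin_db` (both in dB). The background is sampled at the
#' wire's depth, laterally offset from the target.
#'
#' @param bmode A `bmode_image`.
#' @param wires Data frame of wire truth positions `x`, `z` (metres),
#'   any order.
#' @param margin_db Differentiability margin in dB (default 6).
#' @param window Half-width of the peak window (m).
#' @return List: `penetration_m` (0 if no wire qualifies, with
#'   `detected = FALSE`), `per_wire` tibble.
#' @export
penetration_depth <- function(bmode, wires, margin_db = 6, window = 3e-3) {
  g <- bmode$grid
  wires <- wires[order(wires$z), , drop = FALSE]
  per <- purrr::map_dfr(seq_len(nrow(wires)), function(i) {
    jx <- which(abs(g$x - wires$x[i]) <= window)
    jz <- which(abs(g$z - wires$z[i]) <= window)
    pk <- max(bmode$intensity_db[jz, jx])
    bg_jx <- which(abs(g$x - wires$x[i]) > 2 * window)
    bg <- mean(bmode$intensity_db[jz, bg_jx])
    tibble::tibble(z_m = wires$z[i], peak_db = pk, background_db = bg,
                   differentiable = pk - bg >= margin_db)
  })
  ok <- per$differentiable
  list(
    penetration_m = if (any(ok)) max(per$z_m[ok]) else 0,
    detected = any(ok),
    per_wire = per
  )
}

#' Fractional bandwidth of an echo waveform
#'
#' Ratio between the full width at half maximum of the magnitude spectrum
#' and the centre frequency, the centre being the midpoint of the two
#' half-maximum crossings.
#'
#' @param x Real echo waveform (or its magnitude spectrum, see
#'   `is_spectrum`).
#' @param fs Sampling rate in Hz.
#' @param is_spectrum If TRUE, `x` is already a one-sided magnitude
#'   spectrum sampled at `fs / length(x)` resolution.
#' @return Fractional bandwidth (dimensionless).
#' @export
fractional_bandwidth <- function(x, fs, is_spectrum = FALSE) {
  if (is_spectrum) {
    mag <- x
    df <- fs / (2 * (length(x) - 1))
  } else {
    n <- length(x)
    sp <- Mod(stats::fft(x))[1:(floor(n / 2) + 1)]
    mag <- sp
    df <- fs / n
  }
  pk <- max(mag)
  i <- which.max(mag)
  half <- pk / 2
  li <- i
  while (li > 1 && mag[li - 1] >= half) li <- li - 1
  ri <- i
  while (ri < length(mag) && mag[ri + 1] >= half) ri <- ri + 1
  if ((li == 1 && mag[1] >= half) ||
      (ri == length(mag) && mag[length(mag)] >= half)) {
    rlang::abort("Spectrum has no half-maximum crossings.",
                 class = "echopatch_metrics_error")
  }
  f_lo <- (li - 1 - (mag[li] - half) / (mag[li] - mag[li - 1])) * df
  f_hi <- (ri - 1 + (mag[ri] - half) / (mag[ri] - mag[ri + 1])) * df
  (f_hi - f_lo) / ((f_hi + f_lo) / 2)
}

#' Insertion loss of a pulse-echo measurement
#'
#' `|20 log10(Vr / Vt) + 1.9 + 2.2e-4 * 2d * fr^2|` in dB, where 1.9 dB
#' accounts for the transmission loss into the quartz reflector and
#' 2.2e-4 dB/(mm MHz^2) for water attenuation over the two-way path.
#'
#' @param vr Received voltage (> 0).
#' @param vt Transmitted voltage (> 0).
#' @param d_mm One-way water path in millimetres.
#' @param fr_mhz Frequency in MHz.
#' @return Insertion loss in dB.
#' @export
insertion_loss <- function(vr, vt, d_mm, fr_mhz) {
  if (any(vr <= 0) || any(vt <= 0)) {
    rlang::abort("Voltages must be positive.",
                 class = "echopatch_metrics_error")
  }
  abs(20 * log10(vr / vt) + 1.9 + 2.2e-4 * 2 * d_mm * fr_mhz^2)
}

#' Relative resistance
#'
#' `R / R0`, the standard strain-characterization ratio for stretchable
#' conductors.
#'
#' @param r Resistance at strain (ohm).
#' @param r0 Resistance at 0% strain (ohm, > 0).
#' @return Dimensionless ratio.
#' @export
relative_resistance <- function(r, r0) {
  if (any(r0 <= 0)) {
    rlang::abort("`r0` must be positive.", class = "echopatch_metrics_error")
  }
  r / r0
}
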