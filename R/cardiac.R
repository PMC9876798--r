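# Local maxima with a minimum prominence (fraction of signal range).
# Plateaus (runs of tied samples, common in rasterized waveforms) count
# as a single peak at the centre of the run. Prominence of a peak:
# height above the higher of the two deepest valleys separating it from
# larger neighbours.
find_peaks <- function(x, min_prominence_frac = 0.1) {
  r <- rle(x)
  v <- r$values
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(v))) < 0) + 1
  if (length(cand) == 0) return(integer(0))
  rng <- diff(range(v))
  if (rng == 0) return(integer(0))
  keep <- vapply(cand, function(i) {
    # nearest strictly higher run on each side (or the series end)
    li <- which(v[seq_len(i - 1)] > v[i])
    l0 <- if (length(li)) max(li) else 1
    ri <- which(v[(i + 1):n] > v[i])
    r0 <- if (length(ri)) i + min(ri) else n
    vl <- min(v[l0:i])
    vr <- min(v[i:r0])
    (v[i] - max(vl, vr)) / rng >= min_prominence_frac
  }, logical(1))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  as.integer(floor((starts[cand[keep]] + ends[cand[keep]]) / 2))
}

#' Track tissue interfaces through an M-mode image
#'
#' Ridge tracker for the two cavity-bounding interfaces (near = septal
#' side, far = posterior-wall side). In each frame, each interface is the
#' intensity-weighted centroid of the pixels within `search_window` of
#' the previous frame's position that lie within 6 dB of the local ridge
#' maximum; frames whose windows contain no pixel 6 dB above the display
#' floor lose the track and are interpolated and flagged.
#'
#' @param mmode An `mmode_image`.
#' @param init_near,init_far Initial interface depths in metres (must lie
#'   inside the image, `init_near < init_far`).
#' @param search_window Half-width of the per-frame search window (m).
#' @return Object of class `interface_tracks`: tibble `frame`, `time_s`,
#'   `near_m`, `far_m`, `tracked`.
#' @export
track_interfaces <- function(mmode, init_near, init_far,
                             search_window = 8e-3) {
  stopifnot(inherits(mmode, "mmode_image"))
  z <- mmode$z
  if (init_near < min(z) || init_far > max(z) || init_near >= init_far) {
    rlang::abort("Initial depths must bracket the cavity inside the image.",
                 class = "echopatch_cardiac_error")
  }
  n_fr <- ncol(mmode$intensity_db)
  track_one <- function(init) {
    pos <- numeric(n_fr)
    ok <- logical(n_fr)
    prev <- init
    for (k in seq_len(n_fr)) {
      jj <- which(abs(z - prev) <= search_window)
      col <- mmode$intensity_db[jj, k]
      if (length(jj) == 0 || max(col) < mmode$floor_db + 6) {
        pos[k] <- NA_real_
        ok[k] <- FALSE
        next
      }
      ridge <- col >= max(col) - 6
      w <- 10^(col[ridge] / 20)
      cand <- sum(z[jj][ridge] * w) / sum(w)
      # continuity: clamp the per-frame jump to the window
      cand <- prev + max(min(cand - prev, search_window), -search_window)
      pos[k] <- cand
      ok[k] <- TRUE
      prev <- cand
    }
    if (any(!ok)) {
      pos <- stats::approx(which(ok), pos[ok], xout = seq_len(n_fr),
                           rule = 2)$y
    }
    list(pos = pos, ok = ok)
  }
  near <- track_one(init_near)
  far <- track_one(init_far)
  structure(
    tibble::tibble(
      frame = seq_len(n_fr), time_s = mmode$times,
      near_m = near$pos, far_m = far$pos,
      tracked = near$ok & far$ok
    ),
    class = c("interface_tracks", class(tibble::tibble()))
  )
}

#' Per-cycle LV internal diameters from interface tracks
#'
#' `LVID(t) = far - near`; cycles are delimited by the end-diastolic
#' (maximum-diameter) peaks of the LVID waveform, and per cycle
#' LVIDd = max, LVIDs = min.
#'
#' @param tracks An `interface_tracks` (or tibble with `time_s`,
#'   `near_m`, `far_m`).
#' @param min_prominence_frac Peak-prominence threshold as a fraction of
#'   the waveform range.
#' @return Tibble: `cycle`, `t_start_s`, `t_end_s`, `lvidd_m`, `lvids_m`,
#'   `fractional_shortening`.
#' @export
lvid_waveforms <- function(tracks, min_prominence_frac = 0.1) {
  lvid <- tracks$far_m - tracks$near_m
  if (any(lvid <= 0)) {
    rlang::abort("Far interface must stay below the near interface.",
                 class = "echopatch_cardiac_error")
  }
  pks <- find_peaks(lvid, min_prominence_frac)
  if (length(pks) < 2) {
    rlang::abort("No complete cardiac cycle detected in the LVID waveform.",
                 class = "echopatch_cardiac_error")
  }
  purrr::map_dfr(seq_len(length(pks) - 1), function(i) {
    span <- pks[i]:pks[i + 1]
    dd <- max(lvid[span])
    ds <- min(lvid[span])
    tibble::tibble(
      cycle = i,
      t_start_s = tracks$time_s[pks[i]],
      t_end_s = tracks$time_s[pks[i + 1]],
      lvidd_m = dd, lvids_m = ds,
      fractional_shortening = fractional_shortening(dd, ds)
    )
  })
}

#' Fractional shortening
#'
#' `(LVIDd - LVIDs) / LVIDd`, the M-mode contractility index.
#'
#' @param lvidd End-diastolic internal diameter (> 0).
#' @param lvids End-systolic internal diameter (<= lvidd).
#' @return Fraction in `[0, 1)`.
#' @export
fractional_shortening <- function(lvidd, lvids) {
  if (any(lvidd <= 0) || any(lvids > lvidd)) {
    rlang::abort("Require 0 < lvids <= lvidd.",
                 class = "echopatch_cardiac_error")
  }
  (lvidd - lvids) / lvidd
}

#' LV volume from a segmentation mask (Simpson's method of disks)
#'
#' The cavity's long axis is the principal axis of the mask pixels; the
#' cavity is sliced into `n_disks` equal-thickness slabs perpendicular to
#' that axis, and the volume is the sum of circular disks
#' `V = sum (pi/4) d_i^2 (L / n_disks)` with `d_i` the slice diameter
#' (estimated from the slice's pixel area, which is less sensitive to
#' raster noise than its min-max extent) and `L` the long-axis length.
#' An `area_length` alternative
#' (`V = 8 A^2 / (3 pi L)`) is available.
#'
#' @param mask Binary matrix (single cavity region; if several connected
#'   regions are present the analysis proceeds on all foreground pixels
#'   and the result is flagged).
#' @param pixel_mm Pixel size in millimetres.
#' @param n_disks Number of Simpson disks (default 20).
#' @param method `"simpson"` (default) or `"area_length"`.
#' @return Volume in ml (0 for an empty mask, with attribute
#'   `empty = TRUE`).
#' @export
volume_from_mask <- function(mask, pixel_mm, n_disks = 20L,
                             method = c("simpson", "area_length")) {
  method <- match.arg(method)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(structure(0, empty = TRUE))
  }
  pts <- idx * pixel_mm
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  ev <- eigen(stats::cov(pc), symmetric = TRUE)
  long_axis <- ev$vectors[, 1]
  u <- pc %*% long_axis         # along long axis
  len <- max(u) - min(u) + pixel_mm # pixel extent, not centre-to-centre
  if (method == "area_length") {
    area <- nrow(idx) * pixel_mm^2
    return(8 * area^2 / (3 * pi * len) / 1e3)
  }
  edges <- seq(min(u) - pixel_mm / 2, min(u) - pixel_mm / 2 + len,
               length.out = n_disks + 1)
  slab <- pmin(findInterval(u, edges, rightmost.closed = TRUE), n_disks)
  thick <- len / n_disks
  # disk diameter estimated from the slab's pixel area (mean width);
  # less raster bias than the min-max extent
  widths <- vapply(seq_len(n_disks), function(i) {
    sum(slab == i) * pixel_mm^2 / thick
  }, numeric(1))
  sum(pi / 4 * widths^2 * thick) / 1e3 # mm^3 -> ml
}

#' LV volume waveform from a mask stack
#'
#' @param masks Binary array (frame x row x col), e.g. from
#'   [beating_lv()] or a segmentation model.
#' @param pixel_mm Pixel size in millimetres.
#' @param frame_dt Frame interval in seconds.
#' @param n_disks Simpson disk count.
#' @return Object of class `volume_waveform`: tibble `time_s`,
#'   `volume_ml`.
#' @export
volume_waveform <- function(masks, pixel_mm, frame_dt, n_disks = 20L) {
  n_fr <- dim(masks)[1]
  vol <- vapply(seq_len(n_fr), function(k) {
    as.numeric(volume_from_mask(masks[k, , ], pixel_mm, n_disks))
  }, numeric(1))
  structure(
    tibble::tibble(time_s = (seq_len(n_fr) - 1) * frame_dt,
                   volume_ml = vol),
    class = c("volume_waveform", class(tibble::tibble()))
  )
}

#' Per-cycle cardiac indices from an LV volume waveform
#'
#' Cycles are delimited by consecutive end-diastolic peaks (local maxima
#' with prominence of at least 10% of the waveform range). Per cycle:
#' EDV = max, ESV = min, SV = EDV - ESV, EF = 100 SV / EDV,
#' HR = 60 / period, CO = SV x HR / 1000 (l/min).
#'
#' @param vol A `volume_waveform` or tibble with `time_s`, `volume_ml`.
#' @param min_prominence_frac Peak-prominence threshold.
#' @return Object of class `cardiac_indices`: tibble `cycle`,
#'   `t_start_s`, `t_end_s`, `edv_ml`, `esv_ml`, `sv_ml`, `ef_pct`,
#'   `hr_bpm`, `co_lpm`.
#' @export
indices_from_waveform <- function(vol, min_prominence_frac = 0.1) {
  v <- vol$volume_ml
  t <- vol$time_s
  pks <- find_peaks(v, min_prominence_frac)
  if (length(pks) < 2) {
    rlang::abort("No complete cardiac cycle in the volume waveform.",
                 class = "echopatch_cardiac_error")
  }
  out <- purrr::map_dfr(seq_len(length(pks) - 1), function(i) {
    span <- pks[i]:pks[i + 1]
    edv <- max(v[span])
    esv <- min(v[span])
    sv <- edv - esv
    period <- t[pks[i + 1]] - t[pks[i]]
    hr <- 60 / period
    tibble::tibble(
      cycle = i, t_start_s = t[pks[i]], t_end_s = t[pks[i + 1]],
      edv_ml = edv, esv_ml = esv, sv_ml = sv,
      ef_pct = 100 * sv / edv, hr_bpm = hr, co_lpm = sv * hr / 1000
    )
  })
  structure(out, class = c("cardiac_indices", class(tibble::tibble())))
}

#' Heart rate from a periodic waveform
#'
#' `60 / mean inter-peak interval`, plus the per-beat instantaneous
#' series.
#'
#' @param signal Periodic waveform values.
#' @param dt Sample interval in seconds.
#' @param min_prominence_frac Peak-prominence threshold.
#' @return List: `mean_bpm`, `beats` tibble (`time_s`,
#'   `instantaneous_bpm`).
#' @export
heart_rate <- function(signal, dt, min_prominence_frac = 0.1) {
  pks <- find_peaks(signal, min_prominence_frac)
  if (length(pks) < 2) {
    rlang::abort("Need at least two peaks to estimate a rate.",
                 class = "echopatch_cardiac_error")
  }
  iv <- diff(pks) * dt
  list(
    mean_bpm = 60 / mean(iv),
    beats = tibble::tibble(time_s = (pks[-1] - 1) * dt,
                           instantaneous_bpm = 60 / iv)
  )
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` against means `(a + b) / 2`; the limits of
#' agreement are `mean(d) +/- 1.96 sd(d)` (sample sd), and the fraction
#' of points inside the limits is reported.
#'
#' @param a,b Paired measurements (equal length >= 2).
#' @return Object of class `bland_altman`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    rlang::abort("`a` and `b` must be paired vectors of length >= 2.",
                 class = "echopatch_cardiac_error")
  }
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  structure(
    list(
      pairs = tibble::tibble(average = (a + b) / 2, difference = d),
      mean_difference = m, sd_difference = s,
      loa_lower = lo, loa_upper = hi,
      within_limits_fraction = mean(d >= lo & d <= hi)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean diff %.3g, limits [%.3g, %.3g], %.1f%% within\n",
    x$mean_difference, x$loa_lower, x$loa_upper,
    100 * x$within_limits_fraction
  ))
  invisible(x)
}
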