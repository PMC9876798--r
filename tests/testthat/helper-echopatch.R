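# Shared fixtures, built in code.

default_array <- function() linear_array()

# Wrap a dB matrix as a bmode_image on the given grid.
bmode_from_db <- function(db, grid, floor_db = -60) {
  structure(list(intensity_db = db, grid = grid, floor_db = floor_db),
            class = "bmode_image")
}

# Synthetic M-mode with Gaussian ridges at per-frame depths (metres).
mmode_from_ridges <- function(z, times, ridge_depths, ridge_sigma = 1e-3,
                              floor_db = -60) {
  n_fr <- length(times)
  img <- matrix(floor_db, nrow = length(z), ncol = n_fr)
  for (k in seq_len(n_fr)) {
    for (zr in ridge_depths[[k]]) {
      amp <- exp(-0.5 * ((z - zr) / ridge_sigma)^2)
      img[, k] <- pmax(img[, k], floor_db + (0 - floor_db) * amp)
    }
  }
  structure(
    list(intensity_db = img, z = z, times = times, x = 0,
         frame_dt = if (n_fr > 1) times[2] - times[1] else NA_real_,
         floor_db = floor_db),
    class = "mmode_image"
  )
}

# Filled-ellipse binary mask (semi-axes in mm, long axis along rows).
ellipse_mask <- function(a_mm, b_mm, pixel_mm, pad_mm = 2) {
  nr <- ceiling(2 * (a_mm + pad_mm) / pixel_mm)
  nc <- ceiling(2 * (b_mm + pad_mm) / pixel_mm)
  rr <- (seq_len(nr) - (nr + 1) / 2) * pixel_mm
  cc <- (seq_len(nc) - (nc + 1) / 2) * pixel_mm
  (outer(rr^2 / a_mm^2, cc^2 / b_mm^2, `+`) <= 1) * 1L
}

# Localized window grid around a wire for PSF measurements.
wire_window <- function(z0, x0 = 0, depth = 8e-3, width = 10e-3,
                        n_axial = 161L, n_lateral = 101L) {
  pixel_grid(depth, width, n_axial, n_lateral, z_min = z0 - depth / 2,
             x_centre = x0)
}
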