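test_that("pixel spacing follows the inclusive-extent convention", {
  expect_equal(unname(pixel_spacing(140e-3, 160e-3, 1001, 801)),
               c(0.14e-3, 0.2e-3))
  # round-trip identity
  sp <- pixel_spacing(60e-3, 30e-3, 241, 121)
  expect_equal(sp[["dy"]] * 240, 60e-3)
  expect_equal(sp[["dx"]] * 120, 30e-3)
  expect_error(pixel_spacing(60e-3, 30e-3, 1, 121),
               class = "echopatch_imaging_error")
})

test_that("delay-and-sum localizes a point target to one grid cell", {
  a <- default_array()
  ph <- wire_phantom(tibble::tibble(x = 0, z = 50e-3))
  ch <- simulate_channel_data(ph, a, plane_sequence(a))
  g <- wire_window(50e-3)
  fr <- das_beamform(ch, g, 1)
  pk <- arrayInd(which.max(Mod(fr$values)), dim(fr$values))
  expect_lte(abs(g$z[pk[1]] - 50e-3), g$dz)
  expect_lte(abs(g$x[pk[2]]), g$dx)
  # all-zero channel data -> all-zero frame
  ch0 <- ch
  ch0$samples[] <- 0
  expect_true(all(Mod(das_beamform(ch0, g, 1)$values) == 0))
  expect_error(das_beamform(ch, g, 5), class = "echopatch_imaging_error")
})

test_that("coherent compounding is a weighted complex sum", {
  a <- default_array()
  ph <- wire_phantom(tibble::tibble(x = 0, z = 30e-3))
  ch <- simulate_channel_data(ph, a, plane_sequence(a, c(-5, 0, 5)))
  g <- wire_window(30e-3)
  f1 <- das_beamform(ch, g, 1)
  expect_equal(compound(list(f1, f1, f1))$values, 3 * f1$values)
  neg <- f1
  neg$values <- -f1$values
  expect_true(all(Mod(compound(list(f1, neg))$values) == 0))
  g2 <- wire_window(30e-3, n_axial = 81L)
  f2 <- das_beamform(ch, g2, 1)
  expect_error(compound(list(f1, f2)), class = "echopatch_imaging_error")
  # one-call compounding agrees with the per-event route
  fr_all <- beamform_compound(ch, g)
  fr_sum <- compound(lapply(1:3, function(k) das_beamform(ch, g, k)))
  expect_equal(fr_all$values, fr_sum$values, tolerance = 1e-12)
})

test_that("log compression maps intensity ratios to dB and clips", {
  vals <- matrix(complex(real = c(1, 0.1, 0, 0.5)), 2, 2)
  fr <- structure(list(values = vals,
                       grid = pixel_grid(1e-3, 1e-3, 2, 2, z_min = 1e-3)),
                  class = "beamformed_frame")
  bm <- envelope_logcompress(fr)
  expect_equal(bm$intensity_db[1, 1], 0)
  expect_equal(bm$intensity_db[2, 1], -20)
  expect_equal(bm$intensity_db[1, 2], -60)
  expect_equal(max(bm$intensity_db), 0)
  expect_true(all(bm$intensity_db >= bm$floor_db))
  fr$values[] <- 0
  expect_error(envelope_logcompress(fr), class = "echopatch_imaging_error")
})

test_that("log compression preserves the ordering of magnitudes", {
  set.seed(5)
  vals <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  fr <- structure(list(values = vals,
                       grid = pixel_grid(1e-3, 1e-3, 8, 8, z_min = 1e-3)),
                  class = "beamformed_frame")
  bm <- envelope_logcompress(fr, floor_db = -200)
  expect_equal(order(Mod(vals)), order(bm$intensity_db))
})

test_that("scan conversion preserves columns and constants", {
  r <- seq(10e-3, 50e-3, length.out = 41)
  single <- scan_convert(matrix(seq_along(r), ncol = 1), 0, r,
                         upsample = 1)
  expect_equal(ncol(single$values), 1)
  expect_lt(max(abs(single$values[, 1] - seq_along(r))), 1e-9)
  # uniform sector stays uniform inside the mask
  th <- seq(-30, 30, length.out = 21)
  u <- scan_convert(matrix(7, nrow = 41, ncol = 21), th, r, upsample = 2,
                    floor = 0)
  expect_lt(max(abs(u$values[u$mask] - 7)), 1e-6)
  expect_true(all(u$values[!u$mask] == 0))
  # default upsampling factor is 5
  expect_identical(formals(scan_convert)$upsample, 5L)
  expect_error(scan_convert(matrix(1, 41, 3), c(0, 2, 1), r),
               class = "echopatch_imaging_error")
})

test_that("M-mode stacks the chosen scanline over frames", {
  g <- pixel_grid(40e-3, 10e-3, 81, 21, z_min = 20e-3)
  mk <- function(zc) {
    db <- matrix(-60, 81, 21)
    db[, 11] <- pmax(-60, -60 + 60 * exp(-0.5 * ((g$z - zc) / 1e-3)^2))
    bmode_from_db(db, g)
  }
  static <- extract_mmode(list(mk(30e-3), mk(30e-3), mk(30e-3)), x = 0,
                          frame_dt = 0.02)
  expect_true(all(static$intensity_db[, 1] == static$intensity_db[, 2]))
  # oscillating target: ridge period equals the motion period
  f_frame <- 25
  t <- (0:49) / f_frame
  frames <- lapply(t, function(tt) mk(35e-3 + 5e-3 * sin(2 * pi * tt / 1)))
  mm <- extract_mmode(frames, x = 0, frame_dt = 1 / f_frame)
  ridge <- mm$z[apply(mm$intensity_db, 2, which.max)]
  expect_lt(max(abs(ridge - (35e-3 + 5e-3 * sin(2 * pi * t / 1)))),
            0.5e-3)
  # period from upward mean-crossings (robust to depth quantization)
  up <- which(diff(ridge > 35e-3) == 1)
  expect_lt(abs(mean(diff(up)) / f_frame - 1), 1 / f_frame)
  expect_error(extract_mmode(frames[1], x = 0),
               class = "echopatch_imaging_error")
  expect_error(extract_mmode(frames, x = 1), class = "echopatch_imaging_error")
})
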