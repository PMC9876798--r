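test_that("fwhm recovers analytic widths with sub-sample interpolation", {
  x <- seq(-6, 6, by = 0.01)
  gauss <- exp(-0.5 * x^2) # sigma = 1 mm on a 0.01 mm grid
  expect_equal(fwhm(gauss, 0.01), 2 * sqrt(2 * log(2)), tolerance = 0.005)
  rect <- as.numeric(abs(x) <= 1.5) # width 3
  expect_equal(fwhm(rect, 0.01), 3, tolerance = 0.011)
  bimodal <- c(0, 1, 0.2, 1, 0)
  expect_error(fwhm(bimodal, 1), class = "echopatch_metrics_error")
  expect_error(fwhm(c(1, 0.5, 0.1), 1), class = "echopatch_metrics_error")
  expect_error(fwhm(rep(0.9, 50), 1), class = "echopatch_metrics_error")
})

test_that("location accuracy is symmetric and scale invariant", {
  expect_equal(location_accuracy(9.6, 10), 0.96)
  expect_equal(location_accuracy(10, 10), 1)
  expect_equal(location_accuracy(10.4, 10), 0.96)
  for (k in c(0.1, 3, 1e3)) {
    expect_equal(location_accuracy(9.6 * k, 10 * k),
                 location_accuracy(9.6, 10))
  }
  expect_error(location_accuracy(1, 0), class = "echopatch_metrics_error")
})

test_that("dynamic range extrapolates the grey-contrast line to 0 and 255", {
  dr <- dynamic_range(c(-15, 15), c(38.7, 159.8))
  expect_equal(round(dr$dynamic_range_db, 1), 63.2)
  expect_equal(round(dr$contrast_at_255, 1), 38.6)
  expect_equal(round(dr$contrast_at_0, 1), -24.6)
  # exact two-point anchor case
  expect_equal(dynamic_range(c(-10, 40), c(0, 255))$dynamic_range_db, 50)
  # collinear points are fit-invariant
  three <- dynamic_range(c(-15, 0, 15), c(10, 90, 170))
  two <- dynamic_range(c(-15, 15), c(10, 170))
  expect_equal(three$dynamic_range_db, two$dynamic_range_db)
  # closed form 255 / slope versus a brute-force fit on random lines
  set.seed(31)
  for (i in 1:20) {
    m <- runif(1, 0.5, 8)
    b <- runif(1, 0, 80)
    cx <- sort(runif(5, -20, 20))
    gy <- m * cx + b
    expect_equal(dynamic_range(cx, gy)$dynamic_range_db, 255 / m,
                 tolerance = 1e-9)
  }
  expect_error(dynamic_range(c(-15, 15), c(100, 50)),
               class = "echopatch_metrics_error")
  expect_error(dynamic_range(5, 100), class = "echopatch_metrics_error")
})

test_that("cnr matches its defining ratio and detects ROI misuse", {
  img <- matrix(c(9, 11, 10, 5, 7, 6), nrow = 1)
  expect_equal(cnr(img, 1:2, 4:5), 4 / 2)
  sym <- matrix(c(1, 2, 3, 3, 2, 1), nrow = 1)
  expect_equal(cnr(sym, 1:3, 4:6), 0)
  expect_error(cnr(img, 1:2, 2:3), class = "echopatch_metrics_error")
  expect_error(cnr(img, integer(0), 4:5), class = "echopatch_metrics_error")
  expect_error(cnr(matrix(c(1, 1, 1, 1), 1), 1:2, 3:4),
               class = "echopatch_metrics_error")
})

test_that("snr is peak-over-noise in dB and scale invariant", {
  g <- pixel_grid(40e-3, 20e-3, 81, 41, z_min = 30e-3)
  db <- matrix(-20, 81, 41) # noise bed: linear 0.1
  db[41, 21] <- 0 # target peak: linear 1
  bm <- bmode_from_db(db, g)
  roi <- matrix(FALSE, 81, 41)
  roi[1:20, ] <- TRUE
  s <- snr_depth(bm, tibble::tibble(x = 0, z = 50e-3), roi)
  expect_equal(s$snr_db, 20)
  # common rescaling (dB offset) cancels
  bm2 <- bmode_from_db(db - 12, g, floor_db = -80)
  expect_equal(snr_depth(bm2, tibble::tibble(x = 0, z = 50e-3), roi)$snr_db,
               20)
  expect_error(snr_depth(bm, tibble::tibble(x = 0, z = 50e-3),
                         matrix(FALSE, 81, 41)),
               class = "echopatch_metrics_error")
})

test_that("penetration depth applies the 6-dB differentiability rule", {
  g <- pixel_grid(140e-3, 20e-3, 281, 41, z_min = 0)
  db <- matrix(-40, 281, 41)
  wires <- tibble::tibble(x = 0, z = seq(20e-3, 140e-3, 20e-3))
  for (z0 in wires$z) {
    i <- which.min(abs(g$z - z0))
    db[i, 21] <- if (z0 < 130e-3) -10 else -39 # deepest buried
  }
  bm <- bmode_from_db(db, g)
  out <- penetration_depth(bm, wires)
  expect_equal(out$penetration_m, 120e-3)
  expect_true(out$detected)
  # degenerate margin returns the deepest wire outright
  expect_equal(penetration_depth(bm, wires, margin_db = 0)$penetration_m,
               140e-3)
  # all wires visible -> deepest wire depth
  db2 <- db
  db2[which.min(abs(g$z - 140e-3)), 21] <- -10
  expect_equal(penetration_depth(bmode_from_db(db2, g), wires)$penetration_m,
               140e-3)
})

test_that("fractional bandwidth reads the -6 dB spectral width", {
  # spectrum route: symmetric triangle, FWHM = fc -> 1.0
  n <- 201
  mag <- pmax(0, 1 - abs(seq_len(n) - 101) / 50) # peak at bin 101
  fs <- 2 * (n - 1) # df = 1 per bin
  # half-max crossings at f = 75 and 125 -> width 50, centre 100
  bw <- fractional_bandwidth(mag, fs, is_spectrum = TRUE)
  expect_equal(bw, 50 / 100, tolerance = 1e-6)
  # pure tone: near-zero fractional width
  t <- seq(0, 1e-4, by = 1e-8)
  tone <- sin(2 * pi * 3e6 * t)
  expect_lt(fractional_bandwidth(tone, 1e8), 0.02)
  expect_error(fractional_bandwidth(c(1, 0.9, 0.8), 10, is_spectrum = TRUE),
               class = "echopatch_metrics_error")
})

test_that("insertion loss follows the quartz/water correction formula", {
  expect_equal(insertion_loss(1, 1, 0, 3), 1.9)
  expect_equal(insertion_loss(0.1, 1, 0, 3), 18.1)
  expect_equal(insertion_loss(0.1, 1, 40, 3),
               abs(-20 + 1.9 + 2.2e-4 * 80 * 9))
  expect_equal(round(insertion_loss(0.1, 1, 40, 3), 2), 17.94)
  expect_error(insertion_loss(0, 1, 0, 3), class = "echopatch_metrics_error")
})

test_that("relative resistance reduces to the printed ratio", {
  expect_equal(round(relative_resistance(44.87, 1.74), 2), 25.79)
  expect_equal(relative_resistance(1.74, 1.74), 1)
  expect_equal(relative_resistance(3.48, 1.74), 2)
  expect_error(relative_resistance(1, 0), class = "echopatch_metrics_error")
})
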