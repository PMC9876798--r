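test_that("interface tracking follows static and moving ridges", {
  z <- seq(10e-3, 100e-3, by = 0.5e-3)
  times <- (0:59) / 30
  static <- mmode_from_ridges(z, times,
                              lapply(times, function(t) c(30e-3, 80e-3)))
  tr <- track_interfaces(static, init_near = 28e-3, init_far = 82e-3)
  expect_lt(max(abs(tr$near_m - 30e-3)), 0.5e-3)
  expect_lt(max(abs(tr$far_m - 80e-3)), 0.5e-3)
  expect_true(all(tr$tracked))

  # sinusoidal motion: amplitude recovered within 10%
  near_t <- 30e-3 + 3e-3 * sin(2 * pi * times / 1)
  far_t <- 80e-3 - 5e-3 * sin(2 * pi * times / 1)
  moving <- mmode_from_ridges(z, times,
                              Map(c, near_t, far_t))
  tr2 <- track_interfaces(moving, init_near = 30e-3, init_far = 80e-3)
  expect_equal(diff(range(tr2$near_m)) / 2, 3e-3, tolerance = 0.1 * 3e-3)
  expect_equal(diff(range(tr2$far_m)) / 2, 5e-3, tolerance = 0.1 * 5e-3)
  expect_error(track_interfaces(static, init_near = 1e-3, init_far = 200e-3),
               class = "echopatch_cardiac_error")
})

test_that("LVID waveforms yield per-cycle diameters and shortening", {
  times <- (0:119) / 30
  lvid <- (40 + 10 * sin(2 * pi * times / 1)) * 1e-3
  tracks <- tibble::tibble(time_s = times, near_m = 30e-3,
                           far_m = 30e-3 + lvid)
  cyc <- lvid_waveforms(tracks)
  expect_gte(nrow(cyc), 2)
  expect_lt(max(abs(cyc$lvidd_m - 50e-3)), 1e-4)
  expect_lt(max(abs(cyc$lvids_m - 30e-3)), 1e-4)
  expect_equal(cyc$fractional_shortening,
               (cyc$lvidd_m - cyc$lvids_m) / cyc$lvidd_m)
  # per-cycle amplitude drift is tracked cycle by cycle
  amp <- (10 - 1.5 * floor(times)) * 1e-3
  tracks2 <- tibble::tibble(time_s = times, near_m = 30e-3,
                            far_m = 70e-3 + amp * sin(2 * pi * times))
  cyc2 <- lvid_waveforms(tracks2)
  expect_true(all(diff(cyc2$lvidd_m - cyc2$lvids_m) < 0))
  flat <- tibble::tibble(time_s = times, near_m = 30e-3, far_m = 70e-3)
  expect_error(lvid_waveforms(flat), class = "echopatch_cardiac_error")
})

test_that("fractional shortening is the normalized diameter change", {
  expect_equal(fractional_shortening(50, 30), 0.4)
  expect_equal(fractional_shortening(42, 42), 0)
  expect_equal(fractional_shortening(48, 30), 0.375)
  expect_error(fractional_shortening(30, 48),
               class = "echopatch_cardiac_error")
  # stays within [0, 1) whenever preconditions hold
  set.seed(8)
  dd <- runif(50, 20, 70)
  ds <- runif(50, 0, 1) * dd
  fs <- fractional_shortening(dd, ds)
  expect_true(all(fs >= 0 & fs < 1))
})

test_that("Simpson disk volumes match the prolate-spheroid closed form", {
  mask <- ellipse_mask(40, 20, 0.2)
  v <- volume_from_mask(mask, 0.2, n_disks = 200)
  expect_equal(v, (4 / 3) * pi * 40 * 20^2 / 1e3, tolerance = 0.02)
  # scale consistency: finer raster, same physical object
  mask2 <- ellipse_mask(40, 20, 0.1)
  expect_equal(volume_from_mask(mask2, 0.1, n_disks = 200), v,
               tolerance = 0.01 * v)
  # orientation invariance: long axis found by PCA
  vt <- volume_from_mask(t(mask), 0.2, n_disks = 200)
  expect_equal(vt, v, tolerance = 1e-6 * v)
  expect_equal(as.numeric(volume_from_mask(matrix(0L, 10, 10), 0.2)), 0)
  # area-length alternative agrees for an ellipse
  va <- volume_from_mask(mask, 0.2, method = "area_length")
  expect_equal(va, (4 / 3) * pi * 40 * 400 / 1e3, tolerance = 0.05)
})

test_that("cardiac indices derive per-cycle EF, SV, CO and HR", {
  t <- (0:119) / 30
  vol <- tibble::tibble(time_s = t,
                        volume_ml = 85 + 35 * cos(2 * pi * t / 0.8))
  idx <- indices_from_waveform(vol)
  expect_gte(nrow(idx), 2)
  expect_equal(idx$edv_ml, rep(120, nrow(idx)), tolerance = 0.5)
  expect_equal(idx$esv_ml, rep(50, nrow(idx)), tolerance = 0.5)
  expect_equal(idx$sv_ml, idx$edv_ml - idx$esv_ml)
  expect_equal(idx$ef_pct, 100 * idx$sv_ml / idx$edv_ml)
  expect_equal(idx$ef_pct, rep(100 * 70 / 120, nrow(idx)), tolerance = 0.7)
  expect_equal(idx$hr_bpm, rep(75, nrow(idx)), tolerance = 1)
  expect_equal(idx$co_lpm, idx$sv_ml * idx$hr_bpm / 1000)
  # printed-scale check: SV 70 ml at HR 130 bpm is about 9 l/min
  expect_equal(round(70 * 130 / 1000, 1), 9.1)
  flat <- tibble::tibble(time_s = t, volume_ml = rep(100, length(t)))
  expect_error(indices_from_waveform(flat),
               class = "echopatch_cardiac_error")
})

test_that("heart rate is 60 over the mean inter-peak interval", {
  dt <- 1 / 100
  t <- seq(0, 6, by = dt)
  expect_equal(heart_rate(sin(2 * pi * t / 0.5), dt)$mean_bpm, 120,
               tolerance = 0.5)
  expect_equal(heart_rate(sin(2 * pi * t / 1.0), dt)$mean_bpm, 60,
               tolerance = 0.5)
  # generator recovery at a coarse frame rate
  lv <- beating_lv(heart_rate = 140, frame_rate = 30, n_cycles = 6)
  hr <- heart_rate(-lv$truth$volume_ml, lv$frame_dt)
  expect_equal(hr$mean_bpm, 140, tolerance = 2)
  expect_error(heart_rate(c(0, 1, 0), 0.1), class = "echopatch_cardiac_error")
})

test_that("Bland-Altman limits bracket ~95% of Gaussian differences", {
  x <- c(10, 12, 9, 14)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)
  ba3 <- bland_altman(x, x + 3)
  expect_equal(ba3$mean_difference, -3)
  expect_equal(ba3$loa_upper - ba3$loa_lower, 0)
  # seeded Monte-Carlo versus normal theory
  set.seed(123)
  b <- rnorm(500, 100, 10)
  a <- b + rnorm(500, 0, 1)
  ba <- bland_altman(a, b)
  expect_equal(ba$within_limits_fraction, 0.95, tolerance = 0.032)
  expect_equal(ba$loa_upper - ba$mean_difference,
               1.96 * ba$sd_difference)
  expect_error(bland_altman(1:3, 1:4), class = "echopatch_cardiac_error")
})

test_that("tidy, glance and autoplot methods cover the result types", {
  lv <- beating_lv(n_cycles = 3)
  vw <- volume_waveform(lv$masks, lv$pixel_mm, lv$frame_dt)
  idx <- indices_from_waveform(vw)
  expect_s3_class(tidy(idx), "tbl_df")
  gl <- glance(idx)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("ef_pct", "sv_ml", "hr_bpm", "co_lpm") %in% names(gl)))
  ba <- bland_altman(vw$volume_ml, lv$truth$volume_ml)
  expect_s3_class(tidy(ba), "tbl_df")
  expect_equal(glance(ba)$n, nrow(vw))
  expect_s3_class(autoplot(vw), "ggplot")
  expect_s3_class(autoplot(ba), "ggplot")
})
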