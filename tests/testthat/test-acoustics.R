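test_that("rms matches its defining formula", {
  expect_equal(rms(c(1, -1)), 1)
  expect_equal(rms(rep(-3.2, 17)), 3.2)
  # sine of amplitude A over whole periods -> A / sqrt(2)
  t <- seq(0, 1, length.out = 10001)[-10001]
  expect_equal(rms(2.5 * sin(2 * pi * 5 * t)), 2.5 / sqrt(2),
               tolerance = 1e-3)
  expect_error(rms(numeric(0)), class = "echopatch_acoustics_error")
})

test_that("phantom containers validate their scatterers", {
  ph <- phantom(tibble::tibble(x = 0, z = 30e-3))
  expect_equal(ph$y, 0)
  expect_equal(ph$amplitude, 1)
  expect_error(phantom(tibble::tibble(x = 0, y = 0, z = -1e-3)),
               class = "echopatch_acoustics_error")
  expect_error(phantom(tibble::tibble(x = Inf, y = 0, z = 1e-3)),
               class = "echopatch_acoustics_error")
})

test_that("channel data places echoes at the two-way time of flight", {
  a <- default_array()
  ph <- wire_phantom(tibble::tibble(x = 0, z = 40e-3))
  ch <- simulate_channel_data(ph, a, plane_sequence(a))
  # centre element: t = 2 z / c (element at x = 0.2 mm, negligible offset)
  env <- Mod(analytic_signal(ch$samples[, 16, 1]))
  t_peak <- (which.max(env) - 1) / ch$fs
  expect_lt(abs(t_peak - 2 * 40e-3 / 1540), 1 / ch$fs)
})

test_that("channel simulation is linear and geometrically reciprocal", {
  a <- default_array()
  sq <- plane_sequence(a, 10)
  p1 <- phantom(tibble::tibble(x = -3e-3, z = 30e-3, amplitude = 1))
  p2 <- phantom(tibble::tibble(x = 5e-3, z = 45e-3, amplitude = 0.7))
  both <- phantom(tibble::tibble(x = c(-3e-3, 5e-3), z = c(30e-3, 45e-3),
                                 amplitude = c(1, 0.7)))
  dur <- 80e-6
  ch1 <- simulate_channel_data(p1, a, sq, duration = dur)
  ch2 <- simulate_channel_data(p2, a, sq, duration = dur)
  chb <- simulate_channel_data(both, a, sq, duration = dur)
  expect_equal(chb$samples, ch1$samples + ch2$samples, tolerance = 1e-12)
  # doubling reflectivity doubles the echo
  p1d <- phantom(tibble::tibble(x = -3e-3, z = 30e-3, amplitude = 2))
  expect_equal(simulate_channel_data(p1d, a, sq, duration = dur)$samples,
               2 * ch1$samples, tolerance = 1e-9)
  # mirror the phantom and the steering: channels reverse across elements
  sqm <- plane_sequence(a, -10)
  p1m <- phantom(tibble::tibble(x = 3e-3, z = 30e-3, amplitude = 1))
  chm <- simulate_channel_data(p1m, a, sqm, duration = dur)
  expect_equal(chm$samples[, 32:1, 1], ch1$samples[, , 1],
               tolerance = 1e-9)
})

test_that("empty phantoms and seeded noise behave deterministically", {
  a <- default_array()
  sq <- plane_sequence(a)
  empty <- phantom(tibble::tibble(x = numeric(0), y = numeric(0),
                                  z = numeric(0), amplitude = numeric(0)))
  ch0 <- simulate_channel_data(empty, a, sq, duration = 30e-6)
  expect_true(all(ch0$samples == 0))
  chn1 <- simulate_channel_data(empty, a, sq, duration = 30e-6,
                                noise_rms = 1, seed = 99)
  chn2 <- simulate_channel_data(empty, a, sq, duration = 30e-6,
                                noise_rms = 1, seed = 99)
  expect_identical(chn1$samples, chn2$samples)
  expect_equal(rms(as.vector(chn1$samples)), 1, tolerance = 0.02)
  expect_error(simulate_channel_data(empty, a, sq, noise_rms = 1),
               class = "echopatch_acoustics_error")
  expect_error(simulate_channel_data(empty, a, sq, fs = 1e6),
               class = "echopatch_acoustics_error")
})

test_that("field maps show spherical spreading and lateral symmetry", {
  one <- linear_array(1, 0.4e-3, 0.3e-3)
  fm <- simulate_field(one, plane_delays(one, 0),
                       list(x = 0, z = c(20e-3, 40e-3), y = 0))
  # on-axis: doubling the range halves the RMS
  expect_equal(fm$rms_pressure[1, 1] / fm$rms_pressure[2, 1], 2,
               tolerance = 0.01)

  a <- default_array()
  g <- field_grid(c(-6e-3, 6e-3), c(10e-3, 40e-3), dx = 1e-3, dz = 2e-3)
  fm2 <- simulate_field(a, plane_delays(a, 0), g)
  flipped <- fm2$rms_pressure[, ncol(fm2$rms_pressure):1]
  expect_lt(max(abs(fm2$rms_pressure - flipped)) / max(fm2$rms_pressure),
            1e-6)
  expect_true(all(fm2$rms_pressure >= 0))
  expect_error(simulate_field(a, plane_delays(a, 0),
                              list(x = 0, z = c(-1e-3, 10e-3), y = 0)),
               class = "echopatch_acoustics_error")
})

test_that("a focused field peaks at the focus across its depth row", {
  a <- default_array()
  fm <- simulate_field(a, focus_delays(a, 40e-3),
                       list(x = seq(-5e-3, 5e-3, 0.5e-3), z = 40e-3, y = 0))
  expect_equal(fm$x[which.max(fm$rms_pressure)], 0)
})

test_that("the analytic signal envelope recovers a tone's amplitude", {
  t <- seq(0, 1e-5, by = 1e-8)
  x <- 1.7 * cos(2 * pi * 3e6 * t)
  env <- Mod(analytic_signal(x))
  mid <- seq(100, length(t) - 100)
  expect_equal(mean(env[mid]), 1.7, tolerance = 0.01)
})
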