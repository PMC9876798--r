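# Plain-text container I/O. Every writer emits a YAML sidecar
# (<path>.meta.yaml) carrying format_version, provenance (config hash,
# seed) and the metadata needed to reconstruct the object; readers refuse
# mismatched format versions.

FORMAT_VERSION <- 1L

write_meta <- function(path, meta) {
  meta$format_version <- FORMAT_VERSION
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
}

read_meta <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  if (!identical(as.integer(meta$format_version), FORMAT_VERSION)) {
    rlang::abort(sprintf(
      "Container format version %s does not match the supported version %d.",
      meta$format_version, FORMAT_VERSION
    ), class = "echopatch_io_error")
  }
  meta
}

#' Write and read RF channel data as CSV
#'
#' Long-format CSV (`event`, `element`, `sample`, `value`) with a YAML
#' sidecar holding the sampling parameters, the array geometry and the
#' per-event delay/apodization laws, sufficient to reconstruct the
#' `channel_data` object.
#'
#' @param channel A `channel_data`.
#' @param path CSV file path.
#' @return `read_channel_csv()` returns a `channel_data`.
#' @export
write_channel_csv <- function(channel, path) {
  d <- dim(channel$samples)
  df <- data.frame(
    event = rep(seq_len(d[3]), each = d[1] * d[2]),
    element = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample = rep(seq_len(d[1]), times = d[2] * d[3]),
    value = as.vector(channel$samples)
  )
  utils::write.csv(df, path, row.names = FALSE)
  arr <- channel$array
  write_meta(path, list(
    kind = "channel_data", fs = channel$fs, t0 = channel$t0,
    c = channel$c, n_samples = d[1], n_elements = d[2], n_events = d[3],
    noise_rms = channel$noise_rms, seed = channel$seed,
    array = list(
      n_elements = arr$n_elements, pitch = arr$pitch,
      element_width = arr$element_width,
      element_length = arr$element_length,
      centre_frequency = arr$centre_frequency,
      fractional_bandwidth = arr$fractional_bandwidth,
      flat = isTRUE(arr$flat),
      positions = as.vector(arr$positions),
      normals = as.vector(arr$normals)
    ),
    pulse = list(
      centre_frequency = channel$sequence$pulse$centre_frequency,
      fractional_bandwidth = channel$sequence$pulse$fractional_bandwidth
    ),
    events = lapply(channel$sequence$events, function(e) {
      list(kind = e$kind, steer_angle = e$steer_angle,
           delays = as.numeric(e$delays),
           apodization = as.numeric(e$apodization))
    })
  ))
  invisible(path)
}

#' @rdname write_channel_csv
#' @export
read_channel_csv <- function(path) {
  meta <- read_meta(path)
  df <- utils::read.csv(path)
  samples <- array(0, dim = c(meta$n_samples, meta$n_elements,
                              meta$n_events))
  samples[cbind(df$sample, df$element, df$event)] <- df$value
  am <- meta$array
  arr <- linear_array(am$n_elements, am$pitch, am$element_width,
                      am$element_length, am$centre_frequency,
                      am$fractional_bandwidth)
  arr$positions <- matrix(unlist(am$positions), ncol = 3,
                          dimnames = list(NULL, c("x", "y", "z")))
  arr$normals <- matrix(unlist(am$normals), ncol = 3,
                        dimnames = list(NULL, c("x", "y", "z")))
  arr$flat <- isTRUE(am$flat)
  p <- pulse(meta$pulse$centre_frequency,
             meta$pulse$fractional_bandwidth)
  events <- lapply(meta$events, function(e) {
    structure(
      list(kind = e$kind, steer_angle = e$steer_angle,
           focal_point = NULL, virtual_source = NULL,
           delays = as.numeric(unlist(e$delays)),
           apodization = as.numeric(unlist(e$apodization)),
           n_elements = am$n_elements),
      class = "transmit_event"
    )
  })
  structure(
    list(samples = samples, fs = meta$fs, t0 = meta$t0, c = meta$c,
         array = arr, sequence = transmit_sequence(events, p),
         noise_rms = meta$noise_rms, seed = meta$seed),
    class = "channel_data"
  )
}

#' Write and read a B-mode image as CSV (plus PNG display export)
#'
#' The CSV holds the dB intensity matrix; the sidecar carries the pixel
#' grid. `write_bmode_png()` maps dB linearly onto 8-bit grey over
#' `[floor_db, 0]` (floor -> 0, 0 dB -> 255).
#'
#' @param bmode A `bmode_image`.
#' @param path Output path.
#' @return `read_bmode_csv()` returns a `bmode_image`;
#'   `bmode_to_grey()` the 8-bit integer matrix.
#' @export
write_bmode_csv <- function(bmode, path) {
  utils::write.table(bmode$intensity_db, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  g <- bmode$grid
  write_meta(path, list(
    kind = "bmode_image", floor_db = bmode$floor_db,
    depth = g$depth, width = g$width, n_axial = g$n_axial,
    n_lateral = g$n_lateral, z_min = min(g$z),
    x_centre = mean(range(g$x))
  ))
  invisible(path)
}

#' @rdname write_bmode_csv
#' @export
read_bmode_csv <- function(path) {
  meta <- read_meta(path)
  vals <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(vals) <- NULL
  grid <- pixel_grid(meta$depth, meta$width, meta$n_axial,
                     meta$n_lateral, z_min = meta$z_min,
                     x_centre = meta$x_centre)
  structure(list(intensity_db = vals, grid = grid,
                 floor_db = meta$floor_db),
            class = "bmode_image")
}

#' @rdname write_bmode_csv
#' @export
bmode_to_grey <- function(bmode) {
  g <- (bmode$intensity_db - bmode$floor_db) / (0 - bmode$floor_db)
  matrix(as.integer(round(255 * pmin(pmax(g, 0), 1))),
         nrow = nrow(bmode$intensity_db))
}

#' @rdname write_bmode_csv
#' @export
write_bmode_png <- function(bmode, path) {
  png::writePNG(bmode_to_grey(bmode) / 255, path)
  invisible(path)
}

#' Write and read segmentation mask stacks as numbered PNGs
#'
#' One 8-bit PNG per frame (`mask_0001.png`, ...) in a directory, plus a
#' YAML sidecar (`masks.meta.yaml`) with the frame interval and pixel
#' size.
#'
#' @param masks Binary array (frame x row x col).
#' @param dir Output directory (created if needed).
#' @param pixel_mm Pixel size in millimetres.
#' @param frame_dt Frame interval in seconds.
#' @return `read_masks_png()` returns a list `masks`, `pixel_mm`,
#'   `frame_dt`.
#' @export
write_masks_png <- function(masks, dir, pixel_mm, frame_dt) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_fr <- dim(masks)[1]
  for (k in seq_len(n_fr)) {
    m <- masks[k, , ] * 1.0
    png::writePNG(m, file.path(dir, sprintf("mask_%04d.png", k)))
  }
  write_meta(file.path(dir, "masks"),
             list(kind = "mask_stack", n_frames = n_fr,
                  pixel_mm = pixel_mm, frame_dt = frame_dt))
  invisible(dir)
}

#' @rdname write_masks_png
#' @export
read_masks_png <- function(dir) {
  meta <- read_meta(file.path(dir, "masks"))
  files <- sort(list.files(dir, pattern = "^mask_\\d+\\.png$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    (m > 0.5) * 1L
  })
  masks <- array(0L, dim = c(length(frames), nrow(frames[[1]]),
                             ncol(frames[[1]])))
  for (k in seq_along(frames)) masks[k, , ] <- frames[[k]]
  list(masks = masks, pixel_mm = meta$pixel_mm, frame_dt = meta$frame_dt)
}

#' Write and read tidy report tables
#'
#' @param report A data frame.
#' @param path CSV path.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
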