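#' Default run configuration
#'
#' Nested list mirroring the YAML run-config schema. Array defaults are
#' the wearable 3 MHz imager parameters; the sequence defaults to
#' wide-beam compounding (97 angles over 75 degrees, here reduced in the
#' bundled demo config for speed); every stochastic stage carries an
#' explicit seed.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    array = list(n_elements = 32L, pitch_mm = 0.4, width_mm = 0.3,
                 length_mm = 2.3, fc_mhz = 3, bandwidth = 0.55),
    sequence = list(strategy = "widebeam", n_angles = 97L, span_deg = 75,
                    focal_depth_mm = 60),
    grid = list(depth_mm = 60, width_mm = 40, n_axial = 301L,
                n_lateral = 201L, z_min_mm = 5),
    phantom = list(kind = "wires", preset = "depth-ladder"),
    cardiac = list(edv_ml = 120, esv_ml = 50, heart_rate_bpm = 75,
                   frame_rate_hz = 30, n_cycles = 4),
    c_mps = 1540, fs_mhz = 20, noise_rms = 0, floor_db = -60,
    seed = 1L, output_dir = "echopatch-out"
  )
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) {
      rlang::abort(sprintf("Invalid config at `%s`: %s", field, msg),
                   class = "echopatch_config_error")
    }
  }
  chk(cfg$array$pitch_mm > cfg$array$width_mm, "array.pitch",
      "pitch must exceed element width")
  chk(cfg$array$width_mm > 0, "array.width", "must be positive")
  chk(cfg$array$n_elements >= 1, "array.n_elements", "must be >= 1")
  chk(cfg$array$fc_mhz > 0, "array.fc", "must be positive")
  chk(cfg$sequence$strategy %in% c("plane", "focus", "widebeam"),
      "sequence.strategy", "must be plane, focus or widebeam")
  chk(cfg$grid$depth_mm > 0 && cfg$grid$width_mm > 0, "grid",
      "extents must be positive")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
      "an explicit integer seed is required")
  invisible(cfg)
}

config_array <- function(cfg) {
  linear_array(cfg$array$n_elements, cfg$array$pitch_mm * 1e-3,
               cfg$array$width_mm * 1e-3, cfg$array$length_mm * 1e-3,
               cfg$array$fc_mhz * 1e6, cfg$array$bandwidth)
}

config_sequence <- function(cfg, arr) {
  p <- pulse(cfg$array$fc_mhz * 1e6, cfg$array$bandwidth)
  switch(cfg$sequence$strategy,
    widebeam = compounding_sequence(arr, cfg$sequence$span_deg,
                                    cfg$sequence$n_angles, pulse = p,
                                    c = cfg$c_mps),
    plane = plane_sequence(arr, 0, p, cfg$c_mps),
    focus = focus_sequence(arr, cfg$sequence$focal_depth_mm * 1e-3, p,
                           cfg$c_mps)
  )
}

config_phantom <- function(cfg) {
  ph <- cfg$phantom
  if (identical(ph$kind, "wires")) {
    if (!is.null(ph$preset)) {
      wire_phantom(ph$preset)
    } else {
      wire_phantom(tibble::tibble(x = unlist(ph$x_mm) * 1e-3,
                                  z = unlist(ph$z_mm) * 1e-3))
    }
  } else if (identical(ph$kind, "inclusions")) {
    inclusion_phantom(
      tibble::tibble(x = unlist(ph$x_mm) * 1e-3, z = unlist(ph$z_mm) * 1e-3,
                     radius = unlist(ph$radius_mm) * 1e-3,
                     contrast_db = unlist(ph$contrast_db)),
      density = ph$density %||% 20, seed = cfg$seed
    )
  } else {
    rlang::abort("Invalid config at `phantom.kind`: must be wires or inclusions.",
                 class = "echopatch_config_error")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end demo pipeline
#'
#' Executes the staged pipeline phantom -> simulate -> image -> metrics
#' -> cardiac, writing each stage's artifact (CSV/PNG with YAML sidecars)
#' into the configured output directory. Re-running with an identical
#' config reproduces the artifacts bit for bit: deterministic stages are
#' pure functions of the config and stochastic stages are driven by the
#' config seed. Every sidecar embeds the config hash.
#'
#' @param config A config list (see [default_config()]) or the path to a
#'   YAML file with the same structure.
#' @param stage One of `"phantom"`, `"simulate"`, `"image"`, `"metrics"`,
#'   `"cardiac"`, `"all"`; earlier stages are run as needed.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = default_config(), stage = "all") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  validate_config(cfg)
  stage <- match.arg(stage, c("phantom", "simulate", "image", "metrics",
                              "cardiac", "all"))
  stages <- c("phantom", "simulate", "image", "metrics", "cardiac")
  run <- if (stage == "all") stages else
    stages[seq_len(match(stage, stages))]
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(cfg)
  arts <- list()

  ph <- config_phantom(cfg)
  if ("phantom" %in% run) {
    p <- file.path(out_dir, "phantom.csv")
    utils::write.csv(as.data.frame(ph), p, row.names = FALSE)
    write_meta(p, list(kind = "phantom", config_hash = hash,
                       seed = cfg$seed))
    arts$phantom <- p
  }
  if (!any(c("simulate", "image", "metrics", "cardiac") %in% run)) {
    return(invisible(arts))
  }

  arr <- config_array(cfg)
  seq <- config_sequence(cfg, arr)
  ch <- simulate_channel_data(ph, arr, seq, fs = cfg$fs_mhz * 1e6,
                              noise_rms = cfg$noise_rms,
                              seed = if (cfg$noise_rms > 0) cfg$seed,
                              c = cfg$c_mps)
  if ("simulate" %in% run) {
    p <- file.path(out_dir, "channel.csv")
    write_channel_csv(ch, p)
    meta <- read_meta(p)
    meta$config_hash <- hash
    yaml::write_yaml(meta, paste0(p, ".meta.yaml"))
    arts$channel <- p
  }

  bm <- NULL
  if (any(c("image", "metrics") %in% run)) {
    grid <- pixel_grid(cfg$grid$depth_mm * 1e-3, cfg$grid$width_mm * 1e-3,
                       cfg$grid$n_axial, cfg$grid$n_lateral,
                       z_min = cfg$grid$z_min_mm * 1e-3)
    bm <- envelope_logcompress(beamform_compound(ch, grid),
                               floor_db = cfg$floor_db)
    if ("image" %in% run) {
      p <- file.path(out_dir, "bmode.csv")
      write_bmode_csv(bm, p)
      pp <- file.path(out_dir, "bmode.png")
      write_bmode_png(bm, pp)
      arts$bmode <- p
      arts$bmode_png <- pp
    }
  }

  if ("metrics" %in% run) {
    res <- resolution_set(bm, ph)
    report <- tibble::tibble(
      name = c(rep("axial_fwhm", nrow(res)), rep("lateral_fwhm", nrow(res))),
      value = c(res$axial_fwhm_mm, res$lateral_fwhm_mm),
      units = "mm",
      depth_mm = rep(res$z_mm, 2), offset_mm = rep(res$x_mm, 2)
    )
    p <- file.path(out_dir, "metrics.csv")
    write_report_csv(report, p)
    write_meta(p, list(kind = "report", config_hash = hash,
                       seed = cfg$seed))
    arts$metrics <- p
  }

  if ("cardiac" %in% run) {
    cc <- cfg$cardiac
    lv <- beating_lv(cc$edv_ml, cc$esv_ml, cc$heart_rate_bpm,
                     cc$frame_rate_hz, cc$n_cycles, seed = cfg$seed)
    vw <- volume_waveform(lv$masks, lv$pixel_mm, lv$frame_dt)
    idx <- indices_from_waveform(vw)
    p1 <- file.path(out_dir, "volume_waveform.csv")
    write_report_csv(vw, p1)
    p2 <- file.path(out_dir, "indices.csv")
    write_report_csv(tidy(idx), p2)
    write_meta(p2, list(kind = "cardiac_indices", config_hash = hash,
                        seed = cfg$seed))
    arts$volume_waveform <- p1
    arts$indices <- p2
  }
  invisible(arts)
}
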