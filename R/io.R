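#' Read and write duplex frame sequences
#'
#' Two on-disk containers are supported. `format = "tiff"` writes a
#' multi-page TIFF (pages alternate B-mode and colour per frame, 32-bit
#' float, colour velocities scaled from the +/- Nyquist range into [0, 1])
#' plus a JSON sidecar `<path>.json` holding the geometry metadata
#' (`pixel_pitch`, `timestamps`, `nyquist`, coordinate convention);
#' round-trips are exact to 32-bit float precision. `format = "rds"` stores
#' the full object and round-trips bit-identically. Reading fails with a
#' hard error naming any missing metadata field.
#'
#' @param frames A `duplex_sequence`.
#' @param path Output path (`.tif`/`.tiff` or `.rds`).
#' @param format `"tiff"` or `"rds"`; inferred from the extension when
#'   missing.
#' @return `write_frames()` returns `path` invisibly; `read_frames()`
#'   returns a `duplex_sequence`.
#' @export
write_frames <- function(frames, path, format = NULL) {
  stopifnot(inherits(frames, "duplex_sequence"))
  format <- format %||% if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "tiff"
  if (format == "rds") {
    saveRDS(frames, path)
    return(invisible(path))
  }
  n <- dim(frames$color)[3]
  pages <- vector("list", 2 * n)
  for (f in seq_len(n)) {
    pages[[2 * f - 1]] <- pmin(pmax(frames$bmode[, , f], 0), 1)
    pages[[2 * f]] <- (frames$color[, , f] + frames$nyquist) / (2 * frames$nyquist)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    pixel_pitch = frames$pixel_pitch,
    timestamps = frames$times,
    nyquist = frames$nyquist,
    n_frames = n,
    coordinate_convention = paste(
      "lateral = mm from field left edge, axial = depth in mm from the",
      "transducer face, both at pixel centres, 0-based indices"),
    channel_order = c("bmode", "color"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "tiff"
  if (format == "rds") {
    x <- readRDS(path)
    stopifnot(inherits(x, "duplex_sequence"))
    return(x)
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(c("pixel_pitch", "timestamps", "nyquist", "n_frames"),
                     names(meta))
  if (length(missing)) {
    stop("metadata missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- meta$n_frames
  if (length(pages) != 2 * n) {
    stop("frame count mismatch: expected ", 2 * n, " pages (bmode+color), got ",
         length(pages), call. = FALSE)
  }
  d <- dim(pages[[1]])
  bmode <- array(0, c(d[1], d[2], n))
  color <- array(0, c(d[1], d[2], n))
  for (f in seq_len(n)) {
    bmode[, , f] <- pages[[2 * f - 1]]
    color[, , f] <- pages[[2 * f]] * 2 * meta$nyquist - meta$nyquist
  }
  structure(
    list(bmode = bmode, color = color, times = meta$timestamps,
         pixel_pitch = meta$pixel_pitch, nyquist = meta$nyquist,
         truth = NULL, beats = NULL, scene = NULL, wave = NULL, seed = NULL),
    class = "duplex_sequence")
}

#' Read and write beat tables as CSV
#'
#' The on-disk schema uses unit-suffixed headers: `beat_index`, `start_s`,
#' `end_s`, `psv_cms`, `edv_cms`, `tav_cms`, `fhr_bpm`, `sd_ratio`, `pi`,
#' `ri`, `edv_absent`, `edv_reversed`. Values round-trip losslessly to at
#' least 12 significant digits.
#'
#' @param beats A beat table from [detect_beats()].
#' @param path CSV path.
#' @return `write_beat_table()` returns `path` invisibly;
#'   `read_beat_table()` a beat tibble with in-memory column names.
#' @export
write_beat_table <- function(beats, path) {
  b <- doppler_indices(beats)
  out <- data.frame(
    beat_index = b$beat, start_s = b$start_s, end_s = b$end_s,
    psv_cms = b$psv, edv_cms = b$edv, tav_cms = b$tav,
    fhr_bpm = b$fhr, sd_ratio = b$sd_ratio, pi = b$pi, ri = b$ri,
    edv_absent = b$edv_absent, edv_reversed = b$edv_reversed)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beat_table
#' @export
read_beat_table <- function(path) {
  x <- utils::read.csv(path)
  tibble::tibble(
    beat = x$beat_index, start_s = x$start_s, end_s = x$end_s,
    psv = x$psv_cms, edv = x$edv_cms, tav = x$tav_cms, fhr = x$fhr_bpm,
    sd_ratio = x$sd_ratio, pi = x$pi, ri = x$ri,
    edv_absent = as.logical(x$edv_absent),
    edv_reversed = as.logical(x$edv_reversed))
}

#' Run configuration
#'
#' Reads a YAML run configuration and merges it over the documented
#' defaults. Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list merged over the file values.
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 0,
    carrier_mhz = 2.5, prf = 3000, gate_mm = 2, frame_rate = 20,
    tracking = list(window = 10, threshold_policy = "otsu",
                    threshold = 0.3, min_region_area = 20, connectivity = 8),
    spectral = list(power_fraction = 0.95, smooth_window = 3,
                    fhr_band = c(60, 240), n_velocity = 513,
                    time_step = 0.002, broadening_sd = 1, noise_floor = 0),
    monitoring = list(interval = 600, variability = "sd",
                      percentile_rule = 7),
    waveform = list(fhr = 140, psv = 52.2, edv = 20, duration = 10,
                    absent_edv_fraction = 0),
    scene = list(field_width = 40, field_depth = 60, pixel_pitch = 0.5,
                 n_frames = 100, artery_radius = 2, vein_radius = 2.5,
                 color_noise_sd = 2))
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- utils::modifyList(utils::modifyList(defaults, user), overrides)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the simulation/analysis pipeline
#'
#' Executes the requested stages in order on a shared seeded state and
#' writes each stage's artifacts plus a JSON manifest (config, seed, config
#' hash, per-stage outputs) into `out_dir`.
#'
#' Stages: `simulate` (render frames + ground truth), `track` (gate
#' trajectory CSV + summary), `spectra` (spectrogram -> envelope -> beat
#' table CSV + summary), `monitor` (segment summaries), `validate`
#' (tracker-vs-truth gate discrepancy + Bland-Altman on gate positions).
#'
#' @param config A [run_config()] (or `NULL` for defaults).
#' @param stages Character vector, subset of
#'   `c("simulate", "track", "spectra", "monitor", "validate")`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("simulate", "track", "spectra"),
                         out_dir = ".") {
  cfg <- config %||% run_config()
  known <- c("simulate", "track", "spectra", "monitor", "validate")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage name(s): ", paste(bad, collapse = ", "),
         "; known stages: ", paste(known, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  state <- new.env(parent = emptyenv())

  need_sim <- function() {
    if (is.null(state$frames)) {
      wave <- do.call(waveform_spec, cfg$waveform)
      scene <- do.call(scene_spec, c(cfg$scene,
                                     list(frame_rate = cfg$frame_rate,
                                          seed = cfg$seed)))
      state$wave <- wave
      state$frames <- render_sequence(scene, wave, seed = cfg$seed)
    }
  }

  for (stage in stages) {
    if (stage == "simulate") {
      need_sim()
      p <- file.path(out_dir, "frames.rds")
      write_frames(state$frames, p, format = "rds")
      pt <- file.path(out_dir, "ground_truth.csv")
      utils::write.csv(state$frames$truth, pt, row.names = FALSE)
      outputs$simulate <- c(p, pt)
    } else if (stage == "track") {
      need_sim()
      tr <- cfg$tracking
      state$track <- track_sequence(state$frames, window = tr$window,
                                    threshold_policy = tr$threshold_policy,
                                    threshold = tr$threshold,
                                    min_region_area = tr$min_region_area,
                                    connectivity = tr$connectivity,
                                    gate_length = cfg$gate_mm)
      p <- file.path(out_dir, "trajectory.csv")
      utils::write.csv(
        state$track[, c("frame", "time_s", "lateral_mm", "axial_mm", "status")],
        p, row.names = FALSE)
      outputs$track <- p
    } else if (stage == "spectra") {
      need_sim()
      sp <- cfg$spectral
      wavegen <- generate_waveform(state$wave, seed = derive_seed(cfg$seed, 1))
      spg <- synthesize_spectrogram(wavegen, prf = cfg$prf,
                                    carrier_mhz = cfg$carrier_mhz,
                                    n_velocity = sp$n_velocity,
                                    time_step = sp$time_step,
                                    broadening_sd = sp$broadening_sd,
                                    noise_floor = sp$noise_floor,
                                    seed = cfg$seed)
      env <- extract_envelope(spg, power_fraction = sp$power_fraction,
                              smooth_window = sp$smooth_window)
      beats <- detect_beats(env, fhr_band = sp$fhr_band)
      state$beats <- beats
      p <- file.path(out_dir, "beats.csv")
      write_beat_table(beats, p)
      ps <- file.path(out_dir, "spectra_summary.json")
      bi <- doppler_indices(beats)
      jsonlite::write_json(list(
        n_beats = nrow(beats), mean_fhr = mean(beats$fhr),
        mean_sd_ratio = mean(bi$sd_ratio, na.rm = TRUE),
        mean_pi = mean(bi$pi), mean_ri = mean(bi$ri),
        absent_edv_fraction = absent_edv_fraction(beats)),
        ps, auto_unbox = TRUE, digits = NA)
      outputs$spectra <- c(p, ps)
    } else if (stage == "monitor") {
      if (is.null(state$beats)) {
        stop("stage 'monitor' requires 'spectra' earlier in the run",
             call. = FALSE)
      }
      seg <- segment_record(state$beats,
                            interval = cfg$monitoring$interval)
      p <- file.path(out_dir, "segments.csv")
      utils::write.csv(seg, p, row.names = FALSE)
      outputs$monitor <- p
    } else if (stage == "validate") {
      if (is.null(state$track)) {
        stop("stage 'validate' requires 'track' earlier in the run",
             call. = FALSE)
      }
      tracked <- dplyr::filter(state$track, .data$status == "tracking")
      truth <- state$frames$truth[tracked$frame, ]
      gd <- gate_discrepancy(tracked, truth, threshold = 2)
      p <- file.path(out_dir, "validation.json")
      jsonlite::write_json(c(
        as.list(tidy(gd)),
        list(bland_altman_lateral = unclass(
          tidy(bland_altman(a = tracked$lateral_mm, b = truth$lateral_mm))[-1]))),
        p, auto_unbox = TRUE, digits = NA)
      outputs$validate <- p
    }
  }

  manifest <- list(
    package = "fetodoppler",
    version = as.character(utils::packageVersion("fetodoppler")),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    stages = stages,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
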