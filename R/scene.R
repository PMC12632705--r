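#' Duplex scene specification
#'
#' Geometry and texture parameters for the synthetic duplex scene: a pulsatile
#' artery and a steady vein (a rigid pair) moving through a B-mode speckle
#' field with a co-registered colour-Doppler velocity overlay.
#'
#' Coordinates: lateral = mm from the left edge of the field, axial = depth in
#' mm from the transducer face, both measured at pixel centres with 0-based
#' indexing (pixel index 0 sits at 0 mm).
#'
#' @param field_width,field_depth Field of view, mm.
#' @param pixel_pitch Pixel spacing, mm (isotropic).
#' @param frame_rate Frames per second.
#' @param n_frames Number of frames.
#' @param artery_radius,vein_radius Vessel radii, mm.
#' @param vein_offset Lateral/axial offset (mm, length-2) of the vein centre
#'   relative to the artery centre.
#' @param vein_velocity Constant vein flow velocity, cm/s (opposite sign to
#'   the artery by convention: flow toward the transducer is positive).
#' @param trajectory A list describing the vessel-pair centroid path:
#'   `list(type = "static")`, `list(type = "sinusoid", amplitude, period,
#'   axis)` (axis `"lateral"` or `"axial"`), or `list(type = "random_walk",
#'   max_speed)` with `max_speed` in mm/s.
#' @param speckle_mean,speckle_var Mean and variance of the gamma-distributed
#'   B-mode speckle texture (display units in [0, 1]).
#' @param color_noise_sd SD (cm/s) of additive Gaussian noise on every colour
#'   pixel (vessels and background alike; background mean is 0).
#' @param nyquist Colour-scale Nyquist velocity, cm/s; velocities wrap
#'   (alias) beyond it.
#' @param seed Default integer seed for [render_sequence()].
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(field_width = 40, field_depth = 60, pixel_pitch = 0.5,
                       frame_rate = 20, n_frames = 100,
                       artery_radius = 2, vein_radius = 2.5,
                       vein_offset = c(0, 7), vein_velocity = -8,
                       trajectory = list(type = "static"),
                       speckle_mean = 0.35, speckle_var = 0.01,
                       color_noise_sd = 2, nyquist = 46.2, seed = 0) {
  stopifnot(pixel_pitch > 0, field_width > 0, field_depth > 0,
            frame_rate > 0, n_frames >= 1, artery_radius > 0, vein_radius > 0,
            length(vein_offset) == 2, nyquist > 0, color_noise_sd >= 0)
  structure(
    list(field_width = field_width, field_depth = field_depth,
         pixel_pitch = pixel_pitch, frame_rate = frame_rate,
         n_frames = n_frames, artery_radius = artery_radius,
         vein_radius = vein_radius, vein_offset = vein_offset,
         vein_velocity = vein_velocity, trajectory = trajectory,
         speckle_mean = speckle_mean, speckle_var = speckle_var,
         color_noise_sd = color_noise_sd, nyquist = nyquist, seed = seed),
    class = "scene_spec")
}

# Vessel-pair centroid path sampled at frame times; returns a matrix
# [n_frames x 2] of (lateral, axial) mm for the *artery* centre.
scene_trajectory <- function(scene, times, seed) {
  centre <- c(scene$field_width / 2, scene$field_depth / 2)
  traj <- scene$trajectory
  n <- length(times)
  pos <- matrix(rep(centre, each = n), ncol = 2)
  if (identical(traj$type, "static")) {
    # keep centre
  } else if (identical(traj$type, "sinusoid")) {
    ax <- if (identical(traj$axis %||% "lateral", "axial")) 2L else 1L
    pos[, ax] <- pos[, ax] + traj$amplitude * sin(2 * pi * times / traj$period)
  } else if (identical(traj$type, "random_walk")) {
    # smooth bounded-speed walk: low-pass filtered white acceleration,
    # speed clamped to max_speed
    dt <- if (n > 1) times[2] - times[1] else 1
    steps <- with_seed(seed, matrix(stats::rnorm(2 * n), ncol = 2))
    vel <- apply(steps, 2, function(s) {
      v <- stats::filter(s, rep(1 / 8, 8), sides = 1)
      v[is.na(v)] <- 0
      as.numeric(v)
    })
    spd <- sqrt(rowSums(vel^2))
    scale <- ifelse(spd > 0, pmin(1, 1 / spd), 0) * traj$max_speed
    vel <- vel * scale          # |velocity| <= max_speed mm/s
    pos <- cbind(centre[1] + cumsum(vel[, 1] * dt),
                 centre[2] + cumsum(vel[, 2] * dt))
    # reflect at a conservative interior margin so vessels stay in field
    margin <- traj$margin %||% 10
    pos[, 1] <- reflect_interval(pos[, 1], margin, scene$field_width - margin)
    pos[, 2] <- reflect_interval(pos[, 2], margin, scene$field_depth - margin)
  } else {
    stop("unknown trajectory type: ", traj$type, call. = FALSE)
  }
  pos
}

#' Render a duplex frame sequence with ground truth
#'
#' Rasterises the moving artery/vein pair into co-registered B-mode and
#' colour-Doppler grids. Artery colour pixels carry the instantaneous
#' waveform velocity (plus noise), vein pixels a constant opposite-sign
#' velocity, background pixels zero-mean noise; all colour values wrap at the
#' scene Nyquist velocity. B-mode is gamma speckle with darker vessel lumina.
#'
#' @param scene A [scene_spec()].
#' @param wave A [waveform_spec()] driving the artery velocity.
#' @param seed Integer seed (defaults to `scene$seed`); one seed drives the
#'   trajectory, the absent-EDV plan and all pixel noise.
#' @return A list of class `"duplex_sequence"`: `bmode` and `color` arrays
#'   `[axial, lateral, frame]`, `times` (s), `pixel_pitch` (mm), `nyquist`,
#'   `truth` (tibble: `frame`, `time_s`, `lateral_mm`, `axial_mm`,
#'   `velocity_cms`), `scene`, `wave`.
#' @export
render_sequence <- function(scene, wave, seed = scene$seed) {
  stopifnot(inherits(scene, "scene_spec"), inherits(wave, "waveform_spec"))
  n_lat <- round(scene$field_width / scene$pixel_pitch)
  n_ax <- round(scene$field_depth / scene$pixel_pitch)
  times <- (seq_len(scene$n_frames) - 1) / scene$frame_rate

  period <- 60 / wave$fhr
  n_beats <- max(1L, floor(max(times) / period + 1e-9) + 1L)
  plan <- beat_plan(wave, n_beats, derive_seed(seed, 1))
  v_art <- waveform_velocity(wave, times, plan)

  centres <- scene_trajectory(scene, times, derive_seed(seed, 2))
  # both vessels must stay inside the field on every frame
  for (f in seq_len(scene$n_frames)) {
    a <- centres[f, ]; v <- a + scene$vein_offset
    if (a[1] < scene$artery_radius || a[1] > scene$field_width - scene$artery_radius ||
        a[2] < scene$artery_radius || a[2] > scene$field_depth - scene$artery_radius ||
        v[1] < scene$vein_radius || v[1] > scene$field_width - scene$vein_radius ||
        v[2] < scene$vein_radius || v[2] > scene$field_depth - scene$vein_radius) {
      stop("vessel leaves the field at frame ", f, call. = FALSE)
    }
  }

  lat_mm <- (seq_len(n_lat) - 1) * scene$pixel_pitch
  ax_mm <- (seq_len(n_ax) - 1) * scene$pixel_pitch
  latg <- matrix(lat_mm, n_ax, n_lat, byrow = TRUE)
  axg <- matrix(ax_mm, n_ax, n_lat)

  color <- array(0, dim = c(n_ax, n_lat, scene$n_frames))
  bmode <- array(0, dim = c(n_ax, n_lat, scene$n_frames))

  noise_seed <- derive_seed(seed, 3)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(noise_seed)
  shape <- if (scene$speckle_var > 0) scene$speckle_mean^2 / scene$speckle_var
  for (f in seq_len(scene$n_frames)) {
    a <- centres[f, ]; vv <- a + scene$vein_offset
    art <- (latg - a[1])^2 + (axg - a[2])^2 <= scene$artery_radius^2
    vein <- (latg - vv[1])^2 + (axg - vv[2])^2 <= scene$vein_radius^2
    cf <- matrix(0, n_ax, n_lat)
    cf[art] <- v_art[f]
    cf[vein] <- scene$vein_velocity
    if (scene$color_noise_sd > 0) {
      cf <- cf + matrix(stats::rnorm(n_ax * n_lat, 0, scene$color_noise_sd),
                        n_ax, n_lat)
    }
    color[, , f] <- wrap_nyquist(cf, scene$nyquist)
    bf <- if (is.null(shape)) {
      matrix(scene$speckle_mean, n_ax, n_lat)
    } else {
      matrix(stats::rgamma(n_ax * n_lat, shape = shape,
                           scale = scene$speckle_var / scene$speckle_mean),
             n_ax, n_lat)
    }
    bf[art | vein] <- bf[art | vein] * 0.2   # anechoic lumina
    bmode[, , f] <- pmin(bf, 1)
  }
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }

  structure(
    list(bmode = bmode, color = color, times = times,
         pixel_pitch = scene$pixel_pitch, nyquist = scene$nyquist,
         truth = tibble::tibble(frame = seq_len(scene$n_frames),
                                time_s = times,
                                lateral_mm = centres[, 1],
                                axial_mm = centres[, 2],
                                velocity_cms = v_art),
         beats = plan, scene = scene, wave = wave, seed = seed),
    class = "duplex_sequence")
}

# alias velocities beyond +/- nyquist onto the opposite side of the scale
wrap_nyquist <- function(v, nyquist) {
  ((v + nyquist) %% (2 * nyquist)) - nyquist
}

#' @export
print.duplex_sequence <- function(x, ...) {
  d <- dim(x$color)
  cat("<duplex_sequence> ", d[3], " frames of ", d[1], "x", d[2],
      " px (", x$pixel_pitch, " mm pitch), ",
      "Nyquist ", x$nyquist, " cm/s\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fold values back into [lo, hi] by reflection
reflect_interval <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}
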