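test_that("waveform cycles hit the exact PSV and EDV", {
  wf <- generate_waveform(waveform_spec(psv = 52.2, edv = 20, fhr = 140,
                                        duration = 10), seed = 1)
  v <- wf$signal$velocity_cms
  dt <- 1 / wf$spec$sample_rate
  period <- 60 / 140
  for (b in seq_len(nrow(wf$beats))) {
    i0 <- round(wf$beats$start_s[b] / dt) + 1
    i1 <- round(wf$beats$end_s[b] / dt) + 1
    cyc <- v[i0:i1]
    expect_equal(max(cyc), 52.2, tolerance = 1e-9)
    expect_equal(min(cyc), 20, tolerance = 1e-9)
  }
  expect_error(generate_waveform(waveform_spec(fhr = 20)), "fhr")
})

test_that("absent-EDV assignment is exact and seeded", {
  spec <- waveform_spec(duration = 100 * 60 / 140, fhr = 140,
                        absent_edv_fraction = 0.25)
  wf <- generate_waveform(spec, seed = 11)
  expect_identical(nrow(wf$beats), 100L)
  expect_identical(sum(wf$beats$edv == 0), 25L)
  # reproducibility: same seed, same assignment
  wf2 <- generate_waveform(spec, seed = 11)
  expect_identical(wf$signal, wf2$signal)
  expect_identical(wf$beats, wf2$beats)
  # reversed variant drives flagged beats negative
  wr <- generate_waveform(waveform_spec(duration = 100 * 60 / 140, fhr = 140,
                                        absent_edv_fraction = 0.25,
                                        reversed_edv = TRUE), seed = 11)
  expect_identical(sum(wr$beats$edv < 0), 25L)
})

test_that("waveform TAV matches an independent trapezoidal oracle", {
  wf <- generate_waveform(waveform_spec(psv = 52.2, edv = 20, fhr = 140,
                                        duration = 10), seed = 0)
  # golden value computed beforehand by an independent trapezoidal
  # integration of the stated shape (S/D 2.61 default)
  expect_equal(wf$beats$tav[1], 31.17714492297937, tolerance = 1e-9)
  pi_beat <- (wf$beats$psv[1] - wf$beats$edv[1]) / wf$beats$tav[1]
  expect_equal(pi_beat, 1.0328078494534223, tolerance = 1e-9)
  # live oracle: pracma::trapz over each cycle
  dt <- 1 / wf$spec$sample_rate
  for (b in c(1, 5, 10)) {
    i0 <- round(wf$beats$start_s[b] / dt) + 1
    i1 <- round(wf$beats$end_s[b] / dt) + 1
    tt <- wf$signal$time_s[i0:i1]
    vv <- wf$signal$velocity_cms[i0:i1]
    expect_equal(wf$beats$tav[b],
                 pracma::trapz(tt, vv) / (tt[length(tt)] - tt[1]),
                 tolerance = 1e-10)
  }
})

test_that("rendered scenes carry the waveform in the artery and stay seeded", {
  # noise off + zero waveform: artery colour pixels are exactly zero
  w0 <- waveform_spec(psv = 1e-12, edv = 0, fhr = 140, duration = 1)
  sc <- scene_spec(n_frames = 10, color_noise_sd = 0, speckle_var = 0,
                   vein_velocity = 0)
  fr0 <- render_sequence(sc, w0, seed = 1)
  expect_lt(max(abs(fr0$color)), 1e-9)

  # static trajectory: ground-truth centroid constant
  frs <- render_sequence(scene_spec(n_frames = 20, color_noise_sd = 0),
                         healthy_wave(duration = 2), seed = 2)
  expect_equal(length(unique(frs$truth$lateral_mm)), 1L)
  expect_equal(length(unique(frs$truth$axial_mm)), 1L)

  # noise off: per-frame mean artery colour equals the waveform at frame times
  sc3 <- scene_spec(n_frames = 40, color_noise_sd = 0, speckle_var = 0)
  w3 <- healthy_wave(duration = 2)
  fr3 <- render_sequence(sc3, w3, seed = 0)
  pitch <- fr3$pixel_pitch
  lat <- (seq_len(dim(fr3$color)[2]) - 1) * pitch
  ax <- (seq_len(dim(fr3$color)[1]) - 1) * pitch
  for (f in c(1, 10, 25, 40)) {
    mask <- outer(ax, lat, function(y, x) {
      (x - fr3$truth$lateral_mm[f])^2 + (y - fr3$truth$axial_mm[f])^2 <=
        sc3$artery_radius^2
    })
    vals <- fr3$color[, , f][mask]
    expect_equal(mean(vals), fr3$truth$velocity_cms[f], tolerance = 1e-9)
  }

  # reproducibility contract: same seed + spec, bit-identical arrays
  a <- render_sequence(moving_scene(seed = 5, n_frames = 12),
                       healthy_wave(duration = 1), seed = 5)
  b <- render_sequence(moving_scene(seed = 5, n_frames = 12),
                       healthy_wave(duration = 1), seed = 5)
  expect_identical(a$color, b$color)
  expect_identical(a$bmode, b$bmode)

  # configuration error when the vessel pair cannot stay in the field
  expect_error(
    render_sequence(scene_spec(field_depth = 12, vein_offset = c(0, 7),
                               n_frames = 3),
                    healthy_wave(duration = 1)),
    "frame 1")
})

test_that("rendered artery area approximates the configured disk", {
  for (r in c(2, 3)) {  # radii of 4 and 6 pixels at 0.5 mm pitch
    fr <- render_sequence(scene_spec(n_frames = 2, artery_radius = r,
                                     color_noise_sd = 0),
                          healthy_wave(duration = 0.5), seed = 1)
    area_px <- sum(fr$color[, , 1] != 0) -
      sum(abs(fr$color[, , 1] - fr$scene$vein_velocity) < 1e-12)
    expect_equal(area_px, pi * r^2 / fr$pixel_pitch^2, tolerance = 0.1)
  }
})

test_that("spectrogram geometry, aliasing and energy spread behave", {
  expect_equal(nyquist_velocity(3000, 2.5), 46.2)
  expect_error(nyquist_velocity(3000, 2.5, angle_deg = 90), "90")
  expect_error(synthesize_spectrogram(
    tibble::tibble(time_s = 0:1, velocity_cms = 0), angle_deg = 90), "90")

  # zero velocity: ridge sits on the zero-velocity bin at all times
  flat <- tibble::tibble(time_s = seq(0, 1, 0.01), velocity_cms = 0)
  spg <- synthesize_spectrogram(flat, broadening_sd = 0, noise_floor = 0)
  ridge <- apply(spg$power, 2, which.max)
  expect_true(all(spg$velocity_axis[ridge] == 0))

  # super-Nyquist velocity wraps to the opposite side
  over <- tibble::tibble(time_s = seq(0, 1, 0.01),
                         velocity_cms = 1.1 * 46.2)
  spg2 <- synthesize_spectrogram(over, broadening_sd = 0, noise_floor = 0)
  ridge2 <- spg2$velocity_axis[apply(spg2$power, 2, which.max)]
  expect_equal(unique(round(ridge2, 1)), -0.9 * 46.2, tolerance = 0.01)

  # noise off: >= 99% of column energy within 3 broadening SDs of the truth
  wf <- generate_waveform(healthy_wave(duration = 2), seed = 3)
  spg3 <- synthesize_spectrogram(wf, broadening_sd = 1, noise_floor = 0)
  v_true <- stats::approx(wf$signal$time_s, wf$signal$velocity_cms,
                          xout = spg3$time)$y
  for (j in seq(1, length(spg3$time), by = 50)) {
    near <- abs(spg3$velocity_axis - v_true[j]) <= 3
    expect_gte(sum(spg3$power[near, j]) / sum(spg3$power[, j]), 0.99)
  }

  # seeded reproducibility with noise on
  s1 <- synthesize_spectrogram(wf, noise_sd = 0.3, seed = 9)
  s2 <- synthesize_spectrogram(wf, noise_sd = 0.3, seed = 9)
  expect_identical(s1$power, s2$power)
})
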