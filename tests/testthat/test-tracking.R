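test_that("pulsatility map equals the two-pass variance oracle", {
  # trivial cases first
  same <- array(3, c(4, 4, 5))
  expect_true(all(pulsatility_map(same)$variance == 0))
  alt <- array(0, c(2, 2, 4))
  alt[1, 1, ] <- c(0, 1, 0, 1)
  expect_equal(pulsatility_map(alt)$variance[1, 1], 0.25)
  # random small windows against an independently coded two-pass oracle
  set.seed(123)
  for (i in 1:10) {
    d <- c(sample(4:16, 2), sample(2:8, 1))
    arr <- array(rnorm(prod(d), sd = 10), d)
    expect_equal(pulsatility_map(arr)$variance, variance_oracle(arr),
                 tolerance = 1e-10)
  }
  expect_error(pulsatility_map(array(0, c(3, 3, 1))), "2 frames")
})

test_that("variance map peaks inside the artery, not the steady vein", {
  fr <- render_sequence(scene_spec(n_frames = 20, seed = 4),
                        healthy_wave(duration = 1), seed = 4)
  map <- pulsatility_map(fr)
  peak <- which(map$variance == max(map$variance), arr.ind = TRUE)[1, ]
  peak_mm <- (peak - 1) * fr$pixel_pitch
  truth <- fr$truth[1, ]
  d_art <- sqrt((peak_mm[2] - truth$lateral_mm)^2 +
                (peak_mm[1] - truth$axial_mm)^2)
  expect_lte(d_art, fr$scene$artery_radius + fr$pixel_pitch)
  # artery region outranks any vein remnant
  regions <- segment_pulsatile(map)
  expect_gte(nrow(regions), 1)
  top <- select_primary(regions)
  expect_lt(abs(top$axial_mm - truth$axial_mm), fr$scene$artery_radius)
})

test_that("segmentation orders regions by area and honours the minimum", {
  zero <- structure(list(variance = matrix(0, 10, 10), window_length = 4,
                         pixel_pitch = 1), class = "pulsatility_map")
  expect_identical(nrow(segment_pulsatile(zero)), 0L)
  # two disjoint supra-threshold disks, areas ~300 and ~120 px
  v <- matrix(0, 60, 60)
  xy <- expand.grid(r = 1:60, c = 1:60)
  d1 <- (xy$r - 18)^2 + (xy$c - 18)^2 <= 9.8^2
  d2 <- (xy$r - 45)^2 + (xy$c - 45)^2 <= 6.2^2
  v[cbind(xy$r[d1], xy$c[d1])] <- 10
  v[cbind(xy$r[d2], xy$c[d2])] <- 8
  map <- structure(list(variance = v, window_length = 4, pixel_pitch = 1),
                   class = "pulsatility_map")
  regions <- segment_pulsatile(map, threshold_policy = "fraction",
                               threshold = 0.3)
  expect_identical(nrow(regions), 2L)
  expect_true(regions$area[1] > regions$area[2])
  expect_equal(regions$area[1], sum(d1))
  expect_equal(regions$area[2], sum(d2))
})

test_that("primary selection breaks ties by variance then depth", {
  r <- tibble::tibble(label = 1:2, area = c(300L, 120L),
                      mean_variance = c(2, 9),
                      lateral_mm = c(5, 20), axial_mm = c(30, 10))
  expect_identical(select_primary(r)$label, 1L)          # larger area wins
  r$area <- c(200L, 200L)
  expect_identical(select_primary(r)$label, 2L)          # higher variance
  r$mean_variance <- c(5, 5)
  expect_identical(select_primary(r)$label, 2L)          # shallower centroid
  expect_error(select_primary(r[0, ]), class = "no_pulsatile_region")
})

test_that("gate registration returns the unweighted centroid in mm", {
  # symmetric disk: centroid at the disk centre to within half a pixel
  v <- matrix(0, 80, 80)
  xy <- expand.grid(r = 1:80, c = 1:80)
  inside <- (xy$r - 41)^2 + (xy$c - 31)^2 <= 8^2
  v[cbind(xy$r[inside], xy$c[inside])] <- 5
  map <- structure(list(variance = v, window_length = 4, pixel_pitch = 1),
                   class = "pulsatility_map")
  gate <- register_gate(select_primary(segment_pulsatile(map)))
  expect_equal(gate$lateral_mm, 30, tolerance = 0.5)
  expect_equal(gate$axial_mm, 40, tolerance = 0.5)
  expect_equal(gate$length_mm, 2)

  # L-shaped 3-pixel region at (0,0),(0,1),(1,0) with 1 mm pitch
  vl <- matrix(0, 6, 6)
  vl[1, 1] <- vl[1, 2] <- vl[2, 1] <- 1
  mapl <- structure(list(variance = vl, window_length = 4, pixel_pitch = 1),
                    class = "pulsatility_map")
  g <- register_gate(select_primary(
    segment_pulsatile(mapl, min_region_area = 1)))
  expect_equal(g$lateral_mm, 1 / 3)
  expect_equal(g$axial_mm, 1 / 3)
})

test_that("gate registration is translation-equivariant", {
  fr <- render_sequence(scene_spec(n_frames = 12, seed = 6,
                                   color_noise_sd = 0),
                        healthy_wave(duration = 1), seed = 6)
  gate0 <- register_gate(select_primary(segment_pulsatile(
    pulsatility_map(fr))))
  sh <- fr$color
  di <- 7; dj <- -5
  shifted <- array(0, dim(sh))
  shifted[(1 + di):dim(sh)[1], 1:(dim(sh)[2] + dj), ] <-
    sh[1:(dim(sh)[1] - di), (1 - dj):dim(sh)[2], ]
  gate1 <- register_gate(select_primary(segment_pulsatile(
    pulsatility_map(shifted, pixel_pitch = fr$pixel_pitch))))
  expect_equal(gate1$axial_mm - gate0$axial_mm, di * fr$pixel_pitch,
               tolerance = 1e-9)
  expect_equal(gate1$lateral_mm - gate0$lateral_mm, dj * fr$pixel_pitch,
               tolerance = 1e-9)
})

test_that("sequence tracking follows static, moving and lost targets", {
  # static scene: constant trajectory
  fr <- render_sequence(scene_spec(n_frames = 25, seed = 7),
                        healthy_wave(duration = 1.5), seed = 7)
  tr <- track_sequence(fr)
  expect_true(all(tr$status == "tracking"))
  expect_lt(diff(range(tr$lateral_mm)), 1)
  expect_lt(diff(range(tr$axial_mm)), 1)

  # sinusoidal trajectory: tracked lateral position correlates with truth
  frs <- render_sequence(
    scene_spec(n_frames = 100,
               trajectory = list(type = "sinusoid", amplitude = 10,
                                 period = 10, axis = "lateral"),
               seed = 8),
    healthy_wave(duration = 5), seed = 8)
  trs <- track_sequence(frs)
  # the window centroid estimates the average position over the variance
  # window, so compare against the window-mean ground truth
  truth_avg <- vapply(trs$frame, function(i) {
    mean(frs$truth$lateral_mm[(i - 9):i])
  }, numeric(1))
  expect_gt(cor(trs$lateral_mm, truth_avg), 0.99)

  # vein-only scene (no pulsatile flow): everything is lost, gates NA
  frv <- render_sequence(scene_spec(n_frames = 20, color_noise_sd = 0,
                                    seed = 9),
                         waveform_spec(psv = 10, edv = 10, duration = 1),
                         seed = 9)
  trv <- track_sequence(frv)
  expect_true(all(trv$status == "lost"))
  expect_true(all(is.na(trv$lateral_mm)))

  expect_error(track_sequence(fr, window = 26), "shorter")
})

test_that("noise never improves the within-2-mm fraction", {
  fracs <- vapply(c(0, 4, 10), function(nsd) {
    res <- vapply(0:1, function(s) {
      fr <- render_sequence(moving_scene(seed = s, n_frames = 40,
                                         color_noise_sd = nsd),
                            healthy_wave(duration = 2), seed = s)
      tr <- track_sequence(fr)
      gd <- gate_discrepancy(tr, fr$truth[tr$frame, ])
      c(gd$lateral_within, gd$axial_within)
    }, numeric(2))
    mean(res)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-9))
})
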