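test_that("envelope tracks a constant ridge to within one velocity bin", {
  flat <- tibble::tibble(time_s = seq(0, 1, 0.01), velocity_cms = 30)
  spg <- synthesize_spectrogram(flat, broadening_sd = 0, noise_floor = 0)
  env <- extract_envelope(spg)
  bw <- attr(env, "bin_width")
  expect_true(all(abs(env$velocity_cms - 30) <= bw))
  expect_false(any(env$flagged))
})

test_that("an all-noise spectrogram yields a flagged zero envelope", {
  spg <- synthesize_spectrogram(
    tibble::tibble(time_s = seq(0, 1, 0.01), velocity_cms = 0),
    broadening_sd = 0, noise_floor = 0)
  spg$power[] <- 0.25          # pure flat noise, no ridge
  spg$noise_floor <- 0.25
  env <- extract_envelope(spg)
  expect_true(all(env$flagged))
  expect_true(all(env$velocity_cms == 0))
})

test_that("envelope recovers the synthetic waveform within 5% of PSV", {
  wf <- generate_waveform(healthy_wave(duration = 4), seed = 2)
  spg <- synthesize_spectrogram(wf, broadening_sd = 0.3, noise_floor = 0)
  env <- extract_envelope(spg)
  v_true <- stats::approx(wf$signal$time_s, wf$signal$velocity_cms,
                          xout = env$time_s)$y
  expect_lte(max(abs(env$velocity_cms - v_true)), 0.05 * wf$spec$psv)
})

test_that("envelope is invariant to uniform power scaling", {
  wf <- generate_waveform(healthy_wave(duration = 3), seed = 5)
  spg <- synthesize_spectrogram(wf, broadening_sd = 0.5, noise_floor = 0)
  e1 <- extract_envelope(spg)
  spg$power <- spg$power * 37.5
  e2 <- extract_envelope(spg)
  expect_identical(e1$velocity_cms, e2$velocity_cms)
})

test_that("reversed flow is traced on the negative side", {
  rev <- tibble::tibble(time_s = seq(0, 1, 0.01), velocity_cms = -25)
  spg <- synthesize_spectrogram(rev, broadening_sd = 0, noise_floor = 0)
  env <- extract_envelope(spg)
  expect_true(all(abs(env$velocity_cms + 25) <= attr(env, "bin_width")))
})

test_that("beat detection recovers rate, extrema and absent-EDV counts", {
  wf <- generate_waveform(healthy_wave(duration = 10), seed = 3)
  spg <- synthesize_spectrogram(wf, broadening_sd = 0, noise_floor = 0)
  beats <- detect_beats(extract_envelope(spg))
  expect_gte(nrow(beats), 20)
  expect_lt(abs(mean(beats$fhr) - 140), 2)
  expect_lt(abs(mean(beats$psv) - 40), 1)
  expect_lt(abs(mean(beats$edv) - 40 / 2.61), 1)
  expect_false(any(beats$edv_absent))
  # beat intervals partition the spanned time to within one time bin
  expect_lt(abs(sum(beats$interval_s) -
                (max(beats$end_s) - min(beats$start_s))), spg$time_step)

  # a quarter of beats absent, exactly recovered
  wa <- generate_waveform(
    waveform_spec(psv = 40, edv = 40 / 2.61, fhr = 140,
                  duration = 100.5 * 60 / 140,
                  absent_edv_fraction = 0.25), seed = 13)
  spga <- synthesize_spectrogram(wa, broadening_sd = 0, noise_floor = 0)
  ba <- detect_beats(extract_envelope(spga))
  expect_identical(sum(ba$edv_absent), 25L)
  expect_equal(absent_edv_fraction(ba), 25 / nrow(ba))

  # constant envelope: no beats to find
  flat <- structure(tibble::tibble(time_s = seq(0, 5, 0.01),
                                   velocity_cms = 20),
                    class = c("doppler_envelope", "tbl_df", "tbl", "data.frame"))
  expect_error(detect_beats(flat), class = "no_beats")
  expect_error(detect_beats(flat[1:100, ]), "2 seconds")
})

test_that("absent-EDV fraction counts beats against the threshold", {
  b <- tibble::tibble(edv = c(rep(10, 75), rep(0, 25)))
  expect_equal(absent_edv_fraction(b), 0.25)
  expect_equal(absent_edv_fraction(tibble::tibble(edv = rep(10, 5))), 0)
  expect_error(absent_edv_fraction(tibble::tibble(edv = numeric())), "nonempty")
  # seeded 1000-beat stream at the pre-eclamptic participant's absent rate:
  # recovered fraction inside the binomial 95% interval around 0.249
  set.seed(99)
  stream <- tibble::tibble(edv = ifelse(runif(1000) < 0.249, 0, 12))
  half <- 1.96 * sqrt(0.249 * 0.751 / 1000)
  expect_lt(abs(absent_edv_fraction(stream) - 0.249), half)
})

test_that("acceleration detection finds injected FHR bumps", {
  t <- seq(0, 1200, by = 1)
  base <- rep(140, length(t))
  none <- detect_accelerations(tibble::tibble(time_s = t, fhr_bpm = base))
  expect_identical(nrow(none), 0L)

  one <- base
  one[t >= 300 & t < 330] <- 160          # 20 bpm for 30 s
  ev <- detect_accelerations(tibble::tibble(time_s = t, fhr_bpm = one))
  expect_identical(nrow(ev), 1L)
  expect_lte(ev$start_s, 301)
  expect_gte(ev$end_s, 328)
  expect_equal(ev$peak_bpm, 160)

  # two bumps separated by a sub-threshold dip -> two events (brute-force
  # scan oracle: count maximal runs above baseline + 15 lasting >= 15 s)
  two <- base
  two[t >= 300 & t < 330] <- 160
  two[t >= 330 & t < 350] <- 148          # dip below threshold
  two[t >= 350 & t < 380] <- 162
  df <- tibble::tibble(time_s = t, fhr_bpm = two)
  ev2 <- detect_accelerations(df)
  over <- two >= 140 + 15
  runs <- rle(over)
  oracle_n <- sum(runs$values & runs$lengths >= 15)
  expect_identical(nrow(ev2), oracle_n)
  expect_identical(nrow(ev2), 2L)
})
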