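# Shared fixture builders; everything is generated in code at test time.

# healthy-profile waveform kept below the 46.2 cm/s Nyquist of the default
# acquisition constants, preserving the 2.61 S/D ratio
healthy_wave <- function(duration = 10, fhr = 140, psv = 40,
                         sd_ratio = 2.61, ...) {
  waveform_spec(fhr = fhr, psv = psv, edv = psv / sd_ratio,
                duration = duration, ...)
}

# small moving-artery scene for tracker tests
moving_scene <- function(seed = 0, n_frames = 60, ...) {
  scene_spec(trajectory = list(type = "random_walk", max_speed = 2),
             n_frames = n_frames, seed = seed, ...)
}

# beat stream with absolute times for monitoring tests: `minutes` of beats
# at a constant rate with given per-beat velocities
synthetic_beats <- function(minutes, fhr = 140, psv = 40, edv = 40 / 2.61,
                            tav = NULL, fhr_jitter = 0, seed = 1) {
  period <- 60 / fhr
  n <- floor(minutes * 60 / period)
  starts <- (seq_len(n) - 1) * period
  f <- if (fhr_jitter > 0) {
    withr::with_seed(seed, fhr + stats::rnorm(n, 0, fhr_jitter))
  } else {
    rep(fhr, n)
  }
  tibble::tibble(
    beat = seq_len(n), start_s = starts, end_s = starts + period,
    psv = psv, edv = edv,
    tav = tav %||% (edv + (psv - edv) * 0.347),
    fhr = f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independently coded two-pass variance oracle (population variance)
variance_oracle <- function(arr) {
  d <- dim(arr)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      x <- abs(arr[i, j, ])
      m <- sum(x) / length(x)
      out[i, j] <- sum((x - m)^2) / length(x)
    }
  }
  out
}
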