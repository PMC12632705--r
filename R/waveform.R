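#' Umbilical-artery waveform specification
#'
#' Parameters of the synthetic umbilical-artery velocity waveform: a smooth
#' systolic upstroke (raised cosine) to the peak systolic velocity followed by
#' an exponential-like diastolic decay to the end diastolic velocity at the
#' end of each cycle. Defaults emulate a healthy third-trimester umbilical
#' artery: S/D ratio 2.61 and, with the default shape, a pulsatility index
#' close to 1.04.
#'
#' @param fhr Fetal heart rate, beats per minute (30-300; default 140).
#' @param psv Peak systolic velocity, cm/s.
#' @param edv End diastolic velocity, cm/s.
#' @param systolic_fraction Fraction of the cycle occupied by the systolic
#'   upstroke (0-1 exclusive).
#' @param decay_rate Dimensionless rate of the diastolic exponential decay.
#' @param duration Total signal duration, seconds.
#' @param sample_rate Sampling rate, Hz; must be at least 10 samples/beat.
#' @param absent_edv_fraction Fraction of beats whose end-diastolic velocity
#'   is forced to zero (absent end-diastolic flow).
#' @param reversed_edv If `TRUE`, flagged beats instead end in reversed
#'   (negative) flow at `-0.1 * psv`.
#' @return A list of class `"waveform_spec"`.
#' @export
waveform_spec <- function(fhr = 140, psv = 52.2, edv = 20,
                          systolic_fraction = 0.3, decay_rate = 3,
                          duration = 10, sample_rate = 500,
                          absent_edv_fraction = 0, reversed_edv = FALSE) {
  if (!is.finite(fhr) || fhr < 30 || fhr > 300) {
    stop("`fhr` must be within [30, 300] bpm", call. = FALSE)
  }
  stopifnot(psv > 0, psv >= edv, systolic_fraction > 0, systolic_fraction < 1,
            duration > 0, absent_edv_fraction >= 0, absent_edv_fraction <= 1)
  if (sample_rate < 10 * fhr / 60) {
    stop("`sample_rate` must be at least 10 samples per beat", call. = FALSE)
  }
  structure(
    list(fhr = fhr, psv = psv, edv = edv,
         systolic_fraction = systolic_fraction, decay_rate = decay_rate,
         duration = duration, sample_rate = sample_rate,
         absent_edv_fraction = absent_edv_fraction,
         reversed_edv = reversed_edv),
    class = "waveform_spec")
}

# Deterministic per-beat plan: which beats carry absent/reversed EDV and the
# per-beat end-diastolic velocity. Exactly round(fraction * n) beats are
# flagged, chosen by a seeded draw.
beat_plan <- function(spec, n_beats, seed) {
  edv_beat <- rep(spec$edv, n_beats)
  flagged <- rep(FALSE, n_beats)
  n_abs <- round(spec$absent_edv_fraction * n_beats)
  if (n_abs > 0) {
    idx <- with_seed(seed, sample.int(n_beats, n_abs))
    flagged[idx] <- TRUE
    edv_beat[idx] <- if (isTRUE(spec$reversed_edv)) -0.1 * spec$psv else 0
  }
  tibble::tibble(beat = seq_len(n_beats), edv = edv_beat, flagged = flagged)
}

# Analytic waveform velocity at arbitrary times, given the per-beat EDV plan.
# The upstroke of beat b rises from the previous beat's EDV (the waveform is
# continuous across cycle boundaries); the decay ends at beat b's own EDV.
# Times past the planned beats reuse the last beat's EDV.
waveform_velocity <- function(spec, t, plan) {
  period <- 60 / spec$fhr
  a <- spec$systolic_fraction
  k <- spec$decay_rate
  b <- pmin(floor(t / period) + 1, nrow(plan))
  u <- t %% period / period
  edv_end <- plan$edv[b]
  edv_start <- plan$edv[pmax(b - 1, 1)]
  v <- numeric(length(t))
  rise <- u <= a
  g_r <- 0.5 * (1 - cos(pi * u[rise] / a))
  v[rise] <- edv_start[rise] + (spec$psv - edv_start[rise]) * g_r
  s <- (u[!rise] - a) / (1 - a)
  g_d <- (exp(-k * s) - exp(-k)) / (1 - exp(-k))
  v[!rise] <- edv_end[!rise] + (spec$psv - edv_end[!rise]) * g_d
  v
}

#' Generate a synthetic umbilical-artery velocity waveform
#'
#' Samples the analytic waveform on a uniform time grid. Within each complete
#' cycle the sample nearest the systolic peak is pinned to the exact PSV and
#' the final sample of the cycle to the exact per-beat EDV, so per-cycle
#' extrema equal the specified values to machine precision. Beats flagged by
#' `absent_edv_fraction` have their EDV forced to 0 (or to reversed flow).
#'
#' @param spec A [waveform_spec()].
#' @param seed Integer seed controlling the absent-EDV beat assignment.
#' @return A list of class `"ua_waveform"` with elements `signal` (tibble:
#'   `time_s`, `velocity_cms`), `beats` (ground-truth tibble: `beat`,
#'   `start_s`, `end_s`, `psv`, `edv`, `tav`, `fhr`, `edv_absent`),
#'   `spec`, and `seed`. `tav` is the trapezoidal time average over the cycle.
#' @export
generate_waveform <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "waveform_spec"))
  period <- 60 / spec$fhr
  n_beats <- floor(spec$duration / period + 1e-9)
  if (n_beats < 1) stop("`duration` must cover at least one beat", call. = FALSE)
  plan <- beat_plan(spec, n_beats, seed)

  dt <- 1 / spec$sample_rate
  t <- seq(0, spec$duration, by = dt)
  v <- waveform_velocity(spec, t, plan)

  starts <- (plan$beat - 1) * period
  peaks <- starts + spec$systolic_fraction * period
  ends <- plan$beat * period
  # pin the per-cycle extrema to the exact specified values
  i_peak <- pmin(round(peaks / dt) + 1, length(t))
  i_end <- pmin(round(ends / dt) + 1, length(t))
  v[i_peak] <- spec$psv
  v[i_end] <- plan$edv
  v[1] <- plan$edv[1]

  tav <- vapply(seq_len(n_beats), function(b) {
    i0 <- round(starts[b] / dt) + 1
    i1 <- i_end[b]
    trapz_mean(t[i0:i1], v[i0:i1])
  }, numeric(1))

  beats <- tibble::tibble(
    beat = plan$beat, start_s = starts, end_s = ends,
    psv = spec$psv, edv = plan$edv, tav = tav, fhr = spec$fhr,
    edv_absent = plan$flagged & !isTRUE(spec$reversed_edv),
    edv_reversed = plan$flagged & isTRUE(spec$reversed_edv))

  structure(
    list(signal = tibble::tibble(time_s = t, velocity_cms = v),
         beats = beats, spec = spec, seed = seed),
    class = "ua_waveform")
}

# time average by trapezoidal rule over one cycle
trapz_mean <- function(t, v) {
  n <- length(t)
  sum(diff(t) * (v[-1] + v[-n]) / 2) / (t[n] - t[1])
}

#' @export
print.ua_waveform <- function(x, ...) {
  cat("<ua_waveform> ", nrow(x$beats), " beats, FHR ", x$spec$fhr,
      " bpm, PSV ", x$spec$psv, " cm/s, EDV ", x$spec$edv, " cm/s, ",
      x$spec$duration, " s @ ", x$spec$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

# Evaluate a seeded draw without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation: one user-facing seed per run, distinct
# streams per stage. Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 31859 + 7919 * k) %% 2147483647L
}
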