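#' Extract the maximum-velocity envelope from a spectrogram
#'
#' For each time column the envelope is the velocity bin at which the
#' cumulative above-noise-floor power, accumulated from zero velocity outward
#' on the flow-direction side, reaches `power_fraction` of that side's total.
#' The flow-direction side (positive or negative velocities) is chosen per
#' run as the side holding the majority of above-floor power; columns whose
#' power sits mostly on the opposite side (reversed or aliased flow) are
#' traced there with the opposite sign. The trace is smoothed by a moving
#' median. The estimate is scale-free: multiplying the spectrogram power by
#' a constant leaves the envelope unchanged.
#'
#' @param spg A `doppler_spectrogram`.
#' @param power_fraction Cumulative-power fraction defining the envelope
#'   (default 0.95).
#' @param smooth_window Moving-median window in time bins (odd; `<= 1`
#'   disables smoothing).
#' @param noise_floor Power floor subtracted before accumulation. `NULL`
#'   uses the spectrogram's own recorded floor when present, else the
#'   per-column median power.
#' @return A tibble of class `"doppler_envelope"`: `time_s`, `velocity_cms`,
#'   `flagged` (TRUE where the column was indistinguishable from noise and
#'   the envelope set to 0). Attributes: `nyquist`, `bin_width`, `side`.
#' @export
extract_envelope <- function(spg, power_fraction = 0.95, smooth_window = 3,
                             noise_floor = NULL) {
  stopifnot(inherits(spg, "doppler_spectrogram"),
            power_fraction > 0, power_fraction <= 1)
  p <- spg$power
  axis <- spg$velocity_axis
  n_t <- ncol(p)
  floor_val <- noise_floor %||% spg$noise_floor %||% 0
  above <- if (length(floor_val) == 1 && floor_val == 0 && is.null(noise_floor) &&
               is.null(spg$noise_floor)) {
    sweep(p, 2, apply(p, 2, stats::median), `-`)
  } else {
    p - floor_val
  }
  above[above < 0] <- 0
  # small tolerance so numerically-flat columns count as noise
  tol <- 1e-9 * max(above, 1e-300)

  pos <- axis > 0
  neg <- axis < 0
  side <- if (sum(above[pos, , drop = FALSE]) >= sum(above[neg, , drop = FALSE])) 1 else -1

  env <- numeric(n_t)
  flagged <- logical(n_t)
  ord_pos <- which(axis >= 0)          # from 0 outward
  ord_neg <- rev(which(axis <= 0))     # from 0 outward (towards -Nyquist)
  prim <- if (side > 0) ord_pos else ord_neg
  seco <- if (side > 0) ord_neg else ord_pos
  for (j in seq_len(n_t)) {
    col <- above[, j]
    pw_prim <- sum(col[prim]); pw_seco <- sum(col[seco])
    use <- if (pw_seco > pw_prim) seco else prim
    tot <- max(pw_prim, pw_seco)
    if (tot <= tol) {
      env[j] <- 0
      flagged[j] <- TRUE
      next
    }
    cum <- cumsum(col[use])
    k <- which(cum >= power_fraction * tot)[1]
    env[j] <- axis[use[k]]
  }
  if (smooth_window > 1) {
    k <- smooth_window + (smooth_window %% 2 == 0)  # force odd
    if (k < length(env)) env <- stats::runmed(env, k, endrule = "median")
  }
  out <- tibble::tibble(time_s = spg$time, velocity_cms = as.numeric(env),
                        flagged = flagged)
  class(out) <- c("doppler_envelope", class(out))
  attr(out, "nyquist") <- spg$nyquist
  attr(out, "bin_width") <- axis[2] - axis[1]
  attr(out, "side") <- side
  out
}

#' Detect beats on a velocity envelope
#'
#' Systolic peaks are located by prominence-based peak picking with a minimum
#' separation of `60/max(fhr_band)` seconds. Each peak-to-peak span is one
#' beat: PSV is the cycle maximum, EDV the envelope value immediately before
#' the next systolic upstroke (the foot of the following rise, robust to
#' dicrotic notches), TAV the cycle mean, and FHR `60/interval`. Beats whose
#' rate falls outside the physiological band are rejected.
#'
#' @param env A `doppler_envelope` (or tibble with `time_s`,
#'   `velocity_cms`).
#' @param fhr_band Allowed fetal-heart-rate band, bpm (default 60-240).
#' @param min_prominence Minimum peak prominence in cm/s; `NULL` uses 30% of
#'   the envelope's 2nd-98th percentile span.
#' @param edv_zero_threshold EDV at or below this value (cm/s) is flagged
#'   absent (default 2).
#' @return A tibble (`beat_table`): `beat`, `start_s`, `end_s`, `psv`,
#'   `edv`, `tav`, `interval_s`, `fhr`, `edv_absent`, `edv_reversed`.
#' @export
detect_beats <- function(env, fhr_band = c(60, 240), min_prominence = NULL,
                         edv_zero_threshold = 2) {
  env <- tibble::as_tibble(env)
  stopifnot(all(c("time_s", "velocity_cms") %in% names(env)))
  t <- env$time_s
  v <- env$velocity_cms
  if (max(t) - min(t) < 2) {
    stop("envelope must span at least 2 seconds", call. = FALSE)
  }
  dt <- stats::median(diff(t))
  min_sep <- max(1L, floor(60 / max(fhr_band) / dt))
  if (is.null(min_prominence)) {
    span <- diff(stats::quantile(v, c(0.02, 0.98), names = FALSE))
    min_prominence <- 0.3 * span
  }
  pk <- find_peaks(v, min_sep = min_sep, min_prominence = min_prominence)
  if (length(pk) < 2) {
    stop(structure(class = c("no_beats", "error", "condition"),
                   list(message = "fewer than 2 systolic peaks detected (non-pulsatile gate placement)",
                        call = NULL)))
  }
  beats <- vector("list", length(pk) - 1)
  for (b in seq_len(length(pk) - 1)) {
    i0 <- pk[b]; i1 <- pk[b + 1]
    interval <- t[i1] - t[i0]
    # foot of the next systolic upstroke: walk back from the next peak
    # while the envelope is non-increasing backwards
    j <- i1
    while (j > i0 + 1 && v[j - 1] <= v[j]) j <- j - 1
    cyc <- i0:(i1 - 1)
    edv <- v[j]
    beats[[b]] <- tibble::tibble(
      start_s = t[i0], end_s = t[i1],
      psv = max(v[cyc]), edv = edv, tav = mean(v[cyc]),
      interval_s = interval, fhr = 60 / interval)
  }
  out <- dplyr::bind_rows(beats) |>
    dplyr::filter(.data$fhr >= fhr_band[1], .data$fhr <= fhr_band[2]) |>
    dplyr::mutate(beat = dplyr::row_number(),
                  edv_absent = .data$edv <= edv_zero_threshold,
                  edv_reversed = .data$edv < 0, .before = 1) |>
    dplyr::relocate("beat")
  out
}

# Local maxima with plateau handling, greedy minimum separation (highest
# first) and a prominence filter.
find_peaks <- function(v, min_sep = 1, min_prominence = 0) {
  n <- length(v)
  if (n < 3) return(integer())
  # compress plateaus: candidate = centre of a run higher than both sides
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- integer()
  for (i in seq_along(r$values)) {
    left <- if (i == 1) -Inf else r$values[i - 1]
    right <- if (i == length(r$values)) -Inf else r$values[i + 1]
    if (r$values[i] > left && r$values[i] > right) {
      cand <- c(cand, floor((starts[i] + ends[i]) / 2))
    }
  }
  if (!length(cand)) return(integer())
  # prominence: lowest descent to the higher neighbouring terrain
  keep <- vapply(cand, function(p) {
    higher_l <- which(v[seq_len(p - 1)] > v[p])
    lo_l <- if (length(higher_l)) min(v[(max(higher_l) + 1):(p - 1)], v[p]) else min(v[seq_len(p)])
    higher_r <- which(v[(p + 1):n] > v[p]) + p
    lo_r <- if (length(higher_r)) min(v[(p + 1):(min(higher_r) - 1)], v[p]) else min(v[p:n])
    v[p] - max(lo_l, lo_r) >= min_prominence
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand)) return(integer())
  # greedy separation, highest peaks first
  ord <- cand[order(v[cand], decreasing = TRUE)]
  sel <- integer()
  for (p in ord) {
    if (!length(sel) || all(abs(sel - p) >= min_sep)) sel <- c(sel, p)
  }
  sort(sel)
}

#' Fraction of beats with absent end-diastolic flow
#'
#' @param beats A beat table from [detect_beats()] (needs an `edv` column).
#' @param edv_zero_threshold EDV at or below this (cm/s) counts as absent.
#' @return The fraction of beats with absent EDV.
#' @export
absent_edv_fraction <- function(beats, edv_zero_threshold = 2) {
  if (!is.data.frame(beats) || nrow(beats) == 0 || !"edv" %in% names(beats)) {
    stop("`beats` must be a nonempty beat table with an `edv` column",
         call. = FALSE)
  }
  mean(beats$edv <= edv_zero_threshold)
}

#' Detect fetal heart rate accelerations
#'
#' Events where the FHR exceeds a rolling-median baseline by at least
#' `rise_threshold` for at least `min_duration` — the standard
#' cardiotocography definition (15 bpm for 15 s).
#'
#' @param fhr_series Tibble with `time_s` and `fhr_bpm` columns (uniformly
#'   or near-uniformly sampled).
#' @param baseline_window Rolling-median window, seconds (default 600).
#' @param rise_threshold Required rise over baseline, bpm (default 15).
#' @param min_duration Minimum event duration, seconds (default 15).
#' @return A tibble: `start_s`, `end_s`, `duration_s`, `peak_bpm`,
#'   `rise_bpm`; zero rows when no accelerations occur.
#' @export
detect_accelerations <- function(fhr_series, baseline_window = 600,
                                 rise_threshold = 15, min_duration = 15) {
  stopifnot(is.data.frame(fhr_series),
            all(c("time_s", "fhr_bpm") %in% names(fhr_series)))
  t <- fhr_series$time_s
  f <- fhr_series$fhr_bpm
  dt <- stats::median(diff(t))
  k <- max(3L, floor(baseline_window / dt))
  k <- min(k, length(f))
  k <- k - (1 - k %% 2)                       # odd
  baseline <- if (k >= 3 && k <= length(f)) {
    stats::runmed(f, k, endrule = "median")
  } else {
    rep(stats::median(f), length(f))
  }
  over <- f >= baseline + rise_threshold
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- which(r$values)
  out <- lapply(ev, function(i) {
    i0 <- starts[i]; i1 <- ends[i]
    dur <- t[i1] - t[i0] + dt
    if (dur < min_duration) return(NULL)
    tibble::tibble(start_s = t[i0], end_s = t[i1], duration_s = dur,
                   peak_bpm = max(f[i0:i1]),
                   rise_bpm = max(f[i0:i1] - baseline[i0:i1]))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          duration_s = numeric(), peak_bpm = numeric(),
                          rise_bpm = numeric())
  }
  out
}
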