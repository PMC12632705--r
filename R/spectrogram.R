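#' Synthesize a spectral-Doppler spectrogram from a velocity waveform
#'
#' Builds a time x velocity power matrix: at each time bin a Gaussian ridge is
#' centred on the (alias-wrapped) instantaneous waveform velocity, with a
#' configurable spectral broadening, constant noise floor and optional
#' multiplicative speckle noise. The velocity axis spans +/- the Nyquist
#' velocity implied by the acquisition constants,
#' \deqn{v_{Nyq} = \frac{PRF}{2}\,\frac{c}{2 f_0 \cos\theta},}
#' and velocities beyond it wrap to the opposite side of the scale.
#'
#' @param wave A [ua_waveform()][generate_waveform] object, or a list/tibble
#'   with `time_s` and `velocity_cms` columns.
#' @param prf Pulse repetition frequency, Hz (default 3000).
#' @param carrier_mhz Transmit carrier, MHz (default 2.5).
#' @param angle_deg Doppler insonation angle, degrees (default 0; 90 is
#'   invalid).
#' @param sound_speed Speed of sound, m/s (default 1540).
#' @param n_velocity Number of velocity bins (odd so 0 is a bin centre).
#' @param time_step Spectrogram column spacing, s.
#' @param broadening_sd Spectral broadening SD, cm/s. `0` concentrates each
#'   column's signal power in the single nearest velocity bin.
#' @param noise_floor Constant additive power floor (power units).
#' @param noise_sd SD of multiplicative speckle-like noise on the signal
#'   ridge (0 disables).
#' @param seed Integer seed for the noise draws.
#' @return A list of class `"doppler_spectrogram"`: `power`
#'   `[n_velocity x n_time]`, `velocity_axis` (cm/s), `time` (s), plus the
#'   acquisition metadata (`prf`, `carrier_mhz`, `angle_deg`, `sound_speed`,
#'   `nyquist`, `time_step`).
#' @export
synthesize_spectrogram <- function(wave, prf = 3000, carrier_mhz = 2.5,
                                   angle_deg = 0, sound_speed = 1540,
                                   n_velocity = 513, time_step = 0.002,
                                   broadening_sd = 1, noise_floor = 0,
                                   noise_sd = 0, seed = 0) {
  stopifnot(prf > 0, carrier_mhz > 0, n_velocity >= 3)
  if (abs(cos(angle_deg * pi / 180)) < 1e-9) {
    stop("Doppler angle of 90 degrees has no velocity projection", call. = FALSE)
  }
  sig <- if (inherits(wave, "ua_waveform")) wave$signal else tibble::as_tibble(wave)
  stopifnot(all(c("time_s", "velocity_cms") %in% names(sig)))

  vnyq <- nyquist_velocity(prf, carrier_mhz, angle_deg, sound_speed)
  axis <- seq(-vnyq, vnyq, length.out = n_velocity)
  dv <- axis[2] - axis[1]

  t_out <- seq(min(sig$time_s), max(sig$time_s), by = time_step)
  v_t <- stats::approx(sig$time_s, sig$velocity_cms, xout = t_out)$y
  v_w <- wrap_nyquist(v_t, vnyq)

  if (broadening_sd > 0) {
    # ridge: Gaussian in velocity, unit peak power
    power <- exp(-outer(axis, v_w, "-")^2 / (2 * broadening_sd^2))
    power[power < 1e-12] <- 0
  } else {
    power <- matrix(0, n_velocity, length(t_out))
    idx <- pmin(pmax(round((v_w + vnyq) / dv) + 1, 1), n_velocity)
    power[cbind(idx, seq_along(t_out))] <- 1
  }
  if (noise_sd > 0) {
    power <- power * with_seed(seed, matrix(
      pmax(0, stats::rnorm(length(power), 1, noise_sd)), nrow(power)))
  }
  power <- power + noise_floor

  structure(
    list(power = power, velocity_axis = axis, time = t_out,
         time_step = time_step, prf = prf, carrier_mhz = carrier_mhz,
         angle_deg = angle_deg, sound_speed = sound_speed,
         nyquist = vnyq, noise_floor = noise_floor),
    class = "doppler_spectrogram")
}

#' Nyquist velocity of a pulsed-Doppler acquisition
#'
#' @param prf Pulse repetition frequency, Hz.
#' @param carrier_mhz Carrier frequency, MHz.
#' @param angle_deg Insonation angle, degrees.
#' @param sound_speed Speed of sound, m/s.
#' @return Nyquist velocity in cm/s.
#' @examples
#' nyquist_velocity(3000, 2.5)  # 46.2 cm/s
#' @export
nyquist_velocity <- function(prf, carrier_mhz, angle_deg = 0,
                             sound_speed = 1540) {
  stopifnot(prf > 0, carrier_mhz > 0)
  ct <- cos(angle_deg * pi / 180)
  if (abs(ct) < 1e-9) stop("angle of 90 degrees is invalid", call. = FALSE)
  (prf / 2) * (sound_speed * 100) / (2 * carrier_mhz * 1e6 * ct)
}

#' @export
print.doppler_spectrogram <- function(x, ...) {
  cat("<doppler_spectrogram> ", length(x$velocity_axis), " velocity bins x ",
      length(x$time), " time bins, Nyquist ", round(x$nyquist, 2),
      " cm/s (PRF ", x$prf, " Hz, ", x$carrier_mhz, " MHz)\n", sep = "")
  invisible(x)
}
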