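#' Hydrophone sensitivity conversions
#'
#' `sensitivity_from_db()` converts an end-of-cable open-circuit sensitivity
#' in dB re 1 V/uPa to V/Pa: `10^((M_dB + 120) / 20)`.
#' `loaded_sensitivity()` applies the preamplifier gain and the capacitive
#' voltage divider formed by the hydrophone, preamplifier and right-angle
#' adapter:
#' \deqn{M_L = G \, M_C \, \frac{C_H}{C_H + C_A + C_C}.}
#'
#' @param mc_db Sensitivity in dB re 1 V/uPa.
#' @return `sensitivity_from_db()`: sensitivity in V/Pa.
#' @examples
#' sensitivity_from_db(-260)  # 1e-7 V/Pa
#' @export
sensitivity_from_db <- function(mc_db) {
  stop_if_not_finite(mc_db, "mc_db")
  10^((mc_db + 120) / 20)
}

#' @rdname sensitivity_from_db
#' @param mc Open-circuit sensitivity, V/Pa.
#' @param gain_db Preamplifier gain in dB (default 20, i.e. x10).
#' @param ch_pf,ca_pf,cc_pf Capacitances (pF) of the hydrophone,
#'   preamplifier and right-angle adapter; defaults 70, 7 and 1.6 pF.
#' @return `loaded_sensitivity()`: loaded sensitivity in V/Pa.
#' @export
loaded_sensitivity <- function(mc, gain_db = 20, ch_pf = 70, ca_pf = 7,
                               cc_pf = 1.6) {
  stopifnot(mc > 0, ch_pf > 0, ca_pf >= 0, cc_pf >= 0)
  g <- 10^(gain_db / 20)
  g * mc * ch_pf / (ch_pf + ca_pf + cc_pf)
}

#' Acoustic intensity metrics from a pressure waveform
#'
#' Instantaneous intensity `p^2 / (rho c)`; the pulse-intensity integral
#' (PII) is its time integral over one pulse. The pulse duration follows the
#' regulatory convention `1.25 x (t90 - t10)`, where t10/t90 bracket the
#' central 90% (specifically the 10%-90% span) of the cumulative PII.
#' I_sppa is `PII / pulse_duration`; I_spta is `PII x PRF` (equivalently
#' I_sppa times the duty factor); the peak rarefactional pressure is
#' `-min(p)`.
#'
#' @param pressure Pressure waveform of one pulse, Pa.
#' @param time Sample times, s (same length), or a scalar sampling interval.
#' @param density Medium density, kg/m^3 (default 1000).
#' @param sound_speed Speed of sound, m/s (default 1540).
#' @param prf Pulse repetition frequency, Hz.
#' @param window_fracs Cumulative-energy fractions bracketing the pulse
#'   (default `c(0.1, 0.9)`).
#' @param duration_factor Multiplier on the bracketed span (default 1.25).
#' @return A tibble: `isppa_wcm2`, `ispta_mwcm2`, `pr_mpa`,
#'   `pulse_duration_s`, `pii_j_cm2`.
#' @export
intensity_metrics <- function(pressure, time, density = 1000,
                              sound_speed = 1540, prf,
                              window_fracs = c(0.1, 0.9),
                              duration_factor = 1.25) {
  if (density <= 0 || sound_speed <= 0) {
    stop("`density` and `sound_speed` must be positive", call. = FALSE)
  }
  stopifnot(prf > 0)
  if (length(time) == 1) {
    time <- (seq_along(pressure) - 1) * time
  }
  stopifnot(length(time) == length(pressure))
  ii <- pressure^2 / (density * sound_speed) / 1e4   # W/cm^2
  n <- length(ii)
  seg <- diff(time) * (ii[-1] + ii[-n]) / 2
  pii <- sum(seg)                                     # J/cm^2 (one pulse)
  if (pii <= 0) stop("waveform carries no energy", call. = FALSE)
  cum <- c(0, cumsum(seg)) / pii
  t10 <- stats::approx(cum, time, xout = window_fracs[1], ties = "ordered")$y
  t90 <- stats::approx(cum, time, xout = window_fracs[2], ties = "ordered")$y
  pd <- duration_factor * (t90 - t10)
  tibble::tibble(
    isppa_wcm2 = pii / pd,
    ispta_mwcm2 = pii * prf * 1000,
    pr_mpa = -min(pressure) / 1e6,
    pulse_duration_s = pd,
    pii_j_cm2 = pii)
}

#' Derate a pressure or intensity value for soft-tissue attenuation
#'
#' Applies the standard derating `A = coeff x depth x f` dB
#' (0.3 dB/(cm MHz) by default): pressures scale by `10^(-A/20)`,
#' intensities by `10^(-A/10)`.
#'
#' @param value Measured value(s) at depth (water-tank).
#' @param depth_cm Depth, cm (>= 0).
#' @param carrier_mhz Carrier frequency, MHz.
#' @param coeff Derating coefficient, dB/(cm MHz).
#' @param kind `"intensity"` or `"pressure"`.
#' @return The derated value(s).
#' @export
derate <- function(value, depth_cm, carrier_mhz, coeff = 0.3,
                   kind = c("intensity", "pressure")) {
  kind <- match.arg(kind)
  if (any(depth_cm < 0)) stop("`depth_cm` must be >= 0", call. = FALSE)
  a_db <- coeff * depth_cm * carrier_mhz
  value * 10^(-a_db / ifelse(kind == "pressure", 20, 10))
}

#' Mechanical index
#'
#' `MI = p_r / sqrt(f)` with the derated peak rarefactional pressure in MPa
#' and the carrier frequency in MHz.
#'
#' @param pr_mpa Derated peak rarefactional pressure, MPa (>= 0).
#' @param carrier_mhz Carrier frequency, MHz (> 0).
#' @return The mechanical index (dimensionless).
#' @examples
#' mechanical_index(0.6, 2.5)  # ~0.38
#' @export
mechanical_index <- function(pr_mpa, carrier_mhz) {
  stopifnot(all(pr_mpa >= 0), carrier_mhz > 0)
  pr_mpa / sqrt(carrier_mhz)
}

#' Acoustic power from a transverse plane scan
#'
#' Integrates intensity over the beam cross-section: pixels whose intensity
#' is within `cutoff_db` of the plane peak (-26.2 dB by default) contribute
#' `intensity x pixel area`.
#'
#' @param intensity Matrix of time-averaged intensities on the scan plane,
#'   W/cm^2.
#' @param spacing_mm Scan grid spacing, mm (isotropic).
#' @param cutoff_db Inclusion threshold relative to the peak, dB (negative;
#'   `-Inf` integrates the full plane).
#' @return Acoustic power in mW (0 with a warning for an all-zero plane).
#' @export
power_from_plane <- function(intensity, spacing_mm, cutoff_db = -26.2) {
  stopifnot(is.matrix(intensity), spacing_mm > 0)
  peak <- max(intensity)
  if (peak <= 0) {
    warning("all-zero intensity plane: zero power")
    return(0)
  }
  mask <- intensity >= peak * 10^(cutoff_db / 10)
  area_cm2 <- (spacing_mm / 10)^2
  sum(intensity[mask]) * area_cm2 * 1000
}
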