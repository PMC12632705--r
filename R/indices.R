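#' Doppler hemodynamic indices
#'
#' Vectorised calculators for the three umbilical-artery Doppler indices used
#' in obstetric practice. All velocities are in cm/s; the indices themselves
#' are dimensionless.
#'
#' * systolic-to-diastolic ratio: `PSV / EDV`, defined only for `EDV > 0`.
#'   When end-diastolic flow is absent (`EDV == 0`) or reversed (`EDV < 0`)
#'   the ratio is returned as `NA` — an explicit absent-EDV marker, never a
#'   division result.
#' * resistance index: `(PSV - EDV) / PSV`. Equals `1 - 1/(S/D)` for positive
#'   EDV, exactly 1 for absent EDV, and exceeds 1 for reversed EDV.
#' * pulsatility index: `(PSV - EDV) / TAV`, with TAV the time-averaged
#'   velocity over one cardiac cycle.
#'
#' @param psv Peak systolic velocity (cm/s). Must be finite; positive for
#'   `resistance_index()`.
#' @param edv End diastolic velocity (cm/s). May be zero (absent) or negative
#'   (reversed).
#' @param tav Time-averaged velocity over the cycle (cm/s); must be positive.
#' @return A numeric vector the length of the inputs.
#' @examples
#' sd_ratio(52.2, 20)        # 2.61
#' resistance_index(52.2, 20) # 0.617
#' pulsatility_index(60, 20, 30)
#' @name doppler-indices
NULL

#' @rdname doppler-indices
#' @export
sd_ratio <- function(psv, edv) {
  stop_if_not_finite(psv, "psv")
  stop_if_not_finite(edv, "edv")
  ifelse(edv > 0, psv / edv, NA_real_)
}

#' @rdname doppler-indices
#' @export
resistance_index <- function(psv, edv) {
  stop_if_not_finite(psv, "psv")
  stop_if_not_finite(edv, "edv")
  if (any(psv <= 0)) {
    stop("`psv` must be > 0 to compute the resistance index", call. = FALSE)
  }
  (psv - edv) / psv
}

#' @rdname doppler-indices
#' @export
pulsatility_index <- function(psv, edv, tav) {
  stop_if_not_finite(psv, "psv")
  stop_if_not_finite(edv, "edv")
  stop_if_not_finite(tav, "tav")
  if (any(tav <= 0)) {
    stop("`tav` must be > 0 to compute the pulsatility index", call. = FALSE)
  }
  (psv - edv) / tav
}

#' Cerebroplacental ratio
#'
#' Ratio of the middle cerebral artery pulsatility index to the umbilical
#' artery pulsatility index; values below ~1 indicate brain-sparing
#' redistribution.
#'
#' @param pi_mca Pulsatility index of the middle cerebral artery.
#' @param pi_ua Pulsatility index of the umbilical artery; must be positive.
#' @return Numeric vector of CPR values.
#' @export
cerebroplacental_ratio <- function(pi_mca, pi_ua) {
  stop_if_not_finite(pi_mca, "pi_mca")
  stop_if_not_finite(pi_ua, "pi_ua")
  if (any(pi_ua <= 0)) {
    stop("`pi_ua` must be > 0 to compute the cerebroplacental ratio",
         call. = FALSE)
  }
  pi_mca / pi_ua
}

#' Add Doppler indices to a table of per-beat velocity summaries
#'
#' Data-frame-first wrapper: takes a table with `psv`, `edv` and (optionally)
#' `tav` columns and appends `sd_ratio`, `ri` and, when `tav` is present,
#' `pi`. Absent/reversed-EDV beats get `sd_ratio = NA`.
#'
#' @param data A data frame with numeric columns `psv`, `edv` and optionally
#'   `tav` (all cm/s).
#' @return The input as a tibble with index columns appended.
#' @examples
#' doppler_indices(data.frame(psv = c(52.2, 50), edv = c(20, 0), tav = c(30, 25)))
#' @export
doppler_indices <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("psv", "edv") %in% names(data))) {
    stop("`data` must contain `psv` and `edv` columns", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$sd_ratio <- sd_ratio(out$psv, out$edv)
  out$ri <- resistance_index(out$psv, out$edv)
  if ("tav" %in% names(out)) {
    out$pi <- pulsatility_index(out$psv, out$edv, out$tav)
  }
  out
}

#' Hadlock-IV estimated fetal weight
#'
#' Evaluates the four-parameter Hadlock regression on fetal biometry. The
#' regression is linear in log10 of the weight in grams:
#'
#' \deqn{\log_{10} EFW = 1.3596 - 0.00386\,AC \cdot FL + 0.0064\,HC +
#'   0.00061\,BPD \cdot AC + 0.0424\,AC + 0.174\,FL}
#'
#' with all biometry in centimetres. The estimated weight is
#' `10^log_weight` grams.
#'
#' @param data Optional data frame with columns `bpd`, `hc`, `ac`, `fl` (cm).
#'   When supplied the vectors are taken from it and the result is the input
#'   tibble with `log_weight` and `efw_g` appended.
#' @param bpd,hc,ac,fl Biparietal diameter, head circumference, abdominal
#'   circumference and femur length in cm; used when `data` is NULL.
#' @return A tibble with `log_weight` (dimensionless, log10 grams) and
#'   `efw_g` (grams).
#' @examples
#' hadlock_efw(bpd = 8.5, hc = 31, ac = 30, fl = 6.5)
#' @export
hadlock_efw <- function(data = NULL, bpd = NULL, hc = NULL, ac = NULL, fl = NULL) {
  if (!is.null(data)) {
    stopifnot(is.data.frame(data))
    need <- c("bpd", "hc", "ac", "fl")
    if (!all(need %in% names(data))) {
      stop("`data` must contain columns bpd, hc, ac, fl", call. = FALSE)
    }
    bpd <- data$bpd; hc <- data$hc; ac <- data$ac; fl <- data$fl
  }
  for (nm in c("bpd", "hc", "ac", "fl")) {
    v <- get(nm)
    stop_if_not_finite(v, nm)
    if (any(v < 0)) stop("`", nm, "` must be >= 0 (cm)", call. = FALSE)
  }
  log_weight <- 1.3596 - 0.00386 * ac * fl + 0.0064 * hc +
    0.00061 * bpd * ac + 0.0424 * ac + 0.174 * fl
  res <- tibble::tibble(log_weight = log_weight, efw_g = 10^log_weight)
  if (!is.null(data)) {
    return(dplyr::bind_cols(tibble::as_tibble(data), res))
  }
  res
}

stop_if_not_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x))) {
    stop("`", name, "` must be finite numeric", call. = FALSE)
  }
  invisible(x)
}
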