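#' Pixel spacing of a reconstructed image
#'
#' Distance between adjacent pixel centres given the physical extent of the
#' image: `depth / (n_axial - 1)` axially and analogously laterally.
#'
#' @param depth Imaging depth (axial extent), mm.
#' @param n_axial,n_lateral Pixel counts along each direction (>= 2).
#' @param width Lateral extent, mm (defaults to `depth`).
#' @return A tibble with `dy_mm` (axial) and `dx_mm` (lateral) spacings.
#' @examples
#' pixel_spacing(100, 101, 101)  # 1 mm in both directions
#' @export
pixel_spacing <- function(depth, n_axial, n_lateral, width = depth) {
  stopifnot(depth > 0, width > 0)
  if (n_axial < 2 || n_lateral < 2) {
    stop("pixel counts must be at least 2", call. = FALSE)
  }
  tibble::tibble(dy_mm = depth / (n_axial - 1),
                 dx_mm = width / (n_lateral - 1))
}

#' Spatial resolution from a point-spread profile (FWHM)
#'
#' Full width at half maximum of a 1-D intensity profile across a wire
#' target, with sub-sample linear interpolation at the half-maximum
#' crossings. The background level defaults to the median of the outer 20%
#' of samples on each tail. Invariant under intensity scaling and constant
#' offsets.
#'
#' @param profile Numeric intensity profile with a unique maximum.
#' @param spacing Sample spacing, mm.
#' @param background Background level; `NULL` estimates it from the tails.
#' @return FWHM resolution in mm.
#' @export
fwhm_resolution <- function(profile, spacing, background = NULL) {
  stopifnot(is.numeric(profile), length(profile) >= 3, spacing > 0)
  if (diff(range(profile)) == 0) {
    stop("flat profile: no peak", call. = FALSE)
  }
  if (is.null(background)) {
    k <- max(1, floor(0.2 * length(profile) / 2))
    background <- stats::median(c(utils::head(profile, k),
                                  utils::tail(profile, k)))
  }
  mx <- max(profile)
  at_max <- which(profile == mx)
  if (length(at_max) > 1 && any(diff(at_max) > 1)) {
    stop("no unique peak: profile has multiple separated maxima", call. = FALSE)
  }
  peak <- at_max[ceiling(length(at_max) / 2)]
  half <- background + (mx - background) / 2
  # left crossing
  il <- peak
  while (il > 1 && profile[il - 1] >= half) il <- il - 1
  xl <- if (il == 1) 1 else {
    (il - 1) + (half - profile[il - 1]) / (profile[il] - profile[il - 1])
  }
  ir <- peak
  n <- length(profile)
  while (ir < n && profile[ir + 1] >= half) ir <- ir + 1
  xr <- if (ir == n) n else {
    ir + (profile[ir] - half) / (profile[ir] - profile[ir + 1])
  }
  (xr - xl) * spacing
}

#' Contrast-to-noise ratio of a target region
#'
#' \deqn{CNR = \frac{\mu_{in} - \mu_{out}}{\sqrt{\sigma_{in}^2 +
#'   \sigma_{out}^2}}}
#' computed on displayed (log-compressed) pixel intensities. Invariant under
#' adding a constant to the whole image; scales out under multiplicative
#' gain.
#'
#' @param img Numeric matrix of displayed pixel intensities.
#' @param inside,outside Logical masks (same shape as `img`), disjoint and
#'   nonempty.
#' @return The CNR (dimensionless); `NA` with a warning when both regions
#'   have zero variance.
#' @export
cnr <- function(img, inside, outside) {
  stopifnot(is.matrix(img), identical(dim(img), dim(inside)),
            identical(dim(img), dim(outside)))
  if (!any(inside) || !any(outside)) {
    stop("both masks must be nonempty", call. = FALSE)
  }
  if (any(inside & outside)) stop("masks must be disjoint", call. = FALSE)
  mu_in <- mean(img[inside]); mu_out <- mean(img[outside])
  s_in <- stats::sd(img[inside]); s_out <- stats::sd(img[outside])
  if (is.na(s_in)) s_in <- 0
  if (is.na(s_out)) s_out <- 0
  if (s_in == 0 && s_out == 0) {
    warning("zero variance in both regions: CNR undefined")
    return(NA_real_)
  }
  (mu_in - mu_out) / sqrt(s_in^2 + s_out^2)
}

#' Dynamic range from greyscale contrast targets
#'
#' Least-squares line of displayed grey value against nominal target
#' contrast (dB); the dynamic range is the contrast span between
#' extrapolated grey values of 255 and 0, i.e. `255 / slope` dB. Invariant
#' to the ordering of the targets.
#'
#' @param target_means Mean grey values (0-255) of the contrast targets.
#' @param nominal_contrasts Nominal target contrasts, dB.
#' @return Dynamic range in dB.
#' @examples
#' dynamic_range(127.5 + 4.25 * c(-12, -6, 0, 6, 12, 18),
#'               c(-12, -6, 0, 6, 12, 18))  # 60 dB
#' @export
dynamic_range <- function(target_means, nominal_contrasts) {
  stopifnot(length(target_means) == length(nominal_contrasts))
  if (length(unique(nominal_contrasts)) < 2) {
    stop("need at least 2 targets with distinct contrasts", call. = FALSE)
  }
  fit <- stats::lm(target_means ~ nominal_contrasts)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0) {
    stop("singular fit: grey values do not vary with contrast", call. = FALSE)
  }
  255 / slope
}

#' Spectral-Doppler velocity accuracy against known velocities
#'
#' Percent error of measured velocities relative to nominal (pump-set)
#' velocities, per condition.
#'
#' @param measured,nominal Equal-length velocity vectors, cm/s; nominal
#'   values must be nonzero.
#' @return A tibble: `measured`, `nominal`, `error_pct`.
#' @export
doppler_velocity_accuracy <- function(measured, nominal) {
  if (length(measured) != length(nominal)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (any(nominal == 0)) {
    stop("nominal velocities must be nonzero", call. = FALSE)
  }
  tibble::tibble(measured = measured, nominal = nominal,
                 error_pct = (measured - nominal) / nominal * 100)
}
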