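#' Pulsatility map from a window of colour-Doppler frames
#'
#' Per-pixel population variance of the colour-Doppler intensity (|velocity|)
#' across several consecutive frames. Pulsatile arterial pixels vary over the
#' cardiac cycle while venous and background pixels do not, so the variance
#' map highlights the artery. The magnitude is used so that alias-wrapped
#' sign flips still register as pulsatile.
#'
#' @param frames A `duplex_sequence` or a 3-D array `[axial, lateral, frame]`
#'   of colour velocities (cm/s).
#' @param window Indices of the frames to use (default: all); length >= 2.
#' @param pixel_pitch Pixel pitch in mm (taken from the sequence when given).
#' @return A list of class `"pulsatility_map"`: `variance` matrix,
#'   `window_length`, `pixel_pitch`.
#' @export
pulsatility_map <- function(frames, window = NULL, pixel_pitch = NULL) {
  if (inherits(frames, "duplex_sequence")) {
    pixel_pitch <- frames$pixel_pitch
    frames <- frames$color
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (is.null(window)) window <- seq_len(dim(frames)[3])
  if (length(window) < 2) {
    stop("the variance window must contain at least 2 frames", call. = FALSE)
  }
  x <- abs(frames[, , window, drop = FALSE])
  n <- length(window)
  m <- rowMeans(x, dims = 2)
  m2 <- rowMeans(x^2, dims = 2)
  structure(
    list(variance = pmax(m2 - m^2, 0), window_length = n,
         pixel_pitch = pixel_pitch),
    class = "pulsatility_map")
}

#' Segment pulsatile regions of a pulsatility map
#'
#' Binarises the variance map (by Otsu's method by default, or at a fixed
#' fraction of its maximum), labels connected components, discards regions below the
#' minimum area, and returns the regions sorted by area, largest first.
#' Centroids are unweighted pixel-count means, converted to mm.
#'
#' @param map A [pulsatility_map()].
#' @param threshold_policy `"otsu"` (default) or `"fraction"` (of the map
#'   maximum). Otsu is the default because with a moving vessel the
#'   lumen/background mixture at the vessel rim can carry several times the
#'   lumen variance, and a fraction-of-max cut then excludes the lumen.
#' @param threshold Fraction of the maximum variance (default 0.3) when
#'   `threshold_policy = "fraction"`.
#' @param min_region_area Minimum region area in pixels (default 20).
#' @param connectivity 4 or 8 (default 8).
#' @return A tibble with one row per region: `label`, `area`,
#'   `mean_variance`, `lateral_mm`, `axial_mm`, sorted by decreasing area,
#'   with the label matrix in attribute `"labels"`. Empty (zero rows) when
#'   nothing exceeds the threshold.
#' @export
segment_pulsatile <- function(map, threshold_policy = c("otsu", "fraction"),
                              threshold = 0.3, min_region_area = 20,
                              connectivity = 8) {
  stopifnot(inherits(map, "pulsatility_map"))
  threshold_policy <- match.arg(threshold_policy)
  v <- map$variance
  cut <- if (threshold_policy == "fraction") {
    threshold * max(v)
  } else {
    otsu_threshold(v)
  }
  mask <- v > cut & v > 0
  empty <- tibble::tibble(label = integer(), area = integer(),
                          mean_variance = numeric(),
                          lateral_mm = numeric(), axial_mm = numeric())
  if (!any(mask)) {
    attr(empty, "labels") <- matrix(0L, nrow(v), ncol(v))
    return(empty)
  }
  labels <- label_components(mask, connectivity)
  pitch <- map$pixel_pitch %||% 1
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  regions <- tibble::tibble(
    label = lab,
    row = idx[, 1], col = idx[, 2],
    variance = v[labels > 0]) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      area = dplyr::n(),
      mean_variance = mean(.data$variance),
      lateral_mm = (mean(.data$col) - 1) * pitch,
      axial_mm = (mean(.data$row) - 1) * pitch) |>
    dplyr::filter(.data$area >= min_region_area) |>
    dplyr::arrange(dplyr::desc(.data$area))
  attr(regions, "labels") <- labels
  regions
}

# Connected-component labeling (4- or 8-connectivity) by iterative flood
# fill over the true pixels of a logical mask.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(c(-1, 0, 1), 3), rep(c(-1, 0, 1), each = 3))[-5, , drop = FALSE]
  }
  nextlab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    labels[start] <- nextlab
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      nbr_r <- r + offs[, 1]; nbr_c <- cc + offs[, 2]
      ok <- nbr_r >= 1 & nbr_r <= nr & nbr_c >= 1 & nbr_c <= nc
      q <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      q <- q[mask[q] & labels[q] == 0L]
      if (length(q)) {
        labels[q] <- nextlab
        stack <- c(stack, q)
      }
    }
  }
  labels
}

# Otsu's threshold on a numeric matrix (256-bin histogram)
otsu_threshold <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = 257),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Select the primary pulsatile region
#'
#' The primary region is the largest segmented area; ties are broken by the
#' higher mean variance, then by the shallower (smaller axial) centroid.
#'
#' @param regions Region tibble from [segment_pulsatile()].
#' @return A one-row tibble.
#' @export
select_primary <- function(regions) {
  if (!is.data.frame(regions) || nrow(regions) == 0) {
    stop_no_pulsatile_region()
  }
  regions |>
    dplyr::arrange(dplyr::desc(.data$area), dplyr::desc(.data$mean_variance),
                   .data$axial_mm) |>
    dplyr::slice(1)
}

stop_no_pulsatile_region <- function() {
  stop(structure(
    class = c("no_pulsatile_region", "error", "condition"),
    list(message = "no pulsatile region found (target lost)", call = NULL)))
}

#' Register the sample gate at a region centroid
#'
#' @param region One-row region tibble (from [select_primary()]).
#' @param gate_length Gate length in mm (default 2, the clinical standard).
#' @return A one-row tibble: `lateral_mm`, `axial_mm`, `length_mm`.
#' @export
register_gate <- function(region, gate_length = 2) {
  stopifnot(is.data.frame(region), nrow(region) == 1, gate_length > 0)
  tibble::tibble(lateral_mm = region$lateral_mm,
                 axial_mm = region$axial_mm,
                 length_mm = gate_length)
}

#' Track a vessel through a duplex sequence
#'
#' Sliding-window application of the pulsatility-map pipeline: for each frame
#' from `window` onward, the variance over the trailing `window` frames is
#' segmented, the primary region selected and its centroid registered as the
#' sample gate. When no pulsatile region is found the last valid gate is held
#' and the frame is flagged `"lost"`; tracking resumes on reacquisition.
#'
#' @param frames A `duplex_sequence`.
#' @param window Variance window length in frames (default 10).
#' @param threshold_policy,threshold,min_region_area,connectivity Passed to
#'   [segment_pulsatile()].
#' @param gate_length Gate length, mm.
#' @return A tibble: `frame`, `time_s`, `lateral_mm`, `axial_mm`, `status`
#'   (`"tracking"` or `"lost"`). Position columns are `NA` while lost with no
#'   prior acquisition.
#' @export
track_sequence <- function(frames, window = 10,
                           threshold_policy = "otsu", threshold = 0.3,
                           min_region_area = 20, connectivity = 8,
                           gate_length = 2) {
  stopifnot(inherits(frames, "duplex_sequence"))
  n <- dim(frames$color)[3]
  if (n < window) {
    stop("sequence shorter than the variance window", call. = FALSE)
  }
  out <- vector("list", n - window + 1)
  last <- c(NA_real_, NA_real_)
  for (i in window:n) {
    map <- pulsatility_map(frames$color, window = (i - window + 1):i,
                           pixel_pitch = frames$pixel_pitch)
    gate <- tryCatch({
      regions <- segment_pulsatile(map, threshold_policy = threshold_policy,
                                   threshold = threshold,
                                   min_region_area = min_region_area,
                                   connectivity = connectivity)
      register_gate(select_primary(regions), gate_length)
    }, no_pulsatile_region = function(e) NULL)
    if (is.null(gate)) {
      out[[i - window + 1]] <- tibble::tibble(
        frame = i, time_s = frames$times[i],
        lateral_mm = last[1], axial_mm = last[2], status = "lost")
    } else {
      last <- c(gate$lateral_mm, gate$axial_mm)
      out[[i - window + 1]] <- tibble::tibble(
        frame = i, time_s = frames$times[i],
        lateral_mm = gate$lateral_mm, axial_mm = gate$axial_mm,
        status = "tracking")
    }
  }
  dplyr::bind_rows(out)
}
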