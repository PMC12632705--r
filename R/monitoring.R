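#' Segment a continuous beat record into fixed intervals
#'
#' Splits a beat stream (absolute times) into consecutive, non-overlapping
#' intervals from the record start; an incomplete trailing interval is
#' dropped. Per segment, beat-wise means of FHR and the Doppler indices are
#' reported; the S/D mean excludes absent-EDV beats (their ratio is
#' undefined) while RI includes them. FHR variability is the within-segment
#' standard deviation of per-beat FHR.
#'
#' @param beats Beat table with `start_s`, `fhr`, `psv`, `edv` and
#'   optionally `tav` columns.
#' @param interval Segment length, seconds (default 600 = 10 min).
#' @param min_beats Segments with fewer beats are flagged (default 10).
#' @return A tibble: `segment`, `start_s`, `end_s`, `n_beats`, `mean_fhr`,
#'   `fhr_variability`, `mean_sd_ratio`, `mean_pi` (when `tav` present),
#'   `mean_ri`, `absent_edv_fraction`, `flagged`. Zero rows (with a warning)
#'   when the record is shorter than one interval.
#' @export
segment_record <- function(beats, interval = 600, min_beats = 10) {
  stopifnot(is.data.frame(beats), nrow(beats) > 0, interval > 0)
  b <- doppler_indices(beats)
  t0 <- min(b$start_s)
  span <- max(b$end_s %||% b$start_s, b$start_s) - t0
  n_seg <- floor(span / interval + 1e-9)
  if (n_seg < 1) {
    warning("record shorter than one interval; no segments produced")
    return(tibble::tibble(segment = integer(), start_s = numeric(),
                          end_s = numeric(), n_beats = integer(),
                          mean_fhr = numeric(), fhr_variability = numeric(),
                          mean_sd_ratio = numeric(), mean_ri = numeric(),
                          absent_edv_fraction = numeric(), flagged = logical()))
  }
  b$segment <- floor((b$start_s - t0) / interval) + 1
  b <- dplyr::filter(b, .data$segment <= n_seg)
  has_tav <- "tav" %in% names(b)
  out <- b |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      start_s = t0 + (.data$segment[1] - 1) * interval,
      end_s = t0 + .data$segment[1] * interval,
      n_beats = dplyr::n(),
      mean_fhr = mean(.data$fhr),
      fhr_variability = if (dplyr::n() > 1) stats::sd(.data$fhr) else 0,
      mean_sd_ratio = mean(.data$sd_ratio, na.rm = TRUE),
      mean_pi = if (has_tav) mean(.data$pi) else NA_real_,
      mean_ri = mean(.data$ri),
      absent_edv_fraction = mean(.data$edv <= 2)) |>
    dplyr::mutate(flagged = .data$n_beats < min_beats)
  out
}

monitor_conditions <- c("healthy", "SGA", "LGA", "diabetes",
                        "pre-eclampsia", "hypertension")

#' Condition-stratified distribution statistics
#'
#' Per perinatal condition, the median, interquartile range (25th/75th
#' percentiles) and 5th/95th percentiles of a per-segment metric — the
#' summary behind condition box plots. Percentiles use linear interpolation
#' between closest ranks (R quantile type 7), recorded in the output.
#'
#' @param segments A data frame of per-segment values with a `condition`
#'   column (vocabulary: healthy, SGA, LGA, diabetes, pre-eclampsia,
#'   hypertension) and the metric column.
#' @param metric Name of the metric column (string).
#' @return A tibble per condition: `condition`, `n`, `median`, `q25`, `q75`,
#'   `q05`, `q95`; attribute `"quantile_type"` records the percentile rule.
#' @export
stratify <- function(segments, metric) {
  stopifnot(is.data.frame(segments), "condition" %in% names(segments),
            metric %in% names(segments))
  bad <- setdiff(unique(segments$condition), monitor_conditions)
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- segments |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data[[metric]]),
      q25 = stats::quantile(.data[[metric]], 0.25, type = 7, names = FALSE),
      q75 = stats::quantile(.data[[metric]], 0.75, type = 7, names = FALSE),
      q05 = stats::quantile(.data[[metric]], 0.05, type = 7, names = FALSE),
      q95 = stats::quantile(.data[[metric]], 0.95, type = 7, names = FALSE)) |>
    dplyr::ungroup()
  attr(out, "quantile_type") <- 7
  attr(out, "metric") <- metric
  out
}

#' Per-segment FHR vs pulsatility-index association
#'
#' Emits the paired per-segment (FHR, PI) table and their Spearman rank
#' correlation with a seeded permutation p-value. Used to check that heart
#' rate and Doppler indices carry complementary information.
#'
#' @param segments Per-segment table with `mean_fhr` and `mean_pi` columns.
#' @param n_perm Number of permutations for the p-value (default 999).
#' @param seed Integer seed for the permutations.
#' @return A list: `pairs` (tibble `mean_fhr`, `mean_pi`), `rho`, `p_value`,
#'   `n`, `degenerate` (TRUE with `rho = NA` when either series is
#'   constant).
#' @export
index_vs_fhr_scatter <- function(segments, n_perm = 999, seed = 0) {
  stopifnot(is.data.frame(segments),
            all(c("mean_fhr", "mean_pi") %in% names(segments)))
  pairs <- tibble::tibble(mean_fhr = segments$mean_fhr,
                          mean_pi = segments$mean_pi)
  pairs <- pairs[stats::complete.cases(pairs), ]
  if (nrow(pairs) < 3) stop("need at least 3 segments", call. = FALSE)
  if (stats::sd(pairs$mean_fhr) == 0 || stats::sd(pairs$mean_pi) == 0) {
    warning("constant series: rank correlation undefined")
    return(list(pairs = pairs, rho = NA_real_, p_value = NA_real_,
                n = nrow(pairs), degenerate = TRUE))
  }
  rho <- stats::cor(pairs$mean_fhr, pairs$mean_pi, method = "spearman")
  perm <- with_seed(seed, replicate(n_perm, {
    stats::cor(pairs$mean_fhr, sample(pairs$mean_pi), method = "spearman")
  }))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(pairs = pairs, rho = rho, p_value = p, n = nrow(pairs),
       degenerate = FALSE)
}
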