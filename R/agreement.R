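#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` between two measurement methods, their mean,
#' sample standard deviation (n-1 denominator, the Bland-Altman convention)
#' and 95% limits of agreement at `mean +/- 1.96 * sd`.
#'
#' @param data Optional data frame holding the two measurement columns.
#' @param a,b Numeric vectors of paired measurements, or (when `data` is
#'   given) the column names as strings.
#' @param label Optional metric name carried into printed/tidied output.
#' @param by Optional grouping vector (e.g. participant id) — when supplied,
#'   pairs are first averaged within group before the analysis (the
#'   per-subject averaging option); default pools all pairs.
#' @return An object of class `"bland_altman"` with elements `data` (tibble:
#'   `a`, `b`, `mean`, `diff`), `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, `label`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' ba <- bland_altman(a = c(2.6, 2.8, 3.0), b = c(2.7, 2.7, 2.9))
#' tidy(ba)
#' @export
bland_altman <- function(data = NULL, a, b, label = NULL, by = NULL) {
  if (!is.null(data)) {
    stopifnot(is.data.frame(data), is.character(a), is.character(b))
    va <- data[[a]]; vb <- data[[b]]
  } else {
    va <- a; vb <- b
  }
  if (length(va) != length(vb)) {
    stop("methods must have equal numbers of measurements", call. = FALSE)
  }
  if (length(va) < 2) stop("need at least 2 paired measurements", call. = FALSE)
  if (any(!is.finite(va)) || any(!is.finite(vb))) {
    stop("paired measurements must be finite", call. = FALSE)
  }
  if (!is.null(by)) {
    va <- as.numeric(tapply(va, by, mean))
    vb <- as.numeric(tapply(vb, by, mean))
  }
  d <- va - vb
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(data = tibble::tibble(a = va, b = vb, mean = (va + vb) / 2, diff = d),
         mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         n = length(d), label = label),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat("Bland-Altman agreement", if (!is.null(x$label)) paste0(" (", x$label, ")"),
      "\n  n pairs:    ", x$n,
      "\n  mean diff:  ", signif(x$mean_diff, digits),
      "\n  sd diff:    ", signif(x$sd_diff, digits),
      "\n  95% LoA:    [", signif(x$loa_low, digits), ", ",
      signif(x$loa_high, digits), "]\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(label = x$label %||% NA_character_, n = x$n,
                 mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high)
}

#' @rdname bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) tidy(x)[-1]

#' Sample-gate discrepancy between two methods
#'
#' Per-image absolute lateral and axial offsets between two sets of sample
#' gates (e.g. autonomous tracker vs sonographer, or tracker vs ground
#' truth), and the fraction of pairs within a clinical threshold on each
#' axis (2 mm by default). The optional Euclidean criterion is also
#' reported.
#'
#' @param gates_a,gates_b Data frames with `lateral_mm` and `axial_mm`
#'   columns, equal row counts, same image geometry.
#' @param threshold Per-axis discrepancy threshold in mm (default 2).
#' @return A list of class `"gate_discrepancy"`: `differences` (tibble
#'   `d_lateral_mm`, `d_axial_mm`, `d_euclidean_mm`), `lateral_within`,
#'   `axial_within`, `euclidean_within`, `threshold`, `n`.
#' @export
gate_discrepancy <- function(gates_a, gates_b, threshold = 2) {
  need <- c("lateral_mm", "axial_mm")
  stopifnot(is.data.frame(gates_a), is.data.frame(gates_b),
            all(need %in% names(gates_a)), all(need %in% names(gates_b)))
  if (nrow(gates_a) != nrow(gates_b) || nrow(gates_a) == 0) {
    stop("gate sets must be nonempty and of equal size", call. = FALSE)
  }
  dl <- abs(gates_a$lateral_mm - gates_b$lateral_mm)
  da <- abs(gates_a$axial_mm - gates_b$axial_mm)
  structure(
    list(differences = tibble::tibble(
           d_lateral_mm = dl, d_axial_mm = da,
           d_euclidean_mm = sqrt(dl^2 + da^2)),
         lateral_within = mean(dl <= threshold),
         axial_within = mean(da <= threshold),
         euclidean_within = mean(sqrt(dl^2 + da^2) <= threshold),
         threshold = threshold, n = length(dl)),
    class = "gate_discrepancy")
}

#' @export
print.gate_discrepancy <- function(x, ...) {
  cat("Sample-gate discrepancy (threshold ", x$threshold, " mm, n = ", x$n,
      ")\n  within, lateral:   ", round(100 * x$lateral_within, 1), "%",
      "\n  within, axial:     ", round(100 * x$axial_within, 1), "%",
      "\n  within, euclidean: ", round(100 * x$euclidean_within, 1), "%\n",
      sep = "")
  invisible(x)
}

#' @rdname gate_discrepancy
#' @param x A `gate_discrepancy` object.
#' @param ... Unused.
#' @method tidy gate_discrepancy
#' @export
tidy.gate_discrepancy <- function(x, ...) {
  tibble::tibble(n = x$n, threshold_mm = x$threshold,
                 lateral_within = x$lateral_within,
                 axial_within = x$axial_within,
                 euclidean_within = x$euclidean_within)
}
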