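# Left-right asymmetry metrics: thresholded areas A_L / A_R, fractional
# areas, dominance classification with onset estimation, and an exact paired
# Wilcoxon signed-rank test.

#' Thresholded left/right areas of a scalar field
#'
#' The per-window maximum (speed, or |vorticity|) over valid ROI cells sets
#' the threshold: cells with value at least `threshold_fraction * max` are
#' retained.  Each retained cell is assigned to the embryo's left or right
#' side by the sign of the 2-D cross product `direction x (cell - point)` of
#' the dividing midline: with the anterior-oriented midline direction, the
#' negative side (+x for a vertical midline) is the embryo's right.  Cells
#' exactly on the midline count half to each side.  Areas are retained-cell
#' counts times the grid-cell area.
#'
#' @param field a window-averaged `scalar_field` (ROI applied).
#' @param threshold_fraction fraction of the per-window maximum, in (0, 1).
#' @param midline a `line2d` dividing left from right.
#' @param roi optional [roi_mask()] applied before quantification.
#' @param v_max optional externally supplied maximum (global-max mode);
#'   default is the per-window maximum.
#' @return an `area_result`: `A_L`, `A_R` (px^2), `f_L`, `f_R` (filled by
#'   [fractional_areas()]), `threshold_fraction`, `field_kind`, `window`,
#'   `n_retained`, `v_max`.
#' @export
threshold_area <- function(field, threshold_fraction, midline, roi = NULL,
                           v_max = NULL) {
  stopifnot(inherits(field, "scalar_field"),
            threshold_fraction > 0, threshold_fraction < 1)
  if (is.null(midline)) stop(bf_condition("bf_empty_error",
                                          "dividing midline undefined"))
  stopifnot(inherits(midline, "line2d"))
  if (!is.null(roi)) field <- apply_roi(field, roi)
  mag <- if (field$kind == "vorticity") abs(field$values) else field$values
  ok <- field$valid & is.finite(mag)
  if (!any(ok)) stop(bf_condition("bf_empty_error", "all cells invalid"))
  vmax <- v_max %||% max(mag[ok])
  retained <- ok & mag >= threshold_fraction * vmax
  h <- if (length(field$x) > 1) field$x[2] - field$x[1] else 1
  cell_area <- h^2
  X <- outer(field$x, rep(1, length(field$y)))
  Y <- outer(rep(1, length(field$x)), field$y)
  d <- midline$direction; p <- midline$point
  cross <- d[1] * (Y - p[2]) - d[2] * (X - p[1])
  nL <- sum(retained & cross > 0) + 0.5 * sum(retained & cross == 0)
  nR <- sum(retained & cross < 0) + 0.5 * sum(retained & cross == 0)
  structure(list(A_L = nL * cell_area, A_R = nR * cell_area,
                 f_L = NA_real_, f_R = NA_real_,
                 threshold_fraction = threshold_fraction,
                 field_kind = field$kind, window = field$window,
                 n_retained = sum(retained), v_max = vmax),
            class = "area_result")
}

#' Fill fractional areas of an area result
#'
#' `f_L = A_L / (A_L + A_R)` and `f_R = A_R / (A_L + A_R)`; 0.5 is the line
#' of symmetry.  Undefined (NA, with a warning) when both areas are zero.
#'
#' @param result an `area_result`.
#' @return the result with `f_L`, `f_R` filled; they sum to 1 whenever
#'   defined.
#' @export
fractional_areas <- function(result) {
  stopifnot(inherits(result, "area_result"))
  tot <- result$A_L + result$A_R
  if (tot > 0) {
    result$f_L <- result$A_L / tot
    result$f_R <- result$A_R / tot
  } else {
    warning("A_L + A_R = 0; fractional areas undefined")
  }
  result
}

#' Classify per-window dominance and estimate its onset
#'
#' A window is labelled `R` when `f_R > 0.5 + delta`, `L` when
#' `f_R < 0.5 - delta`, else `none`.  The end dominance is the label of the
#' final defined window; the onset is the start of the earliest window from
#' which that label persists unbroken through the final window, provided the
#' run spans at least `persistence` windows.
#'
#' @param f_R per-window right fractional areas (NA = window undefined).
#' @param window_starts window start times (hours); default `0, 1, ...`.
#' @param delta symmetric dead-band around 0.5 (default 0.02).
#' @param persistence minimum run length (windows) for a dominance onset.
#' @return list with `labels` (character per window), `end_dominance`,
#'   `onset` (hours, or NA).
#' @export
classify_dominance <- function(f_R, window_starts = seq_along(f_R) - 1,
                               delta = 0.02, persistence = 2L) {
  stopifnot(length(f_R) >= 1, length(window_starts) == length(f_R))
  if (all(is.na(f_R))) stop(bf_condition("bf_empty_error",
                                         "no defined windows"))
  labels <- rep(NA_character_, length(f_R))
  labels[!is.na(f_R)] <- "none"
  labels[!is.na(f_R) & f_R > 0.5 + delta] <- "R"
  labels[!is.na(f_R) & f_R < 0.5 - delta] <- "L"
  defined <- which(!is.na(labels))
  last <- max(defined)
  end_label <- labels[last]
  onset <- NA_real_
  if (end_label %in% c("L", "R")) {
    i <- last
    while (i >= 1 && !is.na(labels[i]) && labels[i] == end_label) i <- i - 1
    run <- last - i
    if (run >= persistence) onset <- window_starts[i + 1]
  }
  list(labels = labels, end_dominance = end_label, onset = onset)
}

# exact null distribution of the signed-rank statistic over all 2^n equally
# likely sign assignments, on doubled ranks so that tied (average) ranks
# stay integral; returns counts indexed by doubled statistic 0..sum(r2)
signed_rank_counts <- function(r2) {
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired differences `x - y`.  Zero differences are
#' dropped and tied absolute differences receive average ranks.  For
#' `n <= exact_max` the p-value is exact, computed from the full null
#' distribution over all `2^n` sign assignments (evaluated by dynamic
#' programming over doubled ranks, identical to direct enumeration); above
#' that a normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param x,y equal-length paired numeric vectors (e.g. per-window `f_L` and
#'   `f_R`); pairs with any NA are dropped.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return a `test_result`: `statistic` (V, rank sum of positive
#'   differences), `p_value`, `n` (non-zero pairs), `method`.
#' @export
paired_rank_test <- function(x, y, exact_max = 25L) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  keep <- !(is.na(x) | is.na(y))
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero")
    return(structure(list(statistic = 0, p_value = 1, n = 0L,
                          method = "degenerate"), class = "test_result"))
  }
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * rk))
    counts <- signed_rank_counts(r2)
    v2 <- as.integer(round(2 * V))
    tot <- 2^n
    p_le <- sum(counts[seq_len(v2 + 1)]) / tot
    p_ge <- sum(counts[seq(v2 + 1, length(counts))]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(statistic = V, p_value = p, n = n, method = method),
            class = "test_result")
}
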