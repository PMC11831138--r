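# Vortex-center detection (Gamma1 swirl criterion), the three midline axes
# (anatomical AM, biophysical BM, flow FM) and center tracking.

#' Signed angle of a direction to the vertical axis
#'
#' Angle between a line direction and +y (anterior), in degrees, clockwise
#' positive (tilt toward +x), collapsed to `(-90, 90]` since a midline is a
#' line, not a ray.
#'
#' @param direction nonzero length-2 vector.
#' @return angle in degrees.
#' @export
angle_to_vertical <- function(direction) {
  stopifnot(length(direction) == 2)
  if (all(direction == 0)) stop("zero direction vector")
  a <- atan2(direction[1], direction[2]) * 180 / pi
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  a
}

#' Construct an oriented 2-D line
#'
#' Direction is normalized and oriented toward the anterior (+y) half-plane
#' (toward +x when exactly horizontal).
#'
#' @param point a point on the line (px).
#' @param direction direction vector (need not be unit).
#' @return a `line2d` with fields `point`, `direction` (unit),
#'   `angle_to_vertical` (degrees).
#' @export
line2d <- function(point, direction) {
  stopifnot(length(point) == 2, length(direction) == 2)
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("zero direction vector")
  d <- direction / n
  if (d[2] < 0 || (d[2] == 0 && d[1] < 0)) d <- -d
  structure(list(point = as.numeric(point), direction = d,
                 angle_to_vertical = angle_to_vertical(d)),
            class = "line2d")
}

#' Midline through two annotated points
#'
#' Builds the anatomical midline (AM) from a two-point annotation along the
#' primitive streak.  For synthetic scenarios the AM is the vertical
#' diameter of the embryonic disc.
#'
#' @param p1,p2 two distinct points (px).
#' @return a `line2d`.
#' @export
midline_from_points <- function(p1, p2) line2d(p1, p2 - p1)

# Gamma1 swirl criterion: mean over a disc neighborhood of the sine of the
# angle between (q - p) and the velocity at q.  |Gamma1| near 1 marks a
# vortex core; |Gamma1| > 2/pi is the conventional closed-swirl bound.
gamma1_field <- function(field, radius) {
  nx <- length(field$x); ny <- length(field$y)
  X <- outer(field$x, rep(1, ny))
  Y <- outer(rep(1, nx), field$y)
  sp <- sqrt(field$u^2 + field$v^2)
  ok <- field$valid & is.finite(sp) & sp > 0
  h <- grid_spacing(field)
  rad_cells <- ceiling(radius / h)
  # size of a complete neighborhood disc; cells with a substantially
  # one-sided neighborhood (grid or ROI border) would report spurious swirl
  # and are excluded as candidates
  offs <- expand.grid(dx = -rad_cells:rad_cells, dy = -rad_cells:rad_cells)
  rr <- sqrt(offs$dx^2 + offs$dy^2) * h
  n_full <- sum(rr > 0 & rr <= radius)
  g1 <- matrix(NA_real_, nx, ny)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      if (!field$valid[ix, iy]) next
      jx <- max(1, ix - rad_cells):min(nx, ix + rad_cells)
      jy <- max(1, iy - rad_cells):min(ny, iy + rad_cells)
      okn <- ok[jx, jy, drop = FALSE]
      wx <- X[jx, jy, drop = FALSE] - X[ix, iy]
      wy <- Y[jx, jy, drop = FALSE] - Y[ix, iy]
      r <- sqrt(wx^2 + wy^2)
      use <- okn & r > 0 & r <= radius
      if (sum(use) < 0.6 * n_full) next
      cr <- (wx * field$v[jx, jy, drop = FALSE] -
               wy * field$u[jx, jy, drop = FALSE]) /
        (r * sp[jx, jy, drop = FALSE])
      g1[ix, iy] <- mean(cr[use])
    }
  }
  g1
}

# connected region (4-connectivity) of cells satisfying `keep`, containing
# (ix0, iy0); returns a logical matrix
flood_region <- function(keep, ix0, iy0) {
  nx <- nrow(keep); ny <- ncol(keep)
  seen <- matrix(FALSE, nx, ny)
  if (!keep[ix0, iy0]) return(seen)
  queue <- list(c(ix0, iy0))
  seen[ix0, iy0] <- TRUE
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] < 1 || q[2] < 1 || q[1] > nx || q[2] > ny) next
      if (seen[q[1], q[2]] || !keep[q[1], q[2]]) next
      seen[q[1], q[2]] <- TRUE
      queue[[length(queue) + 1]] <- q
    }
  }
  seen
}

#' Detect the two counterrotating vortex centers
#'
#' Candidate centers maximize the Gamma1 swirl criterion, one per rotation
#' sign (positive = counterclockwise = left vortex, negative = clockwise =
#' right vortex, y-up frame).  Each candidate is refined to the
#' vorticity-magnitude-weighted centroid of the connected region where
#' |omega| is at least half the candidate's peak; a side is "closed" when
#' |Gamma1| at its candidate exceeds `2/pi`.
#'
#' @param vort vorticity `scalar_field` (ROI applied).
#' @param flow the matching `velocity_field`.
#' @param neighborhood_radius Gamma1 neighborhood radius in px (default 4
#'   grid spacings).
#' @param closed_threshold swirl bound for the closed-vortex flag.
#' @return a `vortex_pair`: per side `center` (or `NULL` when no candidate
#'   of that sign exists), `peak_vorticity`, `gamma1`, `closed`.
#' @export
find_vortex_centers <- function(vort, flow, neighborhood_radius = NULL,
                                closed_threshold = 2 / pi) {
  stopifnot(inherits(vort, "scalar_field"), vort$kind == "vorticity",
            inherits(flow, "velocity_field"))
  h <- grid_spacing(flow)
  rad <- neighborhood_radius %||% (4 * h)
  g1 <- gamma1_field(flow, rad)

  side <- function(sign_) {
    gs <- g1 * sign_
    if (!any(is.finite(gs) & gs > 0))
      return(list(center = NULL, peak_vorticity = NA_real_,
                  gamma1 = NA_real_, closed = FALSE))
    idx <- which(gs == max(gs, na.rm = TRUE), arr.ind = TRUE)[1, ]
    g1c <- g1[idx[1], idx[2]]
    w <- vort$values
    wc <- w[idx[1], idx[2]]
    ctr <- c(flow$x[idx[1]], flow$y[idx[2]])
    peak <- wc
    if (is.finite(wc) && wc * sign_ > 0) {
      keep <- vort$valid & is.finite(w) & (w * sign_) >= 0.5 * abs(wc)
      reg <- flood_region(keep, idx[1], idx[2])
      if (any(reg)) {
        ww <- abs(w); ww[!reg] <- 0
        X <- outer(vort$x, rep(1, length(vort$y)))
        Y <- outer(rep(1, length(vort$x)), vort$y)
        ctr <- c(sum(X * ww) / sum(ww), sum(Y * ww) / sum(ww))
        peak <- sign_ * max(abs(w[reg]), na.rm = TRUE)
      }
    }
    list(center = ctr, peak_vorticity = peak, gamma1 = g1c,
         closed = is.finite(g1c) && abs(g1c) > closed_threshold)
  }

  left <- side(+1)
  right <- side(-1)
  structure(list(left_center = left$center, right_center = right$center,
                 left_peak_vorticity = left$peak_vorticity,
                 right_peak_vorticity = right$peak_vorticity,
                 left_gamma1 = left$gamma1, right_gamma1 = right$gamma1,
                 left_closed = left$closed, right_closed = right$closed),
            class = "vortex_pair")
}

both_closed <- function(pair)
  isTRUE(pair$left_closed) && isTRUE(pair$right_closed) &&
  !is.null(pair$left_center) && !is.null(pair$right_center)

#' Biophysical midline (BM)
#'
#' The line through the midpoint of the two vortex centers, perpendicular to
#' the segment joining them, oriented toward the anterior.  Undefined
#' (`NULL`) unless both vortices are closed.
#'
#' @param pair a `vortex_pair`.
#' @return a `line2d`, or `NULL` when undefined.
#' @export
biophysical_midline <- function(pair) {
  if (!both_closed(pair)) return(NULL)
  seg <- pair$right_center - pair$left_center
  line2d((pair$left_center + pair$right_center) / 2, c(-seg[2], seg[1]))
}

#' Flow midline (FM)
#'
#' The line through the inter-center midpoint, parallel to the local flow:
#' its direction is the mean velocity over grid cells within 10% of the
#' inter-center distance of the midpoint (bilinear interpolation at the
#' midpoint when no cell falls inside).  Undefined when either vortex is
#' open or the local mean speed is below `1e-3` px/frame.
#'
#' @param pair a `vortex_pair`.
#' @param flow the `velocity_field` the pair was detected in.
#' @param radius_fraction neighborhood radius as a fraction of the
#'   inter-center distance.
#' @return a `line2d`, or `NULL` when undefined.
#' @export
flow_midline <- function(pair, flow, radius_fraction = 0.1) {
  if (!both_closed(pair)) return(NULL)
  mid <- (pair$left_center + pair$right_center) / 2
  dist <- sqrt(sum((pair$right_center - pair$left_center)^2))
  rad <- radius_fraction * dist
  X <- outer(flow$x, rep(1, length(flow$y)))
  Y <- outer(rep(1, length(flow$x)), flow$y)
  use <- flow$valid & ((X - mid[1])^2 + (Y - mid[2])^2 <= rad^2)
  if (any(use)) {
    mu <- mean(flow$u[use]); mv <- mean(flow$v[use])
  } else {
    um <- flow$u; um[!flow$valid] <- NA
    vm <- flow$v; vm[!flow$valid] <- NA
    mu <- interp_bilinear(flow$x, flow$y, um, mid[1], mid[2])
    mv <- interp_bilinear(flow$x, flow$y, vm, mid[1], mid[2])
  }
  if (is.na(mu) || is.na(mv) || sqrt(mu^2 + mv^2) < 1e-3) return(NULL)
  line2d(mid, c(mu, mv))
}

#' Track vortex centers across time windows
#'
#' Positions are reported relative to a fixed origin outside the embryonic
#' disc (the image origin `(0, 0)`), together with the Euclidean
#' inter-center distance per window.  Windows with a missing center carry
#' `NA`.
#'
#' @param pairs list of `vortex_pair`s, one per time window.
#' @param windows optional numeric matrix / data.frame with window start and
#'   end times (hours), one row per pair.
#' @return a `center_track` data.frame with columns `window_start`,
#'   `window_end`, `left_x`, `left_y`, `right_x`, `right_y`, `distance`,
#'   `left_closed`, `right_closed`.
#' @export
track_centers <- function(pairs, windows = NULL) {
  stopifnot(length(pairs) >= 1)
  get <- function(p, side) {
    ctr <- p[[paste0(side, "_center")]]
    if (is.null(ctr)) c(NA_real_, NA_real_) else ctr
  }
  L <- t(vapply(pairs, get, numeric(2), side = "left"))
  R <- t(vapply(pairs, get, numeric(2), side = "right"))
  d <- sqrt(rowSums((L - R)^2))
  if (is.null(windows))
    windows <- cbind(seq_along(pairs) - 1, seq_along(pairs))
  out <- data.frame(window_start = windows[, 1], window_end = windows[, 2],
                    left_x = L[, 1], left_y = L[, 2],
                    right_x = R[, 1], right_y = R[, 2], distance = d,
                    left_closed = vapply(pairs, function(p)
                      isTRUE(p$left_closed), logical(1)),
                    right_closed = vapply(pairs, function(p)
                      isTRUE(p$right_closed), logical(1)))
  class(out) <- c("center_track", "data.frame")
  out
}
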