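# Scalar fields derived from velocity fields: speed and vorticity maps,
# time-window averaging, streamline integration and circular ROI masking.

#' Construct a scalar field
#'
#' @param x,y ascending grid coordinates (px), matching the source velocity
#'   field.
#' @param values `length(x) x length(y)` matrix; speed in px/frame (>= 0),
#'   vorticity in 1/frame (signed, positive = counterclockwise).
#' @param valid logical validity matrix.
#' @param kind `"speed"` or `"vorticity"`.
#' @param window optional time interval `c(t0, t1)` in hours.
#' @return a `scalar_field`.
#' @export
scalar_field <- function(x, y, values, valid, kind = c("speed", "vorticity"),
                         window = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(dim(values) == c(length(x), length(y))),
            all(dim(valid) == dim(values)))
  structure(list(x = as.numeric(x), y = as.numeric(y), values = values,
                 valid = valid, kind = kind, window = window),
            class = "scalar_field")
}

#' Circular region-of-interest mask
#'
#' Restricts quantification to the embryonic disc; the extraembryonic
#' surround is stationary and would contribute only noise.
#'
#' @param center disc center (px, math frame).
#' @param radius disc radius (px), > 0.
#' @return an `roi_mask`.
#' @export
roi_mask <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "roi_mask")
}

#' Invalidate cells outside a circular ROI
#'
#' Cells whose center lies outside the disc are flagged invalid; inside
#' cells are untouched.
#'
#' @param field a `velocity_field` or `scalar_field`.
#' @param mask an [roi_mask()].
#' @return the masked field.
#' @export
apply_roi <- function(field, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  dx <- outer(field$x - mask$center[1], rep(1, length(field$y)))
  dy <- outer(rep(1, length(field$x)), field$y - mask$center[2])
  inside <- dx^2 + dy^2 <= mask$radius^2
  field$valid <- field$valid & inside
  field
}

#' Speed magnitude of a velocity field
#'
#' Per-cell \eqn{\sqrt{u^2 + v^2}}; invalid cells propagate.
#'
#' @param field a `velocity_field`.
#' @return a `scalar_field` of kind `"speed"`.
#' @export
speed_field <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  vals <- sqrt(field$u^2 + field$v^2)
  vals[!field$valid] <- NA_real_
  scalar_field(field$x, field$y, vals, field$valid, "speed",
               window = attr(field, "window"))
}

#' Vorticity (curl) of a velocity field
#'
#' \eqn{\omega = \partial v/\partial x - \partial u/\partial y} by central
#' differences on the regular grid, one-sided at the grid borders.  In the
#' y-up frame positive vorticity is counterclockwise rotation.  A cell is
#' valid only if every neighbor entering its stencil is valid.
#'
#' @param field a `velocity_field`.
#' @return a `scalar_field` of kind `"vorticity"`.
#' @export
vorticity_field <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  nx <- length(field$x); ny <- length(field$y)
  if (nx < 3 || ny < 3) stop("vorticity needs at least 3 cells per axis")
  hx <- field$x[2] - field$x[1]
  hy <- field$y[2] - field$y[1]
  u <- field$u; v <- field$v; ok <- field$valid
  um <- u; um[!ok] <- NA; vm <- v; vm[!ok] <- NA

  dvdx <- matrix(NA_real_, nx, ny)
  dvdx[2:(nx - 1), ] <- (vm[3:nx, ] - vm[1:(nx - 2), ]) / (2 * hx)
  dvdx[1, ] <- (vm[2, ] - vm[1, ]) / hx
  dvdx[nx, ] <- (vm[nx, ] - vm[nx - 1, ]) / hx

  dudy <- matrix(NA_real_, nx, ny)
  dudy[, 2:(ny - 1)] <- (um[, 3:ny] - um[, 1:(ny - 2)]) / (2 * hy)
  dudy[, 1] <- (um[, 2] - um[, 1]) / hy
  dudy[, ny] <- (um[, ny] - um[, ny - 1]) / hy

  w <- dvdx - dudy
  valid <- ok & is.finite(w)
  w[!valid] <- NA_real_
  scalar_field(field$x, field$y, w, valid, "vorticity",
               window = attr(field, "window"))
}

field_time_hours <- function(field) {
  fi <- attr(field, "frame_interval") %||% 3
  (field$time_index - 1) * fi / 60
}

#' Average fields over a time window
#'
#' Per-cell mean over the member fields whose pair start time falls in
#' `[window[1], window[2])` hours (all members when `window` is `NULL`).  A
#' cell of the average is valid iff at least half the members are valid
#' there.  For the headline maps, averaging is applied to velocity first and
#' speed/vorticity are derived from the averaged field.
#'
#' @param fields list of `velocity_field`s or `scalar_field`s sharing one
#'   grid.
#' @param window time interval `c(t0, t1)` in hours, or `NULL`.
#' @return a single averaged field of the same class, with the window
#'   recorded.
#' @export
time_average <- function(fields, window = NULL) {
  stopifnot(length(fields) >= 1)
  if (!is.null(window)) {
    tt <- vapply(fields, field_time_hours, numeric(1))
    keep <- tt >= window[1] & tt < window[2]
    fields <- fields[keep]
    if (length(fields) == 0) stop(bf_condition("bf_empty_error",
                                               "empty averaging window"))
  }
  f1 <- fields[[1]]
  n <- length(fields)
  nv <- Reduce(`+`, lapply(fields, function(f) f$valid * 1))
  valid <- nv >= n / 2 & nv > 0
  msum <- function(get) {
    s <- matrix(0, nrow(f1$valid), ncol(f1$valid))
    for (f in fields) {
      m <- get(f)
      m[!f$valid | !is.finite(m)] <- 0
      s <- s + m
    }
    s / pmax(nv, 1)
  }
  if (inherits(f1, "velocity_field")) {
    out <- velocity_field(f1$x, f1$y, msum(function(f) f$u),
                          msum(function(f) f$v), valid,
                          peak_ratio = msum(function(f) f$peak_ratio),
                          time_index = f1$time_index,
                          frame_interval = attr(f1, "frame_interval"))
    attr(out, "window") <- window
    attr(out, "n_members") <- n
    out
  } else {
    vals <- msum(function(f) f$values)
    vals[!valid] <- NA_real_
    out <- scalar_field(f1$x, f1$y, vals, valid, f1$kind, window = window)
    attr(out, "n_members") <- n
    out
  }
}

#' Integrate streamlines through a velocity field
#'
#' Seeds are integrated forward and backward along the normalized velocity
#' direction with a fixed-step 4th-order Runge-Kutta scheme (step = 1/4 grid
#' spacing by default) and bilinear interpolation.  Integration stops at the
#' grid/ROI boundary, in invalid regions, at `max_length` steps, or where
#' the local speed drops below `1e-3` px/frame.
#'
#' @param field a `velocity_field`.
#' @param seeds n x 2 matrix of seed points (px).
#' @param step integration step (px); default `grid spacing / 4`.
#' @param max_length maximum steps per direction.
#' @return list of polylines (m x 2 matrices); a seed at a stagnation point
#'   yields a single-point polyline.
#' @export
streamlines <- function(field, seeds, step = NULL, max_length = 1000L) {
  stopifnot(inherits(field, "velocity_field"))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2)
  h <- step %||% (grid_spacing(field) / 4)
  um <- field$u; um[!field$valid] <- NA
  vm <- field$v; vm[!field$valid] <- NA
  vel1 <- function(p) {
    u <- interp_bilinear(field$x, field$y, um, p[1], p[2])
    v <- interp_bilinear(field$x, field$y, vm, p[1], p[2])
    c(u, v)
  }
  inside_grid <- function(p)
    p[1] >= field$x[1] && p[1] <= field$x[length(field$x)] &&
    p[2] >= field$y[1] && p[2] <= field$y[length(field$y)]
  trace_dir <- function(p0, sgn) {
    pts <- list()
    p <- p0
    for (i in seq_len(max_length)) {
      dir_at <- function(q) {
        v <- vel1(q)
        s <- sqrt(sum(v^2))
        if (any(is.na(v)) || s < 1e-3) return(NULL)
        sgn * v / s
      }
      k1 <- dir_at(p); if (is.null(k1)) break
      k2 <- dir_at(p + h / 2 * k1); if (is.null(k2)) break
      k3 <- dir_at(p + h / 2 * k2); if (is.null(k3)) break
      k4 <- dir_at(p + h * k3); if (is.null(k4)) break
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!inside_grid(p)) break
      pts[[i]] <- p
    }
    if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), ncol = 2)
  }
  lapply(seq_len(nrow(seeds)), function(i) {
    s <- seeds[i, ]
    if (!inside_grid(s)) stop("streamline seed outside grid")
    bwd <- trace_dir(s, -1)
    fwd <- trace_dir(s, +1)
    out <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(s, ncol = 2), fwd)
    colnames(out) <- c("x", "y")
    out
  })
}

#' Render a scalar field heatmap to PNG
#'
#' Speed uses a sequential blue-to-red map; vorticity uses a diverging map
#' with clockwise rotation (negative, y-up) in red and counterclockwise in
#' blue, matching the conventional display of the bilateral vortices.
#'
#' @param field a `scalar_field`.
#' @param file PNG path, or `NULL` to draw on the active device.
#' @param main plot title.
#' @return `file`, invisibly.
#' @export
plot_scalar_field <- function(field, file = NULL, main = field$kind) {
  vals <- field$values
  vals[!field$valid] <- NA
  if (!is.null(file)) grDevices::png(file, width = 640, height = 640)
  if (field$kind == "vorticity") {
    lim <- max(abs(vals), na.rm = TRUE)
    if (!is.finite(lim) || lim == 0) lim <- 1
    pal <- grDevices::colorRampPalette(c("red", "white", "blue"))(64)
    graphics::image(field$x, field$y, vals, zlim = c(-lim, lim), col = pal,
                    asp = 1, xlab = "x (px)", ylab = "y (px)", main = main)
  } else {
    pal <- grDevices::colorRampPalette(c("darkblue", "cyan", "yellow",
                                         "red"))(64)
    graphics::image(field$x, field$y, vals, col = pal, asp = 1,
                    xlab = "x (px)", ylab = "y (px)", main = main)
  }
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}
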