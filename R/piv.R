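# Particle image velocimetry: interrogation-window cross-correlation with
# subpixel Gaussian peak localization, two-pass grid refinement and
# normalized-median vector validation.

#' PIV configuration
#'
#' @param window_size first-pass interrogation window size in px (even, at
#'   least 8).  The second pass uses half this size.
#' @param overlap_fraction window overlap in `[0, 1)`; the grid step is
#'   `window_size * (1 - overlap_fraction)`.
#' @param passes number of passes (1 or 2).  With two passes the second pass
#'   runs at half window size using the validated first-pass field as an
#'   integer predictor shift.
#' @param median_threshold normalized-median-test threshold for vector
#'   validation.
#' @param min_peak_ratio minimum ratio of primary to secondary correlation
#'   peak; vectors below it are invalidated.
#' @param eps stabilizer (px/frame) in the median-residual test.
#' @return a `piv_config` list.
#' @export
piv_config <- function(window_size = 32L, overlap_fraction = 0.5,
                       passes = 2L, median_threshold = 2.0,
                       min_peak_ratio = 1.2, eps = 0.1) {
  stopifnot(window_size >= 8, window_size %% 2 == 0,
            overlap_fraction >= 0, overlap_fraction < 1,
            passes %in% c(1L, 2L), median_threshold > 0, eps >= 0)
  structure(list(window_size = as.integer(window_size),
                 overlap_fraction = overlap_fraction,
                 passes = as.integer(passes),
                 median_threshold = median_threshold,
                 min_peak_ratio = min_peak_ratio, eps = eps),
            class = "piv_config")
}

#' Construct a velocity field
#'
#' Grid coordinates are in the y-up mathematical frame; `u`, `v`,
#' `valid` and `peak_ratio` are `length(x) x length(y)` matrices indexed
#' `[ix, iy]` with both axes ascending.
#'
#' @param x,y ascending grid-center coordinates (px).
#' @param u,v velocity components (px/frame, y-up).
#' @param valid logical matrix of vector validity.
#' @param peak_ratio per-cell correlation quality (may be `NULL`).
#' @param time_index frame-pair index this field belongs to.
#' @param frame_interval minutes per frame (metadata for time averaging).
#' @return a `velocity_field`.
#' @export
velocity_field <- function(x, y, u, v, valid, peak_ratio = NULL,
                           time_index = NA_integer_, frame_interval = NULL) {
  stopifnot(all(diff(x) > 0), all(diff(y) > 0),
            all(dim(u) == c(length(x), length(y))),
            all(dim(v) == dim(u)), all(dim(valid) == dim(u)))
  if (is.null(peak_ratio)) peak_ratio <- matrix(NA_real_, nrow(u), ncol(u))
  f <- structure(list(x = as.numeric(x), y = as.numeric(y), u = u, v = v,
                      valid = valid, peak_ratio = peak_ratio,
                      time_index = time_index),
                 class = "velocity_field")
  attr(f, "frame_interval") <- frame_interval
  f
}

grid_spacing <- function(field) {
  if (length(field$x) > 1) field$x[2] - field$x[1]
  else if (length(field$y) > 1) field$y[2] - field$y[1] else 1
}

# interrogation grid: 1-based top-left corners of windows fully inside an
# H x W frame, plus window-center coordinates (image rows / cols)
interrogation_grid <- function(H, W, win, step) {
  tops_r <- seq(1L, H - win + 1L, by = step)
  tops_c <- seq(1L, W - win + 1L, by = step)
  list(tops_r = tops_r, tops_c = tops_c,
       centers_r = tops_r + (win - 1) / 2,
       centers_c = tops_c + (win - 1) / 2)
}

#' Windowed zero-mean normalized cross-correlation surfaces
#'
#' Computes, for every interrogation window of the configured grid, the
#' circular zero-mean normalized cross-correlation surface between the two
#' frames via frequency-domain products.  Surfaces cover integer shifts in
#' `[-window/2, window/2 - 1]` per axis with zero shift at index
#' `window/2 + 1`.  Constant-intensity (degenerate) windows are flagged and
#' their surfaces are `NaN`.
#'
#' @param frame_a,frame_b image matrices of identical shape (row 1 = top).
#' @param config a [piv_config()]; its `window_size` defines the grid.
#' @return list with `surfaces` (win x win x k array), `centers_r`,
#'   `centers_c` (window centers, image coordinates, one row per window),
#'   `degenerate` (logical k).
#' @export
correlate_windows <- function(frame_a, frame_b, config = piv_config()) {
  stopifnot(all(dim(frame_a) == dim(frame_b)))
  win <- config$window_size
  step <- max(1L, as.integer(round(win * (1 - config$overlap_fraction))))
  H <- nrow(frame_a); W <- ncol(frame_a)
  if (H < win || W < win) stop("window grid does not fit inside the frames")
  g <- interrogation_grid(H, W, win, step)
  gg <- expand.grid(c = g$tops_c, r = g$tops_r)  # column varies fastest
  res <- cpp_cc_batch(frame_a, frame_b, gg$r, gg$c, win,
                      integer(nrow(gg)), integer(nrow(gg)), TRUE)
  list(surfaces = res$surfaces,
       centers_r = rep(g$centers_r, each = length(g$tops_c)),
       centers_c = rep(g$centers_c, times = length(g$tops_r)),
       degenerate = res$degenerate == 1L)
}

#' Subpixel correlation-peak localization
#'
#' Finds the integer peak of a correlation surface and refines it with a
#' three-point Gaussian fit per axis (parabolic fallback when any of the
#' three samples is non-positive).  The peak must be a strict interior
#' maximum; flat surfaces or border peaks yield `valid = FALSE`.
#'
#' @param surface numeric correlation matrix (rows = shift axis 1).
#' @param center 1-based `(row, col)` of the zero-shift cell; defaults to
#'   `floor(dim/2) + 1`, matching [correlate_windows()] surfaces.
#' @return list with `location` (subpixel 1-based matrix coordinates),
#'   `shift` `(dx, dy)` relative to `center`, `valid`, `peak_ratio`.
#' @export
subpixel_peak <- function(surface, center = floor(dim(surface) / 2) + 1) {
  pk <- cpp_peak_locate(surface)
  list(location = c(row = pk[1], col = pk[2]),
       shift = c(dx = pk[2] - center[2], dy = pk[1] - center[1]),
       valid = pk[3] > 0.5, peak_ratio = pk[4])
}

# run validation + replacement on (dr, dc) displacement matrices in image
# coordinates; returns updated matrices plus counts
validate_matrices <- function(dc, dr, valid, peak_ratio, config) {
  res <- cpp_validate(dc, dr, matrix(as.integer(valid), nrow(valid)),
                      peak_ratio, config$median_threshold, config$eps,
                      config$min_peak_ratio)
  list(dc = res$u, dr = res$v, valid = res$valid == 1L,
       n_replaced = res$n_replaced, flagged = res$flagged == 1L)
}

#' Validate and repair a velocity field
#'
#' Applies the normalized median test (Westerweel/Scarano style): a vector is
#' an outlier when the magnitude of its deviation from the 3x3 neighborhood
#' median exceeds `median_threshold * (median neighbor residual + eps)`, or
#' when its correlation peak ratio is below `min_peak_ratio`.  Outliers are
#' replaced by the component-wise median of their valid neighbors (one
#' iteration); outliers with no valid neighbor become invalid.
#'
#' @param field a `velocity_field`.
#' @param config a [piv_config()].
#' @return the validated field; the number of replaced vectors is in
#'   `attr(, "n_replaced")`.
#' @export
validate_vectors <- function(field, config = piv_config()) {
  stopifnot(inherits(field, "velocity_field"))
  if (!any(field$valid)) {
    warning("all vectors invalid; field returned unchanged")
    attr(field, "n_replaced") <- 0L
    return(field)
  }
  res <- cpp_validate(field$u, field$v,
                      matrix(as.integer(field$valid), nrow(field$valid)),
                      field$peak_ratio, config$median_threshold, config$eps,
                      config$min_peak_ratio)
  field$u <- res$u
  field$v <- res$v
  field$valid <- res$valid == 1L
  attr(field, "n_replaced") <- res$n_replaced
  field
}

# bilinear interpolation of matrix M defined on ascending grids gx, gy at
# points (px, py); NA outside the grid hull
interp_bilinear <- function(gx, gy, M, px, py) {
  nx <- length(gx); ny <- length(gy)
  ix <- findInterval(px, gx, rightmost.closed = TRUE)
  iy <- findInterval(py, gy, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(px))
  ok <- ix >= 1 & ix < nx & iy >= 1 & iy < ny
  ok[!is.na(px) & px == gx[nx]] <- ok[!is.na(px) & px == gx[nx]] & TRUE
  if (!any(ok)) return(out)
  i <- ix[ok]; j <- iy[ok]
  tx <- (px[ok] - gx[i]) / (gx[i + 1] - gx[i])
  ty <- (py[ok] - gy[j]) / (gy[j + 1] - gy[j])
  v00 <- M[cbind(i, j)]; v10 <- M[cbind(i + 1, j)]
  v01 <- M[cbind(i, j + 1)]; v11 <- M[cbind(i + 1, j + 1)]
  out[ok] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out
}

piv_pass <- function(frame_a, frame_b, win, step, pred_dr, pred_dc, config) {
  H <- nrow(frame_a); W <- ncol(frame_a)
  g <- interrogation_grid(H, W, win, step)
  nx <- length(g$tops_c); ny <- length(g$tops_r)
  gg <- expand.grid(c = g$tops_c, r = g$tops_r)
  res <- cpp_cc_batch(frame_a, frame_b, gg$r, gg$c, win,
                      as.integer(pred_dr), as.integer(pred_dc), FALSE)
  dim_set <- function(v) matrix(v, nx, ny)
  list(grid = g, nx = nx, ny = ny,
       dr = dim_set(res$dr), dc = dim_set(res$dc),
       peak_ratio = dim_set(res$peak_ratio),
       valid = dim_set(res$valid == 1L))
}

#' Compute PIV velocity fields for an image stack
#'
#' Runs windowed cross-correlation on every consecutive frame pair.  With
#' `passes = 2` a validated first pass at `window_size` provides integer
#' predictor shifts for a refining second pass at half window size.  The
#' returned fields use the y-up mathematical frame (`v = -` image-row
#' displacement); cells whose window center lies outside `roi` are flagged
#' invalid.
#'
#' @param stack an `image_stack` (or H x W x T array).
#' @param config a [piv_config()].
#' @param roi optional [roi_mask()] restricting validity to the embryonic
#'   disc.
#' @param pairs indices of frame pairs to process (default all `T - 1`).
#' @return list of `velocity_field`s, one per processed pair; total counts
#'   of replaced and invalid vectors are in attributes `n_replaced` /
#'   `n_invalid`.
#' @export
compute_piv <- function(stack, config = piv_config(), roi = NULL,
                        pairs = NULL) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  fi <- if (inherits(stack, "image_stack")) stack$frame_interval else 3
  T_ <- dim(frames)[3]
  if (is.null(T_) || T_ < 2) stop("stack must contain at least two frames")
  if (is.null(pairs)) pairs <- seq_len(T_ - 1)
  H <- dim(frames)[1]
  win <- config$window_size
  # the predictor pass runs on a coarse non-overlapping grid; the configured
  # overlap applies to the final (output) pass
  step <- if (config$passes >= 2L) win else
    max(1L, as.integer(round(win * (1 - config$overlap_fraction))))
  out <- vector("list", length(pairs))
  tot_rep <- 0L; tot_inv <- 0L

  for (k in seq_along(pairs)) {
    i <- pairs[k]
    a <- frames[, , i]; b <- frames[, , i + 1]

    g1 <- interrogation_grid(H, ncol(a), win, step)
    n1 <- length(g1$tops_c) * length(g1$tops_r)
    p1 <- piv_pass(a, b, win, step, integer(n1), integer(n1), config)
    v1 <- validate_matrices(p1$dc, p1$dr, p1$valid, p1$peak_ratio, config)
    tot_rep <- tot_rep + v1$n_replaced

    if (config$passes >= 2L) {
      win2 <- win %/% 2L
      step2 <- max(1L, as.integer(round(win2 * (1 - config$overlap_fraction))))
      g2 <- interrogation_grid(H, ncol(a), win2, step2)
      gg2 <- expand.grid(c = g2$centers_c, r = g2$centers_r)
      # predictor: bilinear interpolation of the validated pass-1 field
      dr_m <- v1$dr; dc_m <- v1$dc
      dr_m[!v1$valid] <- NA; dc_m[!v1$valid] <- NA
      dr_fill <- stats::median(dr_m, na.rm = TRUE)
      dc_fill <- stats::median(dc_m, na.rm = TRUE)
      if (!is.finite(dr_fill)) dr_fill <- 0
      if (!is.finite(dc_fill)) dc_fill <- 0
      dr_m[is.na(dr_m)] <- dr_fill; dc_m[is.na(dc_m)] <- dc_fill
      pr <- interp_bilinear(p1$grid$centers_c, p1$grid$centers_r, dr_m,
                            gg2$c, gg2$r)
      pc <- interp_bilinear(p1$grid$centers_c, p1$grid$centers_r, dc_m,
                            gg2$c, gg2$r)
      pr[is.na(pr)] <- dr_fill; pc[is.na(pc)] <- dc_fill
      p2 <- piv_pass(a, b, win2, step2,
                     as.integer(round(pr)), as.integer(round(pc)), config)
      v2 <- validate_matrices(p2$dc, p2$dr, p2$valid, p2$peak_ratio, config)
      tot_rep <- tot_rep + v2$n_replaced
      final <- list(pass = p2, val = v2)
    } else {
      final <- list(pass = p1, val = v1)
    }

    fld <- field_from_pass(final$pass, final$val, H, i, fi)
    if (!is.null(roi)) fld <- apply_roi(fld, roi)
    tot_inv <- tot_inv + sum(!fld$valid)
    out[[k]] <- fld
  }
  attr(out, "n_replaced") <- tot_rep
  attr(out, "n_invalid") <- tot_inv
  attr(out, "frame_interval") <- fi
  out
}

# convert an image-coordinate pass result to a y-up velocity_field
field_from_pass <- function(pass, val, H, time_index, frame_interval) {
  x <- pass$grid$centers_c
  y_img <- pass$grid$centers_r          # image rows, ascending = top-down
  y <- H + 1 - y_img                    # math y, descending
  ord <- order(y)
  velocity_field(x = x, y = y[ord],
                 u = val$dc[, ord, drop = FALSE],
                 v = -val$dr[, ord, drop = FALSE],
                 valid = val$valid[, ord, drop = FALSE],
                 peak_ratio = pass$peak_ratio[, ord, drop = FALSE],
                 time_index = time_index, frame_interval = frame_interval)
}
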