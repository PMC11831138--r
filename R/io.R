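# File I/O: multi-page TIFF stacks with plain-text sidecar metadata, and
# plain-text grid tables for velocity and scalar fields.  Field tables must
# round-trip bit-exactly, hence the %.17g formatting.

#' Write an image stack as a multi-page TIFF
#'
#' Pixel values are rescaled to `[0, 1]` (the scale factor is recorded in the
#' sidecar) and written as 16-bit grayscale pages.  A plain-text `key=value`
#' sidecar (`<path>.meta.txt`) stores pixel size, frame interval, seed,
#' preset and, when the stack came from [simulate_stack()], the ground-truth
#' per-frame vortex parameters.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @param sidecar write the metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  mx <- max(fr)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(fr)[3]), function(i) fr[, , i] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  if (sidecar) {
    sc <- attr(stack, "scenario")
    lines <- c(sprintf("pixel_size=%.17g", stack$pixel_size),
               sprintf("frame_interval=%.17g", stack$frame_interval),
               sprintf("intensity_scale=%.17g", mx),
               sprintf("n_frames=%d", dim(fr)[3]))
    if (!is.null(sc)) {
      lines <- c(lines,
                 sprintf("seed=%d", sc$seed),
                 sprintf("preset=%s", if (is.null(sc$preset)) "custom"
                         else sc$preset),
                 sprintf("disc_center=%.17g,%.17g", sc$disc_center[1],
                         sc$disc_center[2]),
                 sprintf("disc_radius=%.17g", sc$disc_radius))
    }
    tr <- attr(stack, "truth")
    if (!is.null(tr)) {
      lines <- c(lines, paste0(
        "truth.", tr$frame, "=",
        sprintf("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g",
                tr$t_hours, tr$gamma_left, tr$gamma_right,
                tr$left_x, tr$left_y, tr$right_x, tr$right_y)))
    }
    writeLines(lines, paste0(path, ".meta.txt"))
  }
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Restores metadata from the sidecar written by [write_stack()] when
#' present; otherwise `pixel_size`/`frame_interval` fall back to the given
#' defaults.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval fallbacks when no sidecar exists.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, pixel_size = 1, frame_interval = 3) {
  if (!file.exists(path)) stop(bf_condition("bf_input_error",
                                            paste("input not readable:", path)))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  meta_path <- paste0(path, ".meta.txt")
  meta <- list()
  if (file.exists(meta_path)) {
    kv <- readLines(meta_path)
    kv <- kv[!startsWith(kv, "truth.")]
    parts <- strsplit(kv, "=", fixed = TRUE)
    meta <- stats::setNames(lapply(parts, function(p)
      paste(p[-1], collapse = "=")), vapply(parts, `[`, "", 1))
    if (!is.null(meta$pixel_size)) pixel_size <- as.numeric(meta$pixel_size)
    if (!is.null(meta$frame_interval))
      frame_interval <- as.numeric(meta$frame_interval)
    if (!is.null(meta$intensity_scale))
      scale <- as.numeric(meta$intensity_scale)
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  frames <- array(0, dim = c(H, W, length(pages)))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    frames[, , i] <- pg * scale
  }
  st <- structure(list(frames = frames, pixel_size = pixel_size,
                       frame_interval = frame_interval),
                  class = "image_stack")
  attr(st, "meta") <- meta
  st
}

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Serialize a velocity field as a plain-text grid table
#'
#' One row per grid cell with columns `time_index, x, y, u, v, valid,
#' peak_ratio`; `#`-prefixed header lines carry the grid geometry.  Numeric
#' values use full `%.17g` precision so that a write/read cycle is bit-exact.
#'
#' @param field a `velocity_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path) {
  stopifnot(inherits(field, "velocity_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# bilateralflow velocity field",
               sprintf("# nx=%d ny=%d", length(field$x), length(field$y)),
               sprintf("# frame_interval=%.17g",
                       attr(field, "frame_interval") %||% NA_real_),
               "time_index\tx\ty\tu\tv\tvalid\tpeak_ratio"), con)
  g <- expand.grid(ix = seq_along(field$x), iy = seq_along(field$y))
  ti <- field$time_index %||% NA_integer_
  writeLines(paste(rep(ti, nrow(g)),
                   fmt17(field$x[g$ix]), fmt17(field$y[g$iy]),
                   fmt17(field$u[cbind(g$ix, g$iy)]),
                   fmt17(field$v[cbind(g$ix, g$iy)]),
                   as.integer(field$valid[cbind(g$ix, g$iy)]),
                   fmt17(field$peak_ratio[cbind(g$ix, g$iy)]),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a velocity field written by [write_velocity_field()]
#' @param path table path.
#' @return a `velocity_field`.
#' @export
read_velocity_field <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#")
  hdr <- readLines(path, n = 3)
  fi <- suppressWarnings(as.numeric(sub(".*frame_interval=", "", hdr[3])))
  x <- sort(unique(d$x)); y <- sort(unique(d$y))
  ix <- match(d$x, x); iy <- match(d$y, y)
  mk <- function(col) {
    m <- matrix(NA_real_, length(x), length(y))
    m[cbind(ix, iy)] <- col
    m
  }
  vm <- matrix(FALSE, length(x), length(y))
  vm[cbind(ix, iy)] <- d$valid == 1
  velocity_field(x, y, mk(d$u), mk(d$v), vm, mk(d$peak_ratio),
                 time_index = d$time_index[1],
                 frame_interval = if (is.finite(fi)) fi else NULL)
}

#' Serialize a scalar field as a plain-text grid table
#' @param field a `scalar_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scalar_field <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  w <- field$window %||% c(NA_real_, NA_real_)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# bilateralflow scalar field",
               sprintf("# kind=%s", field$kind),
               sprintf("# window=%.17g,%.17g", w[1], w[2]),
               "x\ty\tvalue\tvalid"), con)
  g <- expand.grid(ix = seq_along(field$x), iy = seq_along(field$y))
  writeLines(paste(fmt17(field$x[g$ix]), fmt17(field$y[g$iy]),
                   fmt17(field$values[cbind(g$ix, g$iy)]),
                   as.integer(field$valid[cbind(g$ix, g$iy)]),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a scalar field written by [write_scalar_field()]
#' @param path table path.
#' @return a `scalar_field`.
#' @export
read_scalar_field <- function(path) {
  hdr <- readLines(path, n = 3)
  kind <- sub("# kind=", "", hdr[2], fixed = TRUE)
  w <- suppressWarnings(as.numeric(strsplit(
    sub("# window=", "", hdr[3], fixed = TRUE), ",")[[1]]))
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#")
  x <- sort(unique(d$x)); y <- sort(unique(d$y))
  ix <- match(d$x, x); iy <- match(d$y, y)
  vals <- matrix(NA_real_, length(x), length(y))
  vals[cbind(ix, iy)] <- d$value
  vm <- matrix(FALSE, length(x), length(y))
  vm[cbind(ix, iy)] <- d$valid == 1
  scalar_field(x, y, vals, vm, kind,
               window = if (all(is.finite(w))) w else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so that callers (and the CLI) can map error categories
# to distinct exit codes
bf_condition <- function(class, msg) {
  structure(class = c(class, "bf_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
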