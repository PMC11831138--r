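# Pipeline orchestration: simulate/load -> PIV -> window-averaged maps ->
# midlines -> asymmetry metrics -> report bundle with manifest.

#' Pipeline configuration
#'
#' Exactly one of `preset` (synthetic scenario) or `input` (multi-page TIFF
#' path) must be given.  Times in outputs are hours post motion onset.
#'
#' @param preset synthetic scenario preset name (see [make_scenario()]).
#' @param input path to a multi-page TIFF stack.
#' @param seed RNG seed for the whole run.
#' @param piv a [piv_config()].
#' @param roi optional [roi_mask()]; defaults to the scenario's embryonic
#'   disc (required for TIFF input).
#' @param am anatomical-midline annotation: a 2 x 2 matrix of points along
#'   the primitive streak, or `"synthetic-default"` (the disc's vertical
#'   diameter).
#' @param window_hours width of the short averaging windows (default 1 h;
#'   5 h halves and the full-duration average are always added).
#' @param thresholds retention thresholds as fractions of the per-window
#'   maximum (default 0.3, 0.5, 0.7).
#' @param report_threshold threshold used for dominance classification and
#'   the summary (default 0.5).
#' @param dividing_midline which midline separates L from R for the area
#'   metrics: `"FM"` (default), `"BM"` or `"AM"`.  When the chosen flow
#'   midline is undefined in a window the AM is used as fallback (and
#'   recorded).
#' @param delta,persistence dominance dead-band and run length, see
#'   [classify_dominance()].
#' @param test_after windows starting at or after this time (hours) enter
#'   the paired L/R rank test (default 6).
#' @param detect_onset detect the motion onset from the data and re-zero
#'   time there (default FALSE; synthetic stacks start at onset).
#' @param global_max use the maximum over all windows instead of the
#'   per-window maximum when thresholding.
#' @param derive `"average_then_derive"` (default: average velocity, then
#'   derive speed/vorticity) or `"derive_then_average"`.
#' @param shape,tracer_density,noise_sd,spot_sigma synthetic rendering
#'   parameters, see [simulate_stack()].
#' @param duration override the scenario duration (hours).
#' @param output_dir directory for the report bundle, or `NULL` to skip all
#'   file output.
#' @param write_png,write_fields toggle figure / field-table output.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(preset = NULL, input = NULL, seed = 1L,
                            piv = piv_config(), roi = NULL,
                            am = "synthetic-default", window_hours = 1,
                            thresholds = c(0.3, 0.5, 0.7),
                            report_threshold = 0.5,
                            dividing_midline = c("FM", "BM", "AM"),
                            delta = 0.02, persistence = 2L, test_after = 6,
                            detect_onset = FALSE, global_max = FALSE,
                            derive = c("average_then_derive",
                                       "derive_then_average"),
                            shape = c(256, 256), tracer_density = 0.02,
                            noise_sd = 0.05, spot_sigma = 1.5,
                            duration = NULL, output_dir = NULL,
                            write_png = TRUE, write_fields = TRUE) {
  dividing_midline <- match.arg(dividing_midline)
  derive <- match.arg(derive)
  if (is.null(preset) == is.null(input))
    stop(bf_condition("bf_config_error",
                      "exactly one of `preset` or `input` must be given"))
  if (!all(thresholds > 0 & thresholds < 1) ||
      report_threshold <= 0 || report_threshold >= 1)
    stop(bf_condition("bf_config_error", "thresholds must lie in (0, 1)"))
  if (window_hours <= 0)
    stop(bf_condition("bf_config_error", "window_hours must be positive"))
  structure(list(preset = preset, input = input, seed = as.integer(seed),
                 piv = piv, roi = roi, am = am,
                 window_hours = window_hours, thresholds = thresholds,
                 report_threshold = report_threshold,
                 dividing_midline = dividing_midline, delta = delta,
                 persistence = as.integer(persistence),
                 test_after = test_after, detect_onset = detect_onset,
                 global_max = global_max, derive = derive, shape = shape,
                 tracer_density = tracer_density, noise_sd = noise_sd,
                 spot_sigma = spot_sigma, duration = duration,
                 output_dir = output_dir, write_png = write_png,
                 write_fields = write_fields),
            class = "pipeline_config")
}

#' Detect the motion-onset frame
#'
#' The ROI-median frame-to-frame speed is compared with its baseline level
#' over the first `baseline_pairs` frame pairs; onset is the first pair from
#' which the median speed exceeds `factor` times the baseline for
#' `consecutive` consecutive pairs.  If no pair triggers, 1 is returned with
#' a warning (motion assumed from the first frame).
#'
#' @param x an `image_stack` (at least 10 frames) or a list of
#'   `velocity_field`s from [compute_piv()].
#' @param roi optional [roi_mask()] (used when `x` is a stack).
#' @param config [piv_config()] for the stack case.
#' @param baseline_pairs,factor,consecutive detection parameters.
#' @return 1-based index of the first moving frame pair.
#' @export
detect_motion_onset <- function(x, roi = NULL, config = piv_config(),
                                baseline_pairs = 5L, factor = 2,
                                consecutive = 3L) {
  if (inherits(x, "image_stack")) {
    if (dim(x$frames)[3] < 10)
      stop(bf_condition("bf_input_error",
                        "onset detection needs at least 10 frames"))
    x <- compute_piv(x, config, roi)
  }
  med <- vapply(x, function(f) {
    sp <- sqrt(f$u^2 + f$v^2)
    m <- stats::median(sp[f$valid])
    if (is.na(m)) 0 else m
  }, numeric(1))
  n <- length(med)
  base <- stats::median(med[seq_len(min(baseline_pairs, n))])
  thr <- factor * base
  for (i in seq_len(n - consecutive + 1)) {
    if (all(med[i:(i + consecutive - 1)] > thr)) return(i)
  }
  warning("no motion onset detected; assuming motion from the first frame")
  1L
}

# window-averaged maps + midlines + areas for one time window
quantify_window <- function(fields, window, roi, am_line, config) {
  avg <- time_average(fields, window)
  if (config$derive == "average_then_derive") {
    sp <- speed_field(avg)
    vo <- vorticity_field(avg)
    sp$window <- window; vo$window <- window
  } else {
    sp <- time_average(lapply(fields_in_window(fields, window), speed_field),
                       NULL)
    vo <- time_average(lapply(fields_in_window(fields, window),
                              vorticity_field), NULL)
    sp$window <- window; vo$window <- window
  }
  pair <- find_vortex_centers(vo, avg)
  bm <- biophysical_midline(pair)
  fm <- flow_midline(pair, avg)
  list(window = window, avg = avg, speed = sp, vorticity = vo, pair = pair,
       am = am_line, bm = bm, fm = fm)
}

fields_in_window <- function(fields, window) {
  tt <- vapply(fields, field_time_hours, numeric(1))
  fields[tt >= window[1] & tt < window[2]]
}

midline_angle <- function(line) if (is.null(line)) NA_real_ else
  line$angle_to_vertical

#' Run the full quantification pipeline
#'
#' Orchestrates simulate/load, PIV, window averaging, midline construction
#' and asymmetry quantification, optionally writing the complete report
#' bundle (field tables, CSVs, PNG maps, JSON manifest with checksums).
#' Re-running with an identical configuration reproduces all numeric outputs
#' bit-exactly.
#'
#' @param config a [pipeline_config()].
#' @return a `bf_run` list: `windows` (per-window quantification),
#'   `midlines` (data.frame), `areas` (data.frame), `dominance`,
#'   `rank_test`, `center_track`, `onset_pair`, `fields` (per-pair velocity
#'   fields), plus the scenario and config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  scenario <- NULL
  if (!is.null(config$input)) {
    stack <- read_stack(config$input)
  } else {
    scenario <- make_scenario(config$preset, seed = config$seed,
                              image_size = config$shape[1])
    if (!is.null(config$duration)) scenario$duration <- config$duration
    stack <- simulate_stack(scenario, shape = config$shape,
                            tracer_density = config$tracer_density,
                            spot_sigma = config$spot_sigma,
                            noise_sd = config$noise_sd)
  }

  roi <- config$roi
  if (is.null(roi)) {
    if (is.null(scenario))
      stop(bf_condition("bf_config_error",
                        "an ROI is required for TIFF input"))
    roi <- roi_mask(scenario$disc_center, scenario$disc_radius)
  }

  fields <- compute_piv(stack, config$piv, roi)
  onset <- 1L
  if (config$detect_onset) {
    onset <- detect_motion_onset(fields)
    if (onset > 1) {
      fields <- fields[onset:length(fields)]
      for (i in seq_along(fields)) fields[[i]]$time_index <- i
    }
  }

  fi <- attr(fields[[1]], "frame_interval") %||% stack$frame_interval
  duration_h <- length(fields) * fi / 60
  n_win <- floor(duration_h / config$window_hours + 1e-9)
  hourly <- lapply(seq_len(n_win), function(k)
    c((k - 1) * config$window_hours, k * config$window_hours))

  am_line <- if (identical(config$am, "synthetic-default")) {
    line2d(roi$center, c(0, 1))
  } else {
    midline_from_points(config$am[1, ], config$am[2, ])
  }

  wq <- lapply(hourly, function(w) quantify_window(fields, w, roi, am_line,
                                                   config))

  midlines <- do.call(rbind, lapply(wq, function(q) {
    lc <- q$pair$left_center %||% c(NA, NA)
    rc <- q$pair$right_center %||% c(NA, NA)
    bm_a <- midline_angle(q$bm); fm_a <- midline_angle(q$fm)
    data.frame(window_start = q$window[1], window_end = q$window[2],
               am_angle = am_line$angle_to_vertical,
               bm_angle = bm_a, fm_angle = fm_a,
               bm_fm_sep = abs(bm_a - fm_a),
               left_x = lc[1], left_y = lc[2],
               right_x = rc[1], right_y = rc[2],
               center_distance = sqrt(sum((lc - rc)^2)),
               left_closed = q$pair$left_closed,
               right_closed = q$pair$right_closed,
               left_peak_vorticity = q$pair$left_peak_vorticity,
               right_peak_vorticity = q$pair$right_peak_vorticity)
  }))

  pick_midline <- function(q) {
    ml <- switch(config$dividing_midline, FM = q$fm, BM = q$bm,
                 AM = q$am)
    if (is.null(ml)) list(line = q$am, used = "AM-fallback")
    else list(line = ml, used = config$dividing_midline)
  }

  # global maxima per kind, for global-max thresholding mode
  gmax <- list(speed = NA_real_, vorticity = NA_real_)
  if (config$global_max) {
    for (kind in names(gmax)) {
      gmax[[kind] ] <- max(vapply(wq, function(q) {
        f <- q[[kind]]
        mag <- if (kind == "vorticity") abs(f$values) else f$values
        m <- suppressWarnings(max(mag[f$valid], na.rm = TRUE))
        if (is.finite(m)) m else 0
      }, numeric(1)))
    }
  }

  areas <- do.call(rbind, lapply(wq, function(q) {
    ml <- pick_midline(q)
    do.call(rbind, lapply(c("speed", "vorticity"), function(kind) {
      do.call(rbind, lapply(config$thresholds, function(thr) {
        res <- tryCatch({
          r <- threshold_area(q[[kind]], thr, ml$line,
                              v_max = if (config$global_max)
                                gmax[[kind]] else NULL)
          fractional_areas(r)
        }, bf_error = function(e) NULL)
        data.frame(window_start = q$window[1], window_end = q$window[2],
                   kind = kind, threshold = thr,
                   A_L = res$A_L %||% NA_real_, A_R = res$A_R %||% NA_real_,
                   f_L = res$f_L %||% NA_real_, f_R = res$f_R %||% NA_real_,
                   midline_used = if (is.null(res)) NA_character_ else
                     ml$used)
      }))
    }))
  }))

  rep_rows <- areas$kind == "speed" &
    areas$threshold == config$report_threshold
  f_R <- areas$f_R[rep_rows]
  starts <- areas$window_start[rep_rows]
  dominance <- tryCatch(
    classify_dominance(f_R, starts, delta = config$delta,
                       persistence = config$persistence),
    bf_error = function(e) list(labels = rep(NA_character_, length(f_R)),
                                end_dominance = NA_character_,
                                onset = NA_real_))

  test_rows <- rep_rows & areas$window_start >= config$test_after
  rank_test <- if (sum(test_rows, na.rm = TRUE) >= 1 &&
                   any(!is.na(areas$f_L[test_rows])))
    paired_rank_test(areas$f_L[test_rows], areas$f_R[test_rows])
  else NULL

  track <- track_centers(lapply(wq, `[[`, "pair"),
                         do.call(rbind, hourly))

  halves <- list(c(0, duration_h / 2), c(duration_h / 2, duration_h))
  half_q <- lapply(halves, function(w)
    quantify_window(fields, w, roi, am_line, config))
  full_q <- quantify_window(fields, c(0, duration_h), roi, am_line, config)

  run <- structure(list(config = config, scenario = scenario, roi = roi,
                        fields = fields, windows = wq, half_windows = half_q,
                        full_window = full_q, midlines = midlines,
                        areas = areas, dominance = dominance,
                        rank_test = rank_test, center_track = track,
                        onset_pair = onset, duration_hours = duration_h,
                        n_replaced = attr(fields, "n_replaced"),
                        n_invalid = attr(fields, "n_invalid")),
                   class = "bf_run")
  if (!is.null(config$output_dir)) write_bundle(run, config$output_dir)
  run
}

# deterministic CSV writer: numerics at full precision, LF line endings
write_csv_exact <- function(df, path) {
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- fmt17(df[[nm]])
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(unname(as.list(df)), sep = ",")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

write_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  paths <- character(0)
  add <- function(p) paths[[length(paths) + 1]] <<- p

  p <- file.path(dir, "midlines.csv")
  write_csv_exact(run$midlines, p); add(p)
  p <- file.path(dir, "asymmetry.csv")
  write_csv_exact(run$areas, p); add(p)
  p <- file.path(dir, "center_track.csv")
  write_csv_exact(as.data.frame(run$center_track), p); add(p)

  rep_rows <- run$areas$kind == "speed" &
    run$areas$threshold == cfg$report_threshold
  summary_df <- data.frame(
    window_start = run$areas$window_start[rep_rows],
    f_L = run$areas$f_L[rep_rows], f_R = run$areas$f_R[rep_rows],
    dominance = run$dominance$labels)
  p <- file.path(dir, "summary.csv")
  write_csv_exact(summary_df, p); add(p)

  if (cfg$write_fields) {
    fdir <- file.path(dir, "fields")
    dir.create(fdir, showWarnings = FALSE)
    for (q in c(run$windows, run$half_windows, list(run$full_window))) {
      tag <- sprintf("%g-%gh", q$window[1], q$window[2])
      p <- file.path(fdir, sprintf("velocity_%s.tsv", tag))
      write_velocity_field(q$avg, p); add(p)
      p <- file.path(fdir, sprintf("speed_%s.tsv", tag))
      write_scalar_field(q$speed, p); add(p)
      p <- file.path(fdir, sprintf("vorticity_%s.tsv", tag))
      write_scalar_field(q$vorticity, p); add(p)
    }
  }

  if (cfg$write_png) {
    q <- run$full_window
    p <- file.path(dir, "speed_full.png")
    plot_scalar_field(q$speed, p, main = "time-averaged speed"); add(p)
    p <- file.path(dir, "vorticity_full.png")
    plot_scalar_field(q$vorticity, p,
                      main = "time-averaged vorticity"); add(p)
    p <- file.path(dir, "streamlines_full.png")
    plot_streamline_map(q$avg, run$roi, p); add(p)
  }

  manifest <- list(
    package = "bilateralflow",
    version = as.character(utils::packageVersion("bilateralflow")),
    seed = cfg$seed,
    preset = cfg$preset %||% NA,
    input = cfg$input %||% NA,
    config = cfg[c("window_hours", "thresholds", "report_threshold",
                   "dividing_midline", "delta", "persistence", "test_after",
                   "global_max", "derive", "shape", "tracer_density",
                   "noise_sd", "spot_sigma")],
    piv = unclass(cfg$piv),
    n_replaced_vectors = run$n_replaced,
    n_invalid_vectors = run$n_invalid,
    onset_pair = run$onset_pair,
    end_dominance = run$dominance$end_dominance,
    dominance_onset_hours = run$dominance$onset,
    files = data.frame(name = basename(unlist(paths)),
                       path = unlist(paths),
                       md5 = unname(tools::md5sum(unlist(paths)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}

# streamline overview figure: seeds on a coarse grid inside the ROI
plot_streamline_map <- function(field, roi, file = NULL) {
  seeds <- expand.grid(
    x = seq(min(field$x), max(field$x), length.out = 9),
    y = seq(min(field$y), max(field$y), length.out = 9))
  inside <- (seeds$x - roi$center[1])^2 + (seeds$y - roi$center[2])^2 <=
    (0.9 * roi$radius)^2
  seeds <- as.matrix(seeds[inside, ])
  lines <- streamlines(field, seeds, max_length = 400L)
  if (!is.null(file)) grDevices::png(file, width = 640, height = 640)
  plot(NA, xlim = range(field$x), ylim = range(field$y), asp = 1,
       xlab = "x (px)", ylab = "y (px)", main = "streamlines")
  graphics::symbols(roi$center[1], roi$center[2], circles = roi$radius,
                    inches = FALSE, add = TRUE, fg = "grey")
  for (pl in lines) if (nrow(pl) > 1) graphics::lines(pl, col = "steelblue")
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}
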