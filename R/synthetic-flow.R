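#' @useDynLib bilateralflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate conventions used throughout the package
# --------------------------------------------------
# Images are matrices with row 1 at the top.  All physical quantities live in
# a y-up mathematical frame: x = column index, y = H + 1 - row index, so the
# image top is +y and is taken as the anterior direction of the embryo.
# Positive circulation and positive vorticity mean counterclockwise rotation
# in this frame; with anterior up, the embryo's left side is the viewer's
# left (small x).  The left vortex of the bilateral flow rotates
# counterclockwise (omega > 0) and the right vortex clockwise (omega < 0).

#' Specify a single Lamb-Oseen vortex
#'
#' The generator models each rotating cell-flow vortex as a Lamb-Oseen
#' (regularized) vortex: tangential speed
#' \eqn{u_\theta(r) = \Gamma/(2\pi r)\,(1 - e^{-r^2/r_c^2})}, which is finite
#' (zero) at the core center and decays like a point vortex far away.
#'
#' @param center numeric length-2, vortex center (px, math frame).
#' @param circulation signed circulation Gamma (px^2/frame at the 3-min
#'   reference frame interval); positive = counterclockwise. May be zero
#'   (vortex absent).
#' @param core_radius core radius r_c (px), must be > 0.
#' @return an object of class `vortex_spec`.
#' @export
vortex_spec <- function(center, circulation, core_radius) {
  stopifnot(length(center) == 2, is.finite(circulation), core_radius > 0)
  structure(list(center = as.numeric(center),
                 circulation = as.numeric(circulation),
                 core_radius = as.numeric(core_radius)),
            class = "vortex_spec")
}

#' Define a synthetic bilateral-flow scenario
#'
#' A scenario is a circular embryonic disc containing two (possibly
#' degenerate) counterrotating Lamb-Oseen vortices embedded in a stationary
#' surround.  Circulations grow linearly from zero over `ramp_duration` hours
#' (the initial transient of the real flows); after `dominance_onset` the
#' magnitude of the right-vortex circulation is multiplied by
#' `dominance_factor`.  A uniform `drift` velocity advects the whole flow
#' pattern (vortex centers included) inside the disc.
#'
#' @param disc_center,disc_radius circular embryonic region (px).
#' @param left_vortex,right_vortex [vortex_spec()] objects.
#' @param ramp_duration hours over which circulations ramp linearly from 0.
#' @param dominance_onset hours, or `NULL` for no dominance switch.
#' @param dominance_factor scalar >= 1 applied to |right circulation| after
#'   onset.
#' @param drift uniform background velocity (px/frame at the 3-min
#'   reference interval) inside the disc.
#' @param frame_interval minutes between frames (default 3).  The flow is
#'   fixed in physical time, so halving the frame interval halves per-frame
#'   displacements.
#' @param duration total imaged time in hours (default 10).
#' @param seed RNG seed controlling tracer placement and image noise.
#' @return an object of class `flow_scenario`.
#' @export
flow_scenario <- function(disc_center, disc_radius, left_vortex, right_vortex,
                          ramp_duration = 2, dominance_onset = NULL,
                          dominance_factor = 1, drift = c(0, 0),
                          frame_interval = 3, duration = 10, seed = 1L) {
  stopifnot(inherits(left_vortex, "vortex_spec"),
            inherits(right_vortex, "vortex_spec"),
            disc_radius > 0, length(disc_center) == 2,
            ramp_duration >= 0, ramp_duration <= duration,
            dominance_factor >= 1, length(drift) == 2,
            frame_interval > 0, duration > 0)
  if (!is.null(dominance_onset))
    stopifnot(dominance_onset >= 0, dominance_onset <= duration)
  structure(list(disc_center = as.numeric(disc_center),
                 disc_radius = as.numeric(disc_radius),
                 left_vortex = left_vortex, right_vortex = right_vortex,
                 ramp_duration = as.numeric(ramp_duration),
                 dominance_onset = dominance_onset,
                 dominance_factor = as.numeric(dominance_factor),
                 drift = as.numeric(drift),
                 frame_interval = as.numeric(frame_interval),
                 duration = as.numeric(duration),
                 seed = as.integer(seed)),
            class = "flow_scenario")
}

#' Preset synthetic flow regimes
#'
#' Presets mirror the qualitative regimes seen in live-imaged embryos:
#' \describe{
#'   \item{symmetric}{equal and opposite circulations, mirrored centers, no
#'     dominance switch; the null hypothesis of bilateral symmetry.}
#'   \item{right_dominant}{symmetric until `dominance_onset` (default 6 h),
#'     after which the right circulation is amplified 1.5x; emulates the late
#'     right-side dominance of control embryos.}
#'   \item{left_then_right}{left circulation 20% stronger from the start,
#'     right amplified 1.8x after 6 h, so dominance flips from L to R.}
#'   \item{single_right_vortex}{left circulation zero; only the clockwise
#'     right vortex is present, emulating the degenerate flow of
#'     mitotically arrested embryos.}
#' }
#'
#' At the default 256 px image size the disc has radius 110 px, vortex
#' centers sit 45 px either side of the vertical diameter, core radii are
#' 30 px and |Gamma| = 350 px^2/frame (peak tangential speed about 1.2
#' px/frame).  Frames are 3 min apart for 10 h.
#'
#' @param preset one of `"symmetric"`, `"right_dominant"`,
#'   `"left_then_right"`, `"single_right_vortex"`.
#' @param seed RNG seed stored in the scenario.
#' @param image_size side length in px of the square frame the scenario is
#'   designed for (geometry scales linearly with it).
#' @param dominance_onset,dominance_factor overrides for the dominant
#'   presets.
#' @return a [flow_scenario()].
#' @export
make_scenario <- function(preset = c("symmetric", "right_dominant",
                                     "left_then_right", "single_right_vortex"),
                          seed = 1L, image_size = 256,
                          dominance_onset = 6, dominance_factor = 1.5) {
  preset <- match.arg(preset)
  s <- image_size / 256
  cx <- (image_size + 1) / 2
  ctr <- c(cx, cx)
  d <- 45 * s
  rc <- 30 * s
  gam <- 350 * s
  lv <- vortex_spec(ctr + c(-d, 0), +gam, rc)
  rv <- vortex_spec(ctr + c(+d, 0), -gam, rc)
  sc <- switch(preset,
    symmetric = flow_scenario(ctr, 110 * s, lv, rv, seed = seed),
    right_dominant = flow_scenario(ctr, 110 * s, lv, rv,
                                   dominance_onset = dominance_onset,
                                   dominance_factor = dominance_factor,
                                   seed = seed),
    left_then_right = flow_scenario(ctr, 110 * s,
                                    vortex_spec(ctr + c(-d, 0), +1.2 * gam, rc),
                                    rv,
                                    dominance_onset = dominance_onset,
                                    dominance_factor = 1.5 * 1.2,
                                    seed = seed),
    single_right_vortex = flow_scenario(ctr, 110 * s,
                                        vortex_spec(ctr + c(-d, 0), 0, rc),
                                        rv, seed = seed))
  sc$preset <- preset
  sc
}

# effective (ramped, dominance-adjusted) circulations at time t (hours)
effective_circulations <- function(scenario, t) {
  ramp <- if (scenario$ramp_duration > 0)
    pmin(1, t / scenario$ramp_duration) else 1
  gl <- scenario$left_vortex$circulation * ramp
  gr <- scenario$right_vortex$circulation * ramp
  if (!is.null(scenario$dominance_onset) && t >= scenario$dominance_onset)
    gr <- gr * scenario$dominance_factor
  c(left = gl, right = gr)
}

# The underlying flow is fixed in physical time: circulations and drift are
# expressed in px^2/frame and px/frame at the 3-min reference frame
# interval.  Imaging the same flow at a different frame interval scales
# per-frame displacements proportionally (linearity in the frame interval).
REF_FRAME_MIN <- 3

# vortex centers at time t (hours), displaced by the drift
vortex_centers_at <- function(scenario, t) {
  ref_frames <- t * 60 / REF_FRAME_MIN
  shift <- scenario$drift * ref_frames
  list(left = scenario$left_vortex$center + shift,
       right = scenario$right_vortex$center + shift)
}

lamb_oseen_uv <- function(p, center, gamma, rc) {
  wx <- p[, 1] - center[1]
  wy <- p[, 2] - center[2]
  r2 <- wx^2 + wy^2
  f <- ifelse(r2 > 0, gamma / (2 * pi * r2) * (1 - exp(-r2 / rc^2)), 0)
  cbind(-wy * f, wx * f)
}

#' Analytic scenario velocity
#'
#' Evaluates the ground-truth velocity of a [flow_scenario()]: the
#' superposition of the two Lamb-Oseen vortices (with the circulation ramp
#' and dominance factor applied) plus the drift, and identically zero
#' outside the embryonic disc (stationary extraembryonic surround).  Each
#' off-center vortex is accompanied by its circle-theorem image (opposite
#' circulation at the inverse point with respect to the disc), which cancels
#' the normal velocity on the disc boundary: the bilateral recirculation
#' closes inside the embryonic region instead of leaking across its rim,
#' matching the closed polonaise loops of the real flows.  A vortex at the
#' disc center needs no image.
#'
#' @param p numeric n x 2 matrix (or length-2 vector) of positions (px).
#' @param t time in hours since motion onset, in `[0, duration]`.
#' @param scenario a [flow_scenario()].
#' @return n x 2 matrix of velocities (px/frame, y-up frame).
#' @export
analytic_velocity <- function(p, t, scenario) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  g <- effective_circulations(scenario, t)
  ctr <- vortex_centers_at(scenario, t)
  one_vortex <- function(center, gamma, rc) {
    if (gamma == 0) return(matrix(0, nrow(p), 2))
    v <- lamb_oseen_uv(p, center, gamma, rc)
    w <- center - scenario$disc_center
    d2 <- sum(w^2)
    if (d2 > 1e-12) {
      img <- scenario$disc_center + w * scenario$disc_radius^2 / d2
      v <- v + lamb_oseen_uv(p, img, -gamma, rc)
    }
    v
  }
  v <- one_vortex(ctr$left, g[["left"]], scenario$left_vortex$core_radius) +
    one_vortex(ctr$right, g[["right"]], scenario$right_vortex$core_radius)
  v[, 1] <- v[, 1] + scenario$drift[1]
  v[, 2] <- v[, 2] + scenario$drift[2]
  # convert from the 3-min reference to the scenario's own frame interval
  v <- v * (scenario$frame_interval / REF_FRAME_MIN)
  dx <- p[, 1] - scenario$disc_center[1]
  dy <- p[, 2] - scenario$disc_center[2]
  outside <- dx^2 + dy^2 > scenario$disc_radius^2
  v[outside, ] <- 0
  v
}

#' Create a tracer ensemble
#'
#' Tracers stand in for fluorescently tagged cells.  Positions are uniform
#' over the frame (tracers outside the disc never move, emulating the
#' stationary extraembryonic material); intensities are uniform in
#' `intensity_range`.
#'
#' @param n number of tracers.
#' @param shape image `c(H, W)` in px.
#' @param spot_sigma Gaussian spot standard deviation (px).
#' @param intensity_range range of per-tracer intensities.
#' @return an object of class `tracer_ensemble`.
#' @export
make_tracers <- function(n, shape, spot_sigma = 1.5,
                         intensity_range = c(0.7, 1.3)) {
  stopifnot(n >= 1, spot_sigma > 0, all(intensity_range > 0))
  pos <- cbind(stats::runif(n, 1, shape[2]), stats::runif(n, 1, shape[1]))
  structure(list(positions = pos,
                 intensities = stats::runif(n, intensity_range[1],
                                            intensity_range[2]),
                 spot_sigma = spot_sigma),
            class = "tracer_ensemble")
}

# one RK4 step of size h frames for positions p (n x 2) at time t_h (hours);
# dt_h is the duration of one frame in hours
rk4_step <- function(p, t_h, h, dt_h, vel) {
  k1 <- vel(p, t_h)
  k2 <- vel(p + (h / 2) * k1, t_h + (h / 2) * dt_h)
  k3 <- vel(p + (h / 2) * k2, t_h + (h / 2) * dt_h)
  k4 <- vel(p + h * k3, t_h + h * dt_h)
  p + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Advect tracers through a flow
#'
#' Integrates tracer positions through the scenario's analytic velocity (or
#' any substitute velocity function) with a classical 4th-order Runge-Kutta
#' step per frame interval.  Tracers outside the embryonic disc see zero
#' velocity and therefore stay frozen in place.
#'
#' @param tracers a [make_tracers()] ensemble.
#' @param scenario a [flow_scenario()]; ignored if `velocity_fn` is given.
#' @param t0 start time (hours).
#' @param n_steps number of frame intervals to integrate (>= 1).
#' @param n_substeps RK4 substeps per frame interval (default 1).
#' @param velocity_fn optional `function(p, t_hours) -> n x 2` replacing the
#'   scenario field (used for convergence and conservation checks).
#' @return list of `n_steps + 1` tracer ensembles (including the initial
#'   one).
#' @export
advect_tracers <- function(tracers, scenario = NULL, t0 = 0, n_steps,
                           n_substeps = 1L, velocity_fn = NULL) {
  stopifnot(inherits(tracers, "tracer_ensemble"), n_steps >= 1,
            n_substeps >= 1)
  stopifnot(!is.null(scenario) || !is.null(velocity_fn))
  vel <- if (is.null(velocity_fn))
    function(p, t) analytic_velocity(p, t, scenario) else velocity_fn
  dt_h <- if (inherits(scenario, "flow_scenario"))
    scenario$frame_interval / 60 else 0.05
  h <- 1 / n_substeps
  out <- vector("list", n_steps + 1)
  out[[1]] <- tracers
  p <- tracers$positions
  for (i in seq_len(n_steps)) {
    t_h <- t0 + (i - 1) * dt_h
    for (s in seq_len(n_substeps))
      p <- rk4_step(p, t_h + (s - 1) * h * dt_h, h, dt_h, vel)
    e <- tracers
    e$positions <- p
    out[[i + 1]] <- e
  }
  out
}

#' Render tracer ensembles to an image stack
#'
#' Each tracer becomes an isotropic Gaussian fluorescence spot of its
#' intensity; frames receive additive Gaussian background noise (drawn from
#' the current RNG state) and are clipped at zero.
#'
#' @param tracer_seq list of `tracer_ensemble` objects (one per frame).
#' @param shape image `c(H, W)` in px.
#' @param noise_sd standard deviation of the additive background noise, in
#'   units of a unit-intensity spot peak.
#' @param scenario optional [flow_scenario()]; if given, an error is raised
#'   when the embryonic disc does not fit inside `shape`.
#' @param pixel_size,frame_interval stack metadata (um/px, min).
#' @return an `image_stack`: list with `frames` (H x W x T array),
#'   `pixel_size`, `frame_interval`.
#' @export
render_frames <- function(tracer_seq, shape, noise_sd = 0.05, scenario = NULL,
                          pixel_size = 1, frame_interval = 3) {
  H <- shape[1]; W <- shape[2]
  if (!is.null(scenario)) {
    frame_interval <- scenario$frame_interval
    ctr <- scenario$disc_center; rad <- scenario$disc_radius
    if (ctr[1] - rad < 1 || ctr[1] + rad > W ||
        ctr[2] - rad < 1 || ctr[2] + rad > H)
      stop("image shape cannot contain the embryonic disc")
  }
  T_ <- length(tracer_seq)
  frames <- array(0, dim = c(H, W, T_))
  for (f in seq_len(T_)) {
    tr <- tracer_seq[[f]]
    img <- matrix(0, H, W)
    if (length(tr$intensities) > 0) {
      sg <- tr$spot_sigma
      stopifnot(sg > 0)
      hw <- ceiling(3 * sg) + 1L
      rowc <- H + 1 - tr$positions[, 2]     # math y -> image row
      img <- cpp_render_spots(H, W, rowc, tr$positions[, 1],
                              tr$intensities, sg, hw)
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    img[img < 0] <- 0
    frames[, , f] <- img
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' Simulate a full synthetic image stack for a scenario
#'
#' Seeds the RNG from the scenario, scatters tracers uniformly over the
#' frame, advects them through the analytic field for the scenario duration
#' and renders Gaussian-spot frames with additive noise.  The per-frame
#' ground truth (effective circulations, vortex-center positions) is attached
#' as the `"truth"` attribute.
#'
#' @param scenario a [flow_scenario()].
#' @param shape image `c(H, W)` (default 256 x 256).
#' @param tracer_density tracers per px^2 (default 0.02, giving >= 8 spots
#'   per 16 px interrogation window).
#' @param spot_sigma Gaussian spot sigma in px.
#' @param noise_sd additive background noise level.
#' @param duration override of the scenario duration in hours (shorter stacks
#'   for quick checks).
#' @param t0 start time in hours.
#' @return an `image_stack`.
#' @export
simulate_stack <- function(scenario, shape = c(256, 256),
                           tracer_density = 0.02, spot_sigma = 1.5,
                           noise_sd = 0.05, duration = scenario$duration,
                           t0 = 0) {
  set.seed(scenario$seed)
  n <- round(tracer_density * shape[1] * shape[2])
  tr <- make_tracers(n, shape, spot_sigma = spot_sigma)
  n_steps <- round(duration * 60 / scenario$frame_interval)
  seq_ <- advect_tracers(tr, scenario, t0 = t0, n_steps = n_steps)
  st <- render_frames(seq_, shape, noise_sd = noise_sd, scenario = scenario)
  tt <- t0 + seq(0, n_steps) * scenario$frame_interval / 60
  g <- t(vapply(tt, function(t) effective_circulations(scenario, t),
                numeric(2)))
  cl <- t(vapply(tt, function(t) unlist(vortex_centers_at(scenario, t)),
                 numeric(4)))
  attr(st, "truth") <- data.frame(frame = seq_along(tt), t_hours = tt,
                                  gamma_left = g[, 1], gamma_right = g[, 2],
                                  left_x = cl[, 1], left_y = cl[, 2],
                                  right_x = cl[, 3], right_y = cl[, 4])
  attr(st, "scenario") <- scenario
  st
}

#' Sample the analytic scenario velocity on a regular grid
#'
#' Produces a ground-truth `velocity_field` directly from
#' [analytic_velocity()], bypassing rendering and PIV.  Used as the oracle
#' against PIV output and as a clean input for midline and asymmetry
#' checks.
#'
#' @param scenario a [flow_scenario()].
#' @param t time (hours).
#' @param spacing grid spacing in px.
#' @param shape image extent `c(H, W)` the grid should span.
#' @param roi optional [roi_mask()]; defaults to the scenario disc.
#' @return a `velocity_field` with cells outside the ROI flagged invalid.
#' @export
sample_velocity_field <- function(scenario, t, spacing = 8,
                                  shape = c(256, 256), roi = NULL) {
  x <- seq(spacing / 2, shape[2] - spacing / 2, by = spacing)
  y <- seq(spacing / 2, shape[1] - spacing / 2, by = spacing)
  g <- expand.grid(x = x, y = y)
  v <- analytic_velocity(as.matrix(g), t, scenario)
  u <- matrix(v[, 1], length(x))
  vv <- matrix(v[, 2], length(x))
  fld <- velocity_field(x, y, u, vv, matrix(TRUE, length(x), length(y)),
                        time_index = 1L,
                        frame_interval = scenario$frame_interval)
  roi <- roi %||% roi_mask(scenario$disc_center, scenario$disc_radius)
  apply_roi(fld, roi)
}
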