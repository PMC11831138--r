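test_that("Lamb-Oseen tangential speed matches the closed form", {
  sc <- concentric_scenario(gamma = 2 * pi, rc = 0.5)
  v <- analytic_velocity(c(1, 0), 5, sc)
  expect_equal(sqrt(sum(v^2)), 1 - exp(-4), tolerance = 1e-12)
  # tangential direction: counterclockwise for positive circulation
  expect_gt(v[2], 0)
  expect_equal(v[1], 0, tolerance = 1e-12)
})

test_that("velocity at a vortex center is the drift alone", {
  sc <- concentric_scenario(gamma = 300, rc = 10, drift = c(0.3, -0.2))
  # at t = 0 the drifting center still sits at the origin
  expect_equal(as.numeric(analytic_velocity(c(0, 0), 0, sc)),
               c(0.3, -0.2), tolerance = 1e-12)
})

test_that("the symmetric preset field is mirror-antisymmetric", {
  sc <- make_scenario("symmetric", seed = 1)
  set.seed(42)
  n <- 1500
  th <- runif(n, 0, 2 * pi)
  r <- sqrt(runif(n)) * (sc$disc_radius - 1)
  p <- cbind(sc$disc_center[1] + r * cos(th), sc$disc_center[2] + r * sin(th))
  pm <- cbind(2 * sc$disc_center[1] - p[, 1], p[, 2])
  for (t in c(0.5, 3, 9)) {
    v <- analytic_velocity(p, t, sc)
    vm <- analytic_velocity(pm, t, sc)
    expect_lt(max(abs(v[, 1] + vm[, 1])), 1e-10)
    expect_lt(max(abs(v[, 2] - vm[, 2])), 1e-10)
  }
})

test_that("velocity vanishes outside the embryonic disc", {
  sc <- make_scenario("symmetric", seed = 1)
  th <- seq(0, 2 * pi, length.out = 50)
  p <- cbind(sc$disc_center[1] + (sc$disc_radius + 2) * cos(th),
             sc$disc_center[2] + (sc$disc_radius + 2) * sin(th))
  expect_true(all(analytic_velocity(p, 5, sc) == 0))
})

test_that("the confined field has negligible outflow at the disc rim", {
  sc <- make_scenario("symmetric", seed = 1)
  th <- seq(0, 2 * pi, length.out = 181)
  eps <- 0.5
  p <- cbind(sc$disc_center[1] + (sc$disc_radius - eps) * cos(th),
             sc$disc_center[2] + (sc$disc_radius - eps) * sin(th))
  v <- analytic_velocity(p, 5, sc)
  vn <- v[, 1] * cos(th) + v[, 2] * sin(th)       # radial component
  sp <- sqrt(rowSums(v^2))
  expect_lt(max(abs(vn)), 0.05 * max(sp))
})

test_that("advection is exact for trivial fields", {
  sc <- make_scenario("symmetric", seed = 1)
  sc$left_vortex$circulation <- 0
  sc$right_vortex$circulation <- 0
  set.seed(3)
  tr <- make_tracers(50, c(256, 256))
  # zero field: positions unchanged
  out <- advect_tracers(tr, sc, t0 = 0, n_steps = 5)
  expect_identical(out[[6]]$positions, tr$positions)
  # pure drift: uniform translation by n * u0
  scd <- sc
  scd$drift <- c(0.8, -0.3)
  tr$positions <- matrix(rep(sc$disc_center, each = 40), ncol = 2) +
    matrix(runif(80, -20, 20), ncol = 2)
  tr$intensities <- tr$intensities[1:40]
  out <- advect_tracers(tr, scd, t0 = 0, n_steps = 4)
  expect_equal(out[[5]]$positions,
               tr$positions + matrix(rep(4 * scd$drift, each = 40), ncol = 2),
               tolerance = 1e-9)
})

test_that("rigid-rotation advection conserves orbital radius", {
  omega <- 2 * pi / 200          # one revolution in 200 unit steps
  vf <- function(p, t) cbind(-omega * p[, 2], omega * p[, 1])
  set.seed(5)
  tr <- make_tracers(30, c(100, 100))
  tr$positions <- matrix(runif(60, -40, 40), ncol = 2)
  out <- advect_tracers(tr, scenario = NULL, t0 = 0, n_steps = 200,
                        velocity_fn = vf)
  r0 <- sqrt(rowSums(tr$positions^2))
  r1 <- sqrt(rowSums(out[[201]]$positions^2))
  expect_lt(max(abs(r1 - r0) / r0), 1e-3)
  # and the tracers returned to their starting points
  expect_lt(max(abs(out[[201]]$positions - tr$positions)), 1e-2 * max(r0))
})

test_that("halving the advection step changes positions by < 1e-2 px/frame", {
  sc <- make_scenario("symmetric", seed = 2)
  set.seed(8)
  tr <- make_tracers(100, c(256, 256))
  n <- 10
  a <- advect_tracers(tr, sc, t0 = 3, n_steps = n)
  b <- advect_tracers(tr, sc, t0 = 3, n_steps = n, n_substeps = 2L)
  d <- sqrt(rowSums((a[[n + 1]]$positions - b[[n + 1]]$positions)^2))
  expect_lt(max(d) / n, 1e-2)
})

test_that("rendering produces Gaussian spots with conserved intensity", {
  # empty ensemble, zero noise -> all-zero frames
  e <- structure(list(positions = matrix(numeric(0), ncol = 2),
                      intensities = numeric(0), spot_sigma = 1.5),
                 class = "tracer_ensemble")
  st <- render_frames(list(e), c(64, 64), noise_sd = 0)
  expect_true(all(st$frames == 0))
  # one tracer at an integer position: argmax pixel at that position
  tr <- structure(list(positions = matrix(c(20, 31), 1), intensities = 1,
                       spot_sigma = 1.5), class = "tracer_ensemble")
  st <- render_frames(list(tr), c(64, 64), noise_sd = 0)
  idx <- which(st$frames[, , 1] == max(st$frames[, , 1]), arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(64 + 1 - 31, 20))   # (row, col)
  single <- sum(st$frames)
  # n equal-intensity tracers fully inside: total intensity = n * single
  set.seed(11)
  trn <- make_tracers(25, c(64, 64), intensity_range = c(1, 1))
  trn$positions <- 16 + trn$positions / 2      # keep spots well inside
  stn <- render_frames(list(trn), c(64, 64), noise_sd = 0)
  expect_equal(sum(stn$frames), 25 * single, tolerance = 0.01)
})

test_that("rendering rejects frames too small for the disc", {
  sc <- make_scenario("symmetric", seed = 1)   # disc radius 110
  tr <- make_tracers(5, c(64, 64))
  expect_error(render_frames(list(tr), c(64, 64), scenario = sc),
               "cannot contain")
})

test_that("simulation is deterministic given the scenario seed", {
  sc <- small_scenario(seed = 9)
  a <- simulate_stack(sc, shape = c(128, 128), duration = 0.2)
  b <- simulate_stack(sc, shape = c(128, 128), duration = 0.2)
  expect_identical(a$frames, b$frames)
})

test_that("scenario presets encode the intended regimes", {
  s <- make_scenario("symmetric", seed = 1)
  expect_null(s$dominance_onset)
  expect_equal(s$dominance_factor, 1)
  expect_equal(s$left_vortex$circulation, -s$right_vortex$circulation)
  expect_equal(s$left_vortex$center[2], s$right_vortex$center[2])
  expect_gt(s$left_vortex$circulation, 0)   # left counterclockwise

  r <- make_scenario("right_dominant", seed = 1)
  expect_equal(r$dominance_onset, 6)
  expect_gt(r$dominance_factor, 1)

  v <- make_scenario("single_right_vortex", seed = 1)
  expect_equal(v$left_vortex$circulation, 0)
  expect_lt(v$right_vortex$circulation, 0)

  expect_error(make_scenario("no_such_preset"))
})

test_that("scenario invariants are enforced", {
  lv <- vortex_spec(c(0, 0), 1, 1)
  expect_error(flow_scenario(c(0, 0), 10, lv, lv, ramp_duration = 12,
                             duration = 10))
  expect_error(flow_scenario(c(0, 0), 10, lv, lv, dominance_onset = 11))
  expect_error(flow_scenario(c(0, 0), 10, lv, lv, dominance_factor = 0.5))
  expect_error(vortex_spec(c(0, 0), 1, -1))
})
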