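test_that("autocorrelation peaks at zero shift in every window", {
  st <- translated_pair(c(0, 0), n = 800)
  a <- st$frames[, , 1]
  cw <- correlate_windows(a, a, piv_config(window_size = 32))
  ctr <- 17
  box <- (ctr - 8):(ctr + 8)   # the engine's peak-search range (win/4)
  for (m in seq_len(dim(cw$surfaces)[3])) {
    if (cw$degenerate[m]) next
    s <- cw$surfaces[box, box, m]
    pk <- which(s == max(s), arr.ind = TRUE)
    expect_equal(unname(pk[1, ]), c(9, 9))
  }
})

test_that("an integer circular shift is recovered exactly", {
  set.seed(13)
  a <- matrix(runif(128 * 128), 128)
  a <- (a + a[c(2:128, 1), ] + a[, c(2:128, 1)]) / 3   # mild smoothing
  # content moves +3 columns and up by 2 rows (periodic)
  b <- a[c(3:128, 1:2), c(126:128, 1:125)]
  st <- structure(list(frames = array(c(a, b), c(128, 128, 2)),
                       pixel_size = 1, frame_interval = 3),
                  class = "image_stack")
  f <- compute_piv(st, piv_config(window_size = 32, passes = 1))[[1]]
  # every window's integer peak sits at the imposed shift (the subpixel
  # refinement stays well inside the half-pixel cell)
  expect_true(all(round(f$u[f$valid]) == 3))
  expect_true(all(round(f$v[f$valid]) == 2))    # 2 rows up = +2 in y-up
  expect_lt(max(abs(f$u[f$valid] - 3)), 0.1)
  expect_lt(max(abs(f$v[f$valid] - 2)), 0.1)
})

test_that("frequency-domain correlation equals brute-force direct correlation", {
  set.seed(17)
  for (rep in 1:5) {
    a <- matrix(runif(16 * 16), 16)
    b <- matrix(runif(16 * 16), 16)
    cw <- correlate_windows(a, b, piv_config(window_size = 16))
    expect_equal(dim(cw$surfaces)[3], 1)
    expect_lt(max(abs(cw$surfaces[, , 1] - direct_zncc(a, b))), 1e-8)
  }
})

test_that("subpixel peak localization is accurate and guarded", {
  # symmetric peak at an integer location -> zero fractional part
  s <- matrix(0, 9, 9)
  s[5, 5] <- 1; s[4, 5] <- s[6, 5] <- s[5, 4] <- s[5, 6] <- 0.4
  pk <- subpixel_peak(s)
  expect_true(pk$valid)
  expect_equal(unname(pk$location), c(5, 5), tolerance = 1e-12)
  # Gaussian surface centered at (5.3, 7.8) recovered within 0.05 px
  g <- outer(1:11, 1:15, function(i, j) exp(-((i - 5.3)^2 + (j - 7.8)^2) / 3))
  pk <- subpixel_peak(g)
  expect_lt(max(abs(pk$location - c(5.3, 7.8))), 0.05)
  # flat surface -> invalid
  expect_false(subpixel_peak(matrix(1, 9, 9))$valid)
  # peak on the border -> invalid
  e <- matrix(0, 9, 9); e[1, 5] <- 1
  expect_false(subpixel_peak(e)$valid)
})

test_that("identical frames give a zero field, valid inside the ROI", {
  st <- translated_pair(c(0, 0))
  roi <- roi_mask(c(128.5, 128.5), 100)
  f <- compute_piv(st, piv_config(), roi)[[1]]
  expect_true(all(abs(f$u[f$valid]) < 1e-9))
  expect_true(all(abs(f$v[f$valid]) < 1e-9))
  X <- outer(f$x - 128.5, rep(1, length(f$y)))
  Y <- outer(rep(1, length(f$x)), f$y - 128.5)
  inside <- X^2 + Y^2 <= 100^2
  expect_true(all(f$valid == inside))
})

test_that("a uniform 1.25 px/frame translation is recovered", {
  st <- translated_pair(c(1.25, 0))
  f <- compute_piv(st, piv_config())[[1]]
  expect_lt(abs(median(f$u[f$valid]) - 1.25), 0.1)
  expect_lt(abs(median(f$v[f$valid])), 0.1)
})

test_that("shift recovery meets accuracy bounds", {
  shifts <- list(c(-6, 0), c(-3.5, 0), c(0.5, 0), c(2, 0), c(0, 5.5),
                 c(0, -1))
  # windows with >= 8 tracer spots (single pass, 32 px): MAE < 0.1 px
  cfg1 <- piv_config(passes = 1)
  for (s in shifts) {
    f <- compute_piv(translated_pair(s), cfg1)[[1]]
    mae <- mean(abs(f$u[f$valid] - s[1])) + mean(abs(f$v[f$valid] - s[2]))
    expect_lt(mae, 0.1 * 2)
    # default two-pass engine: median recovery within 0.1 px
    f2 <- compute_piv(translated_pair(s), piv_config())[[1]]
    expect_lt(abs(median(f2$u[f2$valid]) - s[1]), 0.1)
    expect_lt(abs(median(f2$v[f2$valid]) - s[2]), 0.1)
  }
  # with noise at 10% of spot peak: MAE < 0.3 px (single pass)
  f <- compute_piv(translated_pair(c(0.5, 0), noise_sd = 0.1), cfg1)[[1]]
  expect_lt(mean(abs(f$u[f$valid] - 0.5)), 0.3)
})

test_that("grid coordinates do not depend on image content", {
  f1 <- compute_piv(translated_pair(c(0, 0), seed = 1), piv_config())[[1]]
  f2 <- compute_piv(translated_pair(c(2, 1), seed = 99), piv_config())[[1]]
  expect_identical(f1$x, f2$x)
  expect_identical(f1$y, f2$y)
})

test_that("halving the frame interval halves per-frame speeds", {
  sc <- make_scenario("symmetric", seed = 21)
  sc2 <- sc
  sc2$frame_interval <- 1.5
  roi <- roi_mask(sc$disc_center, sc$disc_radius)
  med_speed <- function(s) {
    st <- simulate_stack(s, duration = 0.2, t0 = 4)
    f <- compute_piv(st, piv_config(), roi)
    median(vapply(f, function(x)
      median(sqrt(x$u[x$valid]^2 + x$v[x$valid]^2)), numeric(1)))
  }
  r <- med_speed(sc2) / med_speed(sc)
  expect_equal(r, 0.5, tolerance = 0.15)
})

test_that("vector validation flags and repairs outliers", {
  nx <- 9; ny <- 9
  mk <- function(u, v) velocity_field(seq_len(nx), seq_len(ny), u, v,
                                      matrix(TRUE, nx, ny))
  # uniform field: zero replacements
  f <- mk(matrix(1.0, nx, ny), matrix(-0.5, nx, ny))
  out <- validate_vectors(f, piv_config())
  expect_equal(attr(out, "n_replaced"), 0L)
  expect_identical(out$u, f$u)
  # one cell at 50x magnitude: exactly that cell replaced with neighbor value
  u <- matrix(1.0, nx, ny); u[5, 5] <- 50
  f <- mk(u, matrix(0, nx, ny))
  out <- validate_vectors(f, piv_config())
  expect_equal(attr(out, "n_replaced"), 1L)
  expect_equal(out$u[5, 5], 1.0)
  expect_equal(sum(out$u != u), 1)
  # all-invalid field returned unchanged with a warning
  f$valid[] <- FALSE
  expect_warning(out <- validate_vectors(f, piv_config()), "invalid")
  expect_identical(out$u, f$u)
})

test_that("degenerate constant-intensity windows are flagged", {
  a <- matrix(0, 64, 64)
  a[40:45, 40:45] <- 1
  cw <- correlate_windows(a, a, piv_config(window_size = 16,
                                           overlap_fraction = 0))
  expect_true(any(cw$degenerate))          # empty corners are constant
  expect_false(all(cw$degenerate))         # the textured window is not
  expect_true(all(is.nan(cw$surfaces[, , which(cw$degenerate)[1]])))
})
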