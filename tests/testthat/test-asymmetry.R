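vertical_midline <- function(x0 = 5.5) line2d(c(x0, 0), c(0, 1))

grid_field <- function(values, valid = NULL, kind = "speed", h = 1) {
  nx <- nrow(values); ny <- ncol(values)
  scalar_field((seq_len(nx) - 0.5) * h, (seq_len(ny) - 0.5) * h, values,
               if (is.null(valid)) matrix(TRUE, nx, ny) else valid,
               kind, window = c(0, 1))
}

test_that("thresholded areas match brute-force enumeration on a toy grid", {
  set.seed(23)
  vals <- matrix(runif(100), 10, 10)
  f <- grid_field(vals)
  ml <- vertical_midline(5)         # between cell centers 4.5 and 5.5
  res <- threshold_area(f, 0.5, ml)
  # independent enumeration over all cells
  vmax <- max(vals)
  nL <- nR <- 0
  for (ix in 1:10) for (iy in 1:10) {
    if (vals[ix, iy] >= 0.5 * vmax) {
      cx <- ix - 0.5
      if (cx < 5) nL <- nL + 1 else if (cx > 5) nR <- nR + 1
      else { nL <- nL + 0.5; nR <- nR + 0.5 }
    }
  }
  expect_equal(res$A_L, nL)
  expect_equal(res$A_R, nR)
})

test_that("a mirror-symmetric field gives exactly equal areas", {
  set.seed(29)
  half <- matrix(runif(50), 5, 10)
  vals <- rbind(half, half[5:1, ])          # mirror about x = 5
  f <- grid_field(vals)
  res <- fractional_areas(threshold_area(f, 0.3, vertical_midline(5)))
  expect_identical(res$A_L, res$A_R)
  expect_equal(res$f_L, 0.5)
})

test_that("cells exactly on the midline are split half and half", {
  vals <- matrix(1, 3, 3)                   # all retained (max = 1)
  f <- grid_field(vals)
  res <- threshold_area(f, 0.5, vertical_midline(1.5))
  # column of centers at x = 1.5 sits on the midline: 3 cells split
  expect_equal(res$A_L, 3 + 1.5)
  expect_equal(res$A_R, 3 + 1.5)
})

test_that("areas are non-increasing in the threshold", {
  set.seed(31)
  vals <- matrix(runif(400), 20, 20)
  f <- grid_field(vals)
  ml <- vertical_midline(10)
  res <- lapply(c(0.3, 0.5, 0.7), function(th) threshold_area(f, th, ml))
  expect_true(res[[1]]$A_L >= res[[2]]$A_L && res[[2]]$A_L >= res[[3]]$A_L)
  expect_true(res[[1]]$A_R >= res[[2]]$A_R && res[[2]]$A_R >= res[[3]]$A_R)
  # 0.7-retained cells are a subset of 0.3-retained cells by construction
  expect_lte(res[[3]]$n_retained, res[[1]]$n_retained)
})

test_that("mirror reflection swaps left and right outputs exactly", {
  set.seed(37)
  vals <- matrix(runif(144), 12, 12)
  f <- grid_field(vals)
  fr <- grid_field(vals[12:1, ])            # reflect about x = 6
  ml <- vertical_midline(6)
  a <- fractional_areas(threshold_area(f, 0.5, ml))
  b <- fractional_areas(threshold_area(fr, 0.5, ml))
  expect_identical(a$A_L, b$A_R)
  expect_identical(a$A_R, b$A_L)
  expect_identical(a$f_L, b$f_R)
})

test_that("vorticity thresholds use magnitude; midline rules still apply", {
  vals <- matrix(0, 6, 6)
  vals[2, 3] <- 2; vals[5, 3] <- -1.5       # strong CCW left, CW right
  f <- grid_field(vals, kind = "vorticity")
  res <- threshold_area(f, 0.7, vertical_midline(3))
  expect_equal(res$A_L, 1)                  # |2| >= 1.4
  expect_equal(res$A_R, 1)                  # |-1.5| >= 1.4
})

test_that("fractional areas normalize to one", {
  r <- structure(list(A_L = 30, A_R = 70, f_L = NA, f_R = NA,
                      threshold_fraction = 0.5, field_kind = "speed",
                      window = c(0, 1), n_retained = 100, v_max = 1),
                 class = "area_result")
  out <- fractional_areas(r)
  expect_equal(out$f_R, 0.7)
  expect_equal(out$f_L + out$f_R, 1)
  r$A_L <- 0
  expect_equal(fractional_areas(r)$f_R, 1)
  r$A_L <- r$A_R <- 0
  expect_warning(out <- fractional_areas(r), "undefined")
  expect_true(is.na(out$f_L))
})

test_that("dominance classification follows the dead-band and persistence rules", {
  # constant 0.5: all none, no onset
  out <- classify_dominance(rep(0.5, 5))
  expect_true(all(out$labels == "none"))
  expect_equal(out$end_dominance, "none")
  expect_true(is.na(out$onset))
  # worked example: onset at the third window, end dominance R
  out <- classify_dominance(c(0.50, 0.51, 0.58, 0.60), window_starts = 1:4,
                            delta = 0.02, persistence = 2L)
  expect_equal(out$labels, c("none", "none", "R", "R"))
  expect_equal(out$end_dominance, "R")
  expect_equal(out$onset, 3)
  # a final-window blip shorter than the persistence gives no onset
  out <- classify_dominance(c(0.5, 0.5, 0.5, 0.6), persistence = 2L)
  expect_equal(out$end_dominance, "R")
  expect_true(is.na(out$onset))
  # left dominance mirrored
  out <- classify_dominance(c(0.5, 0.42, 0.40), window_starts = 0:2)
  expect_equal(out$end_dominance, "L")
  expect_equal(out$onset, 1)
  expect_error(classify_dominance(c(NA, NA)), "defined")
})

test_that("increasing the dominance factor raises the post-onset f_R", {
  # analytic fields, bypassing PIV: monotone response of the area metric
  fr <- vapply(c(1, 1.25, 1.5, 2), function(fac) {
    sc <- make_scenario("right_dominant", seed = 1, dominance_factor = fac)
    f <- sample_velocity_field(sc, t = 8, spacing = 8)
    sp <- speed_field(f)
    sp$window <- c(8, 9)
    pair <- find_vortex_centers(vorticity_field(f), f)
    fm <- flow_midline(pair, f)
    fractional_areas(threshold_area(sp, 0.5, fm))$f_R
  }, numeric(1))
  expect_true(all(diff(fr) >= -1e-9))
  expect_equal(fr[1], 0.5, tolerance = 0.02)   # symmetric baseline
  expect_gt(fr[4], fr[1] + 0.05)
})

test_that("the exact signed-rank test matches its definition", {
  # identical series: all differences zero
  expect_warning(r <- paired_rank_test(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(r$p_value, 1)
  # n = 4, all differences positive: two-sided p = 2/16
  r <- paired_rank_test(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(r$statistic, 10)
  expect_equal(r$p_value, 0.125)
  expect_equal(r$n, 4)
})

test_that("the exact test agrees with brute-force enumeration", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(3:8, 1)
    x <- sample(-5:5, n, replace = TRUE) / 2   # ties and zeros likely
    y <- sample(-5:5, n, replace = TRUE) / 2
    if (all(x == y)) x[1] <- x[1] + 1
    got <- paired_rank_test(x, y)
    want <- brute_rank_test(x, y)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
    expect_equal(got$n, want$n)
  }
})

test_that("the exact test matches wilcox.test for tie-free data", {
  set.seed(43)
  x <- rnorm(12); y <- rnorm(12)
  got <- paired_rank_test(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = TRUE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("large samples fall back to the normal approximation", {
  set.seed(47)
  x <- rnorm(40); y <- rnorm(40, 0.5)
  r <- paired_rank_test(x, y)
  expect_equal(r$method, "normal approximation")
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-6)
})
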