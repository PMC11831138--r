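# Shared fixtures, all built in code.

# reduced-geometry bilateral scenario for quick end-to-end checks
small_scenario <- function(preset = "symmetric", seed = 1L, ...)
  make_scenario(preset, seed = seed, image_size = 128, ...)

# a single concentric Lamb-Oseen vortex (no image term), handy for
# closed-form checks
concentric_scenario <- function(gamma = 2 * pi, rc = 0.5, disc_radius = 100,
                                drift = c(0, 0), frame_interval = 3) {
  flow_scenario(disc_center = c(0, 0), disc_radius = disc_radius,
                left_vortex = vortex_spec(c(0, 0), gamma, rc),
                right_vortex = vortex_spec(c(disc_radius / 2, 0), 0, 1),
                ramp_duration = 0, drift = drift,
                frame_interval = frame_interval, duration = 10)
}

# render a frame pair where the second frame's tracers are uniformly
# translated by `shift`
translated_pair <- function(shift, n = 1300, shape = c(256, 256),
                            noise_sd = 0, seed = 7, spot_sigma = 1.5) {
  set.seed(seed)
  tr <- make_tracers(n, shape, spot_sigma = spot_sigma)
  tr2 <- tr
  tr2$positions <- tr$positions +
    matrix(rep(shift, each = n), ncol = 2)
  render_frames(list(tr, tr2), shape, noise_sd = noise_sd)
}

# rotate a scenario's vortex centers (and drift) CLOCKWISE by theta_deg
# about the disc center (clockwise = positive angle-to-vertical); the
# analytic field of the result is the rotation of the original field
rotate_scenario <- function(scenario, theta_deg) {
  th <- -theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(p) as.numeric(scenario$disc_center +
                                  R %*% (p - scenario$disc_center))
  scenario$left_vortex$center <- rot(scenario$left_vortex$center)
  scenario$right_vortex$center <- rot(scenario$right_vortex$center)
  scenario$drift <- as.numeric(R %*% scenario$drift)
  scenario
}

# direct (brute-force) circular zero-mean normalized cross-correlation with
# the same per-lag overlap normalization as the frequency-domain path
direct_zncc <- function(A, B) {
  n <- nrow(A)
  w2 <- n %/% 2
  A0 <- A - mean(A); B0 <- B - mean(B)
  den <- sqrt(sum(A0^2) * sum(B0^2))
  S <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      dr <- i - w2 - 1; dc <- j - w2 - 1
      ridx <- ((seq_len(n) - 1 + dr) %% n) + 1
      cidx <- ((seq_len(n) - 1 + dc) %% n) + 1
      wfac <- ((n - abs(dr)) / n) * ((n - abs(dc)) / n)
      S[i, j] <- sum(A0 * B0[ridx, cidx]) / den / wfac
    }
  }
  S
}

# brute-force exact two-sided signed-rank test by explicit enumeration of
# all 2^n sign assignments (average ranks for ties, zeros dropped)
brute_rank_test <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  Vs <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(rk[signs == 1])
  }, numeric(1))
  p_le <- mean(Vs <= V + 1e-12)
  p_ge <- mean(Vs >= V - 1e-12)
  list(statistic = V, p_value = min(1, 2 * min(p_le, p_ge)), n = n)
}
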