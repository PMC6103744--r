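test_that("preprocessing rejects unusable trials with a classed condition", {
  # stationary fly: total path under 25 mm
  raw <- straight_raw(speed = 0, n = 500)
  expect_error(preprocess_trajectory(raw), class = "trial_rejected")
  # tracking gap
  raw2 <- straight_raw(n = 500)
  raw2 <- raw2[-(100:120), ]
  expect_error(preprocess_trajectory(raw2), class = "trial_rejected")
  # missing samples
  raw3 <- straight_raw(n = 500)
  raw3$x_mm[50] <- NA
  expect_error(preprocess_trajectory(raw3), class = "trial_rejected")
})

test_that("180-degree orientation flips are removed against movement
           direction", {
  raw <- straight_raw(speed = 6, dir_deg = 90, n = 800)
  raw$orientation_deg[300:400] <- 270
  tr <- preprocess_trajectory(raw)
  expect_lt(max(abs(tr$heading - 90)), 1e-6)
  # heading continuous: no step anywhere near 180
  expect_lt(max(abs(diff(tr$heading))), 1)
})

test_that("coordinate filtering matches the two-pole Butterworth response", {
  sr <- 50
  t <- (0:2999) / sr
  f <- 5 # Hz, above the 2.5 Hz cutoff
  raw <- data.frame(t_s = t, x_mm = 20 + 3 * sin(2 * pi * f * t),
                    y_mm = 30 + 6 * t, orientation_deg = 90)
  tr <- preprocess_trajectory(raw)
  bf <- signal::butter(2, 2.5 / (sr / 2), "low")
  gain2 <- digital_gain(bf, f, sr)^2 # zero-phase: applied twice
  amp <- (max(tr$x[500:2500]) - min(tr$x[500:2500])) / 2
  expect_equal(amp / 3, gain2, tolerance = 0.05)
})

test_that("gait parameters follow their kinematic definitions", {
  raw <- straight_raw(speed = 6, dir_deg = 90, n = 1000)
  g <- compute_gait(preprocess_trajectory(raw))
  mid <- 100:900
  expect_equal(g$ground_speed[mid], rep(6, length(mid)), tolerance = 1e-6)
  expect_equal(g$upwind_velocity[mid], rep(6, length(mid)), tolerance = 1e-6)
  expect_true(all(g$angular_velocity[mid] < 1e-6))
  expect_true(all(g$curvature[mid] < 1e-6))
  expect_true(all(g$turn_indicator[mid] == 0))
  expect_true(all(g$moving_mask))

  # circular path of radius r: curvature (180/pi)/r deg/mm; turning is
  # flagged iff r < 180/(20*pi) ~ 2.86 mm
  sr <- 50; t <- (0:999) / sr
  for (r in c(2, 4)) {
    om <- 2 # rad/s
    raw2 <- data.frame(t_s = t, x_mm = 20 + r * cos(om * t),
                       y_mm = 70 + r * sin(om * t),
                       orientation_deg = (om * t * 180 / pi + 90) %% 360)
    g2 <- compute_gait(preprocess_trajectory(raw2, min_path = 5))
    mid <- 200:800
    expect_equal(mean(g2$curvature[mid]), (180 / pi) / r, tolerance = 0.02)
    expect_equal(mean(g2$turn_indicator[mid]), as.numeric(r < 180 / (20 * pi)))
  }

  # speeds below 1 mm/s are masked out
  slow <- straight_raw(speed = 0.5, n = 3000)
  slow$x_mm <- slow$x_mm + cumsum(rep(0.25 / 50, 3000)) # pass the 25-mm gate
  g3 <- compute_gait(preprocess_trajectory(slow))
  expect_true(all(!g3$moving_mask[100:2900]))
  expect_true(all(is.na(g3$curvature[100:2900])))
})

test_that("warping shifts by the advection delay at the fly's position", {
  sr <- 50; n <- 3500
  spec <- stimulus_spec("square_pulse")
  adv <- advection_model()

  # a fly at the inlet: zero delay, warping is the identity
  raw <- straight_raw(speed = 0.6, dir_deg = 0, n = n, x0 = 3, y0 = 139.9)
  raw$y_mm <- rep(139.99, n)
  tr <- preprocess_trajectory(raw)
  g <- compute_gait(tr)
  gw <- warp_to_odor_time(g, tr, spec, adv)
  expect_equal(gw$ground_speed[50:3000], g$ground_speed[50:3000],
               tolerance = 1e-9)

  # a fly parked 59.5 mm downwind: uniform 0.5-s (25-sample) shift
  raw2 <- straight_raw(speed = 0.6, dir_deg = 0, n = n, x0 = 3, y0 = 80.5)
  raw2$y_mm <- rep(80.5, n)
  tr2 <- preprocess_trajectory(raw2)
  g2 <- compute_gait(tr2)
  # a recognizable probe series survives the shift
  g2$upwind_velocity <- sin((1:n) / 7)
  gw2 <- warp_to_odor_time(g2, tr2, spec, adv)
  expect_equal(gw2$upwind_velocity[100:3400],
               g2$upwind_velocity[125:3425], tolerance = 1e-9)

  # warped pre-odor sample count matches the warped onset position
  shift <- 25
  expect_equal(sum(gw2$valid_mask), n - shift)
})

test_that("warping aligns odor onset across starting positions", {
  sr <- 50; n <- 3500
  spec <- stimulus_spec("square_pulse")
  adv <- advection_model()
  env <- make_arena_env(spec, adv)
  onset_idx <- function(y0) {
    raw <- straight_raw(speed = 6, dir_deg = 90, n = n, x0 = 20, y0 = y0)
    raw$y_mm <- pmin(raw$y_mm, 139)
    tr <- preprocess_trajectory(raw)
    g <- compute_gait(tr)
    # record the odor actually encountered as the probe series
    g$upwind_velocity <- env_concentration(env, tr$x, tr$y, tr$t)
    gw <- warp_to_odor_time(g, tr, spec, adv)
    which(gw$upwind_velocity > 0.5)[1]
  }
  idx <- vapply(c(20, 60, 100), onset_idx, numeric(1))
  expect_lt(max(idx) - min(idx), 2) # within one sample
  expect_equal(mean(idx), 501, tolerance = 0.01)
})

test_that("spatial exclusion rules mask walls and post-arrival samples", {
  raw <- straight_raw(speed = 6, dir_deg = 90, n = 1200, x0 = 20, y0 = 10)
  tr <- preprocess_trajectory(raw)
  g <- apply_exclusions(compute_gait(tr), tr)
  # fly reaches the top (y >= 135) at sample ~ (125/6)*50
  hit <- which(tr$y >= 135)[1]
  expect_true(all(!g$valid_mask[hit:1200]))
  expect_true(all(g$valid_mask[10:(hit - 1)]))

  # wall-hugging fly fully masked
  raw2 <- straight_raw(speed = 6, dir_deg = 90, n = 500, x0 = 1, y0 = 10)
  tr2 <- preprocess_trajectory(raw2)
  g2 <- apply_exclusions(compute_gait(tr2), tr2)
  expect_true(all(!g2$valid_mask))

  # centered fly untouched
  raw3 <- straight_raw(speed = 4, dir_deg = 90, n = 500, x0 = 20, y0 = 10)
  tr3 <- preprocess_trajectory(raw3)
  g3 <- apply_exclusions(compute_gait(tr3), tr3)
  expect_true(all(g3$valid_mask))
})

test_that("period comparisons use paired signed-rank tests with Bonferroni
           correction", {
  mk_fly <- function(before, during, after) {
    t <- seq(-30, 25, by = 0.02)
    v <- numeric(length(t))
    v[t < 0] <- before
    v[t >= 0 & t < 10] <- during
    v[t >= 10] <- after
    list(t = t, value = v)
  }
  # identical windows: p = 1
  flies <- replicate(8, mk_fly(1, 1, 1), simplify = FALSE)
  ps <- period_compare(flies)
  expect_true(all(ps$p_values == 1))
  expect_equal(ps$alpha_corrected, 0.05 / 3)

  # all-positive differences at n = 500 hit the normal-approximation floor
  set.seed(7)
  flies2 <- lapply(seq_len(500), function(i)
    mk_fly(before = rnorm(1, 1, 0.1), during = rnorm(1, 3, 0.1) + 1,
           after = rnorm(1, 1, 0.1)))
  ps2 <- period_compare(flies2)
  expect_equal(signif(ps2$p_values[["before-during"]], 2), 1.3e-83)

  # small-sample p matches exhaustive enumeration of sign patterns
  set.seed(21)
  d <- c(rnorm(5, 1), rnorm(5, -1))
  flies3 <- lapply(d, function(di) mk_fly(1, 1 + di, 1))
  ps3 <- period_compare(flies3)
  expect_equal(ps3$p_values[["before-during"]], signed_rank_exact_p(d),
               tolerance = 1e-12)
})

test_that("empirical D-functions recover the commanded turning drives", {
  # heavy stochastic turning spreads the stationary wind-angle occupancy
  # over the full circle so every psi bin is populated
  big <- c(-5000, 5000, -5000, 5000)
  noisy <- list(sigma = 200, p0 = 0.5)
  fit_sin_amp <- function(ens, n, window = NULL) {
    pooled <- do.call(rbind, lapply(seq_len(n), function(k) {
      tr <- ensemble_trajectory(ens, k)
      empirical_d_function(compute_gait(tr), tr, sample_window = window)
    }))
    # occupancy-weighted least squares against sin(psi)
    ok <- is.finite(pooled$mean_turn)
    s <- sin(pooled$psi_mid[ok] * pi / 180)
    w <- pooled$n[ok]
    sum(w * pooled$mean_turn[ok] * s) / sum(w * s^2)
  }

  # odor-gated upwind drive: amplitude kappa5 * ON, with ON adapted near
  # 1/(2 + kd) in constant unit odor (steady-state window only)
  env1 <- nav_environment(function(x, y, t) rep(1, length(x)),
                          bounds = big, duration = 60)
  p1 <- nav_params(kappa5 = 1, kappa6 = 0, kappa3 = 0, kappa4 = 0,
                   sigma = noisy$sigma, p0 = noisy$p0)
  ens1 <- run_ensemble(env1, p1, n_trials = 100, seed = 42,
                       init = list(x = 0, y = 0,
                                   heading = seq(0, 356, length.out = 100)),
                       store_states = FALSE)
  on_inf <- 1 / (2 + 0.01)
  expect_equal(fit_sin_amp(ens1, 100, c(30, 60)), 1 * on_inf,
               tolerance = 0.1)

  # constant downwind drive, no odor: amplitude -kappa6
  env0 <- nav_environment(function(x, y, t) numeric(length(x)),
                          bounds = big, duration = 60)
  p2 <- nav_params(kappa5 = 0, kappa6 = 0.5, sigma = noisy$sigma,
                   p0 = noisy$p0)
  ens2 <- run_ensemble(env0, p2, n_trials = 100, seed = 43,
                       init = list(x = 0, y = 0,
                                   heading = seq(0, 356, length.out = 100)),
                       store_states = FALSE)
  expect_equal(fit_sin_amp(ens2, 100), -0.5, tolerance = 0.1)

  # wind-blind, odor-free agent: flat curve at zero
  p3 <- nav_params(kappa5 = 0, kappa6 = 0, sigma = noisy$sigma,
                   p0 = noisy$p0)
  ens3 <- run_ensemble(env0, p3, n_trials = 30, seed = 44,
                       store_states = FALSE)
  expect_lt(abs(fit_sin_amp(ens3, 30)), 0.05)
})

test_that("the pipeline is deterministic and round-trips through CSV", {
  raw <- straight_raw(speed = 6, dir_deg = 45, n = 600)
  raw$fly_id <- 1; raw$trial_id <- 1; raw$stimulus_id <- 1
  f <- tempfile(fileext = ".csv")
  write_trajectory_table(raw, f)
  # identical input files yield byte-identical outputs
  g1 <- compute_gait(preprocess_trajectory(read_trajectory_table(f)))
  g2 <- compute_gait(preprocess_trajectory(read_trajectory_table(f)))
  expect_identical(g1$ground_speed, g2$ground_speed)
  expect_identical(g1$curvature, g2$curvature)
  # and serialization itself is lossless to within print precision
  g0 <- compute_gait(preprocess_trajectory(raw))
  expect_equal(g1$ground_speed, g0$ground_speed, tolerance = 1e-9)
  unlink(f)
})
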