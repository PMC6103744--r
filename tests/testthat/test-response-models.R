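test_that("adaptive compression has the analytic steady states", {
  sr <- 50
  zero <- signal_trace(numeric(1000), sr)
  ac <- adaptive_compress(zero, kd = 0.01, tau_a = 9.8)
  expect_true(all(ac$A == 0) && all(ac$C == 0))

  # with adaptation frozen (huge tau_a), C at odor = kd is one half
  half <- adaptive_compress(signal_trace(rep(0.01, 500), sr), kd = 0.01,
                            tau_a = 1e12)
  expect_equal(half$C[500], 0.5, tolerance = 1e-6)

  # constant c: A -> c, so C -> c/(2c + kd); run >= 10 tau_a
  cc <- 1
  st <- adaptive_compress(signal_trace(rep(cc, 110 * 50), sr),
                          kd = 0.01, tau_a = 9.8)
  expect_equal(st$C[length(st$C)], cc / (2 * cc + 0.01), tolerance = 1e-4)

  expect_error(adaptive_compress(zero, kd = 0), "kd")
  expect_error(adaptive_compress(zero, tau_a = -1), "tau_a")
})

test_that("static compression is the exponent-1 Hill function", {
  expect_equal(static_compress(0, kd = 0.01), 0)
  expect_equal(static_compress(0.01, kd = 0.01), 0.5)
  expect_equal(static_compress(1, kd = 0.01), 1 / 1.01)
  expect_error(static_compress(1, kd = -2), "kd")
})

test_that("the Euler low-pass matches first-order kinetics and gain", {
  sr <- 50; dt <- 1 / sr
  # unit step reaches 1 - 1/e at t = tau
  tau <- 1
  y <- lowpass(rep(1, 500), tau, dt)
  expect_equal(y[round(tau * sr) + 1], 1 - exp(-1), tolerance = 0.02)

  # steady-state sinusoidal gain matches the analog 1/sqrt(1+(2 pi f tau)^2)
  # within 2% for the fitted time constants over the deliverable band
  for (tau in c(0.72, 4.84)) for (f in c(0.1, 0.5, 1)) {
    t <- (0:9999) * dt
    y <- lowpass(sin(2 * pi * f * t), tau, dt)
    amp <- (max(y[5000:10000]) - min(y[5000:10000])) / 2
    expect_equal(amp, 1 / sqrt(1 + (2 * pi * f * tau)^2), tolerance = 0.02)
  }
  # at the fastest corner (tau = 0.3, f = 1 Hz) the Euler discretization
  # itself deviates from the analog response; the exact discrete gain is
  # |a / (exp(i w dt) - (1 - a))| and the simulation matches IT tightly
  tau <- 0.3; f <- 1
  t <- (0:9999) * dt
  y <- lowpass(sin(2 * pi * f * t), tau, dt)
  amp <- (max(y[5000:10000]) - min(y[5000:10000])) / 2
  a <- dt / tau
  g_disc <- abs(a / (exp(1i * 2 * pi * f * dt) - (1 - a)))
  expect_equal(amp, g_disc, tolerance = 0.005)
  expect_lt(abs(g_disc - 1 / sqrt(1 + (2 * pi * f * tau)^2)) /
              (1 / sqrt(1 + (2 * pi * f * tau)^2)), 0.03)
})

test_that("the OFF differential filter rectifies decreases only", {
  sr <- 50; dt <- 1 / sr
  # constant input at steady state: R1 = R2, OFF = 0
  ff <- off_filter(rep(0.5, 5000), 0.62, 4.84, dt)
  expect_equal(ff$OFF[5000], 0, tolerance = 1e-8)

  # monotically rising input from rest: fast filter leads, OFF stays 0
  ramp <- seq(0, 1, length.out = 2000)
  fr <- off_filter(ramp, 0.62, 4.84, dt)
  expect_true(all(fr$OFF == 0))

  # step down from steady state: OFF follows the closed-form
  # C0*(exp(-t/tau_slow) - exp(-t/tau_fast)), peaking at the predicted time
  C0 <- 0.8; tf <- 0.62; ts <- 4.84
  x <- c(rep(C0, 5000), rep(0, 1500))
  fs <- off_filter(x, tf, ts, dt)
  tpost <- (0:1499) * dt
  theory <- off_step_down_theory(tpost, C0, tf, ts)
  expect_lt(max(abs(fs$OFF[5001:6500] - theory)), 0.02 * max(theory))
  t_peak <- log(ts / tf) / (1 / tf - 1 / ts)
  expect_equal(which.max(fs$OFF[5001:6500]) * dt, t_peak, tolerance = 0.1)

  expect_error(off_filter(ramp, 2, 1, dt), "tau_fast")
})

test_that("model variants compose their stages in the right order", {
  stim <- make_stimulus(stimulus_spec("square_pulse"), 50)
  on <- run_response_model(stim, reference_response_params("ACF", "ON"))
  # rises during odor toward the adapted plateau c/(2c + kd), relaxes after
  expect_gt(max(on$output[501:1000]), 0.5)
  i_peak <- which.max(on$output)
  expect_lt(on$output[1000], max(on$output))  # adaptation decay visible
  expect_gt(i_peak, 500); expect_lt(i_peak, 1000)

  # zero stimulus -> zero output for every variant/channel
  z <- make_stimulus(stimulus_spec("constant_zero"), 50)
  for (v in c("ACF", "FAC", "CF", "FC")) for (ch in c("ON", "OFF")) {
    out <- run_response_model(z, reference_response_params(v, ch))
    expect_true(all(out$output == 0), label = paste(v, ch))
  }

  # CF (no adaptation) saturates on the ascending sweep where ACF does not:
  # deep into the sweep, CF holds near its ceiling while adaptation pulls
  # the ACF response down
  sw <- make_stimulus(stimulus_spec("freq_sweep_up"), 50)
  acf <- run_response_model(sw, reference_response_params("ACF", "ON"))
  cf <- run_response_model(sw, reference_response_params("CF", "ON"))
  late <- 1800:2400 # deep in the sweep, before it ends
  sat <- function(o) mean(o$output[late]) / max(o$output)
  expect_gt(sat(cf), 0.8)
  expect_lt(sat(acf), sat(cf) - 0.3)

  expect_error(response_params("ACF", "ON"), "tau")
  expect_error(response_params("ACF", "OFF", tau_a = 10, tau_off1 = 5,
                               tau_off2 = 1), "smaller")
})

test_that("ON output is bounded in [0,1) and OFF is nonnegative", {
  stims <- list(make_stimulus(stimulus_spec("square_pulse"), 50),
                make_stimulus(stimulus_spec("freq_sweep_up"), 50),
                make_stimulus(stimulus_spec("off_ramp", ramp_duration = 5), 50))
  for (s in stims) for (v in c("ACF", "FAC", "CF", "FC")) {
    on <- run_response_model(s, reference_response_params(v, "ON"))
    expect_true(all(on$output >= 0 & on$output < 1))
    off <- run_response_model(s, reference_response_params(v, "OFF"))
    expect_true(all(off$output >= 0))
  }
})

test_that("ACF and FAC agree in the linear, adaptation-free limit", {
  sr <- 50
  t <- (0:4999) / sr
  # c << kd and tau_a -> inf: both reduce to scaled low-pass filtering
  stim <- signal_trace(1e-6 * (1 + sin(2 * pi * 0.3 * t)) / 2, sr)
  mk <- function(v) response_params(v, "ON", tau_on = 0.72, tau_a = 1e12,
                                    scale = 1)
  a <- run_response_model(stim, mk("ACF"))$output
  f <- run_response_model(stim, mk("FAC"))$output
  expect_equal(a, f, tolerance = 1e-3)
})

test_that("halving the Euler step changes reference-model outputs < 1%", {
  for (ch in c("ON", "OFF")) {
    s50 <- make_stimulus(stimulus_spec("square_pulse"), 50)
    s100 <- make_stimulus(stimulus_spec("square_pulse"), 100)
    p50 <- reference_response_params("ACF", ch, dt = 0.02)
    p100 <- reference_response_params("ACF", ch, dt = 0.01)
    o50 <- run_response_model(s50, p50)$output
    o100 <- run_response_model(s100, p100)$output[seq(1, 7000, by = 2)]
    expect_lt(max(abs(o50 - o100)) / max(o50), 0.01)
  }
})

test_that("step responses grow monotonically with concentration for
           compression-based variants", {
  sr <- 50
  outs <- lapply(c(0.05, 0.2, 1), function(cc) {
    s <- make_stimulus(stimulus_spec("square_pulse", concentration = cc), sr)
    run_response_model(s, reference_response_params("CF", "ON"))$output
  })
  expect_true(all(outs[[1]] <= outs[[2]] + 1e-12))
  expect_true(all(outs[[2]] <= outs[[3]] + 1e-12))
})
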