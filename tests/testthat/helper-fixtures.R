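# Shared fixture builders. Everything is generated in code at test time.

# Raw tracking table for a straight constant-velocity walk.
straight_raw <- function(speed = 6, dir_deg = 90, n = 1500, sr = 50,
                         x0 = 20, y0 = 30) {
  t <- (seq_len(n) - 1) / sr
  data.frame(t_s = t,
             x_mm = x0 + speed * cos(dir_deg * pi / 180) * t,
             y_mm = y0 + speed * sin(dir_deg * pi / 180) * t,
             orientation_deg = rep(dir_deg %% 360, n))
}

# Magnitude response of a digital filter at frequency f (Hz).
digital_gain <- function(bf, f, fs) {
  zb <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$b) - 1))
  za <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$a) - 1))
  abs(sum(bf$b * zb) / sum(bf$a * za))
}

# Closed-form OFF response to a step down from steady state C0 at t = 0:
# R_i decay exponentially, OFF(t) = C0 * (exp(-t/tau_slow) - exp(-t/tau_fast)).
off_step_down_theory <- function(t, C0, tau_fast, tau_slow) {
  pmax(0, C0 * (exp(-t / tau_slow) - exp(-t / tau_fast)))
}

# Exact two-sided p-value of the paired signed-rank test by enumeration of
# all 2^n sign patterns (no ties/zeros assumed).
signed_rank_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
  min(1, p)
}

# Small synthetic plume movie, cached per session (coarse grid keeps the
# suite fast; statistics match the full-resolution generator).
.fixture_cache <- new.env(parent = emptyenv())
test_plume_movie <- function() {
  if (is.null(.fixture_cache$plume))
    .fixture_cache$plume <- make_synthetic_plume(
      plume_gen_params(seed = 4), px_mm = 2.96, fps = 15, duration = 40)
  .fixture_cache$plume
}
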