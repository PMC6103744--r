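#' Navigation model parameters
#'
#' The stochastic navigation agent combines odor-driven modulation of ground
#' speed and turn probability (through the ON and OFF response functions)
#' with deterministic wind-guided turning (sinusoidal D-functions) and an
#' optional bilateral antennal comparison:
#' \itemize{
#'   \item ground speed `v = max(0, v0 + k1*ON - k2*OFF)` (mm/s)
#'   \item turn probability per 20-ms sample `P = P0 - k3*ON + k4*OFF`,
#'     clipped to \[0, 1\]
#'   \item heading change per sample: a stochastic term
#'     `rho * sign(g) * g^2/sigma * dt` with `g ~ N(0, sigma)` and
#'     `rho ~ Bernoulli(P)` (signed squaring preserves turn direction while
#'     giving the heavy-tailed angular-velocity distribution), plus
#'     deterministic per-sample terms `k5*ON*sin(psi)` (odor-gated upwind
#'     drive) and `-k6*sin(psi)` (constant weak downwind drive), plus a
#'     bilateral term `k7*(CL - CR)*dt`.
#' }
#' `psi` is the wind angle relative to the fly (0 = heading upwind). At
#' sample rates other than 50 Hz, all per-sample rates and gains (`P`, `k5`,
#' `k6`) are rescaled by `dt/0.02` so rates per unit time are preserved.
#'
#' The ON and OFF functions are the adaptive-compression models with their
#' reference fitted time constants; `on_scale` and `off_scale` multiply the
#' two functions everywhere they enter (for modelling across-individual
#' variability) and may be vectors with one entry per trial.
#'
#' @param v0 baseline ground speed, mm/s.
#' @param p0 baseline turn probability per 20-ms sample.
#' @param sigma SD of the angular-velocity draw, deg/s.
#' @param kappa1,kappa2 ON/OFF speed modulation, mm/s per unit function.
#' @param kappa3,kappa4 ON/OFF turn-probability modulation (dimensionless).
#' @param kappa5 odor-gated upwind drive, deg/sample.
#' @param kappa6 constant downwind drive, deg/sample.
#' @param kappa7 bilateral gain, deg/s per unit compressed-concentration
#'   difference (0 disables bilateral sensing; 40 and 300 are the gains
#'   explored in simulation).
#' @param on_scale,off_scale multipliers on the ON/OFF functions (scalar or
#'   per-trial vector).
#' @param dt simulation time step, s (0.02 in the arena; 1/15 when stepping
#'   a 15-Hz plume movie).
#' @param antenna_offset distance of the right antennal sample point from
#'   the fly position, mm (one movie pixel, 0.74).
#' @param bilateral_swap if `TRUE`, the left/right antennal signals are
#'   exchanged (sign of the bilateral term inverted).
#' @param kd baseline Hill dissociation constant shared by both channels.
#' @param tau_on,tau_a_on ON filter and adaptation time constants, s.
#' @param tau_off1,tau_off2,tau_a_off OFF fast/slow filter and adaptation
#'   time constants, s.
#' @return An object of class `nav_params`.
#' @export
nav_params <- function(v0 = 6, p0 = 0.12, sigma = 20,
                       kappa1 = 0.45, kappa2 = 0.8, kappa3 = 0.03,
                       kappa4 = 0.75, kappa5 = 5, kappa6 = 0.5,
                       kappa7 = 0, on_scale = 1, off_scale = 1,
                       dt = 0.02, antenna_offset = 0.74,
                       bilateral_swap = FALSE,
                       kd = 0.01, tau_on = 0.72, tau_a_on = 9.8,
                       tau_off1 = 0.62, tau_off2 = 4.84,
                       tau_a_off = 10.08) {
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  if (any(c(kappa1, kappa2, kappa3, kappa4, kappa5, kappa6, kappa7) < 0))
    stop("all kappa coefficients must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (any(on_scale < 0) || any(off_scale < 0))
    stop("on_scale and off_scale must be >= 0")
  if (tau_off1 >= tau_off2) stop("tau_off1 must be smaller than tau_off2")
  structure(list(v0 = v0, p0 = p0, sigma = sigma, kappa1 = kappa1,
                 kappa2 = kappa2, kappa3 = kappa3, kappa4 = kappa4,
                 kappa5 = kappa5, kappa6 = kappa6, kappa7 = kappa7,
                 on_scale = on_scale, off_scale = off_scale, dt = dt,
                 antenna_offset = antenna_offset,
                 bilateral_swap = bilateral_swap, kd = kd,
                 tau_on = tau_on, tau_a_on = tau_a_on,
                 tau_off1 = tau_off1, tau_off2 = tau_off2,
                 tau_a_off = tau_a_off),
            class = "nav_params")
}

#' Wind angle relative to the fly
#'
#' Signed angle of the upwind direction in the fly's frame, in
#' (-180, 180]; 0 means the fly heads straight upwind, 180 straight
#' downwind. The sign convention makes the upwind drive `k5*ON*sin(psi)`
#' rotate the heading toward upwind (a stable fixed point at `psi = 0`) and
#' the downwind drive `-k6*sin(psi)` toward downwind.
#'
#' @param heading heading, deg.
#' @param upwind_dir heading of the upwind direction, deg (default 90).
#' @return psi in degrees.
#' @export
wind_angle <- function(heading, upwind_dir = 90) {
  wrap180(upwind_dir - heading)
}

#' Simulate an ensemble of navigation trials
#'
#' Steps `n_trials` independent agents through the environment. Per step
#' and agent: the odor concentration is sampled at the agent position (and,
#' with `kappa7 > 0`, at the right-antenna point); the ON and OFF response
#' states advance by forward Euler; ground speed, turn probability and the
#' heading update follow the model in [nav_params()]; position integrates
#' `x += dt*v*cos(H)`, `y += dt*v*sin(H)` and is clamped to the domain
#' bounds (heading unchanged at walls).
#'
#' @param env a [nav_environment()].
#' @param params a [nav_params()]; `on_scale`/`off_scale` may be length
#'   `n_trials`.
#' @param n_trials number of independent trials.
#' @param seed RNG seed; a fixed seed gives a bit-identical ensemble.
#' @param init optional list with vectors `x`, `y`, `heading` (recycled to
#'   `n_trials`). Default: uniform random heading and uniform random
#'   position — over the whole domain for arena-type environments, over the
#'   downwind quarter for plume/gradient domains.
#' @param duration trial length, s (default `env$duration`).
#' @param store_states if `TRUE` (default), keep per-sample ON/OFF/odor
#'   matrices.
#' @return An object of class `nav_ensemble`: list with `t`, matrices `x`,
#'   `y`, `heading` (time x trial), optionally `on`, `off`, `odor`,
#'   `speed` and `turn_prob` (the per-sample rate of the stochastic turn
#'   generator, the model's "theoretical" turn probability), plus
#'   `n_random_turns` (per trial), `n_samples`, `params`, `env_info`,
#'   `seed`.
#' @export
run_ensemble <- function(env, params = nav_params(), n_trials = 1,
                         seed = NULL, init = NULL, duration = NULL,
                         store_states = TRUE) {
  stopifnot(inherits(env, "nav_environment"), inherits(params, "nav_params"))
  if (n_trials == 0)
    return(structure(list(t = numeric(0), x = NULL, y = NULL, heading = NULL,
                          n_random_turns = integer(0), n_samples = 0,
                          params = params, env_info = env[c("bounds", "kind")],
                          seed = seed),
                     class = "nav_ensemble"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  dt <- p$dt
  dur <- if (is.null(duration)) env$duration else duration
  nstep <- round(dur / dt)
  b <- env$bounds
  on_scale <- rep_len(p$on_scale, n_trials)
  off_scale <- rep_len(p$off_scale, n_trials)

  if (is.null(init)) {
    hx <- stats::runif(n_trials, b[1], b[2])
    hy <- if (env$kind %in% c("plume", "gradient"))
      stats::runif(n_trials, b[3], b[3] + 0.25 * (b[4] - b[3]))
    else stats::runif(n_trials, b[3], b[4])
    hh <- stats::runif(n_trials, 0, 360)
  } else {
    hx <- rep_len(init$x, n_trials)
    hy <- rep_len(init$y, n_trials)
    hh <- rep_len(init$heading, n_trials)
    if (any(hx < b[1] | hx > b[2] | hy < b[3] | hy > b[4]))
      stop("initial position outside environment bounds")
  }

  # per-sample rescaling so rates per unit time match the 50-Hz calibration
  rf <- dt / 0.02
  a_on <- dt / p$tau_on; a_a_on <- dt / p$tau_a_on
  a_r1 <- dt / p$tau_off1; a_r2 <- dt / p$tau_off2
  a_a_off <- dt / p$tau_a_off
  upwind <- env$upwind_dir
  use_wind <- env$wind
  use_bilat <- p$kappa7 > 0
  swap_sign <- if (p$bilateral_swap) -1 else 1

  x <- hx; y <- hy; H <- hh
  A_on <- ON <- C_on_prev <- numeric(n_trials)
  A_off <- R1 <- R2 <- C_off_prev <- numeric(n_trials)
  odor_prev <- numeric(n_trials)
  Xm <- Ym <- Hm <- matrix(NA_real_, nstep, n_trials)
  if (store_states) ONm <- OFFm <- ODm <- Vm <- Pm <- Xm else
    ONm <- OFFm <- ODm <- Vm <- Pm <- NULL
  n_turns <- integer(n_trials)

  for (k in seq_len(nstep)) {
    tk <- (k - 1) * dt
    odor <- env$conc(x, y, tk)
    if (any(is.nan(odor))) stop("environment returned NaN concentration")

    # ON channel: adaptation and compression, then low-pass
    A_on <- A_on + a_a_on * (odor_prev - A_on)
    C_on <- odor / (odor + p$kd + A_on)
    ON <- ON + a_on * (C_on_prev - ON)
    # OFF channel: separate adaptation state, differential filter
    A_off <- A_off + a_a_off * (odor_prev - A_off)
    C_off <- odor / (odor + p$kd + A_off)
    R1 <- R1 + a_r1 * (C_off_prev - R1)
    R2 <- R2 + a_r2 * (C_off_prev - R2)
    OFF <- pmax(0, R2 - R1)

    on_eff <- on_scale * ON
    off_eff <- off_scale * OFF
    v <- pmax(0, p$v0 + p$kappa1 * on_eff - p$kappa2 * off_eff)
    P <- pmin(1, pmax(0, (p$p0 - p$kappa3 * on_eff + p$kappa4 * off_eff) * rf))
    rho <- stats::runif(n_trials) < P
    g <- stats::rnorm(n_trials, 0, p$sigma)
    dH <- rho * sign(g) * g^2 / p$sigma * dt
    if (use_wind) {
      psi <- (upwind - H) * pi / 180
      dH <- dH + (p$kappa5 * on_eff - p$kappa6) * sin(psi) * rf
    }
    if (use_bilat) {
      ro <- p$antenna_offset
      hr <- H * pi / 180
      xr <- x + ro * sin(hr)
      yr <- y - ro * cos(hr)
      odor_r <- env$conc(xr, yr, tk)
      CL <- odor / (odor + p$kd + A_on)
      CR <- odor_r / (odor_r + p$kd + A_on)
      dH <- dH + swap_sign * p$kappa7 * (CL - CR) * dt
    }
    # position advances with the pre-update heading; then heading updates
    hr <- H * pi / 180
    x <- pmin(b[2], pmax(b[1], x + dt * v * cos(hr)))
    y <- pmin(b[4], pmax(b[3], y + dt * v * sin(hr)))
    H <- H + dH

    Xm[k, ] <- x; Ym[k, ] <- y; Hm[k, ] <- H
    if (store_states) {
      ONm[k, ] <- ON; OFFm[k, ] <- OFF; ODm[k, ] <- odor; Vm[k, ] <- v
      Pm[k, ] <- P
    }
    n_turns <- n_turns + rho
    odor_prev <- odor
    C_on_prev <- C_on
    C_off_prev <- C_off
  }

  structure(list(t = (seq_len(nstep) - 1) * dt, x = Xm, y = Ym,
                 heading = Hm, on = ONm, off = OFFm, odor = ODm,
                 speed = Vm, turn_prob = Pm, n_random_turns = n_turns,
                 n_samples = nstep * n_trials, params = params,
                 env_info = list(bounds = b, kind = env$kind,
                                 source_xy = env$source_xy,
                                 upwind_dir = env$upwind_dir,
                                 stimulus = env$stimulus),
                 seed = seed),
            class = "nav_ensemble")
}

#' @export
print.nav_ensemble <- function(x, ...) {
  n <- if (is.null(x$x)) 0 else ncol(x$x)
  cat(sprintf("<nav_ensemble> %d trials x %d samples (%s environment)\n",
              n, length(x$t), x$env_info$kind))
  invisible(x)
}

#' Simulate a single navigation trial
#'
#' @inheritParams run_ensemble
#' @param init list with scalars `x`, `y`, `heading`, or `NULL` for the
#'   randomized rule of [run_ensemble()].
#' @return A list with `trajectory` (a [trajectory()]) and `states` (data
#'   frame with `t`, `odor`, `on`, `off`, `speed`).
#' @export
simulate_trial <- function(env, params = nav_params(), init = NULL,
                           seed = NULL, duration = NULL) {
  ens <- run_ensemble(env, params, n_trials = 1, seed = seed, init = init,
                      duration = duration, store_states = TRUE)
  list(trajectory = ensemble_trajectory(ens, 1),
       states = data.frame(t = ens$t, odor = ens$odor[, 1],
                           on = ens$on[, 1], off = ens$off[, 1],
                           speed = ens$speed[, 1]))
}

#' Extract one trial of an ensemble as a [trajectory()]
#'
#' @param ens a `nav_ensemble`.
#' @param k trial index.
#' @return A [trajectory()].
#' @export
ensemble_trajectory <- function(ens, k) {
  stopifnot(inherits(ens, "nav_ensemble"), k >= 1, k <= ncol(ens$x))
  trajectory(ens$t, ens$x[, k], ens$y[, k], ens$heading[, k],
             sample_rate = 1 / ens$params$dt,
             arena = ens$env_info$bounds)
}

#' Bilateral antennal sample
#'
#' Compressed concentrations at the left (fly position) and right antenna
#' (one `antenna_offset` perpendicular-right of the heading), both sharing
#' the adaptation state driven by the position odor.
#'
#' @param env a [nav_environment()].
#' @param x,y,heading fly state (vectors allowed).
#' @param A adaptation state(s).
#' @param t time, s.
#' @param params a [nav_params()].
#' @return A list with `CL` and `CR`.
#' @export
bilateral_sample <- function(env, x, y, heading, A, t, params = nav_params()) {
  hr <- heading * pi / 180
  ro <- params$antenna_offset
  odor_l <- env$conc(x, y, t)
  odor_r <- env$conc(x + ro * sin(hr), y - ro * cos(hr), t)
  list(CL = odor_l / (odor_l + params$kd + A),
       CR = odor_r / (odor_r + params$kd + A))
}
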