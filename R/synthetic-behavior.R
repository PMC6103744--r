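#' Generate synthetic walking-fly behavioral data
#'
#' Emulates a raw behavioral dataset so the trajectory pipeline and fitting
#' machinery can be exercised end to end without recorded flies: model
#' agents are simulated in an arena environment (one [run_ensemble()] per
#' stimulus with per-fly ON/OFF scale factors), and their trajectories are
#' written out in the raw tracking-table schema, optionally corrupted with
#' the tracker's characteristic artifacts — Gaussian position jitter,
#' spurious 180-degree orientation flips, and frozen-position (stationary)
#' bouts.
#'
#' @param n_flies number of flies.
#' @param trials_per_fly trials per fly and stimulus.
#' @param stim a [stimulus_spec()] (or list of them).
#' @param nav a [nav_params()]; per-fly scales override `on_scale` and
#'   `off_scale`.
#' @param adv an [advection_model()] for the arena.
#' @param scale_sdlog SD (log scale) of the log-normal per-fly ON/OFF scale
#'   factors; 0 gives identical flies.
#' @param noise_sd SD of added position jitter, mm.
#' @param flips_per_trial expected number of injected orientation-flip
#'   segments per trial (each 0.5-3 s long).
#' @param stops_per_trial expected number of injected frozen bouts per
#'   trial (each 0.5-2 s).
#' @param seed RNG seed.
#' @return A list with `trajectories` (data frame: `t_s`, `x_mm`, `y_mm`,
#'   `orientation_deg`, `fly_id`, `trial_id`, `stimulus_id`), `truth` (data
#'   frame of per-fly scale factors), `flip_mask` (list, per trial, of
#'   logical vectors marking injected flip samples), `nav`, `stimuli`.
#' @export
make_synthetic_behavior <- function(n_flies = 6, trials_per_fly = 2,
                                    stim = stimulus_spec("square_pulse"),
                                    nav = nav_params(),
                                    adv = advection_model(),
                                    scale_sdlog = 0, noise_sd = 0,
                                    flips_per_trial = 0,
                                    stops_per_trial = 0, seed = 1) {
  stimuli <- if (inherits(stim, "stimulus_spec")) list(stim) else stim
  set.seed(seed)
  on_scales <- stats::rlnorm(n_flies, 0, scale_sdlog)
  off_scales <- stats::rlnorm(n_flies, 0, scale_sdlog)
  sr <- 1 / nav$dt
  tabs <- list()
  flip_masks <- list()
  trial_id <- 0L
  for (s in seq_along(stimuli)) {
    env <- make_arena_env(stimuli[[s]], adv, sample_rate = sr)
    p <- nav
    p$on_scale <- rep(on_scales, each = trials_per_fly)
    p$off_scale <- rep(off_scales, each = trials_per_fly)
    n <- n_flies * trials_per_fly
    ens <- run_ensemble(env, p, n_trials = n, seed = seed + s,
                        store_states = FALSE)
    nstep <- length(ens$t)
    for (j in seq_len(n)) {
      trial_id <- trial_id + 1L
      fly <- (j - 1) %/% trials_per_fly + 1L
      x <- ens$x[, j]; y <- ens$y[, j]
      ori <- ens$heading[, j] %% 360
      if (noise_sd > 0) {
        x <- x + stats::rnorm(nstep, 0, noise_sd)
        y <- y + stats::rnorm(nstep, 0, noise_sd)
      }
      fm <- rep(FALSE, nstep)
      nflip <- stats::rpois(1, flips_per_trial)
      for (q in seq_len(nflip)) {
        len <- round(stats::runif(1, 0.5, 3) * sr)
        i0 <- sample.int(max(1, nstep - len), 1)
        seg <- i0:min(nstep, i0 + len - 1)
        fm[seg] <- !fm[seg] # overlapping flips cancel
      }
      ori[fm] <- (ori[fm] + 180) %% 360
      nstop <- stats::rpois(1, stops_per_trial)
      for (q in seq_len(nstop)) {
        len <- round(stats::runif(1, 0.5, 2) * sr)
        i0 <- sample.int(max(1, nstep - len), 1)
        seg <- i0:min(nstep, i0 + len - 1)
        x[seg] <- x[seg[1]]; y[seg] <- y[seg[1]]
      }
      tabs[[trial_id]] <- data.frame(
        t_s = ens$t, x_mm = x, y_mm = y, orientation_deg = ori,
        fly_id = fly, trial_id = trial_id, stimulus_id = s)
      flip_masks[[trial_id]] <- fm
    }
  }
  list(trajectories = do.call(rbind, tabs),
       truth = data.frame(fly_id = seq_len(n_flies),
                          on_scale = on_scales, off_scale = off_scales),
       flip_mask = flip_masks, nav = nav, stimuli = stimuli)
}
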