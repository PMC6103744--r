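#' Map model output to a behavioral prediction
#'
#' @param model_output a [model_state_trace()], [signal_trace()] or numeric
#'   vector of unscaled model drive.
#' @param scale output gain (e.g. mm/s upwind velocity per unit ON).
#' @param baseline additive baseline in behavioral units.
#' @return Numeric vector `baseline + scale * output`.
#' @export
predict_behavior <- function(model_output, scale, baseline = 0) {
  out <- if (inherits(model_output, "model_state_trace"))
    model_output$output else trace_values(model_output)
  baseline + scale * out
}

#' Root-mean-squared error between prediction and target
#' @param prediction,target numeric vectors of equal length.
#' @return A scalar, in the units of the inputs.
#' @export
rmse <- function(prediction, target) {
  prediction <- trace_values(prediction); target <- trace_values(target)
  stopifnot(length(prediction) == length(target))
  sqrt(mean((prediction - target)^2))
}

#' Pearson correlation between prediction and target
#' @inheritParams rmse
#' @return A scalar in \[-1, 1\].
#' @export
pearson <- function(prediction, target) {
  stats::cor(trace_values(prediction), trace_values(target))
}

# Free-parameter layout per variant/channel. OFF slow constant is fitted as
# tau_off1 + d_tau with d_tau > 0 so the fast < slow ordering is structural.
fit_par_names <- function(variant, channel, fit_baseline) {
  adaptive <- variant %in% c("ACF", "FAC")
  nm <- if (channel == "ON") "tau_on" else c("tau_off1", "d_tau")
  if (adaptive) nm <- c(nm, "tau_a")
  nm <- c(nm, "scale")
  if (fit_baseline) nm <- c(nm, "baseline")
  nm
}

par_to_response_params <- function(par, variant, channel, kd, dt) {
  response_params(
    variant = variant, channel = channel, kd = kd, dt = dt,
    tau_a = if ("tau_a" %in% names(par)) unname(par["tau_a"]) else NULL,
    tau_on = if (channel == "ON") unname(par["tau_on"]) else NULL,
    tau_off1 = if (channel == "OFF") unname(par["tau_off1"]) else NULL,
    tau_off2 = if (channel == "OFF")
      unname(par["tau_off1"] + par["d_tau"]) else NULL,
    scale = unname(par["scale"]))
}

#' Fit an ON/OFF response model to behavioral traces
#'
#' Jointly minimizes the pooled sum of squared residuals between scaled model
#' predictions and target traces across all stimulus/target pairs, using
#' bounded Levenberg-Marquardt least squares ([minpack.lm::nls.lm]) with
#' multiple starts from perturbed initial guesses. The baseline `kd` of the
#' Hill compression is held fixed (it is determined separately from
#' dose-response fits to square pulses), and the fast/slow ordering of the
#' OFF filter constants is enforced structurally.
#'
#' @param stimuli list of [signal_trace()] stimuli on a common grid.
#' @param targets list of target traces (numeric or [signal_trace()]), one
#'   per stimulus, same lengths.
#' @param variant,channel model variant and channel (see [response_params()]).
#' @param init named numeric vector of starting values (see
#'   [response_params()] names; `tau_off2` may be given instead of `d_tau`).
#'   Defaults to a generic guess.
#' @param kd fixed baseline dissociation constant.
#' @param baseline fixed additive baseline; by default the mean of each
#'   target over its pre-stimulus samples. Ignored if `fit_baseline = TRUE`.
#' @param fit_baseline if `TRUE`, a common baseline is co-fitted.
#' @param n_starts number of optimizer starts; starts after the first perturb
#'   `init` by log-uniform factors in `perturb`.
#' @param perturb two positive factors bounding the multiplicative start
#'   perturbation (default `c(0.25, 4)`).
#' @param seed optional RNG seed for the start perturbations.
#' @return An object of class `response_fit`: list with `params` (a
#'   [response_params()] at the optimum), `baseline`, `rmse`, `pearson_r`,
#'   `n_points`, `converged`, `cost`, `start_points`.
#' @export
fit_response_model <- function(stimuli, targets, variant, channel,
                               init = NULL, kd = 0.01, baseline = NULL,
                               fit_baseline = FALSE, n_starts = 10,
                               perturb = c(0.25, 4), seed = NULL) {
  if (is_signal_trace(stimuli)) stimuli <- list(stimuli)
  if (!is.list(targets)) targets <- list(targets)
  stopifnot(length(stimuli) >= 1, length(stimuli) == length(targets))
  sr <- stimuli[[1]]$sample_rate
  dt <- 1 / sr
  stim_v <- lapply(stimuli, trace_values)
  targ_v <- lapply(targets, trace_values)
  for (i in seq_along(stim_v))
    if (length(stim_v[[i]]) != length(targ_v[[i]]))
      stop("stimulus and target ", i, " have different lengths")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  # fixed per-pair baseline: mean of the target before the stimulus turns on
  base_fixed <- if (fit_baseline) NULL else if (!is.null(baseline)) {
    rep_len(baseline, length(targets))
  } else {
    vapply(seq_along(stim_v), function(i) {
      pre <- which(cumsum(stim_v[[i]]) == 0)
      if (length(pre) >= 5) mean(targ_v[[i]][pre]) else 0
    }, numeric(1))
  }

  pn <- fit_par_names(variant, channel, fit_baseline)
  default_init <- c(tau_on = 0.5, tau_off1 = 0.5, d_tau = 3, tau_a = 10,
                    scale = 1, baseline = 0)
  start0 <- default_init[pn]
  if (!is.null(init)) {
    init <- unlist(init)
    if ("tau_off2" %in% names(init) && !"d_tau" %in% names(init))
      init["d_tau"] <- init["tau_off2"] - init["tau_off1"]
    keep <- intersect(names(init), pn)
    start0[keep] <- init[keep]
  }
  lower <- c(tau_on = 0.5 * dt, tau_off1 = 0.5 * dt, d_tau = 1e-4,
             tau_a = 0.5 * dt, scale = 0, baseline = -Inf)[pn]
  upper <- c(tau_on = 100, tau_off1 = 100, d_tau = 200, tau_a = 1000,
             scale = 1e4, baseline = Inf)[pn]

  residuals_fn <- function(par) {
    names(par) <- pn
    rp <- par_to_response_params(par, variant, channel, kd, dt)
    b <- if (fit_baseline) rep_len(unname(par["baseline"]), length(stim_v))
         else base_fixed
    unlist(lapply(seq_along(stim_v), function(i) {
      tr <- signal_trace(stim_v[[i]], sr)
      pred <- b[i] + rp$scale * run_response_model(tr, rp)$output
      pred - targ_v[[i]]
    }))
  }

  starts <- vector("list", n_starts)
  starts[[1]] <- start0
  if (n_starts > 1) {
    lp <- log(perturb)
    for (k in 2:n_starts) {
      fac <- exp(stats::runif(length(pn), lp[1], lp[2]))
      s <- start0 * fac
      if (fit_baseline) s["baseline"] <- start0["baseline"]
      starts[[k]] <- pmin(pmax(s, lower + 1e-8), ifelse(is.finite(upper), upper, s))
    }
  }

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = residuals_fn,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-12, ptol = 1e-12, maxiter = 400)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  par <- stats::coef(best)
  names(par) <- pn
  rp <- par_to_response_params(par, variant, channel, kd, dt)
  b <- if (fit_baseline) rep_len(unname(par["baseline"]), length(stim_v))
       else base_fixed
  preds <- lapply(seq_along(stim_v), function(i)
    b[i] + rp$scale * run_response_model(signal_trace(stim_v[[i]], sr), rp)$output)
  all_pred <- unlist(preds); all_targ <- unlist(targ_v)
  r <- if (stats::sd(all_pred) > 0 && stats::sd(all_targ) > 0)
    stats::cor(all_pred, all_targ) else NA_real_
  structure(list(
    params = rp,
    baseline = b,
    rmse = rmse(all_pred, all_targ),
    pearson_r = r,
    n_points = length(all_targ),
    converged = best$info %in% 1:4,
    cost = best$deviance,
    start_points = starts
  ), class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf("<response_fit> %s %s: rmse=%.4g r=%.3f converged=%s\n",
              x$params$variant, x$params$channel, x$rmse, x$pearson_r,
              x$converged))
  print(x$params)
  invisible(x)
}

#' Fit a Hill dose-response function
#'
#' Least-squares fit of `response = baseline + rmax * c^n / (c^n + kd^n)`
#' to (concentration, response) pairs, with multi-start Levenberg-Marquardt.
#'
#' @param concentrations odorant concentrations (e.g. % apple cider vinegar);
#'   must be > 0 and include at least 4 values.
#' @param responses mean behavioral responses at those concentrations.
#' @param init optional named starting values (`kd`, `hill_n`, `rmax`,
#'   `baseline`).
#' @param fit_baseline if `TRUE` an additive baseline is co-fitted
#'   (default fixed at 0).
#' @param n_starts number of optimizer starts.
#' @param seed optional RNG seed for start perturbations.
#' @return An object of class `hill_fit`: list with `kd`, `hill_n`, `rmax`,
#'   `baseline`, `rmse`, `converged`.
#' @export
fit_hill <- function(concentrations, responses, init = NULL,
                     fit_baseline = FALSE, n_starts = 5, seed = NULL) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 4) stop("need at least 4 dose-response pairs")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (diff(range(responses)) == 0)
    stop("responses are flat; Hill parameters are unidentifiable")
  npar <- 3L + as.integer(fit_baseline)
  if (length(concentrations) < npar)
    stop("fewer points than free parameters")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pn <- c("kd", "hill_n", "rmax", if (fit_baseline) "baseline")
  start0 <- c(kd = exp(mean(log(range(concentrations)))), hill_n = 1,
              rmax = max(responses), baseline = 0)[pn]
  if (!is.null(init)) {
    init <- unlist(init)
    keep <- intersect(names(init), pn)
    start0[keep] <- init[keep]
  }
  lower <- c(kd = 1e-8, hill_n = 0.05, rmax = -Inf, baseline = -Inf)[pn]
  upper <- c(kd = 1e6, hill_n = 20, rmax = Inf, baseline = Inf)[pn]
  model <- function(par) {
    cn <- concentrations^par["hill_n"]
    b <- if (fit_baseline) par["baseline"] else 0
    b + par["rmax"] * cn / (cn + par["kd"]^par["hill_n"])
  }
  resid_fn <- function(par) { names(par) <- pn; model(par) - responses }
  best <- NULL
  for (k in seq_len(n_starts)) {
    s <- start0
    if (k > 1) {
      fac <- exp(stats::runif(length(pn), log(0.5), log(2)))
      s <- pmin(pmax(start0 * fac, lower + 1e-9),
                ifelse(is.finite(upper), upper, start0 * fac))
    }
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-14, ptol = 1e-14, maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("Hill fit failed from all starts")
  par <- stats::coef(best); names(par) <- pn
  structure(list(kd = unname(par["kd"]), hill_n = unname(par["hill_n"]),
                 rmax = unname(par["rmax"]),
                 baseline = if (fit_baseline) unname(par["baseline"]) else 0,
                 rmse = sqrt(best$deviance / length(responses)),
                 converged = best$info %in% 1:4),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> kd=%.4g n=%.3f rmax=%.4g baseline=%.4g rmse=%.3g\n",
              x$kd, x$hill_n, x$rmax, x$baseline, x$rmse))
  invisible(x)
}

# Locate cycle boundaries of a periodically modulated stimulus: the trace is
# smoothed with a centered moving average, peaks above half the maximum are
# found, and boundaries are the minima (or the peaks themselves) between
# consecutive peaks.
detect_cycles <- function(stim, boundary = c("minima", "maxima"),
                          smooth_s = 0.5) {
  boundary <- match.arg(boundary)
  sr <- stim$sample_rate
  w <- max(1L, round(smooth_s * sr))
  if (w %% 2 == 0) w <- w + 1L
  s <- as.numeric(stats::filter(stim$value, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- 0
  thr <- 0.5 * max(s)
  if (thr <= 0) stop("no detectable cycles in stimulus")
  up <- which(diff(sign(diff(s))) < 0) + 1L
  peaks <- up[s[up] > thr]
  # enforce minimal separation between peaks
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) > 0.25 * sr)
    peaks <- peaks[keep]
  }
  if (length(peaks) < 2) stop("no detectable cycles in stimulus")
  if (boundary == "maxima") return(peaks)
  vapply(seq_len(length(peaks) - 1), function(j) {
    i0 <- peaks[j]; i1 <- peaks[j + 1]
    i0 + which.min(s[i0:i1]) - 1L
  }, integer(1))
}

#' Jackknife estimate of per-cycle response modulation
#'
#' For a periodically modulated stimulus (e.g. a frequency sweep), computes
#' the min-to-max amplitude of the mean response within each stimulus cycle,
#' with a jackknife standard error over leave-one-group-out means. Cycle
#' boundaries are local minima (ascending sweeps) or maxima (descending
#' sweeps) of the smoothed stimulus.
#'
#' @param per_fly_traces matrix (flies/trials in rows, time in columns) or
#'   list of equal-length numeric vectors: one mean response per fly.
#' @param stimulus the stimulus [signal_trace()] on the same grid.
#' @param n_drop number of flies left out per jackknife estimate (default 1).
#' @param boundary `"minima"` or `"maxima"`: which stimulus extrema delimit
#'   cycles.
#' @param smooth_s stimulus smoothing window for extremum detection, s.
#' @return An object of class `cycle_modulation`: list with `cycle_freqs`
#'   (Hz), `amplitude` (mean over jackknife estimates of the per-cycle
#'   min-to-max amplitude), `se` (jackknife standard error,
#'   `sqrt((n-1)/n * sum((x_i - mean(x))^2))` over the `n` leave-out
#'   estimates), and `n_estimates`.
#' @export
jackknife_cycle_modulation <- function(per_fly_traces, stimulus, n_drop = 1,
                                       boundary = c("minima", "maxima"),
                                       smooth_s = 0.5) {
  if (is.list(per_fly_traces))
    per_fly_traces <- do.call(rbind, per_fly_traces)
  stopifnot(is.matrix(per_fly_traces), nrow(per_fly_traces) >= 2,
            ncol(per_fly_traces) == length(stimulus$value))
  nf <- nrow(per_fly_traces)
  bounds <- detect_cycles(stimulus, boundary = boundary, smooth_s = smooth_s)
  if (length(bounds) < 2) stop("no detectable cycles")
  groups <- split(seq_len(nf), ceiling(seq_len(nf) / n_drop))
  ng <- length(groups)
  if (ng < 2) stop("need at least 2 jackknife groups")
  cyc <- lapply(seq_len(length(bounds) - 1),
                function(j) bounds[j]:bounds[j + 1])
  amp_of <- function(m) vapply(cyc, function(ix) {
    v <- m[ix]; max(v) - min(v)
  }, numeric(1))
  est <- t(vapply(groups, function(g) {
    amp_of(colMeans(per_fly_traces[-g, , drop = FALSE]))
  }, numeric(length(cyc))))
  m <- colMeans(est)
  se <- sqrt((ng - 1) / ng * colSums((est - rep(m, each = ng))^2))
  dur <- (vapply(cyc, length, integer(1)) - 1) / stimulus$sample_rate
  structure(list(cycle_freqs = 1 / dur, amplitude = m, se = se,
                 n_estimates = ng),
            class = "cycle_modulation")
}
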