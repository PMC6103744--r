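#' Trajectory of a walking fly or model agent
#'
#' Arena frame: `x` lateral, `y` increasing upwind (the odor inlet is at the
#' top of the arena, wind blows toward negative `y`). Heading follows the
#' mathematical convention (degrees counter-clockwise from the `+x` axis;
#' 90 deg is straight upwind) and is continuous (unwrapped).
#'
#' @param t time, s (uniform grid).
#' @param x,y position, mm.
#' @param heading unwrapped orientation, deg.
#' @param sample_rate Hz (default 50).
#' @param arena bounds `c(xmin, xmax, ymin, ymax)`, mm; default the
#'   14 x 4 cm behavioral chamber.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(t, x, y, heading, sample_rate = 50,
                       arena = c(0, 40, 0, 140)) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(heading) == n, n >= 2)
  structure(list(t = t, x = x, y = y, heading = heading,
                 sample_rate = sample_rate, arena = arena),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples @ %g Hz, path %.1f mm\n",
              length(x$t), x$sample_rate,
              sum(sqrt(diff(x$x)^2 + diff(x$y)^2))))
  invisible(x)
}

# Unwrap angles in degrees to a continuous series.
unwrap_deg <- function(a) {
  d <- diff(a)
  d <- d - 360 * round(d / 360)
  cumsum(c(a[1], d))
}

# Wrap angles to (-180, 180].
wrap180 <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

condition_rejected <- function(msg) {
  structure(class = c("trial_rejected", "error", "condition"),
            list(message = msg, call = NULL))
}

# Zero-phase Butterworth with odd-reflection edge padding (suppresses the
# startup transients of plain forward-backward filtering).
zero_phase <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1, 3 * max(length(bf$a), length(bf$b)) * 10)
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(np + 1):(np + n)]
}

#' Preprocess a raw tracked trajectory
#'
#' Applies the standard cleaning steps to a raw `(t, x, y, orientation)`
#' table from video tracking: rejection of trials with tracking gaps,
#' correction of spurious ~180 deg orientation flips (the tracker cannot
#' always distinguish head from tail; the branch best aligned with the
#' direction of movement is chosen, and the choice is carried through
#' stationary periods), zero-phase low-pass filtering of coordinates and
#' unwrapped orientation (two-pole Butterworth, 2.5 Hz cutoff), and
#' rejection of trials with total path length below `min_path` mm.
#'
#' @param raw data frame with columns `t_s`, `x_mm`, `y_mm`,
#'   `orientation_deg` sampled at `sample_rate`.
#' @param sample_rate Hz (default 50).
#' @param arena arena bounds `c(xmin, xmax, ymin, ymax)`, mm.
#' @param cutoff_hz Butterworth cutoff (default 2.5).
#' @param min_path minimum total path length, mm (default 25).
#' @param move_thresh speed threshold used when resolving orientation flips,
#'   mm/s (default 1).
#' @return A [trajectory()]. Rejected trials raise a classed condition
#'   (`trial_rejected`) whose message states the reason.
#' @export
preprocess_trajectory <- function(raw, sample_rate = 50,
                                  arena = c(0, 40, 0, 140),
                                  cutoff_hz = 2.5, min_path = 25,
                                  move_thresh = 1) {
  need <- c("t_s", "x_mm", "y_mm", "orientation_deg")
  if (!all(need %in% names(raw)))
    stop("raw trajectory must have columns ", paste(need, collapse = ", "))
  t <- raw$t_s
  dt <- diff(t)
  if (any(abs(dt - 1 / sample_rate) > 0.25 / sample_rate))
    stop(condition_rejected("tracking gap: non-uniform time grid"))
  x <- raw$x_mm; y <- raw$y_mm
  if (anyNA(x) || anyNA(y) || anyNA(raw$orientation_deg))
    stop(condition_rejected("tracking gap: missing samples"))

  h <- unwrap_deg(raw$orientation_deg)

  # resolve head/tail ambiguity: sudden ~180-degree jumps delimit segments
  # of consistent (possibly flipped) orientation; each segment adopts the
  # branch that best correlates with the direction of movement (majority
  # over its moving samples), and segments without movement inherit the
  # previous decision
  n <- length(t)
  vx <- c(diff(x), 0) * sample_rate
  vy <- c(diff(y), 0) * sample_rate
  speed <- sqrt(vx^2 + vy^2)
  moving <- speed >= move_thresh
  movedir <- atan2(vy, vx) * 180 / pi
  seg_id <- cumsum(c(1, as.integer(abs(wrap180(diff(h))) > 120)))
  mis <- cos((h - movedir) * pi / 180)
  seg_flip <- vapply(split(seq_len(n), seg_id), function(idx) {
    ms <- idx[moving[idx]]
    if (!length(ms)) return(NA)
    mean(mis[ms]) < 0
  }, logical(1))
  for (s in seq_along(seg_flip)) if (is.na(seg_flip[s]))
    seg_flip[s] <- if (s == 1) FALSE else seg_flip[s - 1]
  h <- unwrap_deg(h - 180 * seg_flip[seg_id])

  bf <- signal::butter(2, cutoff_hz / (sample_rate / 2), type = "low")
  xf <- zero_phase(bf, x)
  yf <- zero_phase(bf, y)
  hf <- zero_phase(bf, h)

  path <- sum(sqrt(diff(xf)^2 + diff(yf)^2))
  if (path < min_path)
    stop(condition_rejected(sprintf(
      "moved %.1f mm, below the %g mm minimum", path, min_path)))
  trajectory(t, xf, yf, hf, sample_rate = sample_rate, arena = arena)
}

# Central-difference derivative (one-sided at the edges), per second.
cdiff <- function(v, sample_rate) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  d[1] <- v[2] - v[1]
  d[n] <- v[n] - v[n - 1]
  d * sample_rate
}

#' Compute gait-parameter series from a trajectory
#'
#' Derivatives are central differences on the (filtered) coordinate series.
#' Ground speed is the path increment per frame; upwind velocity is the
#' derivative of the `y` coordinate; angular velocity is the absolute
#' derivative of the unwrapped heading; curvature is angular velocity
#' divided by ground speed, defined only on moving samples (ground speed at
#' or above `move_thresh`); the binary turn indicator flags curvature above
#' `turn_thresh`.
#'
#' @param traj a [trajectory()] (typically from [preprocess_trajectory()]).
#' @param move_thresh stationary threshold, mm/s (default 1).
#' @param turn_thresh curvature threshold for turning, deg/mm (default 20).
#' @return An object of class `gait_series`: list of per-sample vectors
#'   `t`, `ground_speed` (mm/s), `upwind_velocity` (mm/s),
#'   `angular_velocity` (deg/s, absolute), `signed_angular_velocity`
#'   (deg/s), `curvature` (deg/mm, `NA` when stationary), `turn_indicator`
#'   (0/1, `NA` when stationary), `moving_mask`, `valid_mask`, and
#'   `sample_rate`.
#' @export
compute_gait <- function(traj, move_thresh = 1, turn_thresh = 20) {
  stopifnot(inherits(traj, "trajectory"))
  sr <- traj$sample_rate
  dx <- cdiff(traj$x, sr)
  dy <- cdiff(traj$y, sr)
  gs <- sqrt(dx^2 + dy^2)
  dh <- cdiff(traj$heading, sr)
  av <- abs(dh)
  moving <- gs >= move_thresh
  curv <- ifelse(moving, av / gs, NA_real_)
  turn <- ifelse(moving, as.numeric(curv > turn_thresh), NA_real_)
  structure(list(t = traj$t, ground_speed = gs, upwind_velocity = dy,
                 angular_velocity = av, signed_angular_velocity = dh,
                 curvature = curv, turn_indicator = turn,
                 moving_mask = moving,
                 valid_mask = rep(TRUE, length(gs)),
                 sample_rate = sr),
            class = "gait_series")
}

gait_fields <- c("ground_speed", "upwind_velocity", "angular_velocity",
                 "signed_angular_velocity", "curvature", "turn_indicator")

#' Warp gait series to odor-encounter time
#'
#' The odor front takes `(y_inlet - y)/wind_speed` seconds to advect from
#' the inlet to the fly, so the true time of odor encounter depends on the
#' fly's position. Each sample during the stimulus is shifted earlier by the
#' advection delay at the fly's position at that time; pre- and post-odor
#' segments are shifted by the delay at the position the fly occupied at
#' odor onset and offset respectively. Re-gridding may skip or repeat
#' individual samples; gaps are filled by repeating the previous sample.
#'
#' @param gait a [gait_series()] from [compute_gait()].
#' @param traj the matching [trajectory()].
#' @param stim the [stimulus_spec()] delivered at the inlet.
#' @param adv an [advection_model()].
#' @return A new `gait_series` on the same grid, with trailing samples that
#'   received no data marked invalid.
#' @export
warp_to_odor_time <- function(gait, traj, stim, adv = advection_model()) {
  stopifnot(inherits(gait, "gait_series"), inherits(traj, "trajectory"),
            inherits(stim, "stimulus_spec"))
  sr <- gait$sample_rate
  n <- length(gait$t)
  y_inlet <- traj$arena[4]
  t_rel <- gait$t - gait$t[1]
  stim_end <- stim$onset + stim$duration +
    if (!is.null(stim$ramp_duration)) stim$ramp_duration else 0
  delay <- (y_inlet - traj$y) / adv$wind_speed
  in_odor <- t_rel >= stim$onset & t_rel < stim_end
  i_on <- which(t_rel >= stim$onset)[1]
  i_off <- which(t_rel >= stim_end)
  i_off <- if (length(i_off)) i_off[1] else n
  d <- delay
  if (!is.na(i_on)) d[t_rel < stim$onset] <- delay[i_on]
  d[t_rel >= stim_end] <- delay[i_off]
  shift <- round(d * sr)
  idx_new <- pmax(1L, seq_len(n) - shift)

  out <- gait
  for (f in gait_fields) {
    v <- rep(NA_real_, n)
    v[idx_new] <- gait[[f]]
    out[[f]] <- locf(v)
  }
  mv <- rep(NA, n); mv[idx_new] <- gait$moving_mask
  out$moving_mask <- as.logical(locf(as.numeric(mv)))
  vv <- rep(NA, n); vv[idx_new] <- as.numeric(gait$valid_mask)
  vv <- locf(vv)
  valid <- !is.na(vv) & vv > 0
  valid[seq_len(n) > max(idx_new)] <- FALSE # tail received no data
  out$valid_mask <- valid
  out$moving_mask[is.na(out$moving_mask)] <- FALSE
  out
}

# last-observation-carried-forward; leading NAs preserved
locf <- function(v) {
  i <- seq_along(v)
  filled <- !is.na(v)
  idx <- cummax(ifelse(filled, i, 0L))
  out <- rep(NA_real_, length(v))
  out[idx > 0] <- v[idx[idx > 0]]
  out
}

#' Apply spatial exclusion rules to a gait series
#'
#' Clears the validity mask for samples within `side_margin` mm of the side
#' walls (where boundary-layer effects slow the odor front) and, optionally,
#' for all samples after the fly first reaches the upwind end of the arena
#' (where geometry constrains movement).
#'
#' @param gait a [gait_series()].
#' @param traj the matching [trajectory()].
#' @param side_margin side-wall margin, mm (default 3).
#' @param exclude_after_top if `TRUE` (default), mask everything after the
#'   fly first comes within `top_margin` mm of the upwind wall.
#' @param top_margin distance from the upwind wall that counts as "reached
#'   the top", mm (default 5).
#' @return The `gait_series` with an updated `valid_mask`.
#' @export
apply_exclusions <- function(gait, traj, side_margin = 3,
                             exclude_after_top = TRUE, top_margin = 5) {
  stopifnot(inherits(gait, "gait_series"), inherits(traj, "trajectory"))
  valid <- gait$valid_mask
  a <- traj$arena
  valid[traj$x < a[1] + side_margin | traj$x > a[2] - side_margin] <- FALSE
  if (exclude_after_top) {
    hit <- which(traj$y >= a[4] - top_margin)
    if (length(hit)) valid[hit[1]:length(valid)] <- FALSE
  }
  gait$valid_mask <- valid
  gait
}

#' Compare gait parameters across trial periods
#'
#' Computes per-fly means of a gait parameter in the before / during / after
#' windows (moving and valid samples only) and runs two-sided paired
#' Wilcoxon signed-rank tests for the three pairwise comparisons, with a
#' Bonferroni-corrected significance threshold. Tests are exact for up to 25
#' paired differences and use the continuity-corrected normal approximation
#' otherwise.
#'
#' @param per_fly a list with one element per fly (or per trial), each a
#'   list/data.frame with `t` (s, relative to odor onset), `value`, and
#'   optionally `moving` and `valid` logical masks.
#' @param windows named list of 2-vectors, s relative to odor onset; default
#'   `before = c(-30, 0)`, `during = c(2, 3)`, `after = c(11, 13)` (i.e.
#'   1-3 s after offset of a 10-s pulse).
#' @param alpha family-wise significance level before correction (0.05).
#' @return An object of class `period_stats`: list with `per_fly_means`
#'   (matrix, one row per fly), `p_values` (named vector for
#'   before-during, before-after, during-after), `alpha_corrected`,
#'   `significant` (logical), `n`.
#' @export
period_compare <- function(per_fly,
                           windows = list(before = c(-30, 0),
                                          during = c(2, 3),
                                          after = c(11, 13)),
                           alpha = 0.05) {
  stopifnot(length(per_fly) >= 5, length(windows) == 3)
  wm <- t(vapply(per_fly, function(f) {
    mv <- if (!is.null(f$moving)) f$moving else rep(TRUE, length(f$value))
    vd <- if (!is.null(f$valid)) f$valid else rep(TRUE, length(f$value))
    vapply(windows, function(w) {
      i <- f$t >= w[1] & f$t < w[2] & mv & vd & !is.na(f$value)
      if (!any(i)) NA_real_ else mean(f$value[i])
    }, numeric(1))
  }, numeric(3)))
  colnames(wm) <- names(windows)
  if (any(colSums(!is.na(wm)) == 0)) stop("empty period window")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  pv <- vapply(pairs, function(pr) {
    a <- wm[, pr[1]]; b <- wm[, pr[2]]
    ok <- !is.na(a) & !is.na(b)
    d <- a[ok] - b[ok]
    nz <- sum(d != 0)
    if (nz == 0) return(1)
    suppressWarnings(stats::wilcox.test(
      a[ok], b[ok], paired = TRUE, exact = nz <= 25,
      correct = TRUE)$p.value)
  }, numeric(1))
  names(pv) <- vapply(pairs, function(pr)
    paste(names(windows)[pr], collapse = "-"), character(1))
  ac <- alpha / length(pairs)
  structure(list(per_fly_means = wm, p_values = pv, alpha_corrected = ac,
                 significant = pv < ac, n = nrow(wm)),
            class = "period_stats")
}

#' @export
print.period_stats <- function(x, ...) {
  cat(sprintf("<period_stats> n=%d, alpha_corrected=%.4g\n", x$n,
              x$alpha_corrected))
  print(signif(x$p_values, 3))
  invisible(x)
}

#' Empirical wind-angle turning curve (D-function)
#'
#' Bins the signed per-sample heading change by the wind angle relative to
#' the fly, psi (0 when heading straight upwind), averaging over moving,
#' valid samples. A fly that turns upwind during odor shows a curve
#' proportional to `sin(psi)`; a downwind drive gives `-sin(psi)`.
#'
#' @param gait a [gait_series()].
#' @param traj the matching [trajectory()].
#' @param upwind_dir direction of the upwind axis in the heading frame, deg
#'   (default 90, i.e. `+y`).
#' @param n_bins number of circular psi bins (default 18, i.e. 20 deg).
#' @param sample_window optional 2-vector of times (s) restricting the
#'   samples used.
#' @return A data frame with `psi_mid` (deg), `mean_turn` (deg per sample,
#'   signed), `n`, `se`.
#' @export
empirical_d_function <- function(gait, traj, upwind_dir = 90, n_bins = 18,
                                 sample_window = NULL) {
  stopifnot(inherits(gait, "gait_series"), inherits(traj, "trajectory"))
  psi <- wrap180(upwind_dir - traj$heading)
  # forward difference: the turn executed FROM each psi (a central
  # difference would mix in the arrival turn, which cancels the drive for
  # stationary heading dynamics)
  n <- length(traj$heading)
  dh <- c(diff(traj$heading), NA_real_) # deg per sample
  keep <- gait$moving_mask & gait$valid_mask & !is.na(dh)
  if (!is.null(sample_window))
    keep <- keep & gait$t >= sample_window[1] & gait$t < sample_window[2]
  edges <- seq(-180, 180, length.out = n_bins + 1)
  bin <- cut(psi[keep], edges, include.lowest = TRUE, labels = FALSE)
  dhk <- dh[keep]
  mid <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  agg <- vapply(seq_len(n_bins), function(b) {
    v <- dhk[bin == b & !is.na(bin)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      n = length(v),
      se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }, numeric(3))
  data.frame(psi_mid = mid, mean_turn = agg["mean", ], n = agg["n", ],
             se = agg["se", ])
}

#' Read and write trajectory tables
#'
#' Plain-CSV serialization of raw trajectory tables in the schema the
#' pipeline ingests: `t_s, x_mm, y_mm, orientation_deg, fly_id, trial_id,
#' stimulus_id`.
#'
#' @param tab data frame in the schema above.
#' @param path file path.
#' @return `write_trajectory_table` returns `path` invisibly;
#'   `read_trajectory_table` returns the data frame.
#' @export
write_trajectory_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path) {
  utils::read.csv(path)
}
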