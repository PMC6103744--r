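#' Space-time plume concentration movie
#'
#' Container for a rasterized plume movie: frames are a 3-d array indexed
#' `[frame, downwind pixel, lateral pixel]`, with concentration normalized
#' so the time-mean at the source pixel is 1. The lateral axis is centered
#' on the source midline; the downwind axis starts at the source plane.
#'
#' @param frames numeric array `(n_frames, n_downwind, n_lateral)`.
#' @param px_mm pixel size, mm (default 0.74).
#' @param fps frame rate, Hz (default 15).
#' @return An object of class `plume_movie` with fields `frames`, `px_mm`,
#'   `fps`, `duration` (s), `domain` `c(downwind extent, lateral extent)`
#'   (mm), `source_xy` (source pixel center in movie coordinates `(x, d)`).
#' @export
plume_movie <- function(frames, px_mm = 0.74, fps = 15) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, px_mm > 0, fps > 0)
  if (any(frames < 0)) stop("concentrations must be >= 0")
  d <- dim(frames)
  structure(list(frames = frames, px_mm = px_mm, fps = fps,
                 duration = d[1] / fps,
                 domain = c(d[2] * px_mm, d[3] * px_mm),
                 source_xy = c(0, px_mm / 2)),
            class = "plume_movie")
}

#' @export
print.plume_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<plume_movie> %d frames @ %g Hz (%g s), %dx%d px (%.2f mm/px), %g x %g mm\n",
    d[1], x$fps, x$duration, d[2], d[3], x$px_mm, x$domain[1], x$domain[2]))
  invisible(x)
}

# Nearest-pixel, nearest-frame lookup. x: signed lateral mm (midline 0);
# d: downwind distance mm from source; t: seconds (frames loop). Returns 0
# outside the imaged grid. Vectorized over equal-length x, d, t.
plume_movie_lookup <- function(movie, x, d, t) {
  dm <- dim(movie$frames)
  nt <- dm[1]; ny <- dm[2]; nx <- dm[3]
  px <- movie$px_mm
  n <- max(length(x), length(d), length(t))
  it <- rep_len((floor(t * movie$fps + 1e-9) %% nt) + 1, n)
  iy <- rep_len(floor(d / px) + 1, n)
  ix <- rep_len(floor(x / px + nx / 2) + 1, n)
  out <- numeric(n)
  ok <- iy >= 1 & iy <= ny & ix >= 1 & ix <= nx
  if (any(ok))
    out[ok] <- movie$frames[cbind(it[ok], iy[ok], ix[ok])]
  out
}

#' Parameters of the synthetic plume generator
#'
#' A kinematic puff model of a turbulent boundary-layer plume: Gaussian
#' puffs are released from the source at a fixed rate, advect downwind at
#' the mean flow speed, widen linearly with travel distance, decay in
#' amplitude with an e-folding length, and ride a slowly meandering
#' centerline (an Ornstein-Uhlenbeck process sampled at release). The
#' result reproduces the qualitative structure of a measured boundary-layer
#' plume — a concentration maximum along the midline that decays
#' monotonically downwind, Gaussian time-averaged cross-sections that widen
#' with distance, and intermittent exposure at the plume edges — without
#' simulating the flow itself.
#'
#' @param mean_speed downwind advection speed, mm/s (default 100, the
#'   10 cm/s wind-tunnel flow).
#' @param puff_rate puff release rate, puffs/s.
#' @param initial_width Gaussian puff width (SD) at the source, mm.
#' @param spread_rate added width per mm of downwind travel (mm/mm).
#' @param meander_sigma stationary SD of the centerline meander, mm.
#' @param meander_tau meander correlation time, s.
#' @param decay_length e-folding length of puff amplitude, mm.
#' @param seed RNG seed; the movie is fully determined by it.
#' @return An object of class `plume_gen_params`.
#' @export
plume_gen_params <- function(mean_speed = 100, puff_rate = 8,
                             initial_width = 6, spread_rate = 0.08,
                             meander_sigma = 12, meander_tau = 3,
                             decay_length = 150, seed = 1) {
  p <- list(mean_speed = mean_speed, puff_rate = puff_rate,
            initial_width = initial_width, spread_rate = spread_rate,
            meander_sigma = meander_sigma, meander_tau = meander_tau,
            decay_length = decay_length, seed = seed)
  if (any(unlist(p[1:4]) <= 0) || meander_tau <= 0 || decay_length <= 0 ||
      meander_sigma < 0)
    stop("plume generator parameters must be positive")
  structure(p, class = "plume_gen_params")
}

#' Generate a synthetic plume movie
#'
#' Rasterizes the puff model of [plume_gen_params()] onto a pixel grid and
#' normalizes so that the time-mean concentration at the source pixel is 1.
#' Defaults match the geometry of the measured plume movie (0.74 mm/pixel,
#' 15 Hz, 240 s, 300 mm downwind by 160 mm lateral); coarser grids and
#' shorter durations give desk-scale movies with the same statistics.
#'
#' @param p a [plume_gen_params()].
#' @param px_mm pixel size, mm.
#' @param fps frame rate, Hz.
#' @param duration movie length, s.
#' @param domain `c(downwind extent, lateral extent)`, mm.
#' @return A [plume_movie()].
#' @export
make_synthetic_plume <- function(p = plume_gen_params(), px_mm = 0.74,
                                 fps = 15, duration = 240,
                                 domain = c(300, 160)) {
  stopifnot(inherits(p, "plume_gen_params"))
  ny <- round(domain[1] / px_mm)
  nx <- round(domain[2] / px_mm)
  nt <- round(duration * fps)
  if (ny < 4 || nx < 4 || nt < 2) stop("domain too small for the parameter set")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(p$seed)

  transit <- domain[1] / p$mean_speed
  # release times padded so the plume is developed at t = 0
  t_rel <- seq(-transit - 1, duration, by = 1 / p$puff_rate)
  # meander: OU process sampled at release times
  dtr <- 1 / p$puff_rate
  a <- exp(-dtr / p$meander_tau)
  innov <- stats::rnorm(length(t_rel), 0, p$meander_sigma * sqrt(1 - a^2))
  offs <- stats::filter(innov, a, method = "recursive")
  offs <- as.numeric(offs)

  dgrid <- (seq_len(ny) - 0.5) * px_mm
  xgrid <- (seq_len(nx) - 0.5) * px_mm - domain[2] / 2
  frames <- array(0, dim = c(nt, ny, nx))
  for (k in seq_len(nt)) {
    tk <- (k - 1) / fps
    d_puff <- p$mean_speed * (tk - t_rel)
    act <- which(d_puff > -3 * p$initial_width &
                 d_puff < domain[1] + 3 * p$initial_width)
    if (!length(act)) next
    f <- matrix(0, ny, nx)
    for (i in act) {
      d0 <- d_puff[i]
      w <- p$initial_width + p$spread_rate * max(d0, 0)
      # puff mass dilutes as the puff widens (2-d), on top of an
      # absorption/escape decay with e-folding decay_length
      amp <- exp(-max(d0, 0) / p$decay_length) * (p$initial_width / w)^2
      # meander offset grows from zero at the source
      cx <- offs[i] * min(1, max(d0, 0) / (domain[1] / 2))
      gy <- exp(-(dgrid - d0)^2 / (2 * w^2))
      gx <- exp(-(xgrid - cx)^2 / (2 * w^2))
      f <- f + amp * outer(gy, gx)
    }
    frames[k, , ] <- f
  }
  ix0 <- floor(nx / 2) + 1L  # pixel containing x = 0
  src_mean <- mean(frames[, 1, ix0])
  if (src_mean <= 0) stop("degenerate plume: no concentration at the source")
  frames <- frames / src_mean
  plume_movie(frames, px_mm = px_mm, fps = fps)
}

#' Intermittency map
#'
#' Fraction of time each pixel spends above a concentration threshold.
#' Within a plume, intermittency of exposure is low (concentration mostly
#' present) near the centerline and high at the edges.
#'
#' @param movie a [plume_movie()].
#' @param threshold concentration threshold (normalized units).
#' @return A matrix `(downwind pixel, lateral pixel)` of fractions in
#'   \[0, 1\].
#' @export
intermittency_map <- function(movie, threshold) {
  stopifnot(inherits(movie, "plume_movie"))
  apply(movie$frames > threshold, c(2, 3), mean)
}
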