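#' Stimulus specification
#'
#' Describes one of the odor waveforms delivered in the behavioral paradigm:
#' square pulses, linear off-ramps from a saturating plateau, rising/falling
#' frequency sweeps (raised sinusoids whose instantaneous frequency moves
#' linearly in time across `freq_range`), a "plume walk" placeholder, or a
#' blank (wind-only) trial.
#'
#' @param kind one of `"square_pulse"`, `"off_ramp"`, `"freq_sweep_up"`,
#'   `"freq_sweep_down"`, `"constant_zero"`.
#' @param concentration peak concentration, normalized so 1.0 is the highest
#'   delivered concentration (10% apple cider vinegar).
#' @param onset stimulus onset time, s.
#' @param duration for pulses, the pulse length; for off-ramps, the length of
#'   the saturating plateau before the ramp; for sweeps, the sweep length. s.
#' @param ramp_duration off-ramps only: time over which the concentration
#'   decreases linearly from `concentration` to 0, s.
#' @param freq_range sweeps only: two frequencies in Hz; the instantaneous
#'   frequency moves linearly from the lower to the upper value (ascending) or
#'   the reverse (descending). Must lie within the deliverable band
#'   \[0.05, 1.5\] Hz.
#' @param trial_length total trial length, s (default 70, as in the behavioral
#'   protocol).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("square_pulse", "off_ramp", "freq_sweep_up",
                                   "freq_sweep_down", "constant_zero"),
                          concentration = 1, onset = 10, duration = NULL,
                          ramp_duration = NULL, freq_range = c(0.1, 1),
                          trial_length = 70) {
  kind <- match.arg(kind)
  if (concentration < 0) stop("concentration must be >= 0")
  if (is.null(duration))
    duration <- if (kind %in% c("freq_sweep_up", "freq_sweep_down")) 40 else 10
  if (duration < 0) stop("duration must be >= 0")
  if (kind == "off_ramp") {
    if (is.null(ramp_duration) || ramp_duration <= 0)
      stop("off_ramp requires a positive ramp_duration")
    if (onset + duration + ramp_duration > trial_length)
      stop("onset + duration + ramp_duration exceeds trial_length")
  } else if (onset + duration > trial_length) {
    stop("onset + duration exceeds trial_length")
  }
  if (kind %in% c("freq_sweep_up", "freq_sweep_down")) {
    freq_range <- sort(as.numeric(freq_range))
    if (length(freq_range) != 2 || freq_range[1] < 0.05 || freq_range[2] > 1.5)
      stop("freq_range must lie within [0.05, 1.5] Hz")
  }
  structure(list(kind = kind, concentration = concentration, onset = onset,
                 duration = duration, ramp_duration = ramp_duration,
                 freq_range = freq_range, trial_length = trial_length),
            class = "stimulus_spec")
}

#' Generate a stimulus waveform
#'
#' Renders a [stimulus_spec()] onto a uniform time grid. Square pulses hold
#' `concentration` on `[onset, onset + duration)`; off-ramps hold the plateau
#' and then decrease linearly to zero over `ramp_duration`; sweeps are raised
#' sinusoids `c/2 * (1 - cos(2*pi*phase(t)))` whose instantaneous frequency is
#' linear in time across `freq_range`.
#'
#' @param spec a [stimulus_spec()].
#' @param sample_rate sampling rate, Hz (default 50, the tracking rate).
#' @return A [signal_trace()] of length `trial_length * sample_rate`.
#' @examples
#' tr <- make_stimulus(stimulus_spec("square_pulse"), sample_rate = 50)
#' range(tr$value)
#' @export
make_stimulus <- function(spec, sample_rate = 50) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- round(spec$trial_length * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  v <- numeric(n)
  cc <- spec$concentration
  on <- spec$onset
  du <- spec$duration
  switch(spec$kind,
    constant_zero = NULL,
    square_pulse = {
      v[t >= on & t < on + du] <- cc
    },
    off_ramp = {
      v[t >= on & t < on + du] <- cc
      rd <- spec$ramp_duration
      i <- t >= on + du & t < on + du + rd
      v[i] <- cc * (1 - (t[i] - on - du) / rd)
    },
    freq_sweep_up = ,
    freq_sweep_down = {
      f <- spec$freq_range
      if (spec$kind == "freq_sweep_down") f <- rev(f)
      i <- t >= on & t < on + du
      tau <- t[i] - on
      # phase(tau) = integral of instantaneous frequency f0 + (f1-f0)*tau/T
      phase <- f[1] * tau + (f[2] - f[1]) * tau^2 / (2 * du)
      v[i] <- cc / 2 * (1 - cos(2 * pi * phase))
    },
    stop("unknown stimulus kind: ", spec$kind)
  )
  signal_trace(v, sample_rate = sample_rate)
}

#' Advection model for odor transport down the arena
#'
#' Transport of the odor front by laminar airflow: a pure delay of
#' `distance / wind_speed`, optionally followed by Gaussian smoothing that
#' emulates diffusive widening of concentration peaks with distance downwind.
#'
#' @param wind_speed airflow speed, mm/s (default 119, i.e. 11.9 cm/s as
#'   measured by anemometer in the arena).
#' @param diffusion_widening Gaussian kernel width in seconds per cm of
#'   travel; 0 (default) gives ideal, delay-only transport.
#' @return An object of class `advection_model`.
#' @export
advection_model <- function(wind_speed = 119, diffusion_widening = 0) {
  stopifnot(wind_speed > 0, diffusion_widening >= 0)
  structure(list(wind_speed = wind_speed,
                 diffusion_widening = diffusion_widening),
            class = "advection_model")
}

#' Advect a stimulus downwind
#'
#' Delays a waveform by `distance_downwind / wind_speed` (sub-sample delays by
#' linear interpolation onto the original grid; the trace is zero before its
#' delayed start). With positive `diffusion_widening` the delayed trace is
#' additionally smoothed by a Gaussian kernel whose width grows linearly with
#' distance.
#'
#' @param trace a [signal_trace()].
#' @param distance_downwind distance from the odor inlet, mm (>= 0).
#' @param model an [advection_model()].
#' @return A [signal_trace()] on the same time grid.
#' @export
advect <- function(trace, distance_downwind, model = advection_model()) {
  stopifnot(is_signal_trace(trace), inherits(model, "advection_model"))
  if (distance_downwind < 0) stop("distance_downwind must be >= 0")
  delay <- distance_downwind / model$wind_speed
  if (delay == 0 && model$diffusion_widening == 0) return(trace)
  v <- stats::approx(trace$t, trace$value, xout = trace$t - delay,
                     yleft = 0, yright = trace$value[length(trace$value)])$y
  if (model$diffusion_widening > 0) {
    sigma_s <- model$diffusion_widening * distance_downwind / 10
    v <- gaussian_smooth(v, sigma_s * trace$sample_rate)
  }
  signal_trace(pmax(v, 0), sample_rate = trace$sample_rate, t0 = trace$t[1])
}

# Zero-phase Gaussian smoothing with a kernel of standard deviation
# `sigma_samples` (in samples); zero-padded at the edges.
gaussian_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_samples))
  k <- stats::dnorm(seq(-half, half), sd = sigma_samples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(numeric(half), x, numeric(half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Extract a "plume walk" stimulus from a plume movie
#'
#' Samples the concentration along a straight upwind transect through a plume
#' movie at walking pace: one sample per movie frame at a point that starts
#' `start_downwind` mm from the source and `start_lateral` mm from the
#' midline, and moves toward the source at `speed`. Sampling stops when the
#' point reaches the source plane. Defaults reproduce the open-loop stimulus
#' used in the behavioral experiments (8.9 cm lateral, 30 cm downwind,
#' 6 mm/s — the average ground speed of walking flies). The movie is looped if
#' the walk outlasts it; points laterally outside the imaged grid read 0.
#'
#' @param movie a [plume_movie()].
#' @param start_lateral signed lateral start position, mm from the midline.
#' @param start_downwind start distance downwind from the source, mm; must lie
#'   within the movie's downwind extent.
#' @param speed walking speed toward the source, mm/s.
#' @return A [signal_trace()] sampled at the movie frame rate.
#' @export
extract_plume_walk <- function(movie, start_lateral = 89,
                               start_downwind = 300, speed = 6) {
  stopifnot(inherits(movie, "plume_movie"), speed > 0)
  L <- movie$domain[1]
  if (start_downwind < 0 || start_downwind > L)
    stop("start_downwind outside the movie domain [0, ", L, "] mm")
  fps <- movie$fps
  n <- floor(start_downwind / speed * fps)
  k <- seq_len(n) - 1
  d <- start_downwind - speed * k / fps
  v <- plume_movie_lookup(movie, x = rep(start_lateral, n), d = d,
                          t = k / fps)
  signal_trace(v, sample_rate = fps)
}
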