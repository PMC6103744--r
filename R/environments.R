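#' Navigation environment
#'
#' A queryable space-time odor concentration field with optional wind.
#' Coordinates follow the trajectory convention: `x` lateral, `y` increasing
#' upwind; with wind present, the upwind direction is `+y` (heading 90 deg).
#' The concentration query returns 0 outside the data domain.
#'
#' @param conc_fn function `(x, y, t)` vectorized over positions, returning
#'   normalized concentration (>= 0).
#' @param bounds domain `c(xmin, xmax, ymin, ymax)`, mm.
#' @param duration trial duration, s.
#' @param wind `TRUE` if a directional airflow is present.
#' @param upwind_dir heading of the upwind direction, deg (default 90).
#' @param source_xy odor source position `c(x, y)` mm, if any.
#' @param kind short label.
#' @return An object of class `nav_environment`.
#' @export
nav_environment <- function(conc_fn, bounds, duration, wind = TRUE,
                            upwind_dir = 90, source_xy = NULL,
                            kind = "custom") {
  stopifnot(is.function(conc_fn), length(bounds) == 4, duration > 0)
  structure(list(conc = conc_fn, bounds = bounds, duration = duration,
                 wind = wind, upwind_dir = upwind_dir,
                 source_xy = source_xy, kind = kind),
            class = "nav_environment")
}

#' @export
print.nav_environment <- function(x, ...) {
  cat(sprintf("<nav_environment> %s, bounds [%g,%g]x[%g,%g] mm, %g s, wind=%s\n",
              x$kind, x$bounds[1], x$bounds[2], x$bounds[3], x$bounds[4],
              x$duration, x$wind))
  invisible(x)
}

#' Concentration query
#'
#' @param env a [nav_environment()].
#' @param x,y positions, mm.
#' @param t time, s.
#' @return Normalized concentrations (0 outside the data domain).
#' @export
env_concentration <- function(env, x, y, t) {
  stopifnot(inherits(env, "nav_environment"))
  env$conc(x, y, t)
}

#' Arena environment driven by an inlet stimulus
#'
#' The commanded stimulus waveform enters at the upwind end of the arena
#' (`y = ymax`) and advects downwind, so the concentration at height `y` is
#' the inlet waveform delayed by `(ymax - y)/wind_speed`, uniform across the
#' arena width.
#'
#' @param stim a [stimulus_spec()] or [signal_trace()].
#' @param adv an [advection_model()].
#' @param bounds arena bounds, mm (default the 14 x 4 cm chamber).
#' @param sample_rate rate at which the inlet waveform is rendered, Hz.
#' @return A [nav_environment()].
#' @export
make_arena_env <- function(stim, adv = advection_model(),
                           bounds = c(0, 40, 0, 140), sample_rate = 50) {
  trace <- if (inherits(stim, "stimulus_spec"))
    make_stimulus(stim, sample_rate) else stim
  stopifnot(is_signal_trace(trace))
  v <- trace$value
  sr <- trace$sample_rate
  nmax <- length(v)
  ytop <- bounds[4]
  ws <- adv$wind_speed
  conc_fn <- function(x, y, t) {
    tt <- t - (ytop - y) / ws
    idx <- floor(tt * sr + 1e-9) + 1
    out <- numeric(length(idx))
    ok <- idx >= 1 & idx <= nmax
    out[ok] <- v[idx[ok]]
    out
  }
  env <- nav_environment(conc_fn, bounds = bounds,
                         duration = nmax / sr, wind = TRUE,
                         source_xy = c(mean(bounds[1:2]), ytop),
                         kind = "arena")
  env$stimulus <- if (inherits(stim, "stimulus_spec")) stim else NULL
  env
}

#' Environment backed by a plume movie
#'
#' Nearest-pixel, nearest-frame lookup into a space-time concentration
#' movie. The source sits at the upwind end (`x = 0`, `y = ymax`); the
#' movie's downwind distance axis maps to `ymax - y`. The movie is looped
#' when the trial outlasts it; the concentration is 0 outside the imaged
#' area.
#'
#' @param movie a [plume_movie()].
#' @param duration trial duration, s (default 180, i.e. a 3-minute trial).
#' @return A [nav_environment()].
#' @export
plume_env <- function(movie, duration = 180) {
  stopifnot(inherits(movie, "plume_movie"))
  L <- movie$domain[1]; W <- movie$domain[2]
  conc_fn <- function(x, y, t) {
    plume_movie_lookup(movie, x = x, d = L - y, t = t)
  }
  nav_environment(conc_fn, bounds = c(-W / 2, W / 2, 0, L),
                  duration = duration, wind = TRUE,
                  source_xy = c(0, L), kind = "plume")
}

#' Windless Gaussian odor gradient environment
#'
#' A static, radially symmetric Gaussian concentration profile with no
#' airflow, used to probe navigation when only odor dynamics (no wind
#' direction cue) are available.
#'
#' @param center_xy gradient peak position `c(x, y)`, mm.
#' @param spatial_sigma Gaussian width, mm.
#' @param peak peak normalized concentration (> 0).
#' @param bounds domain, mm.
#' @param duration trial duration, s.
#' @return A [nav_environment()] with `wind = FALSE`.
#' @export
gradient_env <- function(center_xy = c(0, 250), spatial_sigma = 40,
                         peak = 1, bounds = c(-80, 80, 0, 300),
                         duration = 180) {
  stopifnot(peak > 0, spatial_sigma > 0)
  conc_fn <- function(x, y, t) {
    peak * exp(-((x - center_xy[1])^2 + (y - center_xy[2])^2) /
                 (2 * spatial_sigma^2))
  }
  nav_environment(conc_fn, bounds = bounds, duration = duration,
                  wind = FALSE, source_xy = center_xy, kind = "gradient")
}
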