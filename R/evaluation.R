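#' Source-finding success rate
#'
#' A trial is a success if the agent comes within `radius` mm of the odor
#' source at any time during the trial (boundary inclusive). The standard
#' error is the binomial `sqrt(p*(1-p)/n)`.
#'
#' @param trials a `nav_ensemble` or a list of [trajectory()] objects.
#' @param source_xy source position `c(x, y)` mm; defaults to the
#'   ensemble's environment source.
#' @param radius success radius, mm (default 20, i.e. 2 cm).
#' @param label optional label.
#' @return An object of class `proportion_stats`: list with `successes`,
#'   `n`, `p`, `se`, `label`.
#' @export
success_rate <- function(trials, source_xy = NULL, radius = 20,
                         label = NULL) {
  if (inherits(trials, "nav_ensemble")) {
    if (is.null(source_xy)) source_xy <- trials$env_info$source_xy
    if (is.null(source_xy)) stop("no source position available")
    n <- if (is.null(trials$x)) 0L else ncol(trials$x)
    if (n == 0) stop("success rate undefined for an empty ensemble")
    d2 <- (trials$x - source_xy[1])^2 + (trials$y - source_xy[2])^2
    hit <- apply(d2, 2, min) <= radius^2
  } else {
    if (is.null(source_xy)) stop("source_xy required for trajectory lists")
    n <- length(trials)
    if (n == 0) stop("success rate undefined for zero trials")
    hit <- vapply(trials, function(tr) {
      min((tr$x - source_xy[1])^2 + (tr$y - source_xy[2])^2) <= radius^2
    }, logical(1))
  }
  s <- sum(hit)
  p <- s / n
  structure(list(successes = s, n = n, p = p, se = sqrt(p * (1 - p) / n),
                 label = label),
            class = "proportion_stats")
}

#' @export
print.proportion_stats <- function(x, ...) {
  cat(sprintf("<proportion_stats>%s %d/%d = %.3f (SE %.4f)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$successes, x$n, x$p, x$se))
  invisible(x)
}

#' Compare two success proportions
#'
#' Two-proportion z test with pooled standard error:
#' `z = (p1 - p2) / sqrt(p*(1-p)*(1/n1 + 1/n2))` where `p` pools both
#' samples; the p-value is two-sided from the standard normal distribution.
#'
#' @param a,b [success_rate()] results (`proportion_stats`).
#' @return A list with `z` and `p_value`.
#' @export
compare_proportions <- function(a, b) {
  stopifnot(inherits(a, "proportion_stats"), inherits(b, "proportion_stats"))
  if (a$n == 0 || b$n == 0) stop("cannot compare empty samples")
  pp <- (a$successes + b$successes) / (a$n + b$n)
  denom <- sqrt(pp * (1 - pp) * (1 / a$n + 1 / b$n))
  z <- if (denom == 0) 0 else (a$p - b$p) / denom
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

# Shared binning helper: map ensemble samples onto a spatial grid.
ensemble_bins <- function(ens, bin_mm) {
  b <- ens$env_info$bounds
  nx <- max(1L, ceiling((b[2] - b[1]) / bin_mm))
  ny <- max(1L, ceiling((b[4] - b[3]) / bin_mm))
  ix <- pmin(nx, pmax(1L, floor((as.numeric(ens$x) - b[1]) / bin_mm) + 1L))
  iy <- pmin(ny, pmax(1L, floor((as.numeric(ens$y) - b[3]) / bin_mm) + 1L))
  list(ix = ix, iy = iy, nx = nx, ny = ny,
       cell = (ix - 1L) * ny + iy)
}

#' Mean ON and OFF response strength by position
#'
#' Averages the agents' instantaneous ON and OFF function values in spatial
#' bins, showing where in an odor environment each response is engaged
#' (ON throughout the plume, strongest near the centerline; OFF at the
#' plume edges where the odor envelope is lost).
#'
#' @param ens a `nav_ensemble` run with `store_states = TRUE`.
#' @param bin_mm spatial bin size, mm (default 10).
#' @return A list with matrices `on` and `off` (rows = y bins, cols = x
#'   bins, `NA` where unvisited), `counts`, and bin centers `x_mid`,
#'   `y_mid`.
#' @export
spatial_on_off_maps <- function(ens, bin_mm = 10) {
  stopifnot(inherits(ens, "nav_ensemble"))
  if (is.null(ens$on)) stop("ensemble was run without store_states")
  bb <- ensemble_bins(ens, bin_mm)
  ncell <- bb$nx * bb$ny
  cnt <- tabulate(bb$cell, ncell)
  on_sum <- rowsum(as.numeric(ens$on), bb$cell)
  off_sum <- rowsum(as.numeric(ens$off), bb$cell)
  on_m <- off_m <- rep(NA_real_, ncell)
  cells <- as.integer(rownames(on_sum))
  on_m[cells] <- on_sum[, 1] / cnt[cells]
  off_m[cells] <- off_sum[, 1] / cnt[cells]
  b <- ens$env_info$bounds
  list(on = matrix(on_m, bb$ny, bb$nx), off = matrix(off_m, bb$ny, bb$nx),
       counts = matrix(cnt, bb$ny, bb$nx),
       x_mid = b[1] + (seq_len(bb$nx) - 0.5) * bin_mm,
       y_mid = b[3] + (seq_len(bb$ny) - 0.5) * bin_mm)
}

#' Occupancy density map
#'
#' Proportion of total agent time spent in each spatial bin, optionally on
#' a log10 scale with empty bins floored at one sample (avoiding -Inf).
#'
#' @param ens a `nav_ensemble`.
#' @param bin_mm spatial bin size, mm.
#' @param log_scale if `TRUE`, return `log10` proportions.
#' @return A list with `density` (rows = y bins, cols = x bins),
#'   `x_mid`, `y_mid`.
#' @export
occupancy_map <- function(ens, bin_mm = 10, log_scale = FALSE) {
  stopifnot(inherits(ens, "nav_ensemble"))
  bb <- ensemble_bins(ens, bin_mm)
  cnt <- tabulate(bb$cell, bb$nx * bb$ny)
  total <- sum(cnt)
  dens <- if (log_scale) log10(pmax(cnt, 1) / total) else cnt / total
  b <- ens$env_info$bounds
  list(density = matrix(dens, bb$ny, bb$nx),
       x_mid = b[1] + (seq_len(bb$nx) - 0.5) * bin_mm,
       y_mid = b[3] + (seq_len(bb$ny) - 0.5) * bin_mm)
}

#' Parameter sweep of source-finding performance
#'
#' Runs a seeded ensemble for every cell of a 1- or 2-axis grid over
#' navigation-model gains and records the success proportion. Supported
#' axes: `on_scale`, `off_scale`, `kappa7`, and `wind_gain` (a common
#' multiplier on `kappa5` and `kappa6`).
#'
#' @param env a [nav_environment()].
#' @param base a [nav_params()] used for all non-swept parameters.
#' @param axis1,axis2 lists `list(param = <name>, values = <numeric>)`;
#'   `axis2` may be `NULL` for a 1-d sweep.
#' @param n_per_cell trials per grid cell.
#' @param seed base seed; cell `i` uses `seed + i` so cells are
#'   individually reproducible.
#' @param radius success radius, mm.
#' @param duration trial length, s (default `env$duration`).
#' @return An object of class `sweep_grid`: list with `axis1`, `axis2`,
#'   `success` (matrix `length(values1) x length(values2)`), `se`,
#'   `n_per_cell`.
#' @export
sweep_scales <- function(env, base = nav_params(), axis1, axis2 = NULL,
                         n_per_cell = 100, seed = 1, radius = 20,
                         duration = NULL) {
  apply_axis <- function(p, param, value) {
    switch(param,
      on_scale = { p$on_scale <- value; p },
      off_scale = { p$off_scale <- value; p },
      kappa7 = { p$kappa7 <- value; p },
      wind_gain = { p$kappa5 <- p$kappa5 * value
                    p$kappa6 <- p$kappa6 * value; p },
      stop("unsupported sweep axis: ", param))
  }
  v1 <- axis1$values
  v2 <- if (is.null(axis2)) NA else axis2$values
  succ <- se <- matrix(NA_real_, length(v1), length(v2))
  cell <- 0L
  for (j in seq_along(v2)) for (i in seq_along(v1)) {
    cell <- cell + 1L
    p <- apply_axis(base, axis1$param, v1[i])
    if (!is.null(axis2)) p <- apply_axis(p, axis2$param, v2[j])
    ens <- run_ensemble(env, p, n_trials = n_per_cell, seed = seed + cell,
                        duration = duration, store_states = FALSE)
    sr <- success_rate(ens, radius = radius)
    succ[i, j] <- sr$p
    se[i, j] <- sr$se
  }
  structure(list(axis1 = axis1, axis2 = axis2, success = succ, se = se,
                 n_per_cell = n_per_cell, seed = seed),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("<sweep_grid> %s%s, %d trials/cell\n", x$axis1$param,
              if (is.null(x$axis2)) "" else paste0(" x ", x$axis2$param),
              x$n_per_cell))
  print(round(x$success, 3))
  invisible(x)
}
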