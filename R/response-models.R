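#' Parameters of the ON/OFF odor-response models
#'
#' Four phenomenological model variants map a normalized odor concentration
#' time series onto a behavioral drive. The stages are adaptive Hill
#' compression (a saturating nonlinearity whose half-maximum point is shifted
#' rightward by a slowly integrated odor history) and linear filtering: a
#' single low-pass for the ON channel, or the rectified difference of a slow
#' and a fast low-pass for the OFF channel. Variants differ in stage order and
#' in whether adaptation is present:
#' \describe{
#'   \item{ACF}{adaptive compression, then filtering}
#'   \item{FAC}{filtering, then adaptive compression}
#'   \item{CF}{static compression, then filtering}
#'   \item{FC}{filtering, then static compression}
#' }
#'
#' @param variant one of `"ACF"`, `"FAC"`, `"CF"`, `"FC"`.
#' @param channel `"ON"` or `"OFF"`.
#' @param kd baseline Hill dissociation constant, in normalized concentration
#'   units (default 0.01, from dose-response fits to square pulses).
#' @param tau_a adaptation time constant, s (adaptive variants only).
#' @param tau_on ON low-pass time constant, s (ON channel only).
#' @param tau_off1,tau_off2 fast and slow time constants of the OFF
#'   differential filter, s; requires `tau_off1 < tau_off2`.
#' @param scale output gain mapping the model output to behavioral units
#'   (mm/s of upwind velocity for ON, turn probability for OFF).
#' @param dt Euler integration step, s (default 0.02).
#' @return An object of class `response_params`.
#' @seealso [run_response_model()], [response_param_table()]
#' @export
response_params <- function(variant = c("ACF", "FAC", "CF", "FC"),
                            channel = c("ON", "OFF"),
                            kd = 0.01, tau_a = NULL, tau_on = NULL,
                            tau_off1 = NULL, tau_off2 = NULL,
                            scale = 1, dt = 0.02) {
  variant <- match.arg(variant)
  channel <- match.arg(channel)
  adaptive <- variant %in% c("ACF", "FAC")
  if (kd <= 0) stop("kd must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (adaptive) {
    if (is.null(tau_a) || tau_a <= 0) stop(variant, " requires tau_a > 0")
  } else {
    tau_a <- NULL
  }
  if (channel == "ON") {
    if (is.null(tau_on) || tau_on <= 0) stop("ON channel requires tau_on > 0")
    tau_off1 <- tau_off2 <- NULL
  } else {
    if (is.null(tau_off1) || is.null(tau_off2) ||
        tau_off1 <= 0 || tau_off2 <= 0)
      stop("OFF channel requires tau_off1 > 0 and tau_off2 > 0")
    if (tau_off1 >= tau_off2)
      stop("tau_off1 (fast) must be smaller than tau_off2 (slow)")
    tau_on <- NULL
  }
  structure(list(variant = variant, channel = channel, kd = kd,
                 tau_a = tau_a, tau_on = tau_on, tau_off1 = tau_off1,
                 tau_off2 = tau_off2, scale = scale, dt = dt),
            class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  taus <- if (x$channel == "ON") sprintf("tau_on=%g", x$tau_on) else
    sprintf("tau_off1=%g tau_off2=%g", x$tau_off1, x$tau_off2)
  if (!is.null(x$tau_a)) taus <- paste(taus, sprintf("tau_a=%g", x$tau_a))
  cat(sprintf("<response_params> %s %s: kd=%g %s scale=%g dt=%g\n",
              x$variant, x$channel, x$kd, taus, x$scale, x$dt))
  invisible(x)
}

#' Reference fitted parameter sets for the ON/OFF models
#'
#' The parameter values obtained by nonlinear regression of each model
#' variant against the mean behavioral responses (upwind velocity for ON,
#' turn probability for OFF) to square pulses, off-ramps and frequency
#' sweeps. The ACF rows are the parameter sets used by the navigation model.
#'
#' @return A data frame with one row per (variant, channel) pair and columns
#'   `variant`, `channel`, `tau_on`, `tau_off1`, `tau_off2`, `tau_a`,
#'   `scale`, `rmse`, `pearson_r`.
#' @export
response_param_table <- function() {
  data.frame(
    variant  = rep(c("FAC", "ACF", "FC", "CF"), 2),
    channel  = rep(c("ON", "OFF"), each = 4),
    tau_on   = c(0.34, 0.72, 0.04, 0.30, NA, NA, NA, NA),
    tau_off1 = c(NA, NA, NA, NA, 0.76, 0.62, 0.58, 0.06),
    tau_off2 = c(NA, NA, NA, NA, 3.96, 4.84, 3.00, 5.02),
    tau_a    = c(20.36, 9.8, NA, NA, 16.7, 10.08, NA, NA),
    scale    = c(5.9, 7.3, 4.4, 4.5, 0.3, 0.6, 0.1, 0.3),
    rmse     = c(1.5784, 1.4122, 1.747, 1.7058,
                 0.0345, 0.0336, 0.0409, 0.0389),
    pearson_r = c(0.89, 0.92, 0.85, 0.86, 0.75, 0.77, 0.62, 0.69)
  )
}

#' Build a [response_params()] object from the reference table
#'
#' @param variant,channel model variant and channel, as in [response_params()].
#' @param dt Euler step, s.
#' @return A [response_params()] with the fitted reference values.
#' @export
reference_response_params <- function(variant = "ACF", channel = "ON",
                                      dt = 0.02) {
  tab <- response_param_table()
  row <- tab[tab$variant == variant & tab$channel == channel, ]
  if (nrow(row) != 1) stop("unknown variant/channel combination")
  response_params(variant = variant, channel = channel,
                  tau_a = if (is.na(row$tau_a)) NULL else row$tau_a,
                  tau_on = if (is.na(row$tau_on)) NULL else row$tau_on,
                  tau_off1 = if (is.na(row$tau_off1)) NULL else row$tau_off1,
                  tau_off2 = if (is.na(row$tau_off2)) NULL else row$tau_off2,
                  scale = row$scale, dt = dt)
}

#' First-order Euler low-pass filter
#'
#' Integrates `tau * dy/dt = x - y` by forward Euler from `y = 0`:
#' `y[i] = y[i-1] + (dt/tau) * (x[i-1] - y[i-1])`.
#'
#' @param x input samples ([signal_trace()] or numeric vector).
#' @param tau time constant, s (> 0).
#' @param dt integration step, s.
#' @return Numeric vector of filtered samples.
#' @export
lowpass <- function(x, tau, dt = 0.02) {
  if (tau <= 0) stop("tau must be > 0")
  x <- trace_values(x)
  a <- dt / tau
  n <- length(x)
  u <- a * c(0, x[-n])
  as.numeric(stats::filter(u, 1 - a, method = "recursive"))
}

#' Adaptive Hill compression
#'
#' The adaptation state integrates the odor history,
#' `tau_a * dA/dt = odor - A`, and shifts the Hill half-maximum point:
#' `C = odor / (odor + kd + A)`. Both computed per sample by forward Euler
#' from zero initial state.
#'
#' @param stim odor input ([signal_trace()] or numeric, values >= 0).
#' @param kd baseline dissociation constant (> 0).
#' @param tau_a adaptation time constant, s (> 0).
#' @param dt Euler step, s.
#' @return A list with numeric vectors `A` and `C`.
#' @export
adaptive_compress <- function(stim, kd = 0.01, tau_a = 9.8, dt = 0.02) {
  if (kd <= 0) stop("kd must be > 0")
  if (tau_a <= 0) stop("tau_a must be > 0")
  odor <- trace_values(stim)
  A <- lowpass(odor, tau_a, dt)
  list(A = A, C = odor / (odor + kd + A))
}

#' Static Hill compression
#'
#' Memoryless Hill nonlinearity with exponent 1: `C = odor / (odor + kd)`.
#'
#' @inheritParams adaptive_compress
#' @return Numeric vector of compressed samples.
#' @export
static_compress <- function(stim, kd = 0.01) {
  if (kd <= 0) stop("kd must be > 0")
  odor <- trace_values(stim)
  odor / (odor + kd)
}

#' OFF differential filter
#'
#' Two parallel Euler low-passes with a fast and a slow time constant; the
#' OFF drive is the rectified difference `max(0, R2 - R1)`, which responds
#' to decreases of the input from a previously higher level.
#'
#' @param C input samples (typically compressed odor).
#' @param tau_fast,tau_slow filter time constants, s; `tau_fast < tau_slow`.
#' @param dt Euler step, s.
#' @return A list with numeric vectors `R1` (fast), `R2` (slow), `OFF`.
#' @export
off_filter <- function(C, tau_fast, tau_slow, dt = 0.02) {
  if (tau_fast >= tau_slow) stop("tau_fast must be smaller than tau_slow")
  R1 <- lowpass(C, tau_fast, dt)
  R2 <- lowpass(C, tau_slow, dt)
  list(R1 = R1, R2 = R2, OFF = pmax(0, R2 - R1))
}

#' Run an ON/OFF response model on a stimulus
#'
#' Composes compression and filtering in the order given by the model
#' variant. The returned `output` is the unscaled model drive (ON in
#' \[0, 1), OFF >= 0); multiplication by the output gain belongs to
#' prediction (see [predict_behavior()]).
#'
#' For the filter-first variants (FAC, FC) the filter is applied to the raw
#' odor; in FAC the adaptation state is likewise driven by the raw odor, so
#' that adaptation tracks the stimulus in both stage orders.
#'
#' @param stim odor stimulus, a [signal_trace()] (values >= 0). The Euler
#'   step is taken from the stimulus grid and must match `params$dt`.
#' @param params a [response_params()].
#' @return An object of class `model_state_trace`: a list with `t`, `odor`,
#'   `A`, `C`, `R1`, `R2`, `output`, `sample_rate`, `params`. Absent states
#'   (e.g. `A` for non-adaptive variants) are `NULL`.
#' @examples
#' stim <- make_stimulus(stimulus_spec("square_pulse"), sample_rate = 50)
#' on <- run_response_model(stim, reference_response_params("ACF", "ON"))
#' max(on$output)
#' @export
run_response_model <- function(stim, params) {
  stopifnot(is_signal_trace(stim), inherits(params, "response_params"))
  dt <- 1 / stim$sample_rate
  if (abs(dt - params$dt) > 1e-9)
    stop("stimulus sample rate does not match params$dt")
  odor <- stim$value
  if (any(odor < 0)) stop("odor values must be >= 0")
  p <- params
  A <- C <- R1 <- R2 <- NULL
  if (p$channel == "ON") {
    if (p$variant == "ACF") {
      ac <- adaptive_compress(odor, p$kd, p$tau_a, dt); A <- ac$A; C <- ac$C
      output <- lowpass(C, p$tau_on, dt)
    } else if (p$variant == "CF") {
      C <- static_compress(odor, p$kd)
      output <- lowpass(C, p$tau_on, dt)
    } else if (p$variant == "FC") {
      f <- lowpass(odor, p$tau_on, dt)
      C <- output <- static_compress(f, p$kd)
    } else { # FAC
      f <- lowpass(odor, p$tau_on, dt)
      A <- lowpass(odor, p$tau_a, dt)
      C <- output <- f / (f + p$kd + A)
    }
  } else {
    if (p$variant == "ACF") {
      ac <- adaptive_compress(odor, p$kd, p$tau_a, dt); A <- ac$A; C <- ac$C
      ff <- off_filter(C, p$tau_off1, p$tau_off2, dt)
      R1 <- ff$R1; R2 <- ff$R2; output <- ff$OFF
    } else if (p$variant == "CF") {
      C <- static_compress(odor, p$kd)
      ff <- off_filter(C, p$tau_off1, p$tau_off2, dt)
      R1 <- ff$R1; R2 <- ff$R2; output <- ff$OFF
    } else if (p$variant == "FC") {
      ff <- off_filter(odor, p$tau_off1, p$tau_off2, dt)
      R1 <- ff$R1; R2 <- ff$R2
      C <- output <- static_compress(ff$OFF, p$kd)
    } else { # FAC
      ff <- off_filter(odor, p$tau_off1, p$tau_off2, dt)
      R1 <- ff$R1; R2 <- ff$R2
      A <- lowpass(odor, p$tau_a, dt)
      C <- output <- ff$OFF / (ff$OFF + p$kd + A)
    }
  }
  structure(list(t = stim$t, odor = odor, A = A, C = C, R1 = R1, R2 = R2,
                 output = output, sample_rate = stim$sample_rate,
                 params = params),
            class = "model_state_trace")
}

#' @export
print.model_state_trace <- function(x, ...) {
  cat(sprintf("<model_state_trace> %s %s, %d samples @ %g Hz, output range [%g, %g]\n",
              x$params$variant, x$params$channel, length(x$output),
              x$sample_rate, min(x$output), max(x$output)))
  invisible(x)
}

#' @export
as.data.frame.model_state_trace <- function(x, ...) {
  d <- data.frame(t = x$t, odor = x$odor)
  for (nm in c("A", "C", "R1", "R2")) if (!is.null(x[[nm]])) d[[nm]] <- x[[nm]]
  d$output <- x$output
  d
}
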