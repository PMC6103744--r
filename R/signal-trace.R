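#' Uniformly sampled signal trace
#'
#' A `signal_trace` holds a uniformly sampled time series, typically a
#' normalized odor concentration (1.0 corresponds to the highest delivered
#' concentration, 10% apple cider vinegar) or a model state variable.
#'
#' @param value numeric vector of samples (must be finite).
#' @param sample_rate sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `signal_trace`: a list with elements `t`
#'   (seconds), `value`, and `sample_rate` (Hz).
#' @examples
#' tr <- signal_trace(rep(0, 100), sample_rate = 50)
#' length(tr$t)
#' @export
signal_trace <- function(value, sample_rate, t0 = 0) {
  stopifnot(is.numeric(value), length(value) >= 1,
            is.numeric(sample_rate), sample_rate > 0)
  if (any(!is.finite(value))) stop("signal_trace values must be finite")
  structure(list(
    t = t0 + (seq_along(value) - 1) / sample_rate,
    value = as.numeric(value),
    sample_rate = sample_rate
  ), class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz, t = [%g, %g] s, range [%g, %g]\n",
              length(x$value), x$sample_rate, x$t[1], x$t[length(x$t)],
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.signal_trace <- function(x, ...) {
  data.frame(t_s = x$t, concentration_norm = x$value)
}

#' @export
length.signal_trace <- function(x) length(x$value)

is_signal_trace <- function(x) inherits(x, "signal_trace")

# Coerce a signal_trace or bare numeric vector to numeric samples.
trace_values <- function(x) {
  if (is_signal_trace(x)) x$value else as.numeric(x)
}

#' Read and write signal traces as two-column CSV
#'
#' Traces are serialized as `t_s, concentration_norm`. The time grid must be
#' uniform; the sample rate is recovered from the median time step.
#'
#' @param trace a [signal_trace()].
#' @param path file path.
#' @return `write_signal_trace` returns `path` invisibly; `read_signal_trace`
#'   returns a [signal_trace()].
#' @export
write_signal_trace <- function(trace, path) {
  stopifnot(is_signal_trace(trace))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_trace
#' @export
read_signal_trace <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t_s", "concentration_norm") %in% names(d)))
    stop("expected columns t_s and concentration_norm")
  dt <- diff(d$t_s)
  if (length(dt) < 1 || diff(range(dt)) > 1e-6)
    stop("time grid in ", path, " is not uniform")
  signal_trace(d$concentration_norm, sample_rate = 1 / stats::median(dt),
               t0 = d$t_s[1])
}
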