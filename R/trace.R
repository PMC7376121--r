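#' Construct a pulse-EPR time trace
#'
#' Container for a sampled DEER or ESEEM signal: a uniform, strictly
#' increasing time axis, a real channel, an optional imaginary channel and
#' acquisition metadata.  DEER traces use microseconds, ESEEM traces
#' nanoseconds; the unit travels with the object so downstream code never
#' guesses.
#'
#' @param t Time axis (us for DEER, ns for ESEEM), strictly increasing and
#'   uniformly sampled (relative tolerance 1e-6).
#' @param real Real signal channel, finite, same length as `t`.
#' @param imag Optional imaginary channel, same length.
#' @param unit `"us"` or `"ns"`.
#' @param meta Named list of acquisition metadata.  Recognized keys:
#'   `freq_GHz` (spectrometer frequency), `g_value`, `tau_ns` (first
#'   interpulse delay, ESEEM), `label`.
#' @return An object of class `epr_trace`.
#' @examples
#' tr <- time_trace(seq(0, 2, by = 0.01), exp(-seq(0, 2, by = 0.01)))
#' @export
time_trace <- function(t, real, imag = NULL, unit = c("us", "ns"),
                       meta = list()) {
  unit <- match.arg(unit)
  t <- as.numeric(t); real <- as.numeric(real)
  if (length(t) < 2) stop("time trace needs at least 2 points")
  if (length(real) != length(t)) stop("`real` and `t` lengths differ")
  if (any(!is.finite(t))) stop("non-finite time values")
  if (any(diff(t) <= 0)) stop("time axis must be strictly increasing")
  if (!is_uniform(t)) stop("time axis must be uniformly sampled")
  if (any(!is.finite(real))) stop("non-finite values in real channel")
  if (!is.null(imag)) {
    imag <- as.numeric(imag)
    if (length(imag) != length(t)) stop("`imag` and `t` lengths differ")
    if (any(!is.finite(imag))) stop("non-finite values in imaginary channel")
  }
  stopifnot(is.list(meta))
  structure(list(t = t, real = real, imag = imag, unit = unit, meta = meta),
            class = "epr_trace")
}

#' @export
print.epr_trace <- function(x, ...) {
  cat(sprintf("<epr_trace> %d points, t = %.4g..%.4g %s%s\n",
              length(x$t), min(x$t), max(x$t), x$unit,
              if (is.null(x$imag)) "" else ", complex"))
  if (!is.null(x$meta$label)) cat("  label:", x$meta$label, "\n")
  if (!is.null(x$meta$freq_GHz))
    cat(sprintf("  spectrometer: %.4g GHz, g = %.4g\n",
                x$meta$freq_GHz, x$meta$g_value %||% NA_real_))
  invisible(x)
}

# Time step of a trace (uniform by construction).
trace_dt <- function(trace) trace$t[2] - trace$t[1]

#' Estimate the noise level of a trace
#'
#' Standard deviation of the residuals of a smoothing-spline fit to the
#' real channel.  Used as the reference amplitude when the validation
#' ensemble adds fractional ("50 %") noise to a trace.
#'
#' @param trace An [time_trace()] object.
#' @return Estimated noise standard deviation (signal units).
#' @export
estimate_noise_sd <- function(trace) {
  stopifnot(inherits(trace, "epr_trace"))
  fit <- stats::smooth.spline(trace$t, trace$real)
  stats::sd(trace$real - stats::predict(fit, trace$t)$y)
}
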