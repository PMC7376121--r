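#' Fit a stretched-exponential echo decay
#'
#' Nonlinear least squares of \eqn{A \exp[-(T/\tau_d)^\beta]} to the real
#' channel of a 3pESEEM trace, initialized from a log-log linearization.
#' The stretched exponential is the standard model for the echo envelope
#' of a nitroxide in a frozen glass and proved more robust than polynomial
#' baselines for modulation-depth-preserving normalization.
#'
#' @param trace ESEEM [time_trace()] (ns) with at least 32 points.
#' @return An object of class `stretched_decay`: `A`, `tau_d` (ns),
#'   `beta`.
#' @export
fit_stretched_decay <- function(trace) {
  stopifnot(inherits(trace, "epr_trace"))
  if (length(trace$t) < 32) stop("need at least 32 points to fit the decay")
  T <- trace$t
  v <- trace$real
  beta_lo <- 0.05
  if (stats::sd(v) < 1e-10 * max(abs(mean(v)), 1e-300)) {
    warning("flat trace: stretch exponent pinned at its lower bound")
    return(structure(list(A = mean(v), tau_d = Inf, beta = beta_lo),
                     class = "stretched_decay"))
  }
  A0 <- max(v)
  ratio <- v / A0
  usable <- T > 0 & ratio > 1e-6 & ratio < 0.999
  if (sum(usable) >= 5) {
    y <- log(-log(ratio[usable]))
    cf <- stats::coef(stats::lm(y ~ log(T[usable])))
    beta0 <- min(max(cf[[2]], 0.2), 2)
    tau0 <- exp(-cf[[1]] / beta0)
  } else {
    beta0 <- 1
    tau0 <- max(T)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * exp(-(T / td)^beta),
      start = list(A = A0, td = tau0, beta = beta0),
      lower = c(A = 1e-12, td = 1e-3, beta = beta_lo),
      upper = c(A = Inf, td = Inf, beta = 2),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e)
      stop("stretched-exponential fit failed to converge: ",
           conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  if (est[["beta"]] <= beta_lo + 1e-8)
    warning("stretch exponent at its lower bound; decay poorly determined")
  structure(list(A = est[["A"]], tau_d = est[["td"]], beta = est[["beta"]]),
            class = "stretched_decay")
}

#' Evaluate a stretched-exponential decay
#'
#' @param object A `stretched_decay` from [fit_stretched_decay()].
#' @param t Time axis, ns.
#' @param ... Unused.
#' @return Decay values on `t`.
#' @export
predict.stretched_decay <- function(object, t, ...) {
  if (!is.finite(object$tau_d)) return(rep(object$A, length(t)))
  object$A * exp(-(t / object$tau_d)^object$beta)
}

#' Normalize ESEEM modulation against the echo decay
#'
#' Subtracts the fitted decay and then divides by it:
#' \eqn{out(T) = (V(T) - f(T)) / f(T)}.  This retains the modulation-depth
#' information (a trace \eqn{V = f (1 + m)} maps exactly to m, whatever
#' the decay shape) and makes the result scale-invariant in the echo
#' amplitude.  The imaginary channel, if present, is divided by the decay.
#'
#' @param trace ESEEM [time_trace()] (ns).
#' @param decay A `stretched_decay`, typically from
#'   [fit_stretched_decay()].
#' @return Normalized [time_trace()] oscillating around 0.
#' @export
normalize_modulation <- function(trace, decay) {
  stopifnot(inherits(trace, "epr_trace"), inherits(decay, "stretched_decay"))
  f <- predict(decay, trace$t)
  if (any(f <= 0)) stop("decay model non-positive on the trace support")
  time_trace(trace$t, (trace$real - f) / f,
             imag = if (!is.null(trace$imag)) trace$imag / f,
             unit = trace$unit, meta = trace$meta)
}

#' Fourier spectrum of a normalized ESEEM trace
#'
#' Applies a Hamming window, zero-fills to `zero_fill_factor` times the
#' next power of two and Fourier transforms.  The one-sided spectrum is
#' returned on a MHz axis derived from the (ns) sampling step.
#'
#' @param trace Normalized ESEEM [time_trace()] (ns), uniformly sampled.
#' @param zero_fill_factor Zero-fill multiple of the next power of two
#'   (>= 1).
#' @param detrend Remove a linear baseline before windowing (off by
#'   default; useful when the stretched-exponential correction leaves a
#'   slight residual slope).
#' @return An object of class `eseem_spectrum`: `freq` (MHz, from 0),
#'   `spec` (complex amplitudes), `phase_corrected` flag, `noise_rmsd`
#'   (filled by [deuterium_accessibility()]), `meta`.
#' @export
eseem_spectrum <- function(trace, zero_fill_factor = 2, detrend = FALSE) {
  stopifnot(inherits(trace, "epr_trace"))
  if (!is_uniform(trace$t)) stop("spectrum requires uniform sampling")
  if (zero_fill_factor < 1 || zero_fill_factor != round(zero_fill_factor))
    stop("`zero_fill_factor` must be a positive integer")
  n <- length(trace$t)
  z <- complex(real = trace$real,
               imaginary = trace$imag %||% rep(0, n))
  if (detrend) {
    idx <- seq_len(n)
    z <- z - stats::fitted(stats::lm(Re(z) ~ idx)) -
      1i * stats::fitted(stats::lm(Im(z) ~ idx))
  }
  w <- signal::hamming(n)
  m <- zero_fill_factor * 2^ceiling(log2(n))
  padded <- c(z * w, complex(real = rep(0, m - n)))
  spec <- stats::fft(padded)
  half <- seq_len(m %/% 2 + 1)
  dt_ns <- trace$t[2] - trace$t[1]
  freq <- (half - 1) / (m * dt_ns) * 1e3  # MHz
  structure(list(freq = freq, spec = spec[half], phase_corrected = FALSE,
                 noise_rmsd = NA_real_, meta = trace$meta, dt_ns = dt_ns),
            class = "eseem_spectrum")
}

#' @export
print.eseem_spectrum <- function(x, ...) {
  cat(sprintf("<eseem_spectrum> %d bins, 0..%.3g MHz%s\n",
              length(x$freq), max(x$freq),
              if (x$phase_corrected) ", phase corrected" else ""))
  invisible(x)
}

#' Zero-order phase correction of an ESEEM spectrum
#'
#' Rotates the complex spectrum by the single phase that minimizes the
#' total squared imaginary amplitude over the working band (closed-form
#' solution; of the two stationary phases the minimizing one is chosen,
#' and the remaining 180-degree ambiguity is resolved towards positive
#' absorption).
#'
#' @param spec An [eseem_spectrum()], not yet corrected.
#' @param band Frequency band (MHz) over which the imaginary power is
#'   minimized.
#' @return The spectrum with `spec` rotated, `phase_corrected = TRUE` and
#'   the applied phase (radians) stored as `phase`.
#' @export
phase_correct <- function(spec, band = c(0.5, 8)) {
  stopifnot(inherits(spec, "eseem_spectrum"))
  if (spec$phase_corrected) stop("spectrum is already phase corrected")
  idx <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(idx)) idx <- rep(TRUE, length(spec$freq))
  re <- Re(spec$spec[idx]); im <- Im(spec$spec[idx])
  # minimize f(phi) = sum((im cos phi + re sin phi)^2)
  cc <- sum(re * im)
  qq <- sum(re^2 - im^2)
  phi0 <- 0.5 * atan2(-2 * cc, qq)
  cand <- c(phi0, phi0 + pi / 2)
  imag_power <- function(phi) sum((im * cos(phi) + re * sin(phi))^2)
  phi <- cand[which.min(vapply(cand, imag_power, 1))]
  if (sum(re * cos(phi) - im * sin(phi)) < 0) phi <- phi + pi
  spec$spec <- spec$spec * exp(1i * phi)
  spec$phase_corrected <- TRUE
  spec$phase <- phi
  spec
}

#' Deuterium accessibility from an ESEEM spectrum
#'
#' Relative deuterium (solvent) accessibility is the absolute spectral
#' amplitude at the deuterium Larmor frequency at the recording field.
#' To tolerate field-calibration error the readout takes the maximum of
#' the absolute spectrum within one frequency bin of the nominal nu_D.
#' The error is the RMSD of the imaginary part of the phase-corrected
#' spectrum over a signal-free band.
#'
#' @param spec A phase-corrected [eseem_spectrum()] with `freq_GHz` and
#'   `g_value` metadata.
#' @param noise_band Signal-free band (MHz) for the imaginary-RMSD error
#'   estimate (default 3.5-8, between the 2H and 1H lines).
#' @return An object of class `accessibility_result`: `intensity`,
#'   `error`, `nu_D` (MHz), `condition` (trace label).
#' @export
deuterium_accessibility <- function(spec, noise_band = c(3.5, 8)) {
  stopifnot(inherits(spec, "eseem_spectrum"))
  if (!spec$phase_corrected)
    stop("phase-correct the spectrum first (see `phase_correct()`)")
  freq_GHz <- spec$meta$freq_GHz %||% stop("missing `freq_GHz` metadata")
  g <- spec$meta$g_value %||% 2.006
  nu_D <- larmor_frequency("2H", freq_GHz, g)
  if (nu_D > max(spec$freq))
    stop("deuterium Larmor frequency outside the spectral range")
  bin <- spec$freq[2] - spec$freq[1]
  window <- abs(spec$freq - nu_D) <= bin
  intensity <- max(Mod(spec$spec[window]))
  noise_idx <- spec$freq >= noise_band[1] & spec$freq <= noise_band[2]
  if (!any(noise_idx)) stop("noise band outside the spectral range")
  err <- sqrt(mean(Im(spec$spec[noise_idx])^2))
  structure(list(intensity = intensity, error = err, nu_D = nu_D,
                 condition = spec$meta$label %||% NA_character_),
            class = "accessibility_result")
}

#' @export
print.accessibility_result <- function(x, ...) {
  cat(sprintf("<accessibility_result> %.4g +/- %.2g at nu_D = %.3g MHz (%s)\n",
              x$intensity, x$error, x$nu_D, x$condition))
  invisible(x)
}

#' Percent change in deuterium accessibility between two conditions
#'
#' \eqn{100 (I_{a} - I_{b}) / I_{b}} with first-order error propagation,
#' e.g. nanodisk-reconstituted vs detergent-solubilized samples of the
#' same labelled site.
#'
#' @param a,b [deuterium_accessibility()] results; `b` is the reference
#'   (denominator) condition.
#' @return An object of class `accessibility_change`: `percent`, `error`.
#' @export
percent_change <- function(a, b) {
  stopifnot(inherits(a, "accessibility_result"),
            inherits(b, "accessibility_result"))
  if (b$intensity <= 0) stop("reference intensity must be positive")
  pc <- 100 * (a$intensity - b$intensity) / b$intensity
  err <- 100 * sqrt((a$error / b$intensity)^2 +
                    (a$intensity * b$error / b$intensity^2)^2)
  structure(list(percent = pc, error = err), class = "accessibility_change")
}

#' @export
print.accessibility_change <- function(x, ...) {
  cat(sprintf("<accessibility_change> %+.1f %% +/- %.1f\n",
              x$percent, x$error))
  invisible(x)
}

#' Full ESEEM accessibility chain
#'
#' Convenience wrapper running the complete analysis on a raw 3pESEEM
#' trace: stretched-exponential fit, modulation normalization, windowed
#' and zero-filled Fourier transform, phase correction and deuterium
#' readout.
#'
#' @param trace Raw ESEEM [time_trace()] (ns).
#' @param zero_fill_factor,detrend Passed to [eseem_spectrum()].
#' @param noise_band Passed to [deuterium_accessibility()].
#' @return An `accessibility_result`; the intermediate spectrum is
#'   attached as attribute `"spectrum"`.
#' @export
eseem_accessibility <- function(trace, zero_fill_factor = 2,
                                detrend = FALSE, noise_band = c(3.5, 8)) {
  decay <- fit_stretched_decay(trace)
  norm <- normalize_modulation(trace, decay)
  spec <- phase_correct(eseem_spectrum(norm, zero_fill_factor, detrend))
  out <- deuterium_accessibility(spec, noise_band)
  attr(out, "spectrum") <- spec
  out
}
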