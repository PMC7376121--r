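#' Fit the intermolecular background of a DEER trace
#'
#' Least-squares fit of \eqn{s \exp(-k t^{d/3})} to the tail of the trace,
#' from `fit_start * t_max` onward.  The starting point is the single most
#' influential analysis choice for DEER; the validation ensemble
#' ([validate()]) scans it systematically.  By default the decay rate is
#' constrained to k >= 0; rising ("unphysical") backgrounds, which can
#' genuinely minimize the fit RMSD when the dipolar oscillation is
#' incompletely sampled, are admitted with `allow_unphysical = TRUE` and
#' flagged on the returned object.
#'
#' @param trace DEER [time_trace()] (us).
#' @param fit_start Start of the fitted tail as a fraction of the trace
#'   length, in (0, 1).
#' @param dimension Background dimensionality d (3 = homogeneous 3-D).
#' @param allow_unphysical Permit k < 0 (rising background)?
#' @return An object of class `background_model`: `rate` (k, per us),
#'   `dimension`, `scale`, `fit_start`, `unphysical` flag.
#' @export
fit_background <- function(trace, fit_start = 1 / 3, dimension = 3,
                           allow_unphysical = FALSE) {
  stopifnot(inherits(trace, "epr_trace"))
  if (!is.numeric(fit_start) || fit_start <= 0 || fit_start >= 1)
    stop("`fit_start` must lie in (0, 1)")
  tail_idx <- trace$t >= fit_start * max(trace$t)
  if (sum(tail_idx) < 5)
    stop("fewer than 5 points in the background tail; decrease `fit_start`")
  tt <- trace$t[tail_idx]
  v <- trace$real[tail_idx]
  u <- tt^(dimension / 3)
  # init from log-linearization of the positive part
  vp <- pmax(v, 1e-6 * max(abs(v)))
  init <- stats::coef(stats::lm(log(vp) ~ u))
  k0 <- -init[[2]]; s0 <- exp(init[[1]])
  if (!allow_unphysical) k0 <- max(k0, 1e-8)
  fit <- minpack.lm::nlsLM(
    v ~ s * exp(-k * u),
    start = list(s = s0, k = k0),
    lower = c(s = 1e-12, k = if (allow_unphysical) -Inf else 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(list(rate = est[["k"]], dimension = dimension,
                 scale = est[["s"]], fit_start = fit_start,
                 unphysical = est[["k"]] < 0),
            class = "background_model")
}

#' Evaluate a fitted background model
#'
#' @param object A `background_model` from [fit_background()].
#' @param t Time axis, us.
#' @param ... Unused.
#' @return Background values on `t`.
#' @export
predict.background_model <- function(object, t, ...) {
  deer_background(t, object$rate, object$dimension, object$scale)
}

#' Divide out the intermolecular background (form factor)
#'
#' F(t) = V(t) / B(t), renormalized to its value at t = 0.  Because the
#' tail fit's amplitude absorbs the (1 - lambda) plateau of the
#' intramolecular signal, the raw quotient starts near 1/(1 - lambda);
#' the renormalization restores the conventional form factor, which
#' decays from 1 towards 1 - lambda and so retains the modulation-depth
#' information.
#'
#' @param trace DEER [time_trace()].
#' @param bg A `background_model` from [fit_background()].
#' @return Background-corrected [time_trace()] (form factor).
#' @export
form_factor <- function(trace, bg) {
  stopifnot(inherits(trace, "epr_trace"), inherits(bg, "background_model"))
  B <- predict(bg, trace$t)
  if (any(B <= 0))
    stop("background model non-positive on the trace support")
  F0 <- trace$real[1] / B[1]
  if (F0 <= 0) stop("non-positive signal at t = 0; cannot normalize")
  B <- B * F0
  time_trace(trace$t, trace$real / B,
             imag = if (!is.null(trace$imag)) trace$imag / B,
             unit = trace$unit,
             meta = c(trace$meta[setdiff(names(trace$meta), "label")],
                      list(label = paste0(trace$meta$label %||% "trace",
                                          " (form factor)"))))
}

#' Suppress multispin artifacts by power scaling
#'
#' In a complex with n coupled spins the pair form factors multiply, and
#' sum-combination ghost peaks contaminate the inversion.  Raising the
#' form factor to the power 1/(n-1) approximately restores the pair signal
#' and suppresses the ghost-peak mass.  For n = 2 this is the identity.
#'
#' @param ff Form-factor [time_trace()].
#' @param n_spins Number of coupled spins per complex (>= 2); 5 for a
#'   pentamer (exponent 1/4).
#' @param floor Values below this are clipped (with a warning) before
#'   exponentiation.
#' @return Power-scaled form factor trace.
#' @export
power_scale <- function(ff, n_spins, floor = 1e-3) {
  stopifnot(inherits(ff, "epr_trace"))
  if (!is.numeric(n_spins) || n_spins < 2 || n_spins != round(n_spins))
    stop("`n_spins` must be an integer >= 2")
  v <- ff$real
  if (any(v < floor)) {
    warning(sprintf("%d non-positive form-factor values clipped at %g",
                    sum(v < floor), floor))
    v <- pmax(v, floor)
  }
  time_trace(ff$t, v^(1 / (n_spins - 1)), unit = ff$unit, meta = ff$meta)
}
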