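#' Parameters of a simulated 4-pulse DEER experiment
#'
#' @param mod_depth Modulation depth lambda in [0, 1]: fraction of the echo
#'   amplitude modulated by intra-complex dipolar coupling.
#' @param bg_rate Intermolecular background decay constant k, per us.
#' @param bg_dimension Background dimensionality d (3 = homogeneous 3-D
#'   spin distribution; lower for membrane-confined spins).
#' @param noise_sd Additive Gaussian noise sd as a fraction of V(0).
#' @param time_axis Dipolar evolution time axis, us, uniform from 0.
#' @return An object of class `deer_params`.
#' @export
deer_params <- function(mod_depth = 0.3, bg_rate = 0.05, bg_dimension = 3,
                        noise_sd = 0.01,
                        time_axis = seq(0, 2.5, by = 0.01)) {
  if (!is.numeric(mod_depth) || mod_depth < 0 || mod_depth > 1)
    stop("`mod_depth` must lie in [0, 1]")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be non-negative")
  if (!is.numeric(bg_dimension) || bg_dimension <= 0 || bg_dimension > 6)
    stop("`bg_dimension` must lie in (0, 6]")
  if (any(diff(time_axis) <= 0)) stop("time axis must be strictly increasing")
  if (time_axis[1] != 0) stop("DEER time axis must start at 0")
  structure(list(mod_depth = mod_depth, bg_rate = bg_rate,
                 bg_dimension = bg_dimension, noise_sd = noise_sd,
                 time_axis = as.numeric(time_axis)),
            class = "deer_params")
}

#' Forward-simulate a 4-pulse DEER time trace
#'
#' Evaluates
#' \deqn{V(t) = B(t)\,[(1-\lambda) + \lambda \int K(t,r) P(r)\,dr] + \epsilon(t),}
#' with stretched-exponential intermolecular background
#' \eqn{B(t) = \exp(-k t^{d/3})}, powder-averaged dipolar kernel K and
#' additive Gaussian noise.  Before noise, V(0) = 1 exactly.
#'
#' @param pr Ground-truth [distance_distribution()].
#' @param params A [deer_params()] object.
#' @param seed RNG seed for the noise (deterministic given seed).
#' @return An [time_trace()] in us with Q-band metadata; the simulation
#'   truth (`pr`, `params`) is attached as attribute `"truth"`.
#' @examples
#' pr <- geometry_to_distribution(make_cn_geometry(5, 2.5), default_r_grid())
#' tr <- simulate_deer(pr, deer_params(noise_sd = 0), seed = 1)
#' @export
simulate_deer <- function(pr, params = deer_params(), seed = NULL) {
  stopifnot(inherits(pr, "distance_distribution"),
            inherits(params, "deer_params"))
  t <- params$time_axis
  kernel <- build_kernel(t, pr$r)
  w <- trapz_weights(pr$r)
  ff <- (1 - params$mod_depth) +
    params$mod_depth * drop(kernel$K %*% (w * pr$density))
  B <- exp(-params$bg_rate * t^(params$bg_dimension / 3))
  V <- B * ff
  if (params$noise_sd > 0) {
    V <- V + with_seed(seed, stats::rnorm(length(t), sd = params$noise_sd))
  }
  out <- time_trace(t, V, unit = "us",
                    meta = list(freq_GHz = 34, g_value = 2.006,
                                label = "simulated 4-pulse DEER"))
  attr(out, "truth") <- list(pr = pr, params = params)
  out
}

#' Evaluate the intermolecular DEER background
#'
#' @param t Time axis, us.
#' @param rate Decay constant k, per us.
#' @param dimension Background dimensionality d.
#' @param scale Amplitude at t = 0.
#' @return Background values \eqn{scale \cdot \exp(-k t^{d/3})}.
#' @export
deer_background <- function(t, rate, dimension = 3, scale = 1) {
  scale * exp(-rate * t^(dimension / 3))
}
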