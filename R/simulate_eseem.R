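#' Parameters of a simulated three-pulse ESEEM experiment
#'
#' Describes the pulse sequence pi/2 - tau - pi/2 - T - pi/2 - tau - echo:
#' first interpulse delay tau, incremented delay axis T, nuclear couplings,
#' stretched-exponential echo decay and the noise level.  By default tau
#' sits on the second proton blind spot (2 / nu_H, about 139 ns at X-band)
#' so the matrix 1H modulation is suppressed while 2H modulation survives.
#'
#' @param tau First interpulse delay, ns (> 0).  `NULL` uses the proton
#'   blind spot computed from `freq_GHz` and `g_value`.
#' @param T_axis Incremented delay axis, ns, uniform (12 ns steps by
#'   default).
#' @param couplings List of nuclear couplings, each a list with `nucleus`
#'   (`"1H"`/`"2H"`), modulation amplitude `k` in [0, 1] and optional
#'   `freq` (MHz; defaults to the Larmor frequency at the simulated
#'   field).
#' @param decay List `(A, tau_d, beta)`: echo amplitude, decay time (ns)
#'   and stretch exponent in (0, 2].
#' @param noise_sd Gaussian noise sd as a fraction of A; applied
#'   independently to the real and imaginary channels.
#' @param freq_GHz,g_value Simulated spectrometer frequency and g-value.
#' @return An object of class `eseem_params`.
#' @export
eseem_params <- function(tau = NULL,
                         T_axis = seq(0, by = 12, length.out = 300),
                         couplings = list(
                           list(nucleus = "2H", k = 0.3, freq = NULL),
                           list(nucleus = "1H", k = 0.2, freq = NULL)),
                         decay = list(A = 1, tau_d = 8000, beta = 1.2),
                         noise_sd = 0.01,
                         freq_GHz = 9.5, g_value = 2.006) {
  if (is.null(tau)) tau <- blind_spot_tau(freq_GHz, g_value)
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be positive (ns)")
  if (any(diff(T_axis) <= 0)) stop("T axis must be strictly increasing")
  for (cp in couplings) {
    if (!is.numeric(cp$k) || cp$k < 0 || cp$k > 1)
      stop("modulation amplitudes must lie in [0, 1]")
  }
  if (decay$A <= 0 || decay$tau_d <= 0 ||
      decay$beta <= 0 || decay$beta > 2)
    stop("decay needs A > 0, tau_d > 0 and beta in (0, 2]")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be non-negative")
  structure(list(tau = tau, T_axis = as.numeric(T_axis),
                 couplings = couplings, decay = decay, noise_sd = noise_sd,
                 freq_GHz = freq_GHz, g_value = g_value),
            class = "eseem_params")
}

#' Forward-simulate a three-pulse ESEEM time trace
#'
#' Per nucleus, the echo modulation in the weak-coupling limit (degenerate
#' nuclear frequencies in both electron-spin manifolds) is
#' \deqn{E(T) = 1 - \frac{k}{2} (1 - \cos\omega\tau)(1 - \cos\omega(\tau + T)),}
#' with nuclear angular frequency omega.  The product over nuclei is
#' multiplied by the stretched-exponential echo decay
#' \eqn{A \exp[-(T/\tau_d)^\beta]} and independent Gaussian noise is added
#' to the real and imaginary channels.  At \eqn{\omega\tau = 2\pi m}
#' (blind spot) the modulation of that nucleus vanishes identically.
#'
#' @param params An [eseem_params()] object.
#' @param seed RNG seed for the noise.
#' @return An [time_trace()] in ns with complex channels and ESEEM
#'   metadata (`freq_GHz`, `g_value`, `tau_ns`).
#' @examples
#' tr <- simulate_3peseem(eseem_params(noise_sd = 0))
#' @export
simulate_3peseem <- function(params = eseem_params(), seed = NULL) {
  stopifnot(inherits(params, "eseem_params"))
  T <- params$T_axis
  mod <- rep(1, length(T))
  for (cp in params$couplings) {
    freq <- cp$freq %||%
      larmor_frequency(cp$nucleus, params$freq_GHz, params$g_value)
    omega <- 2 * pi * freq * 1e-3  # rad/ns
    mod <- mod * (1 - (cp$k / 2) * (1 - cos(omega * params$tau)) *
                    (1 - cos(omega * (params$tau + T))))
  }
  dec <- params$decay
  V <- dec$A * exp(-(T / dec$tau_d)^dec$beta) * mod
  im <- rep(0, length(T))
  if (params$noise_sd > 0) {
    sd_abs <- params$noise_sd * dec$A
    noise <- with_seed(seed, stats::rnorm(2L * length(T), sd = sd_abs))
    V <- V + noise[seq_along(T)]
    im <- im + noise[length(T) + seq_along(T)]
  }
  time_trace(T, V, imag = im, unit = "ns",
             meta = list(freq_GHz = params$freq_GHz, g_value = params$g_value,
                         tau_ns = params$tau,
                         label = "simulated 3-pulse ESEEM"))
}
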