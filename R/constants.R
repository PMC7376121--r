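# Physical constants (CODATA 2018).  All spectroscopic frequencies in the
# package trace back to these values.
.const <- list(
  h        = 6.62607015e-34,     # Planck constant, J s (exact)
  mu_B     = 9.2740100783e-24,   # Bohr magneton, J/T
  mu_0     = 1.25663706212e-6,   # vacuum magnetic permeability, N/A^2
  g_e      = 2.00231930436256,   # free-electron g-factor
  gamma_1H = 42.577478518,       # 1H gyromagnetic ratio, MHz/T
  gamma_2H = 6.536               # 2H gyromagnetic ratio, MHz/T
)

#' Dipolar coupling constant for a pair of free electrons
#'
#' Returns the electron-electron dipolar constant
#' \eqn{D = \mu_0 g_e^2 \mu_B^2 / (4 \pi h)} expressed in MHz nm^3, i.e. the
#' perpendicular dipolar frequency of two electron spins 1 nm apart.  The
#' familiar value is 52.04 MHz nm^3; here it is computed from CODATA
#' constants rather than hard-coded.
#'
#' @return Dipolar constant in MHz nm^3 (about 52.04).
#' @examples
#' dipolar_constant()          # ~52.04
#' dipolar_constant() / 2.5^3  # perpendicular frequency at 2.5 nm, MHz
#' @export
dipolar_constant <- function() {
  hz_m3 <- .const$mu_0 / (4 * pi) * (.const$g_e * .const$mu_B)^2 / .const$h
  hz_m3 * 1e27 * 1e-6  # m^3 -> nm^3, Hz -> MHz
}

#' Nuclear Larmor frequency at the field of an EPR measurement
#'
#' Converts the electron resonance condition into a magnetic field,
#' \eqn{B = h \nu_e / (g \mu_B)}, and evaluates the nuclear precession
#' frequency \eqn{\nu_n = \gamma_n B} for 1H or 2H.  Used to locate the
#' deuterium line in ESEEM spectra and to choose the proton blind-spot
#' interpulse delay.
#'
#' @param nucleus `"1H"` or `"2H"`.
#' @param spectrometer_freq Electron (microwave) frequency in GHz.
#' @param g_value Effective g-value of the observed spin (nitroxides:
#'   about 2.006).
#' @return Larmor frequency in MHz.
#' @examples
#' larmor_frequency("1H", 9.5)  # ~14.4 MHz
#' larmor_frequency("2H", 9.5)  # ~2.21 MHz
#' @export
larmor_frequency <- function(nucleus = c("1H", "2H"), spectrometer_freq,
                             g_value = 2.006) {
  nucleus <- match.arg(nucleus)
  stopifnot(is.numeric(spectrometer_freq), spectrometer_freq >= 0,
            is.numeric(g_value), g_value > 0)
  B <- .const$h * spectrometer_freq * 1e9 / (g_value * .const$mu_B)  # Tesla
  gamma <- switch(nucleus, "1H" = .const$gamma_1H, "2H" = .const$gamma_2H)
  gamma * B
}

#' Proton blind-spot interpulse delay for 3pESEEM
#'
#' The proton modulation of a three-pulse ESEEM experiment vanishes when
#' \eqn{(1 - \cos 2\pi\nu_H \tau) = 0}, i.e. at \eqn{\tau = m / \nu_H}.
#' The customary choice is the second blind spot \eqn{\tau = 2/\nu_H}
#' (about 140 ns at X-band), which suppresses the matrix proton signal
#' while retaining deuterium modulation.
#'
#' @inheritParams larmor_frequency
#' @param order Blind-spot order m (default 2).
#' @return Interpulse delay tau in ns.
#' @examples
#' blind_spot_tau(9.5, 2.006)  # ~138.8 ns
#' @export
blind_spot_tau <- function(spectrometer_freq = 9.5, g_value = 2.006,
                           order = 2) {
  nu_H <- larmor_frequency("1H", spectrometer_freq, g_value)
  1e3 * order / nu_H  # 1/MHz = us -> ns
}
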