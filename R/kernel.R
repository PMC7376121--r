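#' Powder-averaged dipolar kernel for DEER inversion
#'
#' Builds the matrix K(t, r) that maps a distance distribution to the
#' intramolecular dipolar form factor of an isotropically oriented sample:
#' \deqn{K(t, r) = \int_0^1 \cos[\omega_{dd}(r) (1 - 3x^2) t] \, dx,}
#' with \eqn{\omega_{dd}(r) = 2\pi D / r^3} and D the electron dipolar
#' constant (about 52.04 MHz nm^3, computed from CODATA constants by
#' [dipolar_constant()]).  Columns are evaluated in closed form through
#' Fresnel integrals; the small-phase regime uses a Taylor expansion to
#' avoid cancellation.
#'
#' @param t_grid Time axis, us, non-negative, strictly increasing.
#' @param r_grid Distance axis, nm, positive, strictly increasing.
#' @return An object of class `dipolar_kernel`: list with matrix `K`
#'   (length(t) x length(r)), `t`, `r`.  K(0, r) = 1 for every r.
#' @examples
#' k <- build_kernel(seq(0, 2, by = 0.01), seq(2, 5, by = 0.1))
#' range(k$K)   # within [-1, 1], first row all 1
#' @export
build_kernel <- function(t_grid, r_grid) {
  t_grid <- as.numeric(t_grid); r_grid <- as.numeric(r_grid)
  if (!length(t_grid) || !length(r_grid)) stop("empty kernel grid")
  if (any(diff(t_grid) <= 0) || any(diff(r_grid) <= 0))
    stop("kernel grids must be strictly increasing")
  if (any(t_grid < 0)) stop("time grid must be non-negative")
  if (any(r_grid <= 0)) stop("distances must be positive")
  # full dipolar phase omega * t (radians); t in us, frequencies in MHz
  omega_t <- outer(t_grid, 2 * pi * dipolar_constant() / r_grid^3)
  K <- matrix(kernel_value(as.vector(omega_t)), nrow = length(t_grid))
  structure(list(K = K, t = t_grid, r = r_grid), class = "dipolar_kernel")
}

# Powder-average integral for a vector of dipolar phases w = omega*t:
#   k(w) = int_0^1 cos(w (1 - 3 x^2)) dx
#        = sqrt(pi/(6w)) [cos(w) C(q) + sin(w) S(q)],  q = sqrt(6w/pi),
# with C, S in the Fresnel convention int_0^x cos/sin(pi u^2 / 2) du.
kernel_value <- function(w) {
  out <- numeric(length(w))
  small <- w < 1e-4
  # series: 1 - (2/5) w^2 + (1.371428...)/24 w^4 + O(w^6)
  ws <- w[small]
  out[small] <- 1 - 0.4 * ws^2 + (48 / 35) / 24 * ws^4
  wl <- w[!small]
  if (length(wl)) {
    q <- sqrt(6 * wl / pi)
    out[!small] <- sqrt(pi / (6 * wl)) *
      (cos(wl) * pracma::fresnelC(q) + sin(wl) * pracma::fresnelS(q))
  }
  out
}

#' @export
print.dipolar_kernel <- function(x, ...) {
  cat(sprintf("<dipolar_kernel> %d x %d, t = 0..%.3g us, r = %.3g..%.3g nm\n",
              length(x$t), length(x$r), max(x$t), min(x$r), max(x$r)))
  invisible(x)
}

#' Default distance grid for DEER inversion
#'
#' 1.5 to 8.0 nm in 0.05 nm steps, the working range of Q-band DEER on
#' nitroxide pairs.
#'
#' @param r_min,r_max,r_step Grid limits and spacing, nm.
#' @return Numeric distance grid.
#' @export
default_r_grid <- function(r_min = 1.5, r_max = 8, r_step = 0.05) {
  seq(r_min, r_max, by = r_step)
}
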