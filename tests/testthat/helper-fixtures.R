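# Fixtures and independent oracles, built in code at test time.

# --- PDB fixtures -----------------------------------------------------------

pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1, altloc = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resn, chain, resno, x, y, z, occ, 0,
          substr(name, 1, 1))
}

# Ideal C5 pentamer: one CYS per chain, CB on a ring of `radius_A` Angstrom.
make_penta_pdb <- function(path, radius_A = 25) {
  lines <- character(0)
  serial <- 0
  for (i in 0:4) {
    th <- 2 * pi * i / 5
    ch <- LETTERS[i + 1]
    ats <- list(
      list("N",  c((radius_A - 2.8) * cos(th), (radius_A - 2.8) * sin(th), 0.5)),
      list("CA", c((radius_A - 1.5) * cos(th), (radius_A - 1.5) * sin(th), 0)),
      list("CB", c(radius_A * cos(th), radius_A * sin(th), 0)))
    for (a in ats) {
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, a[[1]], "CYS", ch, 10,
                                 a[[2]][1], a[[2]][2], a[[2]][3]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Single residue caged inside a cubic lattice of carbon atoms
# (spacing_A Angstrom) filling the tether shell: total steric occlusion.
make_caged_pdb <- function(path, spacing_A = 2.5) {
  lines <- c(pdb_line(1, "CA", "CYS", "A", 1, 0, 0, 0),
             pdb_line(2, "CB", "CYS", "A", 1, 1.5, 0, 0))
  serial <- 2
  grid <- seq(-11, 11, by = spacing_A)
  for (x in grid) for (y in grid) for (z in grid) {
    r <- sqrt((x - 1.5)^2 + y^2 + z^2)
    if (r > 2.5 && r < 11.5) {   # shell around the CB anchor
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, "C", "UNK", "B", serial, x, y, z))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Lone residue with no neighbours at all.
make_lone_pdb <- function(path) {
  writeLines(c(pdb_line(1, "N", "CYS", "A", 1, -1.5, 0.4, 0),
               pdb_line(2, "CA", "CYS", "A", 1, -1.5, 0, 0),
               pdb_line(3, "CB", "CYS", "A", 1, 0, 0, 0),
               "END"), path)
  path
}

# --- independent numerical oracles ------------------------------------------

# Brute-force powder-average kernel by dense trapezoid quadrature.
kernel_quadrature <- function(t_us, r_nm, n = 10000) {
  x <- seq(0, 1, length.out = n + 1)
  w <- 2 * pi * dipolar_constant() / r_nm^3 * t_us
  pracma::trapz(x, cos(w * (1 - 3 * x^2)))
}

# Coordinate-descent NNLS, run to convergence: an independent solver for
# min ||A x - b||^2, x >= 0 (unique optimum when A has full column rank).
cd_nnls <- function(A, b, iters = 500000, tol = 1e-13) {
  H <- crossprod(A)
  g0 <- drop(crossprod(A, b))
  x <- numeric(ncol(A))
  for (it in seq_len(iters)) {
    delta <- 0
    for (j in seq_len(ncol(A))) {
      xj <- max(0, x[j] - (sum(H[j, ] * x) - g0[j]) / H[j, j])
      delta <- max(delta, abs(xj - x[j]))
      x[j] <- xj
    }
    if (delta < tol) break
  }
  x
}

# --- canonical simulation scenarios -----------------------------------------

# Noiseless pentamer DEER trace at the package's reference conditions.
penta_deer <- function(noise_sd = 0, t_max = 5, dt = 0.012,
                       r_grid = default_r_grid(), seed = 1) {
  pr <- geometry_to_distribution(make_cn_geometry(5, 2.5), r_grid, 0.1)
  tr <- simulate_deer(pr, deer_params(noise_sd = noise_sd,
                                      time_axis = seq(0, t_max, by = dt)),
                      seed = seed)
  list(pr = pr, trace = tr, r_grid = r_grid)
}

eseem_2h <- function(k, noise_sd = 0.01, k_1H = 0.2, tau = NULL) {
  eseem_params(tau = tau,
               couplings = list(list(nucleus = "2H", k = k, freq = NULL),
                                list(nucleus = "1H", k = k_1H, freq = NULL)),
               noise_sd = noise_sd)
}
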