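test_that("mini-PDB round trip: residues, coordinates, units", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_lone_pdb(f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3)
  cb <- m$atoms[m$atoms$elety == "CB", ]
  expect_equal(unname(c(cb$x, cb$y, cb$z)), c(0, 0, 0))
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(ca$x, -0.15)  # Angstrom -> nm
})

test_that("altloc records collapse to the highest occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "CYS", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_line(2, "CA", "CYS", "A", 1, 9, 0, 0, occ = 0.6, altloc = "B"),
    pdb_line(3, "CB", "CYS", "A", 1, 1.5, 0, 0),
    "END"), f)
  m <- read_structure(f)
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 0.9)  # the 0.6-occupancy position
})

test_that("malformed coordinate records are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "CYS", "A", 1, 0, 0, 0),
               "ATOM      2  CB CYS A   1      bad coords here",
               "END"), f)
  expect_error(read_structure(f), "line 2")
})

test_that("label cloud survival: free residue ~ 1, caged residue errors", {
  lone <- withr::local_tempfile(fileext = ".pdb")
  make_lone_pdb(lone)
  m <- read_structure(lone)
  cl <- attach_label(m, "A", 1, n_samples = 400, seed = 1)
  expect_equal(nrow(cl$points), 400)  # nothing to clash with
  # all points within the tether shell around CB
  d <- sqrt(rowSums(sweep(cl$points, 2, cl$anchor)^2))
  expect_true(all(d >= 0.4 - 1e-9 & d <= 1.0 + 1e-9))

  caged <- withr::local_tempfile(fileext = ".pdb")
  make_caged_pdb(caged)
  mc <- read_structure(caged)
  expect_error(attach_label(mc, "A", 1, n_samples = 200, seed = 1),
               "looser")
})

test_that("tight restraints keep no more positions than loose ones", {
  f <- withr::local_tempfile(fileext = ".pdb")
  # crowded neighbourhood: a partial cage leaves a survival gradient
  make_caged_pdb(f, spacing_A = 6)
  m <- read_structure(f)
  tight <- attach_label(m, "A", 1, n_samples = 1500, vdw = "tight", seed = 4)
  loose <- attach_label(m, "A", 1, n_samples = 1500, vdw = "loose", seed = 4)
  expect_lte(nrow(tight$points), nrow(loose$points))
  expect_lt(nrow(tight$points), 1500)
})

test_that("missing residues are reported with available chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_lone_pdb(f)
  m <- read_structure(f)
  expect_error(attach_label(m, "Z", 1), "not found")
})

test_that("cloud distance distribution matches the direct pairwise oracle", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_penta_pdb(f)
  m <- read_structure(f)
  a <- attach_label(m, "A", 10, n_samples = 600, seed = 1)
  b <- attach_label(m, "B", 10, n_samples = 600, seed = 2)
  r_grid <- seq(0.5, 8, by = 0.05)
  pd <- cloud_distance_distribution(a, b, r_grid)
  # mean preserved exactly by mass-preserving binning
  direct <- mean(pentaepr:::cross_distances(a$points, b$points))
  expect_equal(distribution_mean(pd), direct, tolerance = 1e-9)
  # a cloud against itself is rejected
  expect_error(cloud_distance_distribution(a, a), "two sites")
  # two single-point clouds 3 nm apart -> delta at 3 nm
  p1 <- a; p1$points <- matrix(c(0, 0, 0), 1)
  p2 <- b; p2$points <- matrix(c(3, 0, 0), 1)
  delta <- cloud_distance_distribution(p1, p2, r_grid)
  expect_equal(distribution_mean(delta), 3, tolerance = 1e-9)
  expect_equal(sum(delta$density > 0), 1)
})

test_that("label clouds are equivariant under rigid motions", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_penta_pdb(f)
  m <- read_structure(f)
  theta <- 0.7
  Rz <- matrix(c(cos(theta), sin(theta), 0,
                 -sin(theta), cos(theta), 0,
                 0, 0, 1), 3, 3)
  shift <- c(1.2, -0.4, 2.2)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% Rz
  m2$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
  c1 <- attach_label(m, "A", 10, n_samples = 300, seed = 6)
  c2 <- attach_label(m2, "A", 10, n_samples = 300, seed = 6)
  # the sampling directions are seed-identical, so transformed clouds of
  # kept points must coincide after applying the same rigid motion
  expect_equal(sweep(c1$points %*% Rz, 2, shift, "+"), c2$points,
               tolerance = 1e-9)
})

test_that("ideal pentamer prediction gives two equal peaks at ratio 1.618", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_penta_pdb(f, radius_A = 25)
  m <- read_structure(f)
  for (grid_step in c(0.02, 0.05)) {
    pr <- oligomer_predicted_distributions(m, 10, 5,
                                           seq(1.5, 8, by = grid_step),
                                           method = "anchor")
    pk <- detect_peaks(pr)
    expect_equal(nrow(pk$peaks), 2)
    expect_equal(pk$d2_d1_ratio, 1.618, tolerance = 0.02)
    expect_true(pk$pentamer_consistent)
    expect_equal(pk$peaks$weight, c(0.5, 0.5), tolerance = 0.02)
  }
  # ratio invariant to the ring radius
  f2 <- withr::local_tempfile(fileext = ".pdb")
  make_penta_pdb(f2, radius_A = 34)
  pr2 <- oligomer_predicted_distributions(read_structure(f2), 10, 5,
                                          seq(1.5, 8, by = 0.02),
                                          method = "anchor")
  expect_equal(detect_peaks(pr2)$d2_d1_ratio, 1.618, tolerance = 0.02)
  # missing chains are rejected
  expect_error(oligomer_predicted_distributions(m, 10, 7), "chains")
})

test_that("accessible-volume pentamer prediction stays pentamer-consistent", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_penta_pdb(f, radius_A = 25)
  m <- read_structure(f)
  # a tight tether shell keeps the clouds compact enough to resolve D1/D2
  pr <- oligomer_predicted_distributions(m, 10, 5, seq(0.5, 8, by = 0.05),
                                         n_samples = 400, seed = 11,
                                         tether_min = 0.55,
                                         tether_max = 0.75)
  pk <- detect_peaks(pr)
  expect_gte(nrow(pk$peaks), 2)
  expect_true(pk$pentamer_consistent)
  # the full default shell blurs the modes together but conserves the
  # overall scale: mean stays between D1 and D2
  pr_wide <- oligomer_predicted_distributions(m, 10, 5,
                                              seq(0.5, 8, by = 0.05),
                                              n_samples = 400, seed = 11)
  d <- sort(unique(round(pair_distances(make_cn_geometry(5, 2.5)), 6)))
  expect_gt(distribution_mean(pr_wide), d[1])
  expect_lt(distribution_mean(pr_wide), d[2])
})

test_that("jittered pentamer fixtures pool into two equal-weight modes", {
  # Monte-Carlo pooling over jittered copies of the ideal pentamer
  r_grid <- seq(1.5, 7, by = 0.05)
  pooled <- numeric(length(r_grid))
  for (s in 1:40) {
    f <- withr::local_tempfile(fileext = ".pdb")
    g <- make_cn_geometry(5, 2.5, jitter_sd = 0.08, seed = s)
    lines <- character(0)
    for (i in 1:5) {
      xyz <- g$sites[i, ] * 10  # nm -> Angstrom
      lines <- c(lines,
                 pdb_line(3 * i - 2, "N", "CYS", LETTERS[i], 10,
                          xyz[1] - 2, xyz[2], xyz[3] + 0.5),
                 pdb_line(3 * i - 1, "CA", "CYS", LETTERS[i], 10,
                          xyz[1] - 1, xyz[2], xyz[3]),
                 pdb_line(3 * i, "CB", "CYS", LETTERS[i], 10,
                          xyz[1], xyz[2], xyz[3]))
    }
    writeLines(c(lines, "END"), f)
    pr_i <- oligomer_predicted_distributions(read_structure(f), 10, 5,
                                             r_grid, method = "anchor")
    pooled <- pooled + pr_i$density
  }
  pk <- detect_peaks(distance_distribution(r_grid, pooled))
  expect_equal(nrow(pk$peaks), 2)
  expect_true(pk$pentamer_consistent)
  expect_equal(pk$peaks$weight, c(0.5, 0.5), tolerance = 0.05)
})

test_that("peak detection handles the canonical shapes", {
  r <- seq(1.5, 6, by = 0.02)
  # two Gaussians at 2.0 / 3.24 nm -> ratio 1.62
  pr <- distance_distribution(r, dnorm(r, 2, 0.1) + dnorm(r, 3.24, 0.12))
  pk <- detect_peaks(pr)
  expect_equal(pk$d2_d1_ratio, 1.62, tolerance = 1e-6)
  expect_true(pk$pentamer_consistent)
  # 2.5 / 4.225 nm -> 1.69: at the edge of the pentamer window
  pk2 <- detect_peaks(distance_distribution(
    r, dnorm(r, 2.5, 0.1) + dnorm(r, 4.225, 0.12)))
  expect_equal(pk2$d2_d1_ratio, 1.69, tolerance = 0.01)
  expect_true(pk2$pentamer_consistent)
  # unimodal: one peak, ratio undefined
  pk3 <- detect_peaks(distance_distribution(r, dnorm(r, 3, 0.2)))
  expect_equal(nrow(pk3$peaks), 1)
  expect_true(is.na(pk3$d2_d1_ratio))
  # sub-prominence bumps are ignored
  pk4 <- detect_peaks(distance_distribution(
    r, dnorm(r, 3, 0.2) + 0.02 * dnorm(r, 5, 0.1)), min_prominence = 0.1)
  expect_equal(nrow(pk4$peaks), 1)
})
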