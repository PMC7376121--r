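#' Attach a spin label by accessible-volume sampling
#'
#' Simplified accessible-volume model of a nitroxide label tethered at a
#' residue: candidate label midpoints are drawn uniformly from a spherical
#' shell (tether length 0.4-1.0 nm) around the residue's C-beta (C-alpha
#' for glycine), and candidates closer than the clash cutoff to any
#' protein heavy atom outside the labelled residue are rejected.  The
#' surviving cloud stands in for the rotamer ensemble of the label; only
#' its midpoint statistics feed the distance distributions.  "Tight" van
#' der Waals restraints map to a 0.25 nm cutoff, "loose" to 0.20 nm
#' (documented constants, overridable via `clash_cutoff`).
#'
#' @param model A [read_structure()] object.
#' @param chain Chain identifier of the labelled residue.
#' @param resno Residue number (as in the PDB file, 1-based).
#' @param n_samples Number of candidate positions to draw.
#' @param tether_min,tether_max Shell radii around the anchor, nm.
#' @param vdw `"tight"` or `"loose"` restraint preset.
#' @param clash_cutoff Explicit clash cutoff, nm (overrides `vdw`).
#' @param seed RNG seed (deterministic cloud given seed).
#' @return An object of class `label_cloud`: `points` (m x 3 matrix, nm),
#'   `site`, `n_attempted`, `clash_cutoff`, `anchor`.
#' @export
attach_label <- function(model, chain, resno, n_samples = 2000,
                         tether_min = 0.4, tether_max = 1.0,
                         vdw = c("tight", "loose"), clash_cutoff = NULL,
                         seed = NULL) {
  stopifnot(inherits(model, "spin_structure"))
  vdw <- match.arg(vdw)
  cutoff <- clash_cutoff %||% switch(vdw, tight = 0.25, loose = 0.20)
  at <- model$atoms
  res <- at[at$chain == chain & at$resno == resno, , drop = FALSE]
  if (!nrow(res))
    stop(sprintf("residue %s/%d not found; chains present: %s",
                 chain, resno, paste(unique(at$chain), collapse = ", ")))
  anchor_row <- res[match(c("CB", "CA"), res$elety), , drop = FALSE]
  anchor_row <- anchor_row[!is.na(anchor_row$elety), , drop = FALSE]
  if (!nrow(anchor_row))
    stop(sprintf("residue %s/%d lacks CB/CA backbone atoms", chain, resno))
  anchor <- as.numeric(anchor_row[1, c("x", "y", "z")])
  env <- at[!(at$chain == chain & at$resno == resno), , drop = FALSE]
  env_xyz <- as.matrix(env[, c("x", "y", "z")])
  # sampling directions live in a residue-local frame built from the
  # backbone, so rigidly transforming the model transforms the cloud
  # identically (equivariance under rotation/translation)
  frame <- residue_frame(res, anchor)
  pts <- with_seed(seed, {
    dir <- matrix(stats::rnorm(3L * n_samples), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    u <- stats::runif(n_samples)
    rad <- (u * (tether_max^3 - tether_min^3) + tether_min^3)^(1 / 3)
    sweep((dir * rad) %*% t(frame), 2, anchor, "+")
  })
  ok <- min_dist_to(pts, env_xyz) >= cutoff
  if (!any(ok))
    stop("no sterically allowed label positions; try a looser clash cutoff")
  structure(list(points = pts[ok, , drop = FALSE],
                 site = list(chain = chain, resno = resno),
                 n_attempted = n_samples, clash_cutoff = cutoff,
                 anchor = anchor),
            class = "label_cloud")
}

# Orthonormal residue frame from backbone atoms: x along CA->CB (or
# CA->N), y from the next independent backbone direction, z = x cross y.
# Falls back to the lab frame when the residue lacks enough atoms.
residue_frame <- function(res, anchor) {
  get_at <- function(name) {
    row <- res[res$elety == name, , drop = FALSE]
    if (nrow(row)) as.numeric(row[1, c("x", "y", "z")]) else NULL
  }
  unit <- function(v) v / sqrt(sum(v^2))
  ca <- get_at("CA"); cb <- get_at("CB"); nn <- get_at("N")
  e1 <- if (!is.null(ca) && !is.null(cb)) unit(cb - ca) else NULL
  ref <- if (!is.null(nn) && !is.null(ca)) nn - ca else NULL
  if (is.null(e1) || is.null(ref)) return(diag(3))
  perp <- ref - sum(ref * e1) * e1
  if (sqrt(sum(perp^2)) < 1e-8) return(diag(3))
  e2 <- unit(perp)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

# Minimum distance from each row of `pts` to the atom set `ref`
# (chunked so the pairwise matrix stays small).
min_dist_to <- function(pts, ref) {
  if (!nrow(ref)) return(rep(Inf, nrow(pts)))
  ref2 <- rowSums(ref^2)
  out <- numeric(nrow(pts))
  chunk <- max(1L, floor(2e6 / nrow(ref)))
  for (start in seq(1, nrow(pts), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(pts))
    p <- pts[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), ref2, "+") - 2 * p %*% t(ref)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' @export
print.label_cloud <- function(x, ...) {
  cat(sprintf("<label_cloud> %s/%d: %d of %d positions kept (cutoff %.2g nm)\n",
              x$site$chain, x$site$resno, nrow(x$points), x$n_attempted,
              x$clash_cutoff))
  invisible(x)
}

#' Distance distribution between two label clouds
#'
#' Mass-preserving histogram of all inter-cloud point-pair distances on a
#' uniform grid (each distance splits its weight linearly between the two
#' flanking grid nodes, so the distribution mean equals the exact mean
#' pairwise distance when the grid covers the support).
#'
#' @param cloud_a,cloud_b [attach_label()] clouds; must be distinct
#'   objects (a cloud against itself is rejected).
#' @param r_grid Uniform distance grid, nm.
#' @return A [distance_distribution()]; distances outside the grid
#'   trigger a truncation warning.
#' @export
cloud_distance_distribution <- function(cloud_a, cloud_b,
                                        r_grid = default_r_grid()) {
  stopifnot(inherits(cloud_a, "label_cloud"), inherits(cloud_b, "label_cloud"))
  if (identical(cloud_a, cloud_b))
    stop("intra-cloud distances are not a pair distribution; pass two sites")
  mass <- bin_distances(cross_distances(cloud_a$points, cloud_b$points),
                        r_grid)
  if (attr(mass, "n_dropped") > 0)
    warning(sprintf("%d pair distances fall outside the grid (truncated)",
                    attr(mass, "n_dropped")))
  distance_distribution(r_grid, mass / (r_grid[2] - r_grid[1]))
}

# All pairwise distances between two point sets, as a vector.
cross_distances <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(as.vector(d2), 0))
}

#' Predicted distance distribution for a labelled Cn oligomer
#'
#' Labels the same residue on `n_subunits` chains, orders the label sites
#' around the symmetry axis and pools the nearest-neighbour (D1) and
#' next-nearest-neighbour (D2) pair distance histograms with equal weight
#' per pair — for a pentamer, 5 + 5 pairs, i.e. 1:1 area.  With
#' `method = "anchor"` the clouds collapse to the anchor atoms, which is
#' useful for ideal-geometry fixtures.
#'
#' @param model A [read_structure()] object.
#' @param resno Residue number present in at least `n_subunits` chains.
#' @param n_subunits Oligomer order (default 5).
#' @param r_grid Uniform distance grid, nm.
#' @param method `"accessible_volume"` (label clouds) or `"anchor"`
#'   (single-point sites at CB/CA).
#' @param chains Chains to use; default: first `n_subunits` chains
#'   containing the residue.
#' @param seed Base RNG seed; chain i uses `seed + i`.
#' @param ... Passed to [attach_label()].
#' @return A [distance_distribution()] (pooled D1 + D2), with the chain
#'   order and per-offset pair sets attached as attribute `"pairs"`.
#' @export
oligomer_predicted_distributions <- function(model, resno, n_subunits = 5,
                                             r_grid = default_r_grid(),
                                             method = c("accessible_volume",
                                                        "anchor"),
                                             chains = NULL, seed = 1, ...) {
  stopifnot(inherits(model, "spin_structure"))
  method <- match.arg(method)
  at <- model$atoms
  have <- unique(at$chain[at$resno == resno & at$elety %in% c("CA", "CB")])
  if (is.null(chains)) chains <- have[seq_len(min(n_subunits, length(have)))]
  if (length(chains) < n_subunits || !all(chains %in% have))
    stop(sprintf("residue %d present in %d chains; %d subunits requested",
                 resno, length(have), n_subunits))
  clouds <- lapply(seq_along(chains), function(i) {
    cl <- attach_label(model, chains[i], resno, seed = seed + i, ...)
    if (method == "anchor") cl$points <- matrix(cl$anchor, nrow = 1)
    cl
  })
  centroids <- t(vapply(clouds, function(cl) colMeans(cl$points), numeric(3)))
  ord <- ring_order(centroids)
  clouds <- clouds[ord]
  n <- n_subunits
  mass <- numeric(length(r_grid))
  pairs <- list()
  for (offset in c(1L, 2L)) {
    for (i in seq_len(n)) {
      j <- (i + offset - 1L) %% n + 1L
      if (offset == 2L && n <= 3L) next
      if (n == 4L && offset == 2L && i > 2L) next  # unique diagonals only
      d <- cross_distances(clouds[[i]]$points, clouds[[j]]$points)
      m <- bin_distances(d, r_grid)
      if (attr(m, "n_dropped") > 0)
        warning("pair distances outside the grid (truncated)")
      mass <- mass + m / sum(m)  # one unit of weight per pair
      pairs[[length(pairs) + 1]] <- list(offset = offset, i = i, j = j)
    }
  }
  out <- distance_distribution(r_grid, mass / (r_grid[2] - r_grid[1]))
  attr(out, "pairs") <- pairs
  attr(out, "chains") <- chains[ord]
  out
}

# Order ring positions by angle about the principal symmetry axis
# (normal = direction of least centroid variance).
ring_order <- function(centroids) {
  ctr <- colMeans(centroids)
  rel <- sweep(centroids, 2, ctr)
  sv <- svd(rel)
  basis <- sv$v[, 1:2, drop = FALSE]
  ang <- atan2(rel %*% basis[, 2], rel %*% basis[, 1])
  order(ang)
}
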