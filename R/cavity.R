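# Van der Waals cavity construction: overlapping atom-centered spheres
# tessellated with a deterministic equal-weight point set, buried points
# removed, near-coincident seam points merged.
#
# The tessellation is anchored to a canonical frame of each connected
# cluster of overlapping spheres (weighted principal axes with
# moment-fixed signs), so cavity points co-rotate with the solute: surface
# areas, volume and downstream energies are invariant under rigid motions
# to machine precision, and well-separated fragments are tessellated
# exactly as they would be alone.

#' Deterministic equal-weight tessellation of the unit sphere
#'
#' Generates \code{n_points} approximately uniform directions by the
#' Fibonacci (golden-angle) lattice. Every point carries the same area
#' weight \code{4*pi/n_points}; the construction is fully deterministic.
#'
#' @param n_points Number of surface points, at least 12.
#' @return List with \code{points} (n x 3 unit vectors) and \code{weights}
#'   (length n, summing to \code{4*pi}).
#' @examples
#' t <- tessellate_unit_sphere(32)
#' sum(t$weights)  # 4*pi
#' @export
tessellate_unit_sphere <- function(n_points) {
  if (!is.numeric(n_points) || n_points < 12)
    stop("n_points must be at least 12")
  n <- as.integer(n_points)
  k <- seq_len(n) - 1L
  golden <- pi * (3 - sqrt(5))
  z <- 1 - (2 * k + 1) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * k
  pts <- cbind(rho * cos(theta), rho * sin(theta), z)
  list(points = pts, weights = rep(4 * pi / n, n))
}

# Connected components of the sphere-overlap graph (spheres overlap when
# their centers are closer than the sum of their radii).
overlap_components <- function(coords, radii) {
  n <- nrow(coords)
  comp <- seq_len(n)
  if (n > 1) {
    d <- as.matrix(dist(coords))
    thr <- outer(radii, radii, "+")
    adj <- d < thr
    repeat {
      new <- comp
      for (a in seq_len(n)) new[a] <- min(comp[adj[a, ]])
      if (identical(new, comp)) break
      comp <- new
    }
  }
  match(comp, unique(comp))
}

# Canonical right-handed-agnostic frame for one atom cluster: columns are
# orthonormal axes; the tessellation pole (unit z) maps to the leading
# principal axis, so axially symmetric clusters are tessellated
# symmetrically about their own axis. Axis signs are fixed by the first
# non-vanishing of: weighted third geometric moment, charge first moment,
# atom-index first moment. Equivariant under rigid motions and
# reflections of the cluster.
canonical_frame <- function(coords, w, q) {
  n <- nrow(coords)
  if (n == 1) return(diag(3))
  c0 <- colSums(coords * w) / sum(w)
  X <- sweep(coords, 2, c0)
  C <- crossprod(X * sqrt(w))
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors
  scale <- sqrt(max(e$values[1], 1e-30))
  for (k in 1:3) {
    pr <- as.vector(X %*% V[, k]) / scale
    m <- sum(w * pr^3) / sum(w)
    if (abs(m) <= 1e-9) m <- sum(q * pr)
    if (abs(m) <= 1e-9) m <- sum(seq_len(n) * pr) / n
    if (m < 0) V[, k] <- -V[, k]
  }
  V[, c(2, 3, 1), drop = FALSE]
}

#' Build the tessellated van der Waals cavity surface
#'
#' Each atom contributes a sphere of its van der Waals radius tessellated
#' at \code{n_points} points with equal areas \code{4*pi*R^2/n_points},
#' oriented along the canonical frame of the atom's overlap cluster.
#' Points falling inside any other atom's sphere (more than \code{1e-9}
#' Angstrom below its surface) are discarded. Surviving points from
#' different spheres can still crowd along seams and make the
#' electrostatic kernel near-singular (an off-diagonal Coulomb entry
#' exceeding the self-interaction diagonal destroys positive
#' definiteness), so points closer than half the local tessera linear
#' size \code{sqrt(4*pi)*R/sqrt(n_points)} (never less than 0.1 Angstrom)
#' are merged: areas summed, position area-averaged and re-projected onto
#' the owner sphere of the larger-area point.
#'
#' @param s A \code{\link{solute}}.
#' @param params A \code{\link{default_parameters}} object supplying radii.
#' @param n_points Tesserae per atom (default 32).
#' @return Object of class \code{"cavity_surface"}: \code{points} (M x 3,
#'   Angstrom), \code{areas} (A^2), \code{owner} (atom index per point),
#'   \code{normals} (unit outward), \code{per_atom_area} (length-N vector
#'   \code{S_A}), \code{total_area}, \code{volume} (A^3), \code{M}.
#' @examples
#' s <- make_born_ion("O", 0)
#' cav <- build_cavity(s)
#' c(cav$M, cav$total_area, cav$volume)
#' @export
build_cavity <- function(s, params = default_parameters(), n_points = 32) {
  stopifnot(inherits(s, "solute"))
  radii <- vapply(s$elements, function(e) vdw_radius(params, e), 0)
  n_atoms <- length(radii)
  tess <- tessellate_unit_sphere(n_points)

  comp <- overlap_components(s$coords, radii)
  zw <- symbol_to_atomic_number(s$elements)
  frames <- lapply(seq_len(max(comp)), function(cc) {
    idx <- comp == cc
    canonical_frame(s$coords[idx, , drop = FALSE], zw[idx], s$charges[idx])
  })

  pts_list <- vector("list", n_atoms)
  for (a in seq_len(n_atoms)) {
    u <- tess$points %*% t(frames[[comp[a]]])
    p <- sweep(u * radii[a], 2, s$coords[a, ], "+")
    keep <- rep(TRUE, nrow(p))
    for (b in seq_len(n_atoms)[-a]) {
      d2 <- (p[, 1] - s$coords[b, 1])^2 + (p[, 2] - s$coords[b, 2])^2 +
        (p[, 3] - s$coords[b, 3])^2
      keep <- keep & d2 >= (radii[b] - 1e-9)^2
      if (!any(keep)) break
    }
    if (any(keep)) {
      pts_list[[a]] <- list(p = p[keep, , drop = FALSE],
                            s = rep(4 * pi * radii[a]^2 / n_points,
                                    sum(keep)),
                            o = rep(a, sum(keep)))
    }
  }
  pts_list <- pts_list[!vapply(pts_list, is.null, TRUE)]
  if (!length(pts_list))
    stop("empty cavity surface: every tessellation point is buried")
  pts <- do.call(rbind, lapply(pts_list, `[[`, "p"))
  areas <- unlist(lapply(pts_list, `[[`, "s"))
  owner <- unlist(lapply(pts_list, `[[`, "o"))

  lsize <- sqrt(4 * pi) * radii[owner] / sqrt(n_points)
  merged <- merge_seam_points(pts, areas, owner, s$coords, radii,
                              pmax(0.1, 0.5 * lsize))
  pts <- merged$pts; areas <- merged$areas; owner <- merged$owner

  normals <- (pts - s$coords[owner, , drop = FALSE]) / radii[owner]
  # re-normalize: merged points were re-projected, guard roundoff
  normals <- normals / sqrt(rowSums(normals^2))

  per_atom <- vapply(seq_len(n_atoms),
                     function(a) sum(areas[owner == a]), 0)

  # divergence-theorem volume, evaluated per overlap cluster about the
  # cluster centroid: exactly invariant under rigid motions and exactly
  # additive over well-separated clusters
  volume <- 0
  pcomp <- comp[owner]
  for (cc in seq_len(max(comp))) {
    sel <- pcomp == cc
    ctr <- colMeans(s$coords[comp == cc, , drop = FALSE])
    rel <- sweep(pts[sel, , drop = FALSE], 2, ctr)
    volume <- volume +
      sum(areas[sel] * rowSums(rel * normals[sel, , drop = FALSE])) / 3
  }

  structure(list(points = pts, areas = areas, owner = owner,
                 normals = normals, per_atom_area = per_atom,
                 total_area = sum(areas), volume = volume,
                 M = nrow(pts), radii = radii, centers = s$coords),
            class = "cavity_surface")
}

# Greedy pairwise merge of surface points closer than their pairwise
# threshold min(min_sep_i, min_sep_j). The merged point takes the summed
# area, the area-weighted average position re-projected onto the sphere of
# the larger-area point's owner, and that owner. min_sep is fixed per
# point at its native tessera size, so merging cannot cascade.
merge_seam_points <- function(pts, areas, owner, centers, radii, min_sep) {
  repeat {
    if (nrow(pts) < 2) break
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
    thr <- outer(min_sep, min_sep, pmin)
    rel <- d / thr
    mn <- which.min(rel)
    if (rel[mn] >= 1) break
    ij <- arrayInd(mn, dim(d))
    i <- ij[1]; j <- ij[2]
    if (areas[j] > areas[i]) { tmp <- i; i <- j; j <- tmp }
    w <- c(areas[i], areas[j]) / (areas[i] + areas[j])
    pos <- w[1] * pts[i, ] + w[2] * pts[j, ]
    a <- owner[i]
    dir <- pos - centers[a, ]
    pos <- centers[a, ] + dir / sqrt(sum(dir^2)) * radii[a]
    pts[i, ] <- pos
    areas[i] <- areas[i] + areas[j]
    pts <- pts[-j, , drop = FALSE]
    areas <- areas[-j]
    owner <- owner[-j]
    min_sep <- min_sep[-j]
  }
  list(pts = pts, areas = areas, owner = owner)
}

#' Cavity volume by the divergence theorem
#'
#' \deqn{V = \frac{1}{3}\sum_i S_i\,(r_i - c)\cdot n_i} accumulated per
#' overlap cluster with \code{c} the cluster's atom centroid, so the
#' discrete sum is exactly invariant under rigid motions and exactly
#' additive over separated fragments.
#'
#' @param cav A \code{\link{build_cavity}} surface.
#' @return Volume in Angstrom^3.
#' @export
cavity_volume <- function(cav) {
  stopifnot(inherits(cav, "cavity_surface"))
  cav$volume
}

#' @export
print.cavity_surface <- function(x, ...) {
  cat(sprintf(
    "Cavity surface: %d points over %d atoms, S = %.3f A^2, V = %.3f A^3\n",
    x$M, length(x$per_atom_area), x$total_area, x$volume))
  invisible(x)
}

#' Dump a cavity surface as a plain-text debug file
#'
#' One line per surface point: owner atom index, position, area, outward
#' normal. Intended for visualization and debugging.
#'
#' @param cav A \code{\link{build_cavity}} surface.
#' @param file Output path.
#' @export
write_surface <- function(cav, file) {
  stopifnot(inherits(cav, "cavity_surface"))
  lines <- c(
    sprintf("# cavity surface: M=%d S=%.6f V=%.6f", cav$M, cav$total_area,
            cav$volume),
    "# owner x y z area nx ny nz",
    sprintf("%d %12.6f %12.6f %12.6f %12.6f %9.6f %9.6f %9.6f",
            cav$owner, cav$points[, 1], cav$points[, 2], cav$points[, 3],
            cav$areas, cav$normals[, 1], cav$normals[, 2], cav$normals[, 3]))
  writeLines(lines, file)
  invisible(file)
}
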