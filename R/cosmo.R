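# Noniterative COSMO electrostatics: assemble the surface self-interaction
# matrix A and the surface-nucleus matrix B, solve Aq = -BQ once in the
# conductor limit, and scale energies and charges by the Born dielectric
# factor 1 - 1/eps.

#' Assemble the COSMO interaction matrices
#'
#' \code{A} is the M x M surface self-interaction matrix with Coulomb
#' off-diagonals \code{1/|r_i - r_j|} and the Klamt-Schuurmann
#' self-energy diagonal \code{diag_const * sqrt(4*pi/S_i)}; \code{B} is
#' the M x N surface-nucleus kernel \code{1/|r_i - R_A|}. All entries in
#' Angstrom^-1.
#'
#' @param s A \code{\link{solute}}.
#' @param cav The \code{\link{build_cavity}} surface built from \code{s}.
#' @param diag_const Self-interaction constant (default 1.07).
#' @return Object of class \code{"cosmo_system"} with fields \code{A},
#'   \code{B}.
#' @export
build_system <- function(s, cav, diag_const = 1.07) {
  stopifnot(inherits(s, "solute"), inherits(cav, "cavity_surface"))
  M <- cav$M
  A <- 1 / as.matrix(dist(cav$points))
  if (M > 1 && any(!is.finite(A[upper.tri(A)])))
    stop("coincident surface points produce a singular kernel; ",
         "rebuild the cavity")
  diag(A) <- diag_const * sqrt(4 * pi / cav$areas)
  n_atoms <- nrow(s$coords)
  B <- matrix(0, M, n_atoms)
  for (a in seq_len(n_atoms)) {
    d <- sqrt((cav$points[, 1] - s$coords[a, 1])^2 +
              (cav$points[, 2] - s$coords[a, 2])^2 +
              (cav$points[, 3] - s$coords[a, 3])^2)
    B[, a] <- 1 / d
  }
  structure(list(A = A, B = B, M = M, n_atoms = n_atoms),
            class = "cosmo_system")
}

#' Solve for the induced surface charges
#'
#' Solves the working equation \code{A q = -B Q} for the conductor-limit
#' surface charges by a dense symmetric positive-definite factorization.
#' The dielectric enters only as the scale factor \code{f = 1 - 1/eps}
#' applied to charges and energies, so the vacuum limit \code{eps -> 1} is
#' exact. The per-atom induced charges \code{q_A} aggregate the scaled
#' (physically induced) charges over each atom's surface patch.
#'
#' @param sys A \code{\link{build_system}} object.
#' @param s The solute the system was built from.
#' @param eps Solvent dielectric constant, > 1.
#' @param owner Owner map of the cavity the system was built on.
#' @return Object of class \code{"cosmo_solution"}: \code{q}
#'   (conductor-limit charges, e), \code{q_atom} (scaled per-atom induced
#'   charges, e), \code{scale}, \code{eps}.
#' @export
solve_surface_charges <- function(sys, s, eps, owner) {
  stopifnot(inherits(sys, "cosmo_system"), inherits(s, "solute"))
  if (!is.numeric(eps) || eps <= 1)
    stop("dielectric constant must exceed 1")
  rhs <- -as.vector(sys$B %*% s$charges)
  ch <- tryCatch(chol(sys$A), error = function(e)
    stop("COSMO matrix is not positive definite (", conditionMessage(e),
         "); raise n_points or check the geometry"))
  q <- backsolve(ch, forwardsolve(t(ch), rhs))
  scale <- 1 - 1 / eps
  q_atom <- vapply(seq_len(sys$n_atoms),
                   function(a) scale * sum(q[owner == a]), 0)
  structure(list(q = q, q_atom = q_atom, scale = scale, eps = eps),
            class = "cosmo_solution")
}

#' Electrostatic solvation energy
#'
#' \deqn{E_{elst} = (1 - 1/\varepsilon)\,\tfrac12\,k_e\, q^T B Q}
#' with \code{q} the conductor-limit surface charges and \code{k_e} the
#' Coulomb constant \code{\link{COULOMB_KCAL}}. Because \code{Aq = -BQ},
#' this equals \code{-(1 - 1/eps) * k_e/2 * q' A q} and is non-positive
#' for any nonzero charge distribution.
#'
#' @param sys A \code{\link{build_system}} object.
#' @param sol The matching \code{\link{solve_surface_charges}} solution.
#' @param s The solute.
#' @param eps Dielectric constant used in the solve.
#' @return Energy in kcal/mol.
#' @export
electrostatic_energy <- function(sys, sol, s, eps) {
  stopifnot(inherits(sys, "cosmo_system"), inherits(sol, "cosmo_solution"))
  if (length(sol$q) != sys$M)
    stop("solution and system dimensions disagree")
  (1 - 1 / eps) * 0.5 * COULOMB_KCAL *
    sum(sol$q * as.vector(sys$B %*% s$charges))
}
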