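# Seed-deterministic synthetic inputs: Born ions, random toy solutes,
# mock quantum-chemistry output texts, and generative training sets that
# close the loop for the parameter fit. No external files, no network.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Single-atom ion fixture
#'
#' One atom at the origin carrying an integer charge: the discretized
#' analogue of the Born ion, for which the electrostatic energy has the
#' closed form \code{\link{born_energy_oracle}}.
#'
#' @param element Element symbol (must have a van der Waals radius).
#' @param charge Integer charge, e.
#' @param name Label.
#' @return A \code{\link{solute}}.
#' @export
make_born_ion <- function(element, charge, name = paste0(element, charge)) {
  solute(element, matrix(0, 1, 3), charges = charge, total_charge = charge,
         name = name)
}

#' Closed-form Born solvation energy
#'
#' \deqn{E = -(1 - 1/\varepsilon)\, k_e\, Q^2 / (2R)} for a point charge
#' \code{Q} centered in a spherical cavity of radius \code{R} — the
#' continuum limit the discretized solver must approach for a single-atom
#' ion.
#'
#' @param Q Charge, e.
#' @param R Cavity radius, Angstrom.
#' @param eps Dielectric constant.
#' @return Energy in kcal/mol.
#' @export
born_energy_oracle <- function(Q, R, eps) {
  -(1 - 1 / eps) * COULOMB_KCAL * Q^2 / (2 * R)
}

#' Reproducible random toy solute
#'
#' Atoms are placed sequentially: each new atom sits 1.0-1.8 Angstrom from
#' a randomly chosen earlier atom in a random direction, rejecting
#' placements that bring any pair closer than 1.0 Angstrom, which yields
#' compact bonded-like clusters. Partial charges are drawn uniformly and
#' shifted so they sum exactly to \code{total_charge}. The same seed always
#' produces the same solute.
#'
#' @param n_atoms Number of atoms.
#' @param seed Integer seed.
#' @param total_charge Integer total charge (default 0).
#' @param elements Pool of element symbols to draw from.
#' @return A \code{\link{solute}}.
#' @export
make_random_solute <- function(n_atoms, seed, total_charge = 0L,
                               elements = c("H", "C", "N", "O")) {
  stopifnot(n_atoms >= 1)
  with_seed(seed, {
    els <- sample(elements, n_atoms, replace = TRUE)
    coords <- matrix(0, n_atoms, 3)
    if (n_atoms > 1) {
      for (i in 2:n_atoms) {
        repeat {
          anchor <- coords[sample.int(i - 1, 1), ]
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- anchor + stats::runif(1, 1.0, 1.8) * u
          d <- sqrt(colSums((t(coords[1:(i - 1), , drop = FALSE]) - cand)^2))
          if (all(d >= 1.0)) break
        }
        coords[i, ] <- cand
      }
    }
    q <- stats::runif(n_atoms, -0.5, 0.5)
    q <- q - (sum(q) - total_charge) / n_atoms
    solute(els, coords, q, total_charge,
           name = sprintf("random-%d-%d", n_atoms, seed))
  })
}

#' Mock MOPAC output text for a solute
#'
#' Emits the blocks \code{\link{parse_mopac_output}} reads — a
#' \code{CHARGE ON SYSTEM} header, a final \code{CARTESIAN COORDINATES}
#' block and a \code{NET ATOMIC CHARGES} table — carrying exactly the
#' numbers of \code{s}, so parser tests are exact to print precision.
#'
#' @param s A \code{\link{solute}}.
#' @return Character vector of lines.
#' @export
make_mopac_text <- function(s) {
  stopifnot(inherits(s, "solute"))
  n <- length(s$elements)
  c(" *******************************************************************",
    " **                     MOPAC (mock output)                       **",
    " *******************************************************************",
    sprintf(" *  CHARGE ON SYSTEM = %+d", s$total_charge),
    "",
    "          CARTESIAN COORDINATES",
    "",
    "    NO.       ATOM           X           Y           Z",
    "",
    sprintf("   %3d       %-2s    %12.6f %12.6f %12.6f", seq_len(n),
            s$elements, s$coords[, 1], s$coords[, 2], s$coords[, 3]),
    "",
    "          NET ATOMIC CHARGES AND DIPOLE CONTRIBUTIONS",
    "",
    "  ATOM NO.   TYPE          CHARGE      No. of ELECS.",
    sprintf("  %3d          %-2s    %12.6f        %8.4f", seq_len(n),
            s$elements, s$charges,
            symbol_to_atomic_number(s$elements) - s$charges),
    "",
    " == MOPAC DONE ==")
}

#' Mock Gaussian log text for a solute
#'
#' Emits a charge/multiplicity line, a \code{Standard orientation} block
#' and a \code{Mulliken charges} table with exactly the numbers of
#' \code{s}, matching what \code{\link{parse_gaussian_output}} expects.
#'
#' @param s A \code{\link{solute}}.
#' @return Character vector of lines.
#' @export
make_gaussian_text <- function(s) {
  stopifnot(inherits(s, "solute"))
  n <- length(s$elements)
  z <- symbol_to_atomic_number(s$elements)
  c(" Entering Gaussian System (mock output)",
    sprintf(" Charge = %2d Multiplicity = 1", s$total_charge),
    "                         Standard orientation:",
    " ---------------------------------------------------------------------",
    " Center     Atomic      Atomic             Coordinates (Angstroms)",
    " Number     Number       Type             X           Y           Z",
    " ---------------------------------------------------------------------",
    sprintf(" %6d %10d %11d    %11.6f %11.6f %11.6f", seq_len(n), z, 0L,
            s$coords[, 1], s$coords[, 2], s$coords[, 3]),
    " ---------------------------------------------------------------------",
    " Mulliken charges:",
    "               1",
    sprintf(" %5d  %-2s  %9.6f", seq_len(n), s$elements, s$charges),
    sprintf(" Sum of Mulliken charges = %9.5f", sum(s$charges)),
    " Normal termination of Gaussian (mock).")
}

# Feature row for one (solute, dielectric) record: runs the real cavity
# and COSMO stages and aggregates per-element areas and induced charges.
solute_features <- function(s, eps, params, n_points = 32,
                            elements = NULL) {
  cav <- build_cavity(s, params, n_points)
  sys <- build_system(s, cav)
  sol <- solve_surface_charges(sys, s, eps, cav$owner)
  e_elst <- electrostatic_energy(sys, sol, s, eps)
  if (is.null(elements)) elements <- sort(unique(s$elements))
  feat <- data.frame(e_elst = e_elst, volume = cav$volume)
  for (el in elements) {
    sel <- s$elements == el
    feat[[paste0("S_", el)]] <- sum(cav$per_atom_area[sel])
    feat[[paste0("q_", el)]] <- sum(sol$q_atom[sel])
  }
  feat$total_area <- cav$total_area
  feat
}

#' Generative synthetic training set for the parameter fit
#'
#' Draws random toy solutes, runs the real cavity and COSMO stages to get
#' their features, and produces reference energies
#' \code{dg_ref = e_elst + dg_corr(p_true) + noise}, making parameter
#' recovery a closed loop: with zero noise the weighted least-squares fit
#' must return the planted coefficients of \code{p_true} exactly.
#'
#' @param p_true Parameter set whose class-\code{cls} coefficients generate
#'   the references.
#' @param n Number of training rows.
#' @param noise_sd Gaussian noise on \code{dg_ref}, kcal/mol.
#' @param seed Integer seed; fixed seed gives an identical table.
#' @param cls Solvent class whose parameters are planted (default "B").
#' @param eps_set Dielectric constants to cycle over, one subset label per
#'   value.
#' @param elements Element pool for the random solutes.
#' @param n_points Tesserae per atom for the feature computation.
#' @return Training data frame for \code{\link{solv_fit}} with attribute
#'   \code{"true"}: the planted coefficient vector in fit order.
#' @export
make_synthetic_training <- function(p_true, n, noise_sd, seed, cls = "B",
                                    eps_set = c(32.61, 24.85, 19.26),
                                    elements = c("H", "C", "N", "O"),
                                    n_points = 32) {
  stopifnot(inherits(p_true, "solv_parameters"), n >= 1)
  rows <- with_seed(seed, {
    sizes <- sample(2:5, n, replace = TRUE)
    totals <- sample(c(-1L, 0L, 0L, 0L, 1L), n, replace = TRUE)
    sub_seeds <- sample.int(2^30, n)
    noise <- stats::rnorm(n, 0, noise_sd)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      s <- make_random_solute(sizes[i], sub_seeds[i], totals[i], elements)
      k <- ((i - 1) %% length(eps_set)) + 1
      feat <- solute_features(s, eps_set[k], p_true, n_points, elements)
      kap <- p_true$kappa[cls, elements]
      gg <- p_true$g[cls, elements]
      s_feat <- as.numeric(feat[paste0("S_", elements)])
      q_feat <- as.numeric(feat[paste0("q_", elements)])
      dg_corr <- unname(p_true$zeta[cls]) * feat$volume +
        sum(kap * s_feat) + sum(gg * q_feat)
      out[[i]] <- cbind(
        data.frame(id = s$name, subset = k, weight = 1,
                   charge_state = totals[i],
                   dg_ref = feat$e_elst + dg_corr + noise[i]),
        feat)
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  true <- c(p_true$kappa[cls, elements], p_true$g[cls, elements],
            unname(p_true$zeta[cls]))
  names(true) <- c(paste0("kappa_", elements), paste0("g_", elements),
                   "zeta")
  attr(rows, "true") <- true
  rows
}
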