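# Nonelectrostatic correction: a linear combination of cavity volume,
# per-element surface areas and per-element induced atomic charges, with
# an optional solvent-specific surface shift for classes C and D.

#' Nonelectrostatic correction energy
#'
#' For solvent classes A and B:
#' \deqn{\Delta G_{corr} = \zeta V + \sum_A \kappa_A S_A + \sum_A g_A q_A}
#' and for classes C and D additionally the solvent shift
#' \eqn{\xi_{solv} \sum_A S_A}. Here \eqn{V} is the cavity volume
#' (Angstrom^3), \eqn{S_A} the exposed area of atom A (Angstrom^2) and
#' \eqn{q_A} the induced (dielectric-scaled) surface charge on atom A's
#' patch, so the charge term vanishes in the vacuum limit. The area term
#' models cavitation plus dispersion; the volume term implicitly accounts
#' for solute polarization.
#'
#' @param p A \code{\link{default_parameters}} object.
#' @param solvent A \code{\link{solvent_spec}}.
#' @param cav The \code{\link{build_cavity}} surface.
#' @param sol The \code{\link{solve_surface_charges}} solution.
#' @param s The solute.
#' @return List with \code{dg_corr} (kcal/mol) and \code{components}, a
#'   named numeric vector of the zeta*V, kappa*S, g*q and xi*S terms.
#' @export
correction_energy <- function(p, solvent, cav, sol, s) {
  stopifnot(inherits(p, "solv_parameters"),
            inherits(solvent, "solvent_spec"),
            inherits(cav, "cavity_surface"),
            inherits(sol, "cosmo_solution"),
            inherits(s, "solute"))
  cls <- solvent$cls
  coef <- lapply(s$elements, function(e) lookup_params(p, cls, e))
  kap <- vapply(coef, `[[`, 0, "kappa")
  gg <- vapply(coef, `[[`, 0, "g")
  zeta_v <- unname(p$zeta[cls]) * cav$volume
  kappa_s <- sum(kap * cav$per_atom_area)
  g_q <- sum(gg * sol$q_atom)
  xi_s <- if (cls %in% c("C", "D")) solvent$xi * cav$total_area else 0
  components <- c(zeta_v = zeta_v, kappa_s = kappa_s, g_q = g_q, xi_s = xi_s)
  list(dg_corr = sum(components), components = components)
}
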