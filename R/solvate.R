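# End-to-end driver: cavity -> COSMO solve -> electrostatic energy ->
# nonelectrostatic correction -> total standard-state solvation free energy.

#' Standard-state solvation free energy of a solute
#'
#' Runs the full pipeline: builds the van der Waals cavity, solves the
#' conductor-limit COSMO equation for the induced surface charges, scales
#' by the Born factor \code{1 - 1/eps}, and adds the class-specific linear
#' correction. Deterministic: repeated calls give identical results.
#'
#' @param s A \code{\link{solute}} (or a file path readable by
#'   \code{\link{read_solute}}).
#' @param solvent A \code{\link{solvent_spec}} or a solvent name.
#' @param params Parameter set (default the shipped one).
#' @param n_points Tesserae per atom (default 32).
#' @param diag_const COSMO self-interaction constant (default 1.07).
#' @return Object of class \code{"solvation_result"} with fields
#'   \code{e_elst}, \code{dg_corr}, \code{dg_solv} (all kcal/mol),
#'   \code{terms} (correction components), \code{M}, \code{total_area},
#'   \code{volume}, \code{q_atom}, \code{solute}, \code{solvent}.
#' @examples
#' s <- make_born_ion("O", -1)
#' r <- solvation_free_energy(s, "water")
#' r
#' @export
solvation_free_energy <- function(s, solvent, params = default_parameters(),
                                  n_points = 32, diag_const = 1.07) {
  if (is.character(s)) s <- read_solute(s)
  if (is.character(solvent)) solvent <- solvent_spec(solvent)
  stopifnot(inherits(s, "solute"), inherits(solvent, "solvent_spec"))

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(what, " stage failed for '", s$name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  cav <- stage("cavity", build_cavity(s, params, n_points))
  sys <- stage("cosmo-assembly", build_system(s, cav, diag_const))
  sol <- stage("cosmo-solve",
               solve_surface_charges(sys, s, solvent$eps, cav$owner))
  e_elst <- stage("electrostatics",
                  electrostatic_energy(sys, sol, s, solvent$eps))
  corr <- stage("correction",
                correction_energy(params, solvent, cav, sol, s))

  structure(list(
    e_elst = e_elst,
    dg_corr = corr$dg_corr,
    dg_solv = e_elst + corr$dg_corr,
    terms = corr$components,
    M = cav$M, total_area = cav$total_area, volume = cav$volume,
    q_atom = sol$q_atom,
    solute = s$name, solvent = solvent),
    class = "solvation_result")
}

#' @export
print.solvation_result <- function(x, ...) {
  cat(sprintf("Solvation of '%s' in %s (class %s, eps = %g)\n",
              x$solute, x$solvent$name, x$solvent$cls, x$solvent$eps))
  cat(sprintf("  surface: M = %d points, S = %.3f A^2, V = %.3f A^3\n",
              x$M, x$total_area, x$volume))
  cat(sprintf("  E_elst   = %10.4f kcal/mol\n", x$e_elst))
  cat(sprintf("  dG_corr  = %10.4f kcal/mol  (zeta*V %.4f, kappa*S %.4f, g*q %.4f, xi*S %.4f)\n",
              x$dg_corr, x$terms[["zeta_v"]], x$terms[["kappa_s"]],
              x$terms[["g_q"]], x$terms[["xi_s"]]))
  cat(sprintf("  dG_solv  = %10.4f kcal/mol\n", x$dg_solv))
  invisible(x)
}

#' @export
as.data.frame.solvation_result <- function(x, ...) {
  data.frame(solute = x$solute, solvent = x$solvent$name,
             class = x$solvent$cls, eps = x$solvent$eps,
             e_elst = x$e_elst, dg_corr = x$dg_corr, dg_solv = x$dg_solv,
             term_zeta_v = x$terms[["zeta_v"]],
             term_kappa_s = x$terms[["kappa_s"]],
             term_g_q = x$terms[["g_q"]],
             term_xi_s = x$terms[["xi_s"]],
             area = x$total_area, volume = x$volume, n_surface = x$M)
}

#' Batch solvation free energies over input files
#'
#' Evaluates \code{\link{solvation_free_energy}} for each input file.
#' Failures are reported per file in the \code{error} column without
#' aborting the batch; row order follows the input order.
#'
#' @param files Character vector of input paths.
#' @param solvent A \code{\link{solvent_spec}} or solvent name.
#' @param format Input format passed to \code{\link{read_solute}}.
#' @param ... Further arguments to \code{\link{solvation_free_energy}}.
#' @return Data frame with one row per file (energies in kcal/mol);
#'   attribute \code{"n_failed"} counts failures.
#' @export
run_batch <- function(files, solvent, format = "auto", ...) {
  if (!length(files)) stop("empty input list")
  if (is.character(solvent)) solvent <- solvent_spec(solvent)
  rows <- lapply(files, function(f) {
    tryCatch({
      s <- read_solute(f, format)
      df <- as.data.frame(solvation_free_energy(s, solvent, ...))
      df$file <- f
      df$error <- NA_character_
      df
    }, error = function(e) {
      data.frame(solute = NA, solvent = solvent$name, class = solvent$cls,
                 eps = solvent$eps, e_elst = NA_real_, dg_corr = NA_real_,
                 dg_solv = NA_real_, term_zeta_v = NA_real_,
                 term_kappa_s = NA_real_, term_g_q = NA_real_,
                 term_xi_s = NA_real_, area = NA_real_, volume = NA_real_,
                 n_surface = NA_integer_, file = f,
                 error = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failed") <- sum(!is.na(out$error))
  out
}
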