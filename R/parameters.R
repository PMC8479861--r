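# Model parameters: van der Waals radii shared by all solvents, and
# per-solvent-class surface (kappa), charge (g) and volume (zeta) coefficients.

#' Elements covered by the shipped parameter set
#'
#' The nine main-group elements for which cavity radii and correction
#' coefficients are available: H, C, N, O, F, S, Cl, Br, I.
#'
#' @format Character vector of element symbols.
#' @export
SOLV_ELEMENTS <- c("H", "C", "N", "O", "F", "S", "Cl", "Br", "I")

#' Coulomb constant in kcal * Angstrom / (mol * e^2)
#'
#' Conversion factor between charge-pair interactions in elementary charges
#' and Angstroms and energies in kcal/mol (CODATA-consistent).
#'
#' @export
COULOMB_KCAL <- 332.0637

#' Default model parameter set
#'
#' Returns the shipped parameterization: one set of modified Bondi van der
#' Waals radii used for every solvent, and per-class coefficients for the
#' nonelectrostatic correction
#' \deqn{\Delta G_{corr} = \zeta V + \sum_A \kappa_A S_A + \sum_A g_A q_A
#'       (+ \xi_{solv} S).}
#' Solvent classes are \code{"A"} (water), \code{"B"} (polar protic),
#' \code{"C"} (polar aprotic) and \code{"D"} (nonpolar, dielectric constant
#' below 9). Class C carries no iodine parameters.
#'
#' @return An object of class \code{"solv_parameters"}: a list with
#'   \item{radii}{named numeric vector, Angstrom, element -> vdW radius}
#'   \item{zeta}{named numeric vector, kcal/(mol A^3), one entry per class}
#'   \item{kappa}{4 x 9 matrix (class x element), kcal/(mol A^2)}
#'   \item{g}{4 x 9 matrix (class x element), kcal/mol; \code{NA} where a
#'     class/element pair is not parameterized}
#' @examples
#' p <- default_parameters()
#' p$radii[["O"]]
#' lookup_params(p, "A", "H")
#' @export
default_parameters <- function() {
  el <- SOLV_ELEMENTS
  radii <- c(0.90, 1.80, 1.96, 1.52, 1.47, 2.34, 1.75, 1.85, 1.98)
  names(radii) <- el
  zeta <- c(A = 0, B = -0.076, C = -0.178, D = -0.129)
  kappa <- rbind(
    A = c(0.124, 0.057, -0.036, 0.070, 0.069, 0.038, -0.016, -0.047, -0.066),
    B = c(0.037, 0.097, 0.017, -0.014, 0.075, 0.076, 0.008, -0.034, -0.031),
    C = c(-0.119, 0.165, 0.148, -0.074, 0.053, 0.129, 0.010, 0.012, NA),
    D = c(-0.133, 0.098, 0.082, -0.065, 0.057, 0.106, 0.061, 0.048, 0.052))
  g <- rbind(
    A = c(10.0, -4.47, 6.28, 1.26, -3.67, -7.00, 14.0, 22.3, 26.9),
    B = c(3.45, -6.09, 6.71, 13.2, 4.87, -13.4, 16.3, 23.3, 17.7),
    C = c(-7.99, 8.88, 11.0, 32.8, 18.9, 18.5, 32.0, 33.0, NA),
    D = c(-39.4, -22.6, -17.2, -6.22, -10.3, -31.5, -21.8, -22.2, -29.3))
  colnames(kappa) <- colnames(g) <- el
  structure(list(radii = radii, zeta = zeta, kappa = kappa, g = g),
            class = "solv_parameters")
}

#' Look up correction coefficients for a solvent class and element
#'
#' @param p A \code{solv_parameters} object.
#' @param cls Solvent class, one of \code{"A"}, \code{"B"}, \code{"C"},
#'   \code{"D"}.
#' @param element Element symbol.
#' @return Named list with components \code{kappa} (kcal/(mol A^2)) and
#'   \code{g} (kcal/mol).
#' @export
lookup_params <- function(p, cls, element) {
  stopifnot(inherits(p, "solv_parameters"))
  if (!cls %in% rownames(p$kappa))
    stop("unknown solvent class '", cls, "'")
  if (!element %in% colnames(p$kappa))
    stop("element '", element, "' is not parameterized (class ", cls, ")")
  k <- p$kappa[cls, element]
  gg <- p$g[cls, element]
  if (is.na(k) || is.na(gg))
    stop("no parameters for element '", element, "' in solvent class ",
         cls)
  list(kappa = unname(k), g = unname(gg))
}

#' Van der Waals radius for an element
#'
#' @inheritParams lookup_params
#' @return Radius in Angstrom.
#' @export
vdw_radius <- function(p, element) {
  stopifnot(inherits(p, "solv_parameters"))
  if (!element %in% names(p$radii))
    stop("element '", element, "' has no van der Waals radius; ",
         "available: ", paste(names(p$radii), collapse = ", "))
  unname(p$radii[element])
}

#' @export
print.solv_parameters <- function(x, ...) {
  cat("Solvation model parameter set\n")
  cat("  elements:", paste(names(x$radii), collapse = " "), "\n")
  cat("  radii (A):", paste(format(x$radii, nsmall = 2), collapse = " "), "\n")
  cat("  zeta (kcal/mol/A^3):",
      paste(names(x$zeta), format(x$zeta), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write a parameter set as a tabular text file
#'
#' Layout mirrors the shipped table: one radii row, then per class a zeta
#' header line and kappa/g rows. Read back with
#' \code{\link{read_parameters}}; the round trip is exact.
#'
#' @param p A \code{solv_parameters} object.
#' @param file Output path.
#' @export
write_parameters <- function(p, file) {
  stopifnot(inherits(p, "solv_parameters"))
  con <- file(file, "w")
  on.exit(close(con))
  el <- names(p$radii)
  writeLines(paste(c("param", el), collapse = "\t"), con)
  writeLines(paste(c("RvdW", format(p$radii, trim = TRUE)), collapse = "\t"),
             con)
  for (cls in rownames(p$kappa)) {
    writeLines(sprintf("class\t%s\tzeta\t%s", cls,
                       format(p$zeta[cls], trim = TRUE)), con)
    writeLines(paste(c(paste0("kappa_", cls),
                       format(p$kappa[cls, ], trim = TRUE)), collapse = "\t"),
               con)
    writeLines(paste(c(paste0("g_", cls),
                       format(p$g[cls, ], trim = TRUE)), collapse = "\t"), con)
  }
  invisible(file)
}

#' Read a parameter set from the tabular text format
#'
#' @param file Path written by \code{\link{write_parameters}}.
#' @return A \code{solv_parameters} object.
#' @export
read_parameters <- function(file) {
  lines <- readLines(file)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  el <- fields[[1]][-1]
  num <- function(x) suppressWarnings(as.numeric(x))
  radii <- num(fields[[2]][-1])
  names(radii) <- el
  zeta <- numeric(0)
  kappa <- g <- NULL
  i <- 3
  while (i <= length(fields)) {
    f <- fields[[i]]
    if (f[1] != "class") stop("malformed parameter file at line ", i)
    cls <- f[2]
    zeta[cls] <- num(f[4])
    kappa <- rbind(kappa, num(fields[[i + 1]][-1]))
    g <- rbind(g, num(fields[[i + 2]][-1]))
    rownames(kappa)[nrow(kappa)] <- rownames(g)[nrow(g)] <- cls
    i <- i + 3
  }
  colnames(kappa) <- colnames(g) <- el
  structure(list(radii = radii, zeta = zeta, kappa = kappa, g = g),
            class = "solv_parameters")
}
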