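# Solvent specifications and the built-in registry.
#
# Class A is water; class B the nonaqueous polar protic solvents (alcohols,
# phenols); class C the polar aprotic solvents; class D the nonpolar
# solvents, defined as those with dielectric constant below 9. Dielectric
# constants are standard literature values at 25 C; per-solvent surface
# shifts xi_solv default to 0 (omitting the shift costs little accuracy)
# and can be supplied through a config file or directly.

#' Construct a solvent specification
#'
#' Either give \code{name} to pull a solvent from the built-in registry
#' (see \code{\link{solvent_registry}}), or give \code{eps} and \code{cls}
#' explicitly for a solvent the registry does not know.
#'
#' @param name Solvent name (registry lookup, case-insensitive), or a free
#'   label when \code{eps}/\code{cls} are given explicitly.
#' @param eps Dielectric constant (> 1).
#' @param cls Solvent class \code{"A"}, \code{"B"}, \code{"C"} or \code{"D"}.
#' @param xi Solvent-specific surface shift xi_solv in kcal/(mol A^2),
#'   used only for classes C and D; default 0.
#' @param registry Registry data frame to look names up in.
#' @return Object of class \code{"solvent_spec"} with fields \code{name},
#'   \code{eps}, \code{cls}, \code{xi}.
#' @examples
#' solvent_spec("water")
#' solvent_spec("cyclopentane", eps = 1.96, cls = "D")
#' @export
solvent_spec <- function(name = NULL, eps = NULL, cls = NULL, xi = 0,
                         registry = solvent_registry()) {
  if (is.null(eps) || is.null(cls)) {
    if (is.null(name)) stop("give either a solvent name or eps + cls")
    key <- tolower(trimws(name))
    hit <- match(key, tolower(registry$name))
    if (is.na(hit)) {
      d <- utils::adist(key, tolower(registry$name))
      near <- registry$name[order(d)][seq_len(min(3, nrow(registry)))]
      stop("unknown solvent '", name, "'; nearest matches: ",
           paste(near, collapse = ", "))
    }
    eps <- registry$eps[hit]
    cls <- registry$cls[hit]
    if (missing(xi)) xi <- registry$xi[hit]
    name <- registry$name[hit]
  }
  cls <- toupper(cls)
  if (!cls %in% c("A", "B", "C", "D"))
    stop("solvent class must be one of A, B, C, D")
  if (!is.numeric(eps) || eps <= 1)
    stop("dielectric constant must exceed 1")
  if (cls == "A") {
    if (tolower(name) != "water")
      stop("class A is reserved for water")
    if (xi != 0) stop("water takes no xi_solv shift")
  }
  if (cls == "D" && eps >= 9)
    stop("class D (nonpolar) requires a dielectric constant below 9, got ",
         eps)
  structure(list(name = name, eps = eps, cls = cls, xi = xi),
            class = "solvent_spec")
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat(sprintf("Solvent: %s (class %s, eps = %g, xi = %g kcal/mol/A^2)\n",
              x$name, x$cls, x$eps, x$xi))
  invisible(x)
}

#' Built-in solvent registry
#'
#' Water plus the polar protic, polar aprotic and nonpolar solvents the
#' model was parameterized against, each with a literature dielectric
#' constant at 25 C and \code{xi = 0}. A plain-text config file can add or
#' override entries; its schema is one solvent per line,
#' \code{name : eps class [xi]}, with \code{#} comments ignored.
#'
#' @param config Optional path to an override config file.
#' @return Data frame with columns \code{name}, \code{eps}, \code{cls},
#'   \code{xi}.
#' @examples
#' r <- solvent_registry()
#' r[r$name == "dimethyl sulfoxide", ]
#' @export
solvent_registry <- function(config = NULL) {
  b <- function(name, eps) data.frame(name = name, eps = eps)
  protic <- rbind(
    b("methanol", 32.61), b("ethanol", 24.85), b("propanol", 20.52),
    b("isopropanol", 19.26), b("butanol", 17.33), b("isobutanol", 16.78),
    b("sec-butanol", 15.94), b("pentanol", 15.13), b("hexanol", 12.51),
    b("heptanol", 11.32), b("octanol", 9.86), b("benzyl alcohol", 12.46),
    b("m-cresol", 12.44), b("methoxyethanol", 17.20))
  aprotic <- rbind(
    b("acetonitrile", 35.69), b("dimethyl sulfoxide", 46.83),
    b("dimethylformamide", 37.22), b("dimethylacetamide", 37.78),
    b("nitromethane", 36.56), b("nitroethane", 28.29),
    b("nitrobenzene", 34.81), b("o-nitrotoluene", 25.67),
    b("benzonitrile", 25.59), b("acetophenone", 17.44),
    b("cyclohexanone", 15.62), b("butanone", 18.25),
    b("4-methyl-2-pentanone", 12.89), b("pyridine", 12.98),
    b("2-methylpyridine", 9.95), b("dichloroethane", 10.13),
    b("o-dichlorobenzene", 9.99), b("bromoethane", 9.01),
    b("sulfolane", 43.30), b("methylformamide", 181.56))
  nonpolar <- rbind(
    b("pentane", 1.84), b("hexane", 1.88), b("heptane", 1.91),
    b("octane", 1.94), b("isooctane", 1.94), b("nonane", 1.96),
    b("decane", 1.98), b("undecane", 1.99), b("dodecane", 2.01),
    b("pentadecane", 2.03), b("hexadecane", 2.04), b("cyclohexane", 2.02),
    b("decalin", 2.20), b("perfluorobenzene", 2.03),
    b("carbon tetrachloride", 2.23), b("isopropyltoluene", 2.23),
    b("mesitylene", 2.27), b("tetrachloroethene", 2.27), b("benzene", 2.27),
    b("sec-butylbenzene", 2.34), b("tert-butylbenzene", 2.34),
    b("butylbenzene", 2.36), b("trimethylbenzene", 2.37),
    b("isopropylbenzene", 2.37), b("toluene", 2.37),
    b("triethylamine", 2.38), b("xylene", 2.40), b("ethylbenzene", 2.43),
    b("carbon disulfide", 2.61), b("tetralin", 2.77),
    b("dibutyl ether", 3.05), b("diisopropyl ether", 3.38),
    b("hexadecyl iodide", 3.53), b("phenyl ether", 3.73),
    b("fluorooctane", 3.89), b("ethoxybenzene", 4.18), b("anisole", 4.22),
    b("diethyl ether", 4.24), b("bromoform", 4.25), b("iodobenzene", 4.55),
    b("chloroform", 4.71), b("dibromoethane", 4.93),
    b("butyl acetate", 4.99), b("bromooctane", 5.02),
    b("bromobenzene", 5.36), b("fluorobenzene", 5.42),
    b("chlorobenzene", 5.70), b("chlorohexane", 5.95),
    b("ethyl acetate", 5.99), b("acetic acid", 6.25), b("aniline", 6.89),
    b("dimethylpyridine", 7.17), b("tetrahydrofuran", 7.43),
    b("decanol", 7.53), b("tributyl phosphate", 8.18), b("nonanol", 8.60),
    b("dichloromethane", 8.93))
  reg <- rbind(
    data.frame(name = "water", eps = 78.36, cls = "A"),
    cbind(protic, cls = "B"),
    cbind(aprotic, cls = "C"),
    cbind(nonpolar, cls = "D"))
  reg$xi <- 0
  rownames(reg) <- NULL
  if (!is.null(config)) reg <- apply_solvent_config(reg, config)
  reg
}

# Parse "name : eps class [xi]" override lines into the registry.
apply_solvent_config <- function(reg, config) {
  lines <- readLines(config)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("bad solvent config line (expected 'name : eps class [xi]'): ",
           ln)
    nm <- trimws(parts[1])
    vals <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(vals) < 2) stop("bad solvent config line: ", ln)
    eps <- as.numeric(vals[1])
    cls <- toupper(vals[2])
    xi <- if (length(vals) >= 3) as.numeric(vals[3]) else 0
    if (is.na(eps) || !cls %in% c("A", "B", "C", "D") || is.na(xi))
      stop("bad solvent config line: ", ln)
    hit <- match(tolower(nm), tolower(reg$name))
    if (is.na(hit)) {
      reg <- rbind(reg, data.frame(name = nm, eps = eps, cls = cls, xi = xi))
    } else {
      reg$eps[hit] <- eps
      reg$cls[hit] <- cls
      reg$xi[hit] <- xi
    }
  }
  reg
}
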