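# The solute container: elements, Cartesian coordinates (Angstrom),
# per-atom partial charges (e) and the total molecular charge.

# Recognized element symbols (main-group + common others); parsers reject
# anything else so corrupt files fail early.
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba")

BOHR_TO_ANGSTROM <- 0.529177

# Case-normalize an element symbol ("cl" -> "Cl"); reject unknowns,
# isotope labels and dummy atoms.
normalize_element <- function(sym) {
  sym <- trimws(sym)
  if (!grepl("^[A-Za-z]{1,2}$", sym))
    stop("invalid element symbol '", sym,
         "' (isotope labels and dummy atoms are not supported)")
  norm <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, 3)))
  if (!norm %in% ELEMENT_SYMBOLS)
    stop("unknown element symbol '", sym, "'")
  norm
}

#' Construct and validate a solute
#'
#' A solute is a rigid molecular structure with fixed per-atom partial
#' charges (elementary-charge units) and an integer total charge, as read
#' from a gas-phase semiempirical calculation. Validation enforces matching
#' lengths, a charge sum consistent with the declared total charge within
#' 0.01 e (printed charges are rounded), and a minimum interatomic distance
#' of 0.1 Angstrom to guard against corrupt parses.
#'
#' @param elements Character vector of element symbols (case-normalized).
#' @param coords Numeric n x 3 matrix of Cartesian coordinates, Angstrom.
#' @param charges Numeric vector of per-atom partial charges, e.
#' @param total_charge Integer total molecular charge, e.
#' @param name Free-text label.
#' @return Object of class \code{"solute"}.
#' @examples
#' s <- solute("O", matrix(0, 1, 3), charges = -1, total_charge = -1,
#'             name = "oxide")
#' s
#' @export
solute <- function(elements, coords, charges, total_charge = 0L,
                   name = "solute") {
  elements <- vapply(as.character(elements), normalize_element, "")
  coords <- matrix(as.numeric(coords), ncol = 3)
  charges <- as.numeric(charges)
  n <- length(elements)
  if (n < 1) stop("a solute needs at least one atom")
  if (nrow(coords) != n || length(charges) != n)
    stop("elements (", n, "), coordinates (", nrow(coords),
         ") and charges (", length(charges), ") must have equal length")
  if (any(!is.finite(coords)) || any(!is.finite(charges)))
    stop("non-finite coordinates or charges")
  if (abs(total_charge - round(total_charge)) > 1e-9)
    stop("total charge must be an integer")
  total_charge <- as.integer(round(total_charge))
  if (abs(sum(charges) - total_charge) > 0.01)
    stop(sprintf(
      "atomic charges sum to %.4f but the declared total charge is %d",
      sum(charges), total_charge))
  if (n > 1) {
    if (min(dist(coords)) < 0.1)
      stop("two atoms closer than 0.1 Angstrom; refusing a likely corrupt ",
           "structure")
  }
  structure(list(name = name, elements = unname(elements), coords = coords,
                 charges = charges, total_charge = total_charge),
            class = "solute")
}

#' @export
print.solute <- function(x, ...) {
  cat(sprintf("Solute '%s': %d atoms, total charge %+d e\n",
              x$name, length(x$elements), x$total_charge))
  df <- data.frame(element = x$elements,
                   x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3],
                   q = x$charges)
  print(utils::head(df, 10), digits = 4)
  if (nrow(df) > 10) cat("... (", nrow(df) - 10, " more atoms)\n", sep = "")
  invisible(x)
}

read_text <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x)
  else unlist(strsplit(x, "\n", fixed = TRUE))
}

#' Parse the plain-text XYZQ interchange format
#'
#' XYZQ is an XYZ dialect carrying charges: line 1 the atom count, line 2
#' \code{"name total_charge"}, then one \code{"El x y z q"} line per atom
#' (whitespace-separated, free-format floats, coordinates in Angstrom,
#' charges in e).
#'
#' @param text A file path, a single string, or a character vector of lines.
#' @return A \code{\link{solute}}.
#' @examples
#' s <- parse_xyzq(c("1", "Hplus 1", "H 0 0 0 1.0"))
#' s$total_charge
#' @export
parse_xyzq <- function(text) {
  lines <- read_text(text)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) <= 2]
  if (length(lines) < 3) stop("XYZQ input too short")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("XYZQ header: bad atom count '", lines[1], "'")
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(hdr) < 2) stop("XYZQ line 2 must be 'name total_charge'")
  total <- suppressWarnings(as.numeric(hdr[length(hdr)]))
  if (is.na(total)) stop("XYZQ header: non-numeric total charge")
  name <- paste(hdr[-length(hdr)], collapse = " ")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop("XYZQ header declares ", n, " atoms but ", length(body),
         " atom lines follow")
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != 5))
    stop("each XYZQ atom line must be 'El x y z q'")
  tab <- do.call(rbind, parts)
  num <- suppressWarnings(apply(tab[, 2:5, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 4)
  if (any(is.na(num))) stop("non-numeric field in XYZQ atom lines")
  solute(tab[, 1], num[, 1:3], num[, 4], total, name = name)
}

#' Write a solute in the XYZQ format
#'
#' Numbers are printed with six decimals; \code{parse_xyzq(write_xyzq(s))}
#' reproduces \code{s} to that precision.
#'
#' @param s A \code{\link{solute}}.
#' @param file Optional path; if \code{NULL} the text is returned invisibly.
#' @return Character vector of lines, invisibly.
#' @export
write_xyzq <- function(s, file = NULL) {
  stopifnot(inherits(s, "solute"))
  lines <- c(
    as.character(length(s$elements)),
    paste(gsub("\\s+", "_", s$name), s$total_charge),
    sprintf("%-2s %12.6f %12.6f %12.6f %10.6f", s$elements,
            s$coords[, 1], s$coords[, 2], s$coords[, 3], s$charges))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Parse a MOPAC output file
#'
#' Reads the last \code{CARTESIAN COORDINATES} block and the last
#' \code{NET ATOMIC CHARGES} table of a completed MOPAC single-point or
#' optimization output. The net atomic charges are the gas-phase
#' semiempirical charges the solvation model consumes. The total charge is
#' taken from the \code{CHARGE ON SYSTEM} header (0, with a warning, if
#' absent). A coordinate block flagged as atomic units is converted to
#' Angstrom.
#'
#' @param text A file path, a single string, or a character vector of lines.
#' @return A \code{\link{solute}}.
#' @export
parse_mopac_output <- function(text) {
  lines <- read_text(text)

  geo_starts <- grep("CARTESIAN COORDINATES", lines)
  if (!length(geo_starts))
    stop("MOPAC parse error: no CARTESIAN COORDINATES block found")
  gs <- geo_starts[length(geo_starts)]
  bohr <- grepl("A\\.U\\.|BOHR", lines[gs], ignore.case = TRUE)
  geo <- parse_numbered_block(lines, gs,
                              c(sym = 2, x = 3, y = 4, z = 5))
  if (!nrow(geo$tab))
    stop("MOPAC parse error: empty CARTESIAN COORDINATES block")

  chg_starts <- grep("NET ATOMIC CHARGES", lines)
  if (!length(chg_starts))
    stop("MOPAC parse error: no NET ATOMIC CHARGES table found")
  cs <- chg_starts[length(chg_starts)]
  chg <- parse_numbered_block(lines, cs, c(sym = 2, q = 3))
  if (!nrow(chg$tab))
    stop("MOPAC parse error: empty NET ATOMIC CHARGES table")

  if (nrow(geo$tab) != nrow(chg$tab))
    stop("MOPAC structural error: geometry has ", nrow(geo$tab),
         " atoms but the charge table has ", nrow(chg$tab))

  total <- 0L
  tc <- grep("CHARGE ON SYSTEM", lines, value = TRUE)
  if (length(tc)) {
    total <- as.integer(sub(".*CHARGE ON SYSTEM *= *([-+]?[0-9]+).*", "\\1",
                            tc[length(tc)]))
  } else {
    kw <- grep("CHARGE=", lines, value = TRUE)
    if (length(kw)) {
      total <- as.integer(sub(".*CHARGE= *([-+]?[0-9]+).*", "\\1", kw[1]))
    } else {
      warning("MOPAC output has no CHARGE record; assuming a neutral solute")
    }
  }

  xyz <- matrix(as.numeric(geo$tab[, c("x", "y", "z")]), ncol = 3)
  if (bohr) xyz <- xyz * BOHR_TO_ANGSTROM
  nm <- sub("\\.(out|log|mop)$", "", basename(if (length(text) == 1 &&
             !grepl("\n", text) && file.exists(text)) text else "mopac"))
  solute(geo$tab[, "sym"], xyz, as.numeric(chg$tab[, "q"]), total, name = nm)
}

# Collect the run of "<index> <fields...>" rows that follows a block header,
# skipping decoration, and stopping at the first non-row line after rows
# have started. Returns a character matrix with the requested columns.
parse_numbered_block <- function(lines, start, cols) {
  tab <- NULL
  started <- FALSE
  i <- start + 1
  while (i <= length(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    is_row <- length(f) >= max(cols) && grepl("^[0-9]+$", f[1]) &&
      grepl("^[A-Za-z]", f[2])
    if (is_row) {
      tab <- rbind(tab, f[cols])
      started <- TRUE
    } else if (started) {
      break
    } else if (i - start > 10) {
      break  # no table near the header
    }
    i <- i + 1
  }
  if (is.null(tab)) tab <- matrix(character(0), 0, length(cols))
  colnames(tab) <- names(cols)
  list(tab = tab, end = i)
}

#' Parse a Gaussian output file
#'
#' Reads the final \code{Standard orientation} (or \code{Input orientation})
#' geometry and the last population-analysis charge table (the
#' \code{Mulliken charges} block, which for a semiempirical Hamiltonian
#' carries the model's atomic charges) of a Gaussian log file. The
#' \code{Charge = n Multiplicity = m} line supplies the total charge.
#'
#' @param text A file path, a single string, or a character vector of lines.
#' @return A \code{\link{solute}}.
#' @export
parse_gaussian_output <- function(text) {
  lines <- read_text(text)

  geo_starts <- grep("(Standard|Input) orientation:", lines)
  if (!length(geo_starts))
    stop("Gaussian parse error: no orientation block found")
  gs <- geo_starts[length(geo_starts)]
  geo <- parse_gaussian_geometry(lines, gs)

  chg_starts <- grep("^ *Mulliken charges", lines)
  if (!length(chg_starts))
    stop("Gaussian parse error: no Mulliken charge table found")
  cs <- chg_starts[length(chg_starts)]
  chg <- parse_numbered_block(lines, cs, c(sym = 2, q = 3))
  if (!nrow(chg$tab))
    stop("Gaussian parse error: Mulliken charge table is empty or truncated")

  if (nrow(geo) != nrow(chg$tab))
    stop("Gaussian structural error: geometry has ", nrow(geo),
         " atoms but the charge table has ", nrow(chg$tab))

  total <- 0L
  tc <- grep("Charge *= *[-+]?[0-9]+ +Multiplicity", lines, value = TRUE)
  if (length(tc)) {
    total <- as.integer(sub(".*Charge *= *([-+]?[0-9]+).*", "\\1", tc[1]))
  } else {
    warning("Gaussian output has no charge/multiplicity line; ",
            "assuming a neutral solute")
  }

  xyz <- matrix(as.numeric(geo[, c("x", "y", "z")]), ncol = 3)
  elements <- atomic_number_to_symbol(as.integer(geo[, "Z"]))
  solute(elements, xyz, as.numeric(chg$tab[, "q"]), total, name = "gaussian")
}

# Orientation table rows: center number, atomic number, atomic type, x y z.
parse_gaussian_geometry <- function(lines, start) {
  tab <- NULL
  started <- FALSE
  i <- start + 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    f <- strsplit(ln, "\\s+")[[1]]
    is_row <- length(f) == 6 && all(grepl("^[-+0-9.]+$", f))
    if (is_row) {
      tab <- rbind(tab, f[c(2, 4, 5, 6)])
      started <- TRUE
    } else if (started) {
      break
    } else if (i - start > 8) {
      break
    }
    i <- i + 1
  }
  if (is.null(tab))
    stop("Gaussian parse error: orientation block has no atom rows")
  colnames(tab) <- c("Z", "x", "y", "z")
  tab
}

atomic_number_to_symbol <- function(z) {
  if (any(z < 1 | z > length(ELEMENT_SYMBOLS)))
    stop("atomic number out of the supported range: ",
         paste(z[z < 1 | z > length(ELEMENT_SYMBOLS)], collapse = ", "))
  ELEMENT_SYMBOLS[z]
}

symbol_to_atomic_number <- function(sym) {
  match(vapply(sym, normalize_element, ""), ELEMENT_SYMBOLS)
}

#' Read a solute with automatic format detection
#'
#' Sniffs the file header: MOPAC outputs carry MOPAC banners or
#' \code{CARTESIAN COORDINATES}, Gaussian logs carry \code{Gaussian} or
#' orientation blocks, and anything starting with a bare atom count is
#' treated as XYZQ.
#'
#' @param file Path to the input file.
#' @param format One of \code{"auto"}, \code{"mopac"}, \code{"gaussian"},
#'   \code{"xyzq"}.
#' @return A \code{\link{solute}}.
#' @export
read_solute <- function(file, format = c("auto", "mopac", "gaussian",
                                         "xyzq")) {
  format <- match.arg(format)
  lines <- readLines(file)
  if (format == "auto") {
    head_txt <- paste(utils::head(lines, 50), collapse = "\n")
    format <- if (grepl("MOPAC|CARTESIAN COORDINATES", head_txt)) "mopac"
      else if (grepl("Gaussian|orientation:", head_txt)) "gaussian"
      else if (grepl("^\\s*[0-9]+\\s*$", lines[1])) "xyzq"
      else stop("cannot detect the format of '", file, "'")
  }
  s <- switch(format,
              mopac = parse_mopac_output(lines),
              gaussian = parse_gaussian_output(lines),
              xyzq = parse_xyzq(lines))
  if (s$name %in% c("mopac", "gaussian"))
    s$name <- sub("\\.[A-Za-z]+$", "", basename(file))
  s
}
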