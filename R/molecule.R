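#' Construct a molecule
#'
#' Builds the molecular-geometry object used by the mean-field backend. Only
#' closed-shell (spin multiplicity 1, even electron count) systems are
#' supported, matching the restricted formulation of the qsGW cycle.
#'
#' @param symbols character vector of element symbols
#' @param xyz numeric matrix (n_atoms x 3) of coordinates in Angstrom
#' @param charge total molecular charge
#' @param multiplicity spin multiplicity; must be 1
#' @return an object of class `qsgw_molecule` with fields `symbols`, `xyz`
#'   (Angstrom), `coords` (bohr), `Z`, `charge` and `n_electrons`
#' @export
molecule <- function(symbols, xyz, charge = 0L, multiplicity = 1L) {
  symbols <- as.character(symbols)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(symbols) < 1L) stop("molecule needs at least one atom")
  if (nrow(xyz) != length(symbols)) stop("xyz must have one row per atom")
  if (multiplicity != 1L)
    stop("only closed-shell molecules (multiplicity 1) are supported")
  unknown <- setdiff(symbols, names(.element_z))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  Z <- unname(.element_z[symbols])
  nel <- sum(Z) - charge
  if (nel <= 0L) stop("no electrons")
  if (nel %% 2L != 0L)
    stop("odd electron count (", nel, "): closed-shell only")
  structure(
    list(symbols = symbols, xyz = xyz, coords = xyz * ANGSTROM_BOHR,
         Z = Z, charge = as.integer(charge), multiplicity = 1L,
         n_electrons = as.integer(nel)),
    class = "qsgw_molecule")
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ dialect: first line atom count, second line comment, then one
#' `element x y z` line per atom, coordinates in Angstrom.
#'
#' @param path path to the XYZ file
#' @param charge,multiplicity passed to [molecule()]
#' @return a `qsgw_molecule`
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 2L]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  if (length(lines) < n + 2L) stop("malformed XYZ: fewer atom lines than declared")
  rec <- lines[3:(n + 2L)]
  parts <- strsplit(trimws(rec), "\\s+")
  symbols <- vapply(parts, `[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  molecule(symbols, xyz, charge = charge, multiplicity = multiplicity)
}

#' @export
print.qsgw_molecule <- function(x, ...) {
  cat("<qsgw_molecule> ", paste(x$symbols, collapse = " "),
      " | charge ", x$charge, ", ", x$n_electrons, " electrons\n", sep = "")
  invisible(x)
}
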