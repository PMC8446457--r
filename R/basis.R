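# Even-tempered Gaussian basis sets and shell-set plumbing.
#
# No standard basis-set files can be redistributed here, so the package owns
# two uncontracted even-tempered families:
#   "et-min" -- minimal-scale sets for oracle tests (small spectral range)
#   "et-dz"  -- double-zeta-like production sets for the benchmark fixtures
# plus an automatic even-tempered auxiliary-basis generator for the RI.

.et_library <- list(
  "et-min" = list(
    H  = list(s = c(0.17, 1.10)),
    He = list(s = c(0.30, 1.70, 9.50)),
    C  = list(s = c(0.16, 0.95, 5.70, 34.0), p = c(0.15, 0.80)),
    N  = list(s = c(0.22, 1.30, 8.00, 48.0), p = c(0.20, 1.10)),
    O  = list(s = c(0.28, 1.70, 10.5, 64.0), p = c(0.27, 1.40)),
    F  = list(s = c(0.35, 2.20, 13.5, 83.0), p = c(0.35, 1.80))
  ),
  "et-dz" = list(
    H  = list(s = c(0.090, 0.62, 4.30)),
    He = list(s = c(0.22, 1.15, 6.00, 31.0)),
    C  = list(s = c(0.140, 0.868, 5.38, 33.4, 207.0, 1283.0),
              p = c(0.120, 0.550, 2.50)),
    N  = list(s = c(0.190, 1.180, 7.30, 45.3, 281.0, 1741.0),
              p = c(0.160, 0.740, 3.40)),
    O  = list(s = c(0.240, 1.490, 9.20, 57.2, 355.0, 2200.0),
              p = c(0.200, 0.930, 4.30)),
    F  = list(s = c(0.300, 1.860, 11.5, 71.5, 443.0, 2750.0),
              p = c(0.250, 1.160, 5.40)),
    Cl = list(s = c(0.130, 0.680, 3.56, 18.6, 97.4, 510.0, 2670.0, 13970.0),
              p = c(0.110, 0.500, 2.30, 10.6, 48.8))
  )
)

.l_of <- c(s = 0L, p = 1L, d = 2L, f = 3L)

#' List available orbital basis sets
#' @return character vector of basis names
#' @export
list_basis_sets <- function() names(.et_library)

# assemble a shell set (the structure handed to the C++ integral engine)
# shells: list of list(l, center (bohr), exps, coefs)
make_shellset <- function(shells) {
  n <- length(shells)
  l <- vapply(shells, function(s) as.integer(s$l), 0L)
  center <- t(vapply(shells, function(s) as.numeric(s$center), numeric(3)))
  nprim <- vapply(shells, function(s) length(s$exps), 0L)
  pstart <- c(0L, cumsum(nprim))
  exps <- unlist(lapply(shells, `[[`, "exps"), use.names = FALSE)
  coefs <- unlist(lapply(shells, function(s) {
    if (is.null(s$coefs)) rep(1, length(s$exps)) else s$coefs
  }), use.names = FALSE)
  ncart <- (l + 1L) * (l + 2L) / 2L
  ss <- list(l = l, center = center, pstart = as.integer(pstart),
             exps = exps, coefs = coefs, nao = sum(ncart),
             ao_shell = rep(seq_len(n), ncart))
  class(ss) <- "qsgw_shellset"
  # AO normalization: scale every cartesian AO to unit self-overlap
  Sraw <- cpp_overlap(ss)
  ss$norm <- 1 / sqrt(diag(Sraw))
  ss
}

# expand an element's even-tempered definition into shells at a center
element_shells <- function(def, center) {
  out <- list()
  for (lname in names(def)) {
    l <- .l_of[[lname]]
    for (a in def[[lname]])
      out[[length(out) + 1L]] <- list(l = l, center = center, exps = a,
                                      coefs = 1)
  }
  out
}

#' Build the orbital shell set for a molecule
#'
#' @param mol a [molecule()]
#' @param basis a basis-set name from [list_basis_sets()], or a list mapping
#'   element symbols to `list(s = exps, p = exps, ...)` definitions
#' @return a `qsgw_shellset`
#' @export
basis_shells <- function(mol, basis = "et-dz") {
  defs <- if (is.character(basis)) {
    if (!basis %in% names(.et_library))
      stop("unknown basis set '", basis, "'")
    .et_library[[basis]]
  } else basis
  shells <- list()
  for (i in seq_along(mol$symbols)) {
    sym <- mol$symbols[i]
    if (!sym %in% names(defs))
      stop("basis has no definition for element ", sym)
    shells <- c(shells, element_shells(defs[[sym]], mol$coords[i, ]))
  }
  make_shellset(shells)
}

# even-tempered sequence covering [lo, hi] with ratio ~beta
et_sequence <- function(lo, hi, beta) {
  if (hi <= lo) return(lo)
  n <- max(1L, ceiling(log(hi / lo) / log(beta))) + 1L
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Build an automatic auxiliary (RI) shell set
#'
#' Generates an even-tempered auxiliary basis per element from the exponents
#' of the orbital basis: for each auxiliary angular momentum L in 0..2 an
#' even-tempered sequence spans the range of orbital-product exponents
#' (sums of primitive exponents) with L-dependent upper cut-offs. `"auto"`
#' is the production quality; `"auto+"` uses a denser progression for the
#' tight integral-closure checks on small systems.
#'
#' @param mol a [molecule()]
#' @param basis orbital basis name or definition (as in [basis_shells()])
#' @param quality `"auto"` or `"auto+"`
#' @return a `qsgw_shellset` of auxiliary functions
#' @export
auto_aux_shells <- function(mol, basis = "et-dz", quality = "auto") {
  defs <- if (is.character(basis)) .et_library[[basis]] else basis
  par <- switch(quality,
    "auto" = list(beta = c(2.5, 3.4, 4.0, 4.0), lmax_heavy = 2L, lmax_h = 1L,
                  p_top = 0.5, d_top = 2.0),
    "auto+" = list(beta = c(1.7, 1.9, 2.0, 2.1, 2.1), lmax_heavy = 4L,
                   lmax_h = 4L, p_top = 1.25, d_top = 2.5),
    stop("unknown aux quality '", quality, "'"))
  shells <- list()
  for (i in seq_along(mol$symbols)) {
    sym <- mol$symbols[i]
    def <- defs[[sym]]
    all_e <- unlist(def, use.names = FALSE)
    amin <- min(all_e)
    amax_s <- max(def$s)
    has_p <- !is.null(def$p)
    amax_p <- if (has_p) max(def$p) else NA_real_
    lo <- 1.6 * amin
    lmax <- if (has_p) par$lmax_heavy else par$lmax_h
    full <- quality == "auto+"  # full product range at every L (tight checks)
    for (L in 0:lmax) {
      hi <- if (full) 2.2 * amax_s
            else if (L == 0) 2.5 * amax_s
            else if (L == 1) {
              if (has_p) par$p_top * (amax_s + amax_p) else 0.6 * amax_s
            } else if (L == 2) {
              if (has_p) par$d_top * amax_p else 0.35 * amax_s
            } else {
              if (has_p) par$d_top * amax_p else 0.25 * amax_s
            }
      hi <- max(hi, lo * 2)
      for (a in et_sequence(lo, hi, par$beta[L + 1L]))
        shells[[length(shells) + 1L]] <- list(l = L, center = mol$coords[i, ],
                                              exps = a, coefs = 1)
    }
  }
  make_shellset(shells)
}
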