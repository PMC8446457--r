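# Normalized AO integral wrappers around the McMurchie-Davidson engine.
# Every cartesian AO is scaled to unit self-overlap (norm vector attached to
# the shell set), which fixes the normalization convention consistently
# across all integral classes.

ao_overlap <- function(ss) {
  S <- cpp_overlap(ss)
  S * tcrossprod(ss$norm)
}

ao_kinetic <- function(ss) {
  T <- cpp_kinetic(ss)
  T * tcrossprod(ss$norm)
}

ao_nuclear <- function(ss, mol) {
  V <- cpp_nuclear(ss, mol$coords, as.numeric(mol$Z))
  V * tcrossprod(ss$norm)
}

#' Exact four-center electron-repulsion integrals (oracle scale)
#'
#' Full `(mu nu | lambda sigma)` tensor in chemists' notation; guarded to
#' small systems, intended for validating the RI factorization.
#'
#' @param ss a `qsgw_shellset`
#' @return a 4-dimensional array, `n_AO^4`
#' @export
ao_eri4 <- function(ss) {
  eri <- cpp_eri4(ss)
  n <- ss$nao
  nrm <- ss$norm
  eri <- eri * outer(outer(nrm, nrm), outer(nrm, nrm))
  array(eri, dim = c(n, n, n, n))
}

# 3-center (mu nu | P), returned flat as (nao^2 x naux)
ao_eri3_flat <- function(ss, aux) {
  x <- cpp_eri3(ss, aux)
  n <- ss$nao
  naux <- aux$nao
  dim(x) <- c(n * n, naux)
  x <- x * as.vector(tcrossprod(ss$norm))
  x <- sweep(x, 2L, aux$norm, `*`)
  x
}

# 2-center Coulomb metric (P|Q)
ao_eri2 <- function(aux) {
  V <- cpp_eri2(aux)
  V * tcrossprod(aux$norm)
}

# symmetric inverse square root with relative eigenvalue cut-off; used for
# the RI metric (drop near-singular directions, warn) and S^{-1/2}
inv_sqrt_sym <- function(M, rtol = 1e-10, warn_label = NULL) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > rtol * max(e$values)
  if (any(!keep) && !is.null(warn_label))
    warning(sprintf("%s: dropped %d near-singular direction(s)", warn_label,
                    sum(!keep)), call. = FALSE)
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / sqrt(e$values[keep]))
}

# B^P_{mu nu} in the symmetric (square-root Coulomb) metric, flat layout
# (nao^2 x nkeep). (pq|rs) ~= sum_P B^P_pq B^P_rs.
build_b_ao <- function(ss, aux) {
  E3 <- ao_eri3_flat(ss, aux)
  V <- ao_eri2(aux)
  e <- eigen(V, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  if (any(!keep))
    warning(sprintf("RI metric: dropped %d near-singular auxiliary direction(s)",
                    sum(!keep)), call. = FALSE)
  W <- e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e$values[keep]),
                                               nrow = sum(keep))
  E3 %*% W
}
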