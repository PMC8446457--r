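# RI tensor in the MO basis (symmetric Coulomb metric).

#' Build the MO-basis RI tensor
#'
#' Transforms the symmetric-metric three-center tensor `B^P_{mu nu}` carried
#' by the mean-field state into the given MO basis:
#' `B^P_pq = sum_{mu nu} b_{mu p} B^P_{mu nu} b_{nu q}`, so that
#' `(pq|rs) ~= sum_P B^P_pq B^P_rs`.
#'
#' @param state a `qsgw_scf` mean-field state (carries the AO tensor)
#' @param b AO->MO coefficient matrix (defaults to the state's orbitals)
#' @return an object of class `ri_tensor` with the flat `(n_mo^2 x n_aux)`
#'   layout in `$Bflat`, plus `n_mo`, `n_aux`
#' @export
build_ri_tensor <- function(state, b = state$b) {
  n_ao <- nrow(b)
  n_mo <- ncol(b)
  naux <- ncol(state$B_ao)
  out <- matrix(0, n_mo * n_mo, naux)
  for (q in seq_len(naux)) {
    Bq <- matrix(state$B_ao[, q], n_ao, n_ao)
    out[, q] <- as.vector(crossprod(b, Bq %*% b))
  }
  structure(list(Bflat = out, n_mo = n_mo, n_aux = naux),
            class = "ri_tensor")
}

#' Extract the RI tensor as a 3-index array
#'
#' @param ri a [build_ri_tensor()] object
#' @return array `n_aux x n_mo x n_mo` with `B[P, p, q]`
#' @export
ri_array <- function(ri) {
  aperm(array(ri$Bflat, dim = c(ri$n_mo, ri$n_mo, ri$n_aux)), c(3, 1, 2))
}

#' @export
print.ri_tensor <- function(x, ...) {
  cat(sprintf("<ri_tensor> %d MOs, %d auxiliary functions\n", x$n_mo, x$n_aux))
  invisible(x)
}
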