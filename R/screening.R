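# RPA screening in the symmetric-metric auxiliary basis: the bubble
# polarizability in imaginary time, its cosine transform, and the screening
# Dyson equation W~(i omega) = (1 - Pi)^{-1} - 1. Only the correlation part
# W~ of the screened interaction is ever stored; the bare part is folded
# into the exchange self-energy analytically.

occ_virt_rows <- function(ri, occ_idx, virt_idx) {
  # rows of the flat (nmo^2 x naux) MO tensor corresponding to (i, a) pairs
  nmo <- ri$n_mo
  as.vector(outer(occ_idx, (virt_idx - 1L) * nmo, `+`))
}

#' RPA polarizability in imaginary time
#'
#' Builds the closed-shell bubble polarizability in the auxiliary basis,
#' `Pi(i tau)_PQ = -2 sum_{i,a} B^P_ia B^Q_ia exp(-(e_a - e_i) tau)`,
#' at every time node of the grid.
#'
#' @param eps MO energies (Hartree), ascending
#' @param n_occ number of doubly occupied orbitals
#' @param ri a [build_ri_tensor()] object
#' @param grid a [build_grids()] object
#' @return array `n_aux x n_aux x n_t`, each slice symmetric negative
#'   semidefinite
#' @export
chi0_itau <- function(eps, n_occ, ri, grid) {
  occ_idx <- seq_len(n_occ)
  virt_idx <- (n_occ + 1L):ri$n_mo
  delta <- as.vector(outer(eps[occ_idx], eps[virt_idx],
                           function(ei, ea) ea - ei))
  if (min(delta) <= 0) stop("gapless spectrum in chi0")
  X <- ri$Bflat[occ_virt_rows(ri, occ_idx, virt_idx), , drop = FALSE]
  naux <- ncol(X)
  out <- array(0, dim = c(naux, naux, grid$n))
  for (k in seq_len(grid$n)) {
    w <- sqrt(2 * exp(-delta * grid$tau[k]))
    out[, , k] <- -crossprod(w * X)
  }
  out
}

# closed-form frequency-domain bubble (used as internal oracle / by tests)
chi0_iomega_direct <- function(eps, n_occ, ri, omega) {
  occ_idx <- seq_len(n_occ)
  virt_idx <- (n_occ + 1L):ri$n_mo
  delta <- as.vector(outer(eps[occ_idx], eps[virt_idx],
                           function(ei, ea) ea - ei))
  X <- ri$Bflat[occ_virt_rows(ri, occ_idx, virt_idx), , drop = FALSE]
  naux <- ncol(X)
  out <- array(0, dim = c(naux, naux, length(omega)))
  for (k in seq_along(omega)) {
    w <- sqrt(4 * delta / (delta^2 + omega[k]^2))
    out[, , k] <- -crossprod(w * X)
  }
  out
}

#' Solve the screening Dyson equation
#'
#' In the symmetric RI metric the bare Coulomb interaction is the identity,
#' so `W~(i omega) = (1 - Pi(i omega))^{-1} - 1`. The result is transformed
#' back to imaginary time with the inverse cosine weights.
#'
#' @param chi0_omega array `n_aux x n_aux x n_w` of polarizability matrices
#'   on the frequency grid (symmetric, negative semidefinite)
#' @param grid a [build_grids()] object
#' @return an object of class `screened_w` with fields `W_omega` and `W_tau`
#'   (arrays over the respective grids)
#' @export
solve_screening <- function(chi0_omega, grid) {
  d <- dim(chi0_omega)
  naux <- d[1]
  nw <- d[3]
  W_omega <- array(0, dim = d)
  I <- diag(naux)
  for (k in seq_len(nw)) {
    A <- I - chi0_omega[, , k]
    ch <- try(chol(A), silent = TRUE)
    if (inherits(ch, "try-error"))
      stop("(1 - Pi) not positive definite: broken RI or gapless system")
    Wk <- chol2inv(ch) - I
    W_omega[, , k] <- (Wk + t(Wk)) / 2
  }
  W_tau <- cos_transform_w2t(W_omega, grid)
  structure(list(W_omega = W_omega, W_tau = W_tau, grid = grid),
            class = "screened_w")
}
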