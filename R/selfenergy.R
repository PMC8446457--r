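# Space-time evaluation of the GW correlation self-energy: G0(i tau) from
# the current spectrum, Sigma_c(i tau) = (G W~)(i tau) as a direct product,
# and the Fourier transform of its even/odd parts to imaginary frequency.
#
# Sign conventions follow the time-ordered Green's function
#   G_pp(tau > 0) = -exp(-(e_p - mu) tau)   (virtual sector),
#   G_pp(tau < 0) = +exp(-(mu - e_p)|tau|)  (occupied sector),
# pinned by the requirement that the G0W0 self-energy of the 2-level model
# reproduces its closed form (see the reference oracle in the test suite).

#' Non-interacting Green's function on the time grid
#'
#' Occupied states contribute only at negative, virtual states only at
#' positive imaginary time; both branches decay thanks to the mid-gap
#' chemical potential.
#'
#' @param eps MO energies (Hartree, ascending)
#' @param n_occ number of doubly occupied orbitals
#' @param mu chemical potential (defaults to mid-gap)
#' @param grid a [build_grids()] object
#' @return an object of class `g0_tau` with `g_minus` (n_occ x n_t decay
#'   magnitudes for tau < 0), `g_plus` (n_virt x n_t for tau > 0),
#'   `eps_ref`, `mu`
#' @export
g0_itau <- function(eps, n_occ, grid,
                    mu = (eps[n_occ] + eps[n_occ + 1]) / 2) {
  n <- length(eps)
  if (n_occ < 1 || n_occ >= n) stop("need both occupied and virtual states")
  if (eps[n_occ + 1] <= eps[n_occ]) stop("gapless spectrum")
  occ <- seq_len(n_occ)
  virt <- (n_occ + 1L):n
  g_minus <- exp(-outer(mu - eps[occ], grid$tau))   # decays: mu > eps_occ
  g_plus <- exp(-outer(eps[virt] - mu, grid$tau))
  structure(list(g_minus = g_minus, g_plus = g_plus, eps_ref = eps, mu = mu,
                 n_occ = n_occ, grid = grid),
            class = "g0_tau")
}

#' Correlation self-energy in imaginary time
#'
#' Direct-product contraction `Sigma_c = G W~` in the MO/auxiliary
#' representation: for each time node,
#' `Sigma_pq(-tau) = -sum_i g^-_i [B_i^T W~(tau) B_i]_pq` (occupied sector)
#' and `Sigma_pq(+tau) = +sum_a g^+_a [B_a^T W~(tau) B_a]_pq` (virtual
#' sector), with `B_m` the `n_aux x n_mo` slice of the RI tensor.
#'
#' @param G a [g0_itau()] object
#' @param W a [solve_screening()] object
#' @param ri a [build_ri_tensor()] object
#' @return list with arrays `plus` and `minus`, each `n_mo x n_mo x n_t`
#' @export
sigma_c_itau <- function(G, W, ri) {
  nmo <- ri$n_mo
  nt <- dim(W$W_tau)[3]
  if (nt != ncol(G$g_minus)) stop("inconsistent grids")
  occ <- seq_len(G$n_occ)
  virt <- (G$n_occ + 1L):nmo
  rows_of <- function(m) (m - 1L) * nmo + seq_len(nmo)  # column m of B_m
  plus <- array(0, dim = c(nmo, nmo, nt))
  minus <- array(0, dim = c(nmo, nmo, nt))
  for (k in seq_len(nt)) {
    Wk <- W$W_tau[, , k]
    U <- ri$Bflat %*% Wk                 # (nmo^2 x naux), rows (p, m)
    Sm <- matrix(0, nmo, nmo)
    for (j in seq_along(occ)) {
      r <- rows_of(occ[j])
      Sm <- Sm - G$g_minus[j, k] *
        tcrossprod(U[r, , drop = FALSE], ri$Bflat[r, , drop = FALSE])
    }
    Sp <- matrix(0, nmo, nmo)
    for (j in seq_along(virt)) {
      r <- rows_of(virt[j])
      Sp <- Sp + G$g_plus[j, k] *
        tcrossprod(U[r, , drop = FALSE], ri$Bflat[r, , drop = FALSE])
    }
    minus[, , k] <- (Sm + t(Sm)) / 2
    plus[, , k] <- (Sp + t(Sp)) / 2
  }
  list(plus = plus, minus = minus)
}

#' Fourier transform of the self-energy to imaginary frequency
#'
#' Splits `Sigma(i tau)` into even and odd parts, transforms the even part
#' with the cosine and the odd part with the sine weights, and returns the
#' Hermitian-decomposed result: `Sigma_pq(i omega) = even + i * odd`, both
#' parts real symmetric matrices.
#'
#' @param sigma_tau list with `plus`/`minus` arrays from [sigma_c_itau()]
#' @param grid a [build_grids()] object
#' @return an object of class `sigma_freq` with `sigma_even`, `sigma_odd`
#'   (`n_mo x n_mo x n_w`) and `omega`
#' @export
sigma_c_t2w <- function(sigma_tau, grid) {
  if (dim(sigma_tau$plus)[3] != grid$n) stop("grid mismatch")
  even <- (sigma_tau$plus + sigma_tau$minus) / 2
  odd <- (sigma_tau$plus - sigma_tau$minus) / 2
  structure(list(sigma_even = cos_transform_t2w(even, grid),
                 sigma_odd = sin_transform_t2w(odd, grid),
                 omega = grid$omega, grid = grid),
            class = "sigma_freq")
}

#' Fock exchange self-energy in the MO basis
#'
#' @param state a `qsgw_scf` state
#' @param b current MO coefficients (defaults to the state's)
#' @param P AO density matrix to build the exchange from (defaults to the
#'   state's 1RDM)
#' @return the `n_mo x n_mo` matrix `Sigma_x` in the given MO basis
#' @export
sigma_x <- function(state, b = state$b, P = state$P) {
  K <- exchange_matrix(state, P)
  crossprod(b, K %*% b)
}
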