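# Mean-field backend: restricted HF / PBE / PBE0 self-consistent field with
# RI Coulomb and exchange builds. This supplies the generalized Kohn-Sham
# starting point (orbitals, energies, Hartree Hamiltonian) for the qsGW cycle.

# J[dP] from the flat symmetric-metric B tensor
ri_coulomb <- function(Bflat, dP) {
  n <- as.integer(sqrt(nrow(Bflat)))
  cvec <- crossprod(Bflat, as.vector(dP))
  matrix(Bflat %*% cvec, n, n)
}

# K[P]_{mu nu} = sum_Q (B_Q P B_Q)_{mu nu}
ri_exchange_k <- function(Bflat, P) {
  n <- as.integer(sqrt(nrow(Bflat)))
  K <- matrix(0, n, n)
  for (q in seq_len(ncol(Bflat))) {
    Bq <- matrix(Bflat[, q], n, n)
    K <- K + Bq %*% P %*% Bq
  }
  (K + t(K)) / 2
}

#' Coulomb (Hartree) matrix for a density change
#'
#' Builds `J[dP]`, the change of the Hartree potential for a (symmetric)
#' change of the AO density matrix, through the RI factorization carried by
#' the mean-field state. Linear in `dP`.
#'
#' @param state a `qsgw_scf` mean-field state
#' @param dP symmetric AO matrix (density or density difference)
#' @return the AO Coulomb matrix `J[dP]`
#' @export
hartree_matrix <- function(state, dP) {
  stopifnot(is.matrix(dP), nrow(dP) == ncol(dP))
  if (max(abs(dP - t(dP))) > 1e-9) stop("dP must be symmetric")
  ri_coulomb(state$B_ao, dP)
}

#' Fock exchange potential for a density matrix
#'
#' Returns the closed-shell Fock exchange potential `Sigma_x = -K[P]/2` such
#' that for a Hartree-Fock reference `H_H + Sigma_x` reproduces the Fock
#' matrix.
#'
#' @param state a `qsgw_scf` mean-field state
#' @param P symmetric AO density matrix (defaults to the state's density)
#' @return the AO exchange matrix
#' @export
exchange_matrix <- function(state, P = state$P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (max(abs(P - t(P))) > 1e-9) stop("P must be symmetric")
  -0.5 * ri_exchange_k(state$B_ao, P)
}

#' Run the mean-field (generalized Kohn-Sham) starting point
#'
#' Solves the restricted closed-shell SCF problem for one of the supported
#' starting-point functionals (PBE, PBE0, HF) with RI Coulomb/exchange and,
#' for the density functionals, Becke-grid quadrature of the XC potential.
#' The chemical potential is placed mid-gap, `(e_HOMO + e_LUMO)/2`.
#'
#' @param mol a [molecule()]
#' @param basis orbital basis name or definition
#' @param functional one of `"PBE"`, `"PBE0"`, `"HF"`
#' @param aux auxiliary basis quality for the RI (`"auto"` or `"auto+"`)
#' @param conv convergence threshold on the maximum DIIS residual element
#' @param max_iter maximum SCF iterations
#' @param grid_params list(n_rad, n_theta, n_phi) for the XC quadrature
#' @param verbose print per-iteration energies
#' @return an object of class `qsgw_scf` with fields `S`, `b` (AO->MO
#'   coefficients), `eps` (Hartree), `occ`, `H_H` (Hartree Hamiltonian),
#'   `P` (AO 1RDM), `mu`, `functional_tag`, `energy`, plus the integral
#'   plumbing reused downstream (`B_ao`, shell sets)
#' @export
run_mean_field <- function(mol, basis = "et-dz",
                           functional = c("PBE0", "PBE", "HF"),
                           aux = "auto", conv = 1e-8, max_iter = 200,
                           grid_params = list(n_rad = 35, n_theta = 6,
                                              n_phi = 12),
                           verbose = FALSE) {
  functional <- match.arg(functional)
  if (mol$multiplicity != 1L) stop("open-shell input rejected")
  ss <- basis_shells(mol, basis)
  auxss <- auto_aux_shells(mol, basis, quality = aux)
  S <- ao_overlap(ss)
  T <- ao_kinetic(ss)
  Vne <- ao_nuclear(ss, mol)
  hcore <- T + Vne
  Bflat <- build_b_ao(ss, auxss)
  n <- ss$nao
  nocc <- mol$n_electrons / 2L
  if (nocc >= n) stop("basis too small: no virtual orbitals")
  X <- inv_sqrt_sym(S, rtol = 1e-10, warn_label = "overlap")
  grid <- NULL
  a_x <- switch(functional, HF = 1.0, PBE0 = 0.25, PBE = 0.0)
  if (functional != "HF")
    grid <- molecular_grid(mol, grid_params$n_rad, grid_params$n_theta,
                           grid_params$n_phi)
  enuc <- 0
  if (length(mol$Z) > 1) {
    D <- as.matrix(dist(mol$coords))
    for (a in 2:length(mol$Z))
      for (b in 1:(a - 1)) enuc <- enuc + mol$Z[a] * mol$Z[b] / D[a, b]
  }

  diag_fock <- function(F) {
    Fo <- crossprod(X, F %*% X)
    e <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    list(eps = e$values[ord], b = X %*% e$vectors[, ord, drop = FALSE])
  }

  build_fock <- function(P) {
    J <- ri_coulomb(Bflat, P)
    F <- hcore + J
    exc <- 0
    if (a_x > 0) {
      K <- ri_exchange_k(Bflat, P)
      F <- F - 0.5 * a_x * K
      exc <- exc - 0.25 * a_x * sum(K * P)
    }
    if (functional != "HF") {
      xc <- xc_matrix(ss, grid, P, functional)
      F <- F + xc$V
      exc <- exc + xc$exc
    }
    energy <- sum(P * hcore) + 0.5 * sum(P * J) + exc + enuc
    list(F = F, energy = energy, J = J)
  }

  # core guess, damped start, then Fock DIIS on FPS-SPF
  sol <- diag_fock(hcore)
  P <- 2 * tcrossprod(sol$b[, seq_len(nocc), drop = FALSE])
  F_hist <- list(); r_hist <- list()
  Fprev <- NULL
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    bf <- build_fock(P)
    F <- bf$F
    resid <- crossprod(X, (F %*% P %*% S - S %*% P %*% F) %*% X)
    rmax <- max(abs(resid))
    trace <- c(trace, rmax)
    if (verbose)
      message(sprintf("  scf it %2d  E = %.10f  |FPS-SPF| = %.2e", it,
                      bf$energy, rmax))
    if (rmax < conv) { converged <- TRUE; break }
    if (it <= 5 && !is.null(Fprev)) {
      F <- 0.7 * F + 0.3 * Fprev  # damped start
    } else if (it > 5) {
      F_hist <- c(F_hist, list(F)); r_hist <- c(r_hist, list(resid))
      if (length(F_hist) > 8) { F_hist <- F_hist[-1]; r_hist <- r_hist[-1] }
      Fd <- try(diis_combine(F_hist, r_hist), silent = TRUE)
      if (!inherits(Fd, "try-error")) F <- Fd
    }
    Fprev <- bf$F
    sol <- diag_fock(F)
    P <- 2 * tcrossprod(sol$b[, seq_len(nocc), drop = FALSE])
  }
  if (!converged)
    stop(sprintf(
      "SCF did not converge in %d iterations (functional %s); residual trace: %s",
      max_iter, functional,
      paste(sprintf("%.1e", tail(trace, 8)), collapse = " ")))
  sol <- diag_fock(bf$F)
  P <- 2 * tcrossprod(sol$b[, seq_len(nocc), drop = FALSE])
  eps <- sol$eps
  homo <- eps[nocc]; lumo <- eps[nocc + 1]
  if (lumo <= homo) stop("gapless mean-field spectrum: qsGW undefined")
  occ <- c(rep(2, nocc), rep(0, n - nocc))
  J <- ri_coulomb(Bflat, P)
  state <- list(
    S = S, b = sol$b, eps = eps, occ = occ,
    H_H = hcore + J, P = P, mu = (homo + lumo) / 2,
    functional_tag = functional,
    fock = bf$F, hcore = hcore, energy = bf$energy,
    n_occ = nocc, n_mo = n, mol = mol, shells = ss, aux_shells = auxss,
    B_ao = Bflat, basis = if (is.character(basis)) basis else "custom",
    n_iter = it, scf_trace = trace)
  class(state) <- "qsgw_scf"
  state
}

#' @export
print.qsgw_scf <- function(x, ...) {
  cat(sprintf(
    "<qsgw_scf> %s/%s  E = %.8f Ha  gap = %.3f eV  (%d AOs, %d aux)\n",
    x$functional_tag, x$basis, x$energy,
    (x$eps[x$n_occ + 1] - x$eps[x$n_occ]) * HARTREE_EV, x$n_mo,
    ncol(x$B_ao)))
  invisible(x)
}

# Pulay DIIS combination used by both SCF and the qsGW driver.
# Solves min || sum_m alpha_m r_m || s.t. sum alpha = 1 (Lagrange system);
# on a singular system drops the oldest pair and retries.
diis_combine <- function(M_hist, r_hist) {
  m <- length(M_hist)
  stopifnot(m >= 1, length(r_hist) == m)
  while (m >= 1) {
    B <- matrix(0, m + 1, m + 1)
    for (i in seq_len(m))
      for (j in seq_len(m))
        B[i, j] <- sum(r_hist[[i]] * r_hist[[j]])
    # scale the residual block so conditioning is size-independent
    sc <- max(diag(B)[seq_len(m)])
    if (sc > 0) B[seq_len(m), seq_len(m)] <- B[seq_len(m), seq_len(m)] / sc
    B[m + 1, seq_len(m)] <- 1
    B[seq_len(m), m + 1] <- 1
    rhs <- c(rep(0, m), 1)
    # near-singular systems (stale, linearly dependent residuals) produce
    # huge coefficients and wreck the extrapolation: drop the oldest pair
    ill <- m > 1 && rcond(B) < 1e-14
    sol <- if (ill) NULL else try(solve(B, rhs), silent = TRUE)
    if (!is.null(sol) && !inherits(sol, "try-error") && all(is.finite(sol)) &&
        max(abs(sol[seq_len(m)])) < 1e4) {
      alpha <- sol[seq_len(m)]
      out <- 0
      for (i in seq_len(m)) out <- out + alpha[i] * M_hist[[i]]
      attr(out, "alpha") <- alpha
      return(out)
    }
    M_hist <- M_hist[-1]; r_hist <- r_hist[-1]
    m <- m - 1
  }
  stop("DIIS system singular for all depths")
}
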