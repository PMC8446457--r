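# independent brute-force reference implementations, used only by tests:
#  - sos_sigma_c: exact sum-over-states G0W0 self-energy from full RPA
#    diagonalization (no grids, no analytic continuation)
#  - rpa_modes:   the RPA excitation energies / auxiliary-space residues
#  - dense_ft:    trapezoid-rule Fourier transforms on a fine uniform grid

rpa_modes <- function(eps, n_occ, ri) {
  nmo <- ri$n_mo
  occ <- seq_len(n_occ)
  virt <- (n_occ + 1L):nmo
  rows <- as.vector(outer(occ, (virt - 1L) * nmo, `+`))
  X <- ri$Bflat[rows, , drop = FALSE]
  delta <- as.vector(outer(eps[occ], eps[virt], function(ei, ea) ea - ei))
  K <- tcrossprod(X)
  M <- diag(delta^2, length(delta)) +
    4 * outer(sqrt(delta), sqrt(delta)) * K
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  Om <- sqrt(pmax(ev$values, 0))
  R <- crossprod(X, sqrt(delta) * ev$vectors)   # n_aux x n_modes
  R <- sweep(R, 2L, sqrt(2 / Om), `*`)
  list(Omega = Om, residues = R, delta = delta)
}

# exact Sigma_c(z) at arbitrary complex z (absolute frequency scale)
sos_sigma_c <- function(eps, n_occ, ri, z) {
  nmo <- ri$n_mo
  occ <- seq_len(n_occ)
  virt <- (n_occ + 1L):nmo
  stopifnot(n_occ * (nmo - n_occ) <= 200)
  md <- rpa_modes(eps, n_occ, ri)
  V <- ri$Bflat %*% md$residues                 # (nmo^2 x n_modes)
  out <- array(0 + 0i, dim = c(nmo, nmo, length(z)))
  for (iz in seq_along(z)) {
    Spq <- matrix(0 + 0i, nmo, nmo)
    for (s in seq_along(md$Omega)) {
      Vs <- matrix(V[, s], nmo, nmo)
      den_occ <- 1 / (z[iz] - eps[occ] + md$Omega[s])
      den_vir <- 1 / (z[iz] - eps[virt] - md$Omega[s])
      Spq <- Spq +
        Vs[, occ, drop = FALSE] %*% (den_occ * t(Vs[, occ, drop = FALSE])) +
        Vs[, virt, drop = FALSE] %*% (den_vir * t(Vs[, virt, drop = FALSE]))
    }
    out[, , iz] <- Spq
  }
  out
}

# reference cosine/sine transform by trapezoid rule on a fine uniform tau grid
dense_ft <- function(f, tau_max, n, omega, kernel = c("cos", "sin")) {
  kernel <- match.arg(kernel)
  tg <- seq(0, tau_max, length.out = n)
  ft <- f(tg)
  h <- tg[2] - tg[1]
  vapply(omega, function(om) {
    k <- if (kernel == "cos") cos(om * tg) else sin(om * tg)
    v <- ft * k
    2 * h * (sum(v) - 0.5 * v[1] - 0.5 * v[n])
  }, 0)
}
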