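# Becke molecular quadrature for the exchange-correlation potential:
# Murray-Handy-Laming radial mapping, product Gauss-Legendre x uniform-phi
# angular grid (exact for spherical harmonics up to degree 2*n_theta - 1),
# and Becke fuzzy-cell partition weights (k = 3, no size adjustment beyond
# Bragg-Slater radii in the radial mapping).

gauss_legendre <- function(n) {
  # Golub-Welsch via the Jacobi matrix
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

radial_grid <- function(n, rm) {
  # Murray-Handy-Laming m = 2: r = rm * (x/(1-x))^2, x_i = i/(n+1)
  i <- seq_len(n)
  x <- i / (n + 1)
  r <- rm * (x / (1 - x))^2
  dr <- rm * 2 * x / (1 - x)^3 / (n + 1)
  list(r = r, w = r^2 * dr)
}

angular_grid <- function(n_theta, n_phi) {
  gl <- gauss_legendre(n_theta)
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  ct <- gl$x
  st <- sqrt(pmax(0, 1 - ct^2))
  pts <- cbind(
    as.vector(outer(st, cos(phi))),
    as.vector(outer(st, sin(phi))),
    rep(ct, times = n_phi))
  w <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
  list(pts = pts, w = w)
}

becke_weights <- function(pts, mol) {
  nat <- length(mol$Z)
  np <- nrow(pts)
  if (nat == 1) return(matrix(1, np, 1))
  d <- matrix(0, np, nat)
  for (a in seq_len(nat))
    d[, a] <- sqrt((pts[, 1] - mol$coords[a, 1])^2 +
                   (pts[, 2] - mol$coords[a, 2])^2 +
                   (pts[, 3] - mol$coords[a, 3])^2)
  Rab <- as.matrix(dist(mol$coords))
  P <- matrix(1, np, nat)
  for (a in seq_len(nat))
    for (b in seq_len(nat)) {
      if (a == b) next
      mu <- (d[, a] - d[, b]) / Rab[a, b]
      f <- mu
      for (k in 1:3) f <- 1.5 * f - 0.5 * f^3
      P[, a] <- P[, a] * 0.5 * (1 - f)
    }
  P / rowSums(P)
}

# full molecular grid: list(pts (np x 3, bohr), w)
molecular_grid <- function(mol, n_rad = 35, n_theta = 6, n_phi = 12) {
  ang <- angular_grid(n_theta, n_phi)
  pts <- NULL
  w <- NULL
  for (a in seq_along(mol$Z)) {
    rm <- .bragg_radius[[mol$symbols[a]]] * ANGSTROM_BOHR
    rad <- radial_grid(n_rad, rm)
    p_a <- kronecker(rad$r, ang$pts)
    p_a <- sweep(p_a, 2L, mol$coords[a, ], `+`)
    w_a <- as.vector(outer(ang$w, rad$w))  # ang fast, rad slow -> match kronecker
    pts <- rbind(pts, p_a)
    w <- c(w, w_a)
  }
  wb <- numeric(length(w))
  # Becke weight of the owning atom for each point
  np_per <- n_rad * n_theta * n_phi
  Pmat <- becke_weights(pts, mol)
  for (a in seq_along(mol$Z)) {
    idx <- ((a - 1) * np_per + 1):(a * np_per)
    wb[idx] <- w[idx] * Pmat[idx, a]
  }
  list(pts = pts, w = wb)
}
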