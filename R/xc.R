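# PBE exchange-correlation for closed-shell densities. Energy densities are
# coded analytically; the potential ingredients (d f / d rho, d f / d sigma,
# f = rho * eps_xc) are obtained by central differences, which is well within
# the accuracy needed for a starting-point functional (the qsGW map itself
# never touches V_xc^DFT).

# PBE exchange energy per particle (spin-unpolarized), sigma = |grad rho|^2
eps_x_pbe <- function(rho, sigma) {
  kappa <- 0.804
  mu <- 0.2195149727645171
  kf <- (3 * pi^2 * rho)^(1 / 3)
  ex_lda <- -3 / (4 * pi) * kf
  s2 <- sigma / (4 * kf^2 * rho^2)
  fx <- 1 + kappa - kappa / (1 + mu * s2 / kappa)
  ex_lda * fx
}

# PW92 correlation energy per particle, unpolarized
eps_c_pw92 <- function(rho) {
  A <- 0.0310907; a1 <- 0.21370
  b1 <- 7.5957; b2 <- 3.5876; b3 <- 1.6382; b4 <- 0.49294
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  srs <- sqrt(rs)
  den <- 2 * A * (b1 * srs + b2 * rs + b3 * rs * srs + b4 * rs^2)
  -2 * A * (1 + a1 * rs) * log(1 + 1 / den)
}

# PBE correlation energy per particle
eps_c_pbe <- function(rho, sigma) {
  beta <- 0.06672455060314922
  gamma <- (1 - log(2)) / pi^2
  ec0 <- eps_c_pw92(rho)
  kf <- (3 * pi^2 * rho)^(1 / 3)
  ks <- sqrt(4 * kf / pi)
  t2 <- sigma / (4 * ks^2 * rho^2)
  expo <- exp(-ec0 / gamma)
  Afac <- (beta / gamma) / pmax(expo - 1, 1e-300)
  num <- 1 + Afac * t2
  den <- 1 + Afac * t2 + Afac^2 * t2^2
  H <- gamma * log(1 + (beta / gamma) * t2 * num / den)
  ec0 + H
}

# f = rho * eps_xc for a given functional mixture
xc_f <- function(rho, sigma, x_frac, use_pbe_x, use_pbe_c) {
  f <- 0
  if (use_pbe_x && x_frac > 0) f <- f + x_frac * rho * eps_x_pbe(rho, sigma)
  if (use_pbe_c) f <- f + rho * eps_c_pbe(rho, sigma)
  f
}

# energy density and derivatives for the SCF build.
# functional: "PBE" (full PBE), "PBE0" (0.75 PBE_x + PBE_c; exact exchange is
# handled separately by the Fock build).
xc_eval <- function(rho, sigma, functional) {
  x_frac <- switch(functional, PBE = 1.0, PBE0 = 0.75,
                   stop("no XC grid part for ", functional))
  live <- rho > 1e-11
  f <- vrho <- vsig <- numeric(length(rho))
  if (any(live)) {
    r <- rho[live]; s <- pmax(sigma[live], 0)
    f[live] <- xc_f(r, s, x_frac, TRUE, TRUE)
    hr <- 1e-6 * r
    vrho[live] <- (xc_f(r + hr, s, x_frac, TRUE, TRUE) -
                   xc_f(r - hr, s, x_frac, TRUE, TRUE)) / (2 * hr)
    hs <- 1e-6 * pmax(s, 1e-10 * r^(8 / 3))
    vsig[live] <- (xc_f(r, s + hs, x_frac, TRUE, TRUE) -
                   xc_f(r, pmax(s - hs, 0), x_frac, TRUE, TRUE)) / (2 * hs)
  }
  list(f = f, vrho = vrho, vsigma = vsig)
}

# XC energy and potential matrix by chunked quadrature
# returns list(exc, V)
xc_matrix <- function(ss, grid, P, functional, chunk = 8000L) {
  n <- ss$nao
  V <- matrix(0, n, n)
  exc <- 0
  np <- nrow(grid$pts)
  for (start in seq(1L, np, by = chunk)) {
    idx <- start:min(start + chunk - 1L, np)
    bb <- cpp_eval_basis(ss, grid$pts[idx, , drop = FALSE])
    phi <- sweep(bb$val, 2L, ss$norm, `*`)
    gx <- sweep(bb$dx, 2L, ss$norm, `*`)
    gy <- sweep(bb$dy, 2L, ss$norm, `*`)
    gz <- sweep(bb$dz, 2L, ss$norm, `*`)
    Pphi <- phi %*% P
    rho <- rowSums(Pphi * phi)
    drx <- 2 * rowSums(Pphi * gx)
    dry <- 2 * rowSums(Pphi * gy)
    drz <- 2 * rowSums(Pphi * gz)
    sigma <- drx^2 + dry^2 + drz^2
    w <- grid$w[idx]
    xc <- xc_eval(pmax(rho, 0), sigma, functional)
    exc <- exc + sum(w * xc$f)
    V <- V + crossprod(phi, (w * xc$vrho) * phi)
    Tm <- crossprod(phi, (2 * w * xc$vsigma) *
                      (drx * gx + dry * gy + drz * gz))
    V <- V + Tm + t(Tm)
  }
  list(exc = exc, V = (V + t(V)) / 2)
}
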