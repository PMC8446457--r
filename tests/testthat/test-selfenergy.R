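# space-time self-energy: G0(i tau), the GW~ contraction, and its transform

test_that("G0 respects time-ordering and particle-hole symmetry", {
  g <- build_grids(1, 1, 8)
  # symmetric two-level spectrum about mu = 0
  G <- g0_itau(c(-0.5, 0.5), 1, g, mu = 0)
  expect_equal(dim(G$g_minus), c(1L, g$n))
  expect_equal(dim(G$g_plus), c(1L, g$n))
  # occupied states only contribute on the negative branch; the magnitudes
  # of the two branches coincide for a particle-hole symmetric spectrum
  expect_equal(G$g_minus, G$g_plus, tolerance = 1e-14)
  expect_equal(as.vector(G$g_plus), exp(-0.5 * g$tau), tolerance = 1e-14)
  expect_error(g0_itau(c(0.2, 0.2), 1, g), "gapless")
})

test_that("one-pole G transforms to the analytic resolvent on the imaginary axis", {
  d <- 0.8  # e_virt - mu
  g <- build_grids(d, d, 12)
  # time-ordered G for a single virtual level: G(tau>0) = -exp(-d tau),
  # even/odd split gives -exp(-d|tau|)/2 and -sign(tau) exp(-d|tau|)/2
  even <- -0.5 * exp(-d * g$tau)
  odd <- -0.5 * exp(-d * g$tau)
  re <- cos_transform_t2w(even, g)
  im <- sin_transform_t2w(odd, g)
  ref <- 1 / (1i * g$omega - d)
  expect_lt(max(abs(re - Re(ref))), 1e-6)
  expect_lt(max(abs(im - Im(ref))), 1e-6)
})

test_that("Sigma_c vanishes in the exchange-only (W~ = 0) limit", {
  tl <- two_level()
  g <- build_grids(tl$delta, tl$delta, 8)
  G <- g0_itau(tl$eps, 1, g)
  W0 <- list(W_tau = array(0, dim = c(1, 1, g$n)),
             W_omega = array(0, dim = c(1, 1, g$n)))
  sig <- sigma_c_itau(G, W0, tl$ri)
  expect_equal(max(abs(sig$plus)), 0)
  expect_equal(max(abs(sig$minus)), 0)
})

test_that("one-orbital contraction reproduces the scalar formula", {
  tl <- two_level()
  g <- build_grids(tl$delta, tl$delta, 8)
  G <- g0_itau(tl$eps, 1, g)
  Wt <- array(-0.25 * exp(-1.3 * g$tau), dim = c(1, 1, g$n))
  sig <- sigma_c_itau(G, list(W_tau = Wt), tl$ri)
  # occupied branch (tau < 0): Sigma_11 = -B^1_11 W~ B^1_11 g^-_1
  b11 <- tl$ri$Bflat[1, 1]
  expect_equal(as.vector(sig$minus[1, 1, ]),
               -b11^2 * as.vector(Wt) * as.vector(G$g_minus),
               tolerance = 1e-13)
  # virtual branch (tau > 0) carries the opposite sign
  b12 <- tl$ri$Bflat[3, 1]
  expect_equal(as.vector(sig$plus[1, 1, ]),
               +b12^2 * as.vector(Wt) * as.vector(G$g_plus),
               tolerance = 1e-13)
})

test_that("even/odd split and parity of the frequency transform", {
  g <- build_grids(0.5, 2, 8)
  set.seed(7)
  M <- crossprod(matrix(rnorm(9), 3))
  decay <- exp(-0.9 * g$tau)
  stack <- array(outer(as.vector(M), decay), dim = c(3, 3, g$n))
  # symmetric in tau -> no odd part
  sig <- sigma_c_t2w(list(plus = stack, minus = stack), g)
  expect_equal(max(abs(sig$sigma_odd)), 0)
  # exp(-d|tau|) M -> Lorentzian times M at the nodes
  ref <- array(outer(as.vector(M), 2 * 0.9 / (0.9^2 + g$omega^2)),
               dim = c(3, 3, g$n))
  expect_lt(max(abs(sig$sigma_even - ref)), 1e-4 * max(abs(M)))
  # linearity is exact
  sig2 <- sigma_c_t2w(list(plus = 2 * stack, minus = 2 * stack), g)
  expect_equal(sig2$sigma_even, 2 * sig$sigma_even, tolerance = 1e-13)
})

test_that("space-time G0W0 self-energy matches the sum-over-states oracle", {
  for (name in c("H2", "He")) {
    st <- mf(name, "et-min", "HF", "auto+")
    pl <- sigma_pipeline(st, n_grid = 16)
    pip <- pl$sig_w$sigma_even + 1i * pl$sig_w$sigma_odd
    ref <- sos_sigma_c(pl$eps, pl$nocc, pl$ri, pl$mu + 1i * pl$grid$omega)
    expect_lt(max(abs(pip - ref)), 1e-4)
  }
})

test_that("Sigma(i tau) and both frequency parts are index-symmetric", {
  # for real orbitals Sigma_pq(tau) = Sigma_qp(tau) exactly (W~ symmetric),
  # hence even and odd parts are both symmetric matrices
  st <- mf("H2O", "et-min", "HF", "auto")
  pl <- sigma_pipeline(st)
  se <- pl$sig_w$sigma_even; so <- pl$sig_w$sigma_odd
  expect_equal(se, aperm(se, c(2, 1, 3)), tolerance = 1e-12)
  expect_equal(so, aperm(so, c(2, 1, 3)), tolerance = 1e-12)
})

test_that("first-order self-energy scales quadratically with the interaction", {
  tl <- two_level()
  lam <- 0.5
  tl2 <- two_level(b11 = sqrt(lam) * 0.9, b12 = sqrt(lam) * 0.35,
                   b22 = sqrt(lam) * 0.8)
  g <- build_grids(tl$delta, tl$delta, 8)
  G <- g0_itau(tl$eps, 1, g)
  first_order_sigma <- function(ri) {
    chi <- chi0_itau(tl$eps, 1, ri, g)          # ~ lambda
    sigma_c_itau(G, list(W_tau = chi), ri)      # W~ frozen at first order
  }
  s1 <- first_order_sigma(tl$ri)
  s2 <- first_order_sigma(tl2$ri)
  expect_equal(s2$minus, lam^2 * s1$minus, tolerance = 1e-12)
  expect_equal(s2$plus, lam^2 * s1$plus, tolerance = 1e-12)
})

test_that("sigma_x transforms the exchange potential to the MO basis", {
  st <- mf("H2", "et-min", "HF", "auto+")
  sx <- sigma_x(st)
  expect_equal(sx, t(sx), tolerance = 1e-12)
  # HF consistency in the MO basis: eps = diag(MO Fock) = diag(H_H + Sx)_MO
  hmo <- crossprod(st$b, (st$H_H) %*% st$b) + sx
  expect_equal(diag(hmo), st$eps, tolerance = 1e-7)
})
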