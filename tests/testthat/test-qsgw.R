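# the qsGW self-consistency engine

test_that("potential construction: modes agree on the diagonal, average off it", {
  # E[p, q] = Re Sigma_pq at the column target; the 2x2 example has
  # Sigma_12(e_1) = 0.3, Sigma_12(e_2) = 0.1
  E <- matrix(c(-0.50, 0.30, 0.10, -0.20), 2, 2)
  E0 <- matrix(c(-0.44, 0.17, 0.17, -0.15), 2, 2)
  sx <- matrix(0, 2, 2)
  vA <- build_vxc_qsgw(E, NULL, sx, mode = "A", noise_cut = 1e-6)
  vB <- build_vxc_qsgw(E, E0, sx, mode = "B", noise_cut = 1e-6)
  expect_equal(diag(vA$vc), diag(vB$vc))          # identical by construction
  expect_equal(vA$vc[1, 2], 0.2)                  # arithmetic mean
  expect_equal(vB$vc[1, 2], 0.17)                 # static off-diagonal
  expect_equal(vA$vc, t(vA$vc))
})

test_that("off-diagonal correlation entries below the noise cut are zeroed", {
  E <- matrix(c(-0.5, 5e-7, 5e-7, -0.2), 2, 2)
  v <- build_vxc_qsgw(E, E, sigma_x = matrix(0, 2, 2), mode = "B",
                      noise_cut = 1e-6)
  expect_equal(v$vc[1, 2], 0)
  expect_equal(v$vc[2, 1], 0)
  expect_equal(diag(v$vc), diag(E))               # diagonal untouched
  # entries above the cut survive
  E2 <- matrix(c(-0.5, 2e-6, 2e-6, -0.2), 2, 2)
  v2 <- build_vxc_qsgw(E2, E2, matrix(0, 2, 2), mode = "B", noise_cut = 1e-6)
  expect_equal(v2$vc[1, 2], 2e-6)
})

test_that("Hamiltonian assembly reproduces the KS Hamiltonian at iteration one", {
  st <- mf("H2O", "et-min", "PBE")
  n <- st$n_mo
  vxc_dft <- st$fock - st$H_H   # backend V_xc in the AO basis
  H <- assemble_hamiltonian(st, st$H_H, matrix(0, n, n), vxc_dft)
  expect_lt(max(abs(H - st$fock)), 1e-10)
  expect_lt(max(abs(H - t(H))), 1e-12)
  expect_error(assemble_hamiltonian(st, st$H_H, matrix(rnorm(n * n), n),
                                    vxc_dft), "asymmetric")
})

test_that("DIIS extrapolation solves the constrained least-squares problem", {
  H1 <- diag(2); r1 <- matrix(c(1, 0, 0, -1), 2)
  # a single stored pair forces alpha = 1
  out <- diis_extrapolate(list(H1), list(r1))
  expect_equal(attr(out, "alpha"), 1)
  expect_equal(unclass(out), H1, ignore_attr = TRUE)
  # two pairs with opposite residuals cancel exactly: alpha = (1/2, 1/2)
  H2 <- 3 * diag(2)
  out2 <- diis_extrapolate(list(H1, H2), list(r1, -r1))
  expect_equal(attr(out2, "alpha"), c(0.5, 0.5))
  expect_equal(unclass(out2), 2 * diag(2), ignore_attr = TRUE)
})

test_that("DIIS coefficients match a brute-force search on the constraint plane", {
  set.seed(9)
  r <- replicate(3, matrix(rnorm(16), 4), simplify = FALSE)
  H <- replicate(3, matrix(rnorm(16), 4), simplify = FALSE)
  out <- diis_extrapolate(H, r)
  alpha <- attr(out, "alpha")
  obj <- function(a) {
    s <- a[1] * r[[1]] + a[2] * r[[2]] + (1 - a[1] - a[2]) * r[[3]]
    sum(s^2)
  }
  # dense grid over the constraint plane
  gr <- as.matrix(expand.grid(a1 = seq(-2, 2, 0.004), a2 = seq(-2, 2, 0.004)))
  vals <- (gr[, 1]^2) * sum(r[[1]] * r[[1]])  # placeholder, computed below
  G11 <- sum(r[[1]] * r[[1]]); G22 <- sum(r[[2]] * r[[2]])
  G33 <- sum(r[[3]] * r[[3]]); G12 <- sum(r[[1]] * r[[2]])
  G13 <- sum(r[[1]] * r[[3]]); G23 <- sum(r[[2]] * r[[3]])
  a1 <- gr[, 1]; a2 <- gr[, 2]; a3 <- 1 - a1 - a2
  vals <- a1^2 * G11 + a2^2 * G22 + a3^2 * G33 +
    2 * a1 * a2 * G12 + 2 * a1 * a3 * G13 + 2 * a2 * a3 * G23
  best <- min(vals)
  expect_lte(obj(alpha[1:2]), best + 1e-6)
})

test_that("Frobenius residual norm is the RMS over matrix entries", {
  expect_equal(frobenius_residual(matrix(0, 3, 3)), 0)
  expect_equal(frobenius_residual(matrix(1, 2, 2)), 1)
  set.seed(10)
  r <- matrix(rnorm(9), 3)
  acc <- 0
  for (i in 1:3) for (j in 1:3) acc <- acc + r[i, j]^2
  expect_equal(frobenius_residual(r), sqrt(acc) / 3)
})

test_that("configuration validation enforces the documented ranges", {
  expect_error(qsgw_config(eps_scf = 0))
  expect_error(qsgw_config(alpha = 0))
  expect_error(qsgw_config(alpha = 1.5))
  expect_error(qsgw_config(n0 = 0))
  expect_error(qsgw_config(mode = "C"))
  cfg <- qsgw_config()
  expect_equal(cfg$mode, "B")
  expect_equal(cfg$eps_scf, 1e-7)
  expect_equal(cfg$n0, 10)
  expect_equal(cfg$alpha, 0.35)
  expect_equal(cfg$noise_cut, 1e-6)
})

test_that("He quasiparticle energies are independent of the starting point", {
  cfg <- qsgw_config(n_grid = 16)
  r_hf <- cached("qsgw|He|HF", run_qsgw(state = mf("He", "et-min", "HF"),
                                        config = cfg))
  r_pbe <- cached("qsgw|He|PBE", run_qsgw(state = mf("He", "et-min", "PBE"),
                                          config = cfg))
  expect_true(r_hf$converged && r_pbe$converged)
  expect_lt(abs(r_hf$IP - r_pbe$IP) * 1000, 1)   # <= 1 meV
})

test_that("a converged solution is a fixed point (restart in <= 2 iterations)", {
  cfg <- qsgw_config(n_grid = 16)
  st <- mf("H2O", "et-min", "PBE0")
  r <- cached("qsgw|H2O|PBE0", suppressWarnings(run_qsgw(state = st,
                                                         config = cfg)))
  expect_true(r$converged)
  expect_true(all(tail(r$nf_trace, 2) < cfg$eps_scf))
  r2 <- suppressWarnings(run_qsgw(state = st, config = cfg,
                                  start = list(eps = r$eps_ha, b = r$b)))
  expect_true(r2$converged)
  expect_lte(r2$iterations, 2L)
  expect_lt(abs(r2$IP - r$IP) * 1000, 0.1)
})

test_that("orthonormality and electron count are conserved every iteration", {
  r <- cached("qsgw|H2O|PBE0", suppressWarnings(
    run_qsgw(state = mf("H2O", "et-min", "PBE0"),
             config = qsgw_config(n_grid = 16))))
  expect_lt(r$invariants["orthonormality"], 1e-8)
  expect_lt(r$invariants["electron_count"], 1e-8)
  expect_lt(r$invariants["idempotency"], 1e-8)
})

test_that("the total Hamiltonian is diagonal in the converged basis", {
  # the self-consistency condition: off-diagonals of F + V_c vanish (the
  # correlation potential itself cancels the Fock off-diagonals)
  st <- mf("H2O", "et-min", "PBE0")
  r <- cached("qsgw|H2O|PBE0", suppressWarnings(
    run_qsgw(state = st, config = qsgw_config(n_grid = 16))))
  P <- 2 * tcrossprod(r$b[, seq_len(r$n_occ)])
  Fao <- st$H_H + hartree_matrix(st, P - st$P) + exchange_matrix(st, P)
  Hmo <- crossprod(r$b, Fao %*% r$b) + r$vc
  off <- Hmo; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-4)
})

test_that("linear mixing with alpha = 1 is the plain fixed-point iteration", {
  st <- mf("He", "et-min", "HF")
  cfg1 <- qsgw_config(mixing = "linear", alpha = 1, n_grid = 16, max_iter = 3)
  cfg2 <- qsgw_config(mixing = "diis", n0 = 1, n_grid = 16, max_iter = 3)
  r1 <- run_qsgw(state = st, config = cfg1)
  r2 <- run_qsgw(state = st, config = cfg2)
  # DIIS with depth 1 forces alpha = 1, i.e. the same plain iteration
  expect_equal(r1$nf_trace, r2$nf_trace, tolerance = 1e-10)
})

test_that("DIIS and linear mixing converge to the same fixed point", {
  st <- mf("CH4", "et-min", "PBE0")
  cfg_d <- qsgw_config(n_grid = 16)
  cfg_m <- qsgw_config(mixing = "linear", alpha = 0.35, n_grid = 16,
                       max_iter = 60)
  r_d <- suppressWarnings(run_qsgw(state = st, config = cfg_d))
  r_m <- suppressWarnings(run_qsgw(state = st, config = cfg_m))
  expect_true(r_d$converged && r_m$converged)
  expect_lt(abs(r_d$IP - r_m$IP) * 1000, 5)   # <= 5 meV
})

test_that("unconverged runs are flagged and carry the full residual trace", {
  st <- mf("He", "et-min", "HF")
  r <- run_qsgw(state = st, config = qsgw_config(n_grid = 16, max_iter = 2))
  expect_false(r$converged)
  expect_equal(r$iterations, 2L)
  expect_length(r$nf_trace, 2L)
})
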