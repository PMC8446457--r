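# shared fixtures: cached mean-field states (expensive) and hand-built toy
# systems used across test files

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

mf <- function(name, basis = "et-min", functional = "HF", aux = "auto") {
  key <- paste("mf", name, basis, functional, aux, sep = "|")
  cached(key, {
    mol <- if (name == "He") molecule("He", matrix(0, 1, 3)) else
      fixture_molecule(name)
    suppressWarnings(run_mean_field(mol, basis = basis,
                                    functional = functional, aux = aux))
  })
}

# full space-time self-energy pipeline for a mean-field state (G0W0, one shot)
sigma_pipeline <- function(st, n_grid = 16) {
  eps <- st$eps
  nocc <- st$n_occ
  ri <- build_ri_tensor(st)
  gap <- eps[nocc + 1] - eps[nocc]
  span <- eps[length(eps)] - eps[1]
  grid <- build_grids(0.45 * gap, 2 * span, n_grid)
  W <- solve_screening(cos_transform_t2w(chi0_itau(eps, nocc, ri, grid), grid),
                       grid)
  G <- g0_itau(eps, nocc, grid, mu = st$mu)
  sig_w <- sigma_c_t2w(sigma_c_itau(G, W, ri), grid)
  list(grid = grid, ri = ri, W = W, G = G, sig_w = sig_w, eps = eps,
       nocc = nocc, mu = st$mu)
}

# synthetic 2-level system with a scalar auxiliary space
two_level <- function(e_occ = -0.5, e_virt = 0.3, b11 = 0.9, b12 = 0.35,
                      b22 = 0.8) {
  ri <- structure(list(Bflat = matrix(c(b11, b12, b12, b22), 4, 1),
                       n_mo = 2L, n_aux = 1L), class = "ri_tensor")
  list(eps = c(e_occ, e_virt), n_occ = 1L, ri = ri,
       delta = e_virt - e_occ, K = b12^2,
       Omega = sqrt((e_virt - e_occ)^2 + 4 * (e_virt - e_occ) * b12^2))
}

# worst-case relative (to the 2/Delta peak) transform errors over a dense
# off-sample Delta scan
transform_errors <- function(grid, n_test = 200) {
  dl <- exp(seq(log(grid$delta_min), log(grid$delta_max),
                length.out = n_test))
  wc <- ws <- wr <- 0
  for (d in dl) {
    f <- exp(-d * grid$tau)
    Lc <- 2 * d / (d^2 + grid$omega^2)
    Ls <- 2 * grid$omega / (d^2 + grid$omega^2)
    wc <- max(wc, max(abs(cos_transform_t2w(f, grid) - Lc)) / (2 / d))
    ws <- max(ws, max(abs(sin_transform_t2w(f, grid) - Ls)) / (2 / d))
    wr <- max(wr, max(abs(cos_transform_w2t(Lc, grid) - f)))
  }
  c(cos = wc, sin = ws, roundtrip = wr)
}
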