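# Paired non-uniform imaginary-time / imaginary-frequency grids with
# least-squares cosine/sine transform weights.
#
# Grid family: logarithmic time nodes; frequency nodes placed one per
# logarithmic bin of the spectral range at the minima ("valleys") of the
# transform-error profile of the time grid. The transform matrices are
# fitted by Lawson-reweighted least squares over a dense logarithmic sample
# of transition energies Delta in [delta_min, delta_max], so that
#   sum_k T_cos[beta, k] exp(-Delta tau_k)  ~=  2 Delta / (Delta^2 + omega^2)
#   sum_k T_sin[beta, k] exp(-Delta tau_k)  ~=  2 omega / (Delta^2 + omega^2)
# and T_cos_inv performs the reverse mapping. Residual rows are weighted by
# Delta, which makes the fit uniform in error relative to the function peak
# (2/Delta for the cosine kernel).

tsvd_solve <- function(A, Y, rtol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > rtol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], Y)) / sv$d[keep])
}

#' Build paired imaginary-time / imaginary-frequency grids
#'
#' Constructs `n_points` time and frequency nodes spanning the spectral range
#' `[delta_min, delta_max]` of particle-hole transition energies, together
#' with least-squares cosine/sine transform weight matrices between the two
#' domains.
#'
#' @param delta_min smallest transition energy (Hartree); must be > 0 --
#'   a gapless spectrum leaves the qsGW propagators undamped
#' @param delta_max largest transition energy (Hartree)
#' @param n_points number of nodes per domain (even, >= 6)
#' @param n_dense number of dense sample points for the least-squares fit
#' @return an object of class `tf_grid` with fields `tau`, `w_tau`, `omega`,
#'   `w_omega`, `T_cos` (n_w x n_t), `T_sin`, `T_cos_inv` (n_t x n_w),
#'   `delta_min`, `delta_max`
#' @export
build_grids <- function(delta_min, delta_max, n_points = 16,
                        n_dense = max(400L, 20L * n_points)) {
  if (!is.finite(delta_min) || delta_min <= 0)
    stop("delta_min must be positive: zero-gap (metallic) spectrum, qsGW undefined")
  if (delta_max < delta_min) stop("delta_max < delta_min")
  if (n_points < 6 || n_points %% 2 != 0)
    stop("n_points must be even and >= 6")
  n <- as.integer(n_points)

  # time nodes: log-spaced across the decay scales of exp(-Delta tau)
  tau <- exp(seq(log(0.5 / delta_max), log(8 / delta_min), length.out = n))
  w_tau <- tau * (log(tau[n] / tau[1]) / (n - 1))  # log-trapezoid weights

  if (delta_max / delta_min < 1 + 1e-9) {
    # degenerate single-transition range: fits become interpolation
    dl <- rep(delta_min, 8L)
    omega <- delta_min * exp(seq(log(0.2), log(5), length.out = n))
  } else {
    dl <- exp(seq(log(delta_min), log(delta_max), length.out = n_dense))
    omega <- pick_omega_nodes(tau, dl, delta_min, delta_max, n)
  }
  w_omega <- omega * c(diff(log(omega))[1], diff(log(omega)))

  # per-row Lawson-refined least-squares transform weights
  E <- exp(-outer(dl, tau)) * dl                   # Delta-weighted design
  Lc <- 2 * dl^2 / (outer(dl^2, omega^2, `+`))     # Delta * Lorentzian
  Ls <- 2 * sweep(dl / (outer(dl^2, omega^2, `+`)), 2L, omega, `*`)
  T_cos <- matrix(0, n, n); T_sin <- matrix(0, n, n)
  for (b in seq_len(n)) {
    T_cos[b, ] <- lawson_fit(E, Lc[, b])
    T_sin[b, ] <- lawson_fit(E, Ls[, b])
  }
  # inverse direction: exp(-Delta tau_k) in the span of the node Lorentzians
  Linv <- 2 * dl / (outer(dl^2, omega^2, `+`))
  Einv <- exp(-outer(dl, tau))
  T_cos_inv <- matrix(0, n, n)
  for (k in seq_len(n)) T_cos_inv[k, ] <- lawson_fit(Linv, Einv[, k])

  structure(list(tau = tau, w_tau = w_tau, omega = omega, w_omega = w_omega,
                 T_cos = T_cos, T_sin = T_sin, T_cos_inv = T_cos_inv,
                 delta_min = delta_min, delta_max = delta_max, n = n),
            class = "tf_grid")
}

# place frequency nodes in the valleys of the transform-error profile:
# one node per logarithmic bin of [0.25 delta_min, 3 delta_max], each at the
# omega where the (cos, sin) least-squares residual over the dense Delta
# sample is smallest. Depends only on the spectral range (scale covariant).
pick_omega_nodes <- function(tau, dl, delta_min, delta_max, n) {
  oms <- exp(seq(log(0.25 * delta_min), log(3 * delta_max),
                 length.out = 12L * n))
  E <- exp(-outer(dl, tau)) * dl
  sv <- svd(E)
  keep <- sv$d > 1e-13 * sv$d[1]
  U <- sv$u[, keep, drop = FALSE]
  Yc <- 2 * dl^2 / (outer(dl^2, oms^2, `+`))
  Ys <- 2 * sweep(dl / (outer(dl^2, oms^2, `+`)), 2L, oms, `*`)
  Rc <- Yc - U %*% crossprod(U, Yc)
  Rs <- Ys - U %*% crossprod(U, Ys)
  err <- pmax(apply(abs(Rc), 2L, max), apply(abs(Rs), 2L, max))
  lb <- seq(log(min(oms)) - 1e-12, log(max(oms)) + 1e-12, length.out = n + 1L)
  bins <- findInterval(log(oms), lb, rightmost.closed = TRUE)
  idx <- vapply(seq_len(n), function(i) {
    sel <- which(bins == i)
    sel[which.min(err[sel])]
  }, 0L)
  sort(oms[idx])
}

# iteratively reweighted (Lawson) least squares: drives the max residual of
# a single fit towards minimax; returns the coefficient vector. Uses fast
# Householder QR (.lm.fit); falls back to truncated SVD on failure.
lawson_fit <- function(A, y, iters = 5L, rtol = 1e-13) {
  w <- rep(1, length(y))
  best_cf <- NULL
  best <- Inf
  for (it in seq_len(iters)) {
    sw <- sqrt(w)
    cf <- tryCatch({
      fit <- .lm.fit(A * sw, y * sw)
      co <- numeric(ncol(A))
      co[fit$pivot] <- fit$coefficients  # .lm.fit returns pivoted order
      co[is.na(co)] <- 0
      co
    }, error = function(e) rep(NA_real_, ncol(A)))
    bad <- anyNA(cf) || any(!is.finite(cf)) || max(abs(cf)) > 3e4
    if (!bad) {
      r <- abs(as.vector(A %*% cf - y))
      m <- max(r)
      bad <- !is.finite(m) || (is.finite(best) && m > 10 * best)
    }
    if (bad) {  # ill-conditioned QR blow-up: regularized SVD solve
      cf <- tsvd_solve(A * sw, y * sw, rtol = rtol)
      r <- abs(as.vector(A %*% cf - y))
      m <- max(r)
    }
    if (m < best) { best <- m; best_cf <- cf }
    if (m < 1e-14 * max(1e-300, max(abs(y)))) break  # interpolation reached
    w <- w * (r + 1e-3 * m)
    mw <- mean(w)
    if (!is.finite(mw) || mw <= 0) break
    w <- w / mw
  }
  as.vector(best_cf)
}

#' @export
print.tf_grid <- function(x, ...) {
  cat(sprintf("<tf_grid> n = %d, Delta in [%.3g, %.3g] Ha (ratio %.3g)\n",
              x$n, x$delta_min, x$delta_max, x$delta_max / x$delta_min))
  invisible(x)
}

# apply a transform matrix Tm (nout x nin) along the last dimension of a
# (n1 x n2 x nin) array or a length-nin vector
apply_transform <- function(Tm, F) {
  if (is.null(dim(F)) || length(dim(F)) == 1L) {
    if (length(F) != ncol(Tm)) stop("grid/sample-length mismatch")
    return(as.vector(Tm %*% F))
  }
  d <- dim(F)
  if (d[length(d)] != ncol(Tm)) stop("grid/sample-length mismatch")
  n12 <- prod(d[-length(d)])
  out <- matrix(F, n12, d[length(d)]) %*% t(Tm)
  array(out, dim = c(d[-length(d)], nrow(Tm)))
}

#' Cosine transform, imaginary time to imaginary frequency
#'
#' Applies the least-squares cosine weights: even functions of tau sampled at
#' the grid's time nodes are mapped to the frequency nodes,
#' `F(i omega_b) = sum_k T_cos[b, k] F(tau_k)`.
#'
#' @param F vector of length `n_t`, or array whose last dimension runs over
#'   the time nodes (e.g. `n x n x n_t` stacks of matrices)
#' @param grid a [build_grids()] object
#' @return same shape with the last dimension over frequency nodes
#' @export
cos_transform_t2w <- function(F, grid) apply_transform(grid$T_cos, F)

#' Sine transform, imaginary time to imaginary frequency
#' @inheritParams cos_transform_t2w
#' @export
sin_transform_t2w <- function(F, grid) apply_transform(grid$T_sin, F)

#' Inverse cosine transform, imaginary frequency to imaginary time
#' @param F vector or array whose last dimension runs over frequency nodes
#' @param grid a [build_grids()] object
#' @export
cos_transform_w2t <- function(F, grid) apply_transform(grid$T_cos_inv, F)

#' Dump a grid to a columnar text file (debug reproducibility)
#' @param grid a `tf_grid`
#' @param path output file
#' @export
write_grid <- function(grid, path) {
  df <- data.frame(tau = grid$tau, w_tau = grid$w_tau, omega = grid$omega,
                   w_omega = grid$w_omega)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
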