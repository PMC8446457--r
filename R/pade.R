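# Analytic continuation by Vidberg-Serene continued-fraction Pade
# approximants. The coefficient recursion runs in compensated double-double
# arithmetic (C++ backend); evaluation is ordinary double precision.

#' Fit a continued-fraction Pade model
#'
#' Vidberg-Serene recursion: `g_1(z_i) = f(z_i)`, `a_i = g_i(z_i)`,
#' `g_{i+1}(z) = (g_i(z_i) - g_i(z)) / ((z - z_i) g_i(z))`. If the recursion
#' hits a vanishing pivot the fit is retried with one point fewer (warning).
#'
#' @param z_nodes distinct complex interpolation points (typically
#'   `1i * omega` on the imaginary axis)
#' @param values complex function values at the nodes
#' @param extended use extended (double-double) precision in the recursion
#' @return an object of class `pade_model` with `nodes`, `coeffs`, `n`
#' @export
fit_pade <- function(z_nodes, values, extended = TRUE) {
  z_nodes <- as.complex(z_nodes)
  values <- as.complex(values)
  n <- length(z_nodes)
  if (n < 2) stop("need at least 2 points")
  if (length(values) != n) stop("length mismatch")
  if (anyDuplicated(round(z_nodes, 14))) stop("duplicate nodes rejected")
  repeat {
    ft <- cpp_pade_fit(z_nodes, values, extended)
    if (ft$status == 0) break
    if (length(z_nodes) <= 2)
      stop("Pade recursion degenerate even at 2 points")
    warning(sprintf(
      "Pade recursion pivot vanished at stage %d; dropping to %d points",
      ft$status, length(z_nodes) - 1L), call. = FALSE)
    z_nodes <- z_nodes[-length(z_nodes)]
    values <- values[-length(values)]
  }
  structure(list(nodes = z_nodes, coeffs = ft$coeffs, n = length(z_nodes)),
            class = "pade_model")
}

#' Evaluate a continued-fraction Pade model
#'
#' Bottom-up evaluation of the continued fraction. Evaluation exactly at a
#' pole of the fraction yields `NA` with a warning (analytic continuation is
#' unreliable next to a pole of the self-energy).
#'
#' @param model a [fit_pade()] object
#' @param z complex evaluation points
#' @return complex values
#' @export
eval_pade <- function(model, z) {
  out <- cpp_pade_eval(model$coeffs, model$nodes, as.complex(z))
  if (anyNA(out))
    warning("Pade evaluation hit a pole of the continued fraction",
            call. = FALSE)
  out
}

#' Continue the self-energy to real frequencies
#'
#' Fits one Pade model per matrix element of `Sigma_c(i omega)` (the even
#' part plus `i` times the odd part over all frequency nodes) and evaluates
#' it just above the real axis at `target + i eta`. Element `(p, q)` of the
#' returned matrix is `Re Sigma_pq` evaluated at `targets[q]`; by the
#' symmetry `Sigma_pq = Sigma_qp` the transpose holds the row-target values,
#' so `(out + t(out))/2` is the frequency-symmetrized (mode A) combination.
#' Elements whose fit or evaluation fails are set to zero (treated as AC
#' noise) with a single collected warning.
#'
#' @param sig a [sigma_c_t2w()] object
#' @param targets real frequencies, one per MO, measured on the same absolute
#'   scale as the grid centre (pass `eps - mu` for quasiparticle energies)
#' @param eta broadening above the real axis (Hartree)
#' @param static_offdiag evaluate off-diagonal elements at the static limit
#'   (origin) instead of the column target -- the mode-B combination in one
#'   pass
#' @return real matrix with `out[p, q] = Re Sigma_pq(targets[q] + i eta)`
#' @export
continue_sigma <- function(sig, targets, eta = 1e-3,
                           static_offdiag = FALSE) {
  nmo <- dim(sig$sigma_even)[1]
  if (length(targets) == 1L) targets <- rep(targets, nmo)
  if (length(targets) != nmo) stop("one target frequency per MO required")
  res <- cpp_continue_sigma(sig$omega, as.numeric(sig$sigma_even),
                            as.numeric(sig$sigma_odd), nmo,
                            as.numeric(targets), eta, static_offdiag)
  if (res$nfail > 0L)
    warning(sprintf("analytic continuation failed for %d element(s); set to 0",
                    res$nfail), call. = FALSE)
  res$E
}
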