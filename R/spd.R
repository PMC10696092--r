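#' Lead-matrix-derived SPD feature matrix
#'
#' A skew-symmetric lead matrix L is turned into a symmetric positive
#' semi-definite matrix by the negative square, \eqn{A = -L^2 = L^\top L}
#' (\eqn{v^\top A v = \|Lv\|^2 \ge 0}), and made strictly positive definite
#' by a small diagonal regularization, \eqn{A + \varepsilon I}. The result is
#' the per-trial feature used with the Riemannian classifiers; its
#' eigenvalues are the squared singular values of L plus \eqn{\varepsilon}.
#'
#' @param L a [lead_matrix()] (or any skew-symmetric matrix).
#' @param epsilon diagonal regularization, must be > 0. Default 0.001.
#' @return symmetric positive definite matrix with channel-id dimnames.
#' @export
lead_spd <- function(L, epsilon = 0.001) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop_invalid("epsilon must be a positive scalar")
  }
  M <- unclass(L)
  A <- crossprod(M) + diag(epsilon, nrow(M))
  A <- (A + t(A)) / 2
  dimnames(A) <- dimnames(M)
  A
}

#' Sample covariance of a multichannel trial
#'
#' Channel-by-channel sample covariance (unbiased, n - 1 denominator, means
#' removed) of a trial, the benchmark feature of Riemannian brain-computer
#' interface classifiers. Optional shrinkage toward the scaled identity,
#' \eqn{(1-\gamma) C + \gamma \, \mathrm{tr}(C)/d \, I}, guards short or
#' rank-deficient windows.
#'
#' @param trial a [multichannel_path()] or a samples x channels matrix.
#' @param shrinkage shrinkage weight \eqn{\gamma \in [0, 1)}; default 0.
#' @return symmetric positive definite covariance matrix.
#' @export
sample_covariance <- function(trial, shrinkage = 0) {
  vals <- if (inherits(trial, "multichannel_path")) trial$values else as.matrix(trial)
  if (shrinkage < 0 || shrinkage >= 1) stop_invalid("shrinkage must lie in [0, 1)")
  d <- ncol(vals)
  if (shrinkage == 0 && nrow(vals) <= d) {
    stop_invalid("need more samples (%d) than channels (%d) unless shrinkage > 0",
                 nrow(vals), d)
  }
  C <- stats::cov(vals)
  if (shrinkage > 0) {
    C <- (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / d) * diag(d)
  }
  chk <- assert_spd(C)
  if (!chk$spd) {
    stop_invalid("trial covariance is rank deficient (min eigenvalue %.3g); use shrinkage > 0",
                 chk$min_eigenvalue)
  }
  C
}

#' Check symmetry and positive definiteness
#'
#' @param M numeric square matrix.
#' @param sym_tol maximum allowed asymmetry `max|M - t(M)|`.
#' @return list with `spd` (logical), `symmetric`, `min_eigenvalue` and
#'   `asymmetry` diagnostics; never throws.
#' @export
assert_spd <- function(M, sym_tol = 1e-10) {
  M <- unclass(as.matrix(M))
  asym <- max(abs(M - t(M)))
  symmetric <- asym <= sym_tol * max(1, max(abs(M)))
  min_eig <- if (symmetric) {
    min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  } else NA_real_
  list(spd = isTRUE(symmetric && min_eig > 0),
       symmetric = symmetric,
       min_eigenvalue = min_eig,
       asymmetry = asym)
}
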