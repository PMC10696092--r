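## Symmetric-matrix functional calculus. Eigenvalues are clipped at `clip`
## before applying f, guarding round-off on epsilon-regularized inputs.
spd_fun <- function(M, f, clip = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, clip)
  e$vectors %*% (f(vals) * t(e$vectors))
}

spd_sqrt <- function(M) spd_fun(M, sqrt)
spd_invsqrt <- function(M) spd_fun(M, function(v) 1 / sqrt(v))
spd_logm <- function(M) spd_fun(M, log)
sym_expm <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

check_spd_input <- function(M, what = "input") {
  chk <- assert_spd(M, sym_tol = 1e-8)
  if (!chk$spd) {
    stop_invalid("%s is not symmetric positive definite (min eig %.3g, asymmetry %.3g)",
                 what, chk$min_eigenvalue, chk$asymmetry)
  }
  invisible(TRUE)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' The geodesic distance on the manifold of symmetric positive definite
#' matrices under the affine-invariant metric,
#' \deqn{\delta(A, B) = \| \log(A^{-1/2} B A^{-1/2}) \|_F
#'       = \Big(\sum_i \log^2 \lambda_i(A^{-1}B)\Big)^{1/2}.}
#' It is symmetric, zero iff A = B, and invariant under congruence
#' \eqn{A \mapsto G A G^\top} by any invertible G.
#'
#' @param A,B symmetric positive definite matrices of equal dimension.
#' @return nonnegative scalar distance.
#' @export
airm_distance <- function(A, B) {
  check_spd_input(A, "A")
  check_spd_input(B, "B")
  if (!all(dim(A) == dim(B))) stop_invalid("A and B must have equal dimension")
  isa <- spd_invsqrt(A)
  W <- isa %*% B %*% isa
  ev <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(pmax(ev, 1e-300))^2))
}

#' Karcher (geometric) mean of SPD matrices
#'
#' The Fréchet mean under the affine-invariant metric, computed by the
#' standard fixed-point iteration in the tangent space: at iterate M, average
#' the whitened logarithms \eqn{\log(M^{-1/2} A_i M^{-1/2})} and step along
#' the exponential map; convergence is declared when the Frobenius norm of
#' the tangent mean drops below `tol`. Initialization is the arithmetic mean;
#' step size 1.
#'
#' @param mats list of SPD matrices (or a 3-D array d x d x n).
#' @param tol convergence tolerance on the tangent-mean norm.
#' @param max_iter maximum iterations (default 200; widely spread inputs
#'   spend a long, slowly contracting transient before the quadratic phase).
#'   Non-convergence raises a warning and
#'   returns the last iterate (diagnostics in attribute `karcher`).
#' @return SPD matrix, with attribute `karcher` = list(iterations, residual,
#'   converged).
#' @export
geometric_mean <- function(mats, tol = 1e-8, max_iter = 200L) {
  mats <- as_spd_list(mats)
  n <- length(mats)
  if (n == 0) stop_invalid("need at least one matrix")
  for (i in seq_len(n)) check_spd_input(mats[[i]], sprintf("matrix %d", i))
  if (n == 1) {
    M <- mats[[1]]
    attr(M, "karcher") <- list(iterations = 0L, residual = 0, converged = TRUE)
    return(M)
  }
  ## tangent-mean (negative gradient) at a point, with cached square roots
  grad_at <- function(M) {
    ism <- spd_invsqrt(M)
    sm <- spd_sqrt(M)
    Tm <- matrix(0, nrow(M), ncol(M))
    for (i in seq_len(n)) {
      Tm <- Tm + spd_logm(ism %*% mats[[i]] %*% ism)
    }
    Tm <- Tm / n
    list(Tm = Tm, res = sqrt(sum(Tm^2)), sm = sm)
  }
  M <- Reduce(`+`, mats) / n
  cur <- grad_at(M)
  converged <- cur$res < tol
  step <- 1
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    ## candidate exponential step; accept only if the gradient norm does
    ## not increase (backtracking keeps the fixed-point iteration stable
    ## on widely spread inputs), else retry from the same point with half
    ## the step
    cand_M <- cur$sm %*% sym_expm(step * cur$Tm) %*% cur$sm
    cand_M <- (cand_M + t(cand_M)) / 2
    cand <- grad_at(cand_M)
    if (cand$res <= cur$res || step < 1e-6) {
      M <- cand_M
      cur <- cand
      step <- min(1, step * 1.5)
    } else {
      step <- step / 2
    }
    converged <- cur$res < tol
  }
  if (!converged) {
    warning(sprintf("Karcher mean did not converge in %d iterations (residual %.3g)",
                    max_iter, cur$res))
  }
  attr(M, "karcher") <- list(iterations = it, residual = cur$res,
                             converged = converged)
  M
}

as_spd_list <- function(mats) {
  if (is.array(mats) && length(dim(mats)) == 3) {
    lapply(seq_len(dim(mats)[3]), function(i) mats[, , i])
  } else if (is.matrix(mats)) {
    list(mats)
  } else {
    as.list(mats)
  }
}

## Half-vectorization with sqrt(2) off-diagonal weights: preserves the
## Frobenius inner product, so Euclidean norms of tangent vectors equal
## Riemannian norms at the reference.
vech_weighted <- function(S) {
  d <- nrow(S)
  up <- upper.tri(S)
  c(diag(S), sqrt(2) * S[up])
}

unvech_weighted <- function(v, d) {
  S <- matrix(0, d, d)
  diag(S) <- v[seq_len(d)]
  S[upper.tri(S)] <- v[-seq_len(d)] / sqrt(2)
  S + t(S) - diag(diag(S))
}

#' Logarithmic and exponential maps on the SPD manifold
#'
#' `log_map` projects an SPD matrix A to the tangent space at `ref` via
#' \eqn{\log(\mathrm{ref}^{-1/2} A \, \mathrm{ref}^{-1/2})} and vectorizes
#' the symmetric result (upper triangle, off-diagonal entries weighted by
#' \eqn{\sqrt2}) so that the Euclidean norm of the tangent vector equals
#' [airm_distance()] from the reference. `exp_map` inverts it. This is the
#' projection used by [tangent_classifier()].
#'
#' @param ref SPD reference point (typically the [geometric_mean()] of the
#'   training features).
#' @param A SPD matrix to project.
#' @param tv tangent vector as returned by `log_map`.
#' @return `log_map`: object of class `spd_tangent` (numeric vector of length
#'   d(d+1)/2 with attribute `reference`). `exp_map`: SPD matrix.
#' @export
log_map <- function(ref, A) {
  check_spd_input(ref, "ref")
  check_spd_input(A, "A")
  isr <- spd_invsqrt(ref)
  S <- spd_logm(isr %*% A %*% isr)
  structure(vech_weighted(S), reference = ref, class = "spd_tangent")
}

#' @rdname log_map
#' @export
exp_map <- function(ref, tv) {
  check_spd_input(ref, "ref")
  d <- nrow(ref)
  v <- as.double(tv)
  if (length(v) != d * (d + 1) / 2) {
    stop_invalid("tangent vector length %d does not match dimension %d",
                 length(v), d)
  }
  S <- unvech_weighted(v, d)
  sr <- spd_sqrt(ref)
  M <- sr %*% sym_expm(S) %*% sr
  (M + t(M)) / 2
}
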