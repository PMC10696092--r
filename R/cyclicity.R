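#' Lead matrix of a multichannel path
#'
#' The lead matrix is the antisymmetric part of the level-2 signature viewed
#' as a d x d matrix,
#' \deqn{L(X) = \tfrac12 (S_2(X) - S_2(X)^\top),}
#' so \eqn{L_{ij}} is the signed area of the path projected onto the channel
#' pair (i, j) (closed by the chord from endpoint to start). A positive
#' \eqn{L_{ij}} is read as channel i leading channel j. L is skew-symmetric
#' with zero diagonal, hence its spectrum is purely imaginary and comes in
#' conjugate pairs; [cyclic_order()] exploits this to recover the temporal
#' ordering of phase-lagged oscillations.
#'
#' @param path a [multichannel_path()] with at least 2 channels.
#' @return a `lead_matrix`: a d x d skew-symmetric matrix with channel-id
#'   dimnames and class attribute `c("lead_matrix", "matrix", "array")`.
#' @export
lead_matrix <- function(path) {
  stopifnot(inherits(path, "multichannel_path"))
  d <- path_dim(path)
  if (d < 2) stop_invalid("lead matrix needs at least 2 channels")
  s2 <- matrix(signature(path, 2L)$tensors[[2]], d, d, byrow = TRUE)
  L <- (s2 - t(s2)) / 2
  dimnames(L) <- list(path$channel_ids, path$channel_ids)
  class(L) <- c("lead_matrix", class(matrix()))
  L
}

#' @export
print.lead_matrix <- function(x, ...) {
  cat(sprintf("<lead_matrix> %d x %d (skew-symmetric)\n", nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Analytic lead matrix of a phase-lagged sine system
#'
#' For the system \eqn{X^i_t = \sin(t - \alpha_i)} on \eqn{[0, T]} with T a
#' positive multiple of \eqn{2\pi} (so the path is closed), the lead matrix
#' has the closed form
#' \deqn{L = \tfrac{T}{2} (y x^\top - x y^\top), \qquad
#'       L_{ij} = \tfrac{T}{2} \sin(\alpha_j - \alpha_i),}
#' with \eqn{x = \sin(\alpha)}, \eqn{y = \cos(\alpha)}; in particular it has
#' rank at most 2. The sign convention here is the one obtained by direct
#' evaluation of the signed-area integral (and matched empirically by
#' [lead_matrix()] on sampled sines): \eqn{L_{ij} > 0} when channel i peaks
#' earlier than channel j, i.e. i leads j. Note that a commonly printed form
#' of this formula carries the opposite sign. Used as a closed-form oracle in
#' tests of [lead_matrix()].
#'
#' @param alphas numeric vector of phase offsets (radians).
#' @param T_total total angular duration; must be a positive multiple of
#'   \eqn{2\pi} for the closed form to be exact.
#' @param amplitude common sine amplitude (entries scale with its square).
#' @return skew-symmetric n x n matrix.
#' @export
analytic_sine_lead_matrix <- function(alphas, T_total, amplitude = 1) {
  alphas <- as.double(alphas)
  if (T_total <= 0) stop_invalid("T_total must be positive")
  x <- sin(alphas)
  y <- cos(alphas)
  amplitude^2 * (T_total / 2) * (outer(y, x) - outer(x, y))
}

#' Cyclic-order recovery from a lead matrix
#'
#' Eigendecomposes the (skew-symmetric) lead matrix. The spectrum is purely
#' imaginary and organized in conjugate pairs; for a single system of
#' phase-lagged oscillations the matrix has rank 2 and the componentwise
#' phases of the dominant eigenvector recover the temporal (cyclic) order of
#' the channels, up to one global rotation and one orientation flip (which of
#' the conjugate pair is taken). With several independent oscillating sets on
#' disjoint channel blocks, each set contributes one dominant conjugate pair
#' whose eigenvector is supported on that block.
#'
#' Deterministic conventions: pairs are sorted by descending eigenvalue
#' modulus, the member with positive imaginary part is reported for each
#' pair, equal-modulus ties are broken by the channel index of the largest
#' eigenvector component, and phases are rotated so the largest-modulus
#' component has phase 0.
#'
#' @param L a [lead_matrix()] (or any skew-symmetric matrix).
#' @param n_pairs number of conjugate pairs to report (<= floor(d/2)).
#' @param rel_tol relative modulus threshold (fraction of the largest
#'   modulus) above which a conjugate pair counts as a detected oscillating
#'   set in `n_sets`.
#' @return object of class `cyclic_order` with fields `eigenvalues` (all d,
#'   sorted by descending modulus), `pairs` (list per requested pair:
#'   `eigenvalue`, `vector`, `modulus` (per channel), `phases` in
#'   \eqn{[0, 2\pi)}, `order` — channel ranking by phase), `n_sets`, and
#'   `channel_ids`.
#' @export
cyclic_order <- function(L, n_pairs = 1L, rel_tol = 0.1) {
  M <- unclass(L)
  d <- nrow(M)
  if (max(abs(M + t(M))) > 1e-8 * max(1, max(abs(M)))) {
    stop_invalid("input is not skew-symmetric")
  }
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L || n_pairs > d %/% 2L) {
    stop_invalid("n_pairs must lie in 1..%d", d %/% 2L)
  }
  ids <- rownames(M)
  if (is.null(ids)) ids <- paste0("ch", seq_len(d))
  eig <- eigen(M)
  anchor_idx <- apply(Mod(eig$vectors), 2, which.max)
  ord <- order(-Mod(eig$values), anchor_idx, -Im(eig$values))
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  mods <- Mod(values)
  lambda_max <- mods[1]
  n_sets <- if (lambda_max <= .Machine$double.eps * d) 0L else {
    sum(mods > rel_tol * lambda_max) %/% 2L
  }
  ## positive-imaginary member of each pair sits at odd positions of `ord`
  pairs <- vector("list", n_pairs)
  pos <- which(Im(values) >= 0)
  for (p in seq_len(n_pairs)) {
    j <- pos[p]
    v <- vectors[, j]
    modv <- Mod(v)
    anchor <- which.max(modv)
    phases <- wrap_angle(Arg(v) - Arg(v[anchor]))
    pairs[[p]] <- list(
      eigenvalue = values[j],
      vector = v,
      modulus = stats::setNames(modv, ids),
      phases = stats::setNames(phases, ids),
      order = ids[order(phases)]
    )
  }
  structure(list(eigenvalues = values, pairs = pairs, n_sets = n_sets,
                 channel_ids = ids, rel_tol = rel_tol),
            class = "cyclic_order")
}

#' @export
print.cyclic_order <- function(x, ...) {
  cat(sprintf("<cyclic_order> d = %d, detected sets = %d\n",
              length(x$channel_ids), x$n_sets))
  cat("top |eigenvalues|:",
      paste(signif(Mod(x$eigenvalues[seq_len(min(6, length(x$eigenvalues)))]), 4),
            collapse = ", "), "\n")
  if (x$n_sets == 0L) {
    cat("no cyclic structure detected\n")
  } else {
    for (p in seq_along(x$pairs)) {
      cat(sprintf("pair %d order: %s\n", p,
                  paste(x$pairs[[p]]$order, collapse = " -> ")))
    }
  }
  invisible(x)
}

#' Channel contribution counts across trials
#'
#' For each trial's chosen eigenvector, marks the `top_k` channels by
#' component modulus and accumulates per-channel totals across trials — the
#' standard summary of which channels drive a given lead-matrix eigenvector
#' in a dataset.
#'
#' @param results list of [cyclic_order()] results sharing a channel set.
#' @param eig_index which conjugate pair's eigenvector to use (1 = dominant).
#' @param top_k how many channels to mark per trial (default 10).
#' @return named integer vector of per-channel counts (sums to
#'   `length(results) * top_k`).
#' @export
channel_contribution_counts <- function(results, eig_index = 1L, top_k = 10L) {
  if (length(results) == 0) stop_invalid("no results supplied")
  ids <- results[[1]]$channel_ids
  d <- length(ids)
  top_k <- as.integer(top_k)
  if (top_k < 1L || top_k > d) stop_invalid("top_k must lie in 1..%d", d)
  counts <- stats::setNames(integer(d), ids)
  for (r in results) {
    if (!identical(r$channel_ids, ids)) {
      stop_invalid("all results must share the same channel set")
    }
    if (eig_index > length(r$pairs)) {
      stop_invalid("eig_index %d exceeds pairs available (%d)",
                   eig_index, length(r$pairs))
    }
    top <- order(-r$pairs[[eig_index]]$modulus)[seq_len(top_k)]
    counts[top] <- counts[top] + 1L
  }
  counts
}

#' Mean eigenvalue-modulus spectrum across trials
#'
#' Averages the sorted eigenvalue moduli of per-trial lead matrices — the
#' summary used to judge how many conjugate pairs dominate in a dataset. A
#' dominance ratio (largest modulus over the median) is reported as a simple
#' diagnostic of whether any cyclic structure stands out.
#'
#' @param results list of [cyclic_order()] results.
#' @return list with `mean_moduli` (sorted descending) and `dominance_ratio`.
#' @export
eigenvalue_spectrum_summary <- function(results) {
  if (length(results) == 0) stop_invalid("no results supplied")
  specs <- vapply(results, function(r) sort(Mod(r$eigenvalues), decreasing = TRUE),
                  numeric(length(results[[1]]$eigenvalues)))
  mean_moduli <- rowMeans(specs)
  med <- stats::median(mean_moduli)
  list(mean_moduli = mean_moduli,
       dominance_ratio = if (med > 0) mean_moduli[1] / med else Inf)
}
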