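#' @keywords internal
"_PACKAGE"

## Run an expression under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Derive a child seed from a master seed and a stream index, staying < 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483399) + 1L
}

## Wrap angles into [0, 2*pi).
wrap_angle <- function(x) {
  x %% (2 * pi)
}

## Wrap angle differences into (-pi, pi].
wrap_diff <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Align recovered phases to reference offsets
#'
#' Cyclic-order phases are defined up to one global rotation and one global
#' orientation flip (the two eigenvectors of a conjugate pair are complex
#' conjugates of each other). This helper finds the rotation/flip that best
#' matches a reference offset vector and reports the residual error, which is
#' how phase-recovery accuracy is assessed.
#'
#' @param phases numeric vector of recovered phases (radians).
#' @param reference numeric vector of generating offsets (radians), same length.
#' @return list with `error` (max absolute residual after alignment, radians),
#'   `flip` (+1 or -1) and `offset` (the global rotation applied).
#' @export
align_phases <- function(phases, reference) {
  stopifnot(length(phases) == length(reference))
  best <- NULL
  for (flip in c(1, -1)) {
    resid <- flip * phases - reference
    offset <- Arg(mean(exp(1i * resid)))
    err <- max(abs(wrap_diff(resid - offset)))
    if (is.null(best) || err < best$error) {
      best <- list(error = err, flip = flip, offset = offset)
    }
  }
  best
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
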