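#' Multichannel path
#'
#' Wraps a multichannel time series (samples x channels) together with its
#' sample instants as a piecewise-linear path in d-dimensional space. This is
#' the input object of [signature()] and [lead_matrix()]: the series
#' \eqn{X_t = (X^1_t, \dots, X^d_t)} is interpreted as the continuous path
#' obtained by linear interpolation between consecutive samples.
#'
#' @param values numeric matrix, samples x channels (a vector is treated as a
#'   single channel). All values must be finite.
#' @param times strictly increasing numeric vector of sample instants in
#'   seconds; defaults to `0, 1, 2, ...` (the signature is invariant to this
#'   choice as long as the order of samples is preserved).
#' @param channel_ids character vector of channel labels; defaults to
#'   `"ch1", "ch2", ...`.
#' @return an object of class `multichannel_path` with fields `times`,
#'   `values` and `channel_ids`.
#' @examples
#' p <- multichannel_path(cbind(sin(seq(0, 2 * pi, length.out = 100)),
#'                              cos(seq(0, 2 * pi, length.out = 100))))
#' p
#' @export
multichannel_path <- function(values, times = NULL, channel_ids = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (n < 2) stop_invalid("a path needs at least 2 samples, got %d", n)
  if (d < 1) stop_invalid("a path needs at least 1 channel")
  if (!all(is.finite(values))) stop_invalid("path values must be finite")
  if (is.null(times)) times <- as.double(seq_len(n) - 1L)
  times <- as.double(times)
  if (length(times) != n) stop_invalid("length(times) must equal nrow(values)")
  if (!all(is.finite(times)) || any(diff(times) <= 0)) {
    stop_invalid("times must be finite and strictly increasing")
  }
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(d))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != d) stop_invalid("need one channel id per channel")
  structure(list(times = times, values = values, channel_ids = channel_ids),
            class = "multichannel_path")
}

#' @export
print.multichannel_path <- function(x, ...) {
  cat(sprintf("<multichannel_path> %d samples x %d channels on [%g, %g] s\n",
              nrow(x$values), ncol(x$values), x$times[1],
              x$times[length(x$times)]))
  cat("channels:", paste(utils::head(x$channel_ids, 8), collapse = ", "),
      if (length(x$channel_ids) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.multichannel_path <- function(x) dim(x$values)

path_dim <- function(path) ncol(path$values)

path_increments <- function(path) {
  diff(path$values)
}

#' Resample a path on its own node sequence
#'
#' Inserts extra collinear nodes by linear interpolation at `times_new`, which
#' must contain all original node instants. Used to exercise reparametrization
#' invariance: the refined path traces the same curve, so its signature is
#' unchanged.
#'
#' @param path a [multichannel_path()].
#' @param times_new strictly increasing instants including all original nodes.
#' @return a `multichannel_path` on the refined grid.
#' @export
resample_path <- function(path, times_new) {
  times_new <- sort(unique(as.double(times_new)))
  if (!all(path$times %in% times_new)) {
    stop_invalid("times_new must contain every original node instant")
  }
  vals <- apply(path$values, 2, function(col) {
    stats::approx(path$times, col, xout = times_new)$y
  })
  multichannel_path(vals, times_new, path$channel_ids)
}
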