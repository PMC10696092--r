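#' Read and write epoch sets
#'
#' Two on-disk representations are supported.
#'
#' **CSV epoch dialect** (canonical, lossless): a long-format CSV with
#' columns `trial`, `channel`, `sample_index`, `value`, plus a JSON sidecar
#' (`<path>.json`) holding `labels`, `channel_ids`, `sample_rate` and
#' optional `subject_ids`.
#'
#' **EDF** (European Data Format, 16-bit): one data record per trial, one
#' signal per channel; labels and subjects go in the same JSON sidecar
#' (plain EDF has no trial-label concept). Values round-trip within the
#' 16-bit quantization of the per-channel physical range. GDF import is not
#' supported.
#'
#' @param epochs an [epoch_set()].
#' @param path file path.
#' @param format `"csv"` or `"edf"` (default guessed from the extension).
#' @param trial_mask optional logical per-trial mask; masked-out (`FALSE`)
#'   trials are dropped (e.g. artifact-marked trials).
#' @return `read_epochs` returns an [epoch_set()]; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(epochs, path, format = guess_format(path)) {
  stopifnot(inherits(epochs, "epoch_set"))
  format <- match.arg(format, c("csv", "edf"))
  if (format == "csv") write_epochs_csv(epochs, path) else write_epochs_edf(epochs, path)
  write_sidecar(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path, format = guess_format(path), trial_mask = NULL) {
  format <- match.arg(format, c("csv", "edf", "gdf"))
  if (format == "gdf") {
    stop_invalid("GDF import is not supported; convert to EDF or the CSV epoch dialect")
  }
  meta <- read_sidecar(path)
  es <- if (format == "csv") read_epochs_csv(path, meta) else read_epochs_edf(path, meta)
  if (!is.null(trial_mask)) {
    n <- dim(es$trials)[1]
    if (!is.logical(trial_mask) || length(trial_mask) != n) {
      stop_invalid("trial_mask must be a logical vector of length %d", n)
    }
    es <- epoch_set(es$trials[trial_mask, , , drop = FALSE],
                    es$labels[trial_mask], es$channel_ids, es$sample_rate,
                    if (!is.null(es$subject_ids)) es$subject_ids[trial_mask])
  }
  es
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = "csv", edf = "edf", gdf = "gdf",
         stop_invalid("cannot guess epoch format from extension '%s'", ext))
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(epochs, path) {
  meta <- list(labels = as.character(epochs$labels),
               channel_ids = epochs$channel_ids,
               sample_rate = epochs$sample_rate)
  if (!is.null(epochs$subject_ids)) meta$subject_ids <- epochs$subject_ids
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_invalid("missing sidecar file '%s'", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

write_epochs_csv <- function(epochs, path) {
  dm <- dim(epochs$trials)
  dt <- data.table::data.table(
    trial = rep(seq_len(dm[1]), each = dm[2] * dm[3]),
    channel = rep(rep(epochs$channel_ids, each = dm[3]), times = dm[1]),
    sample_index = rep(seq_len(dm[3]), times = dm[1] * dm[2]),
    value = as.vector(aperm(epochs$trials, c(3, 2, 1)))
  )
  data.table::fwrite(dt, path)
}

read_epochs_csv <- function(path, meta) {
  dt <- tryCatch(data.table::fread(path),
                 error = function(e) {
                   stop_invalid("failed to parse '%s': %s", path, conditionMessage(e))
                 })
  need <- c("trial", "channel", "sample_index", "value")
  if (!all(need %in% names(dt))) {
    stop_invalid("'%s' lacks required columns %s (found: %s)", path,
                 paste(need, collapse = ", "), paste(names(dt), collapse = ", "))
  }
  n <- max(dt$trial)
  chans <- meta$channel_ids
  s <- max(dt$sample_index)
  if (nrow(dt) != n * length(chans) * s) {
    stop_invalid("'%s' is not a complete trial x channel x sample grid (%d rows, expected %d)",
                 path, nrow(dt), n * length(chans) * s)
  }
  data.table::setorder(dt, trial, channel, sample_index)
  ## rebuild in (sample, channel, trial) order then permute
  data.table::setorderv(dt, c("trial"))
  arr <- array(0, c(n, length(chans), s))
  for (ch_i in seq_along(chans)) {
    sub <- dt[dt$channel == chans[ch_i], ]
    data.table::setorder(sub, trial, sample_index)
    arr[, ch_i, ] <- matrix(sub$value, nrow = n, ncol = s, byrow = TRUE)
  }
  epoch_set(arr, meta$labels, chans, meta$sample_rate, meta$subject_ids)
}

## ---- minimal EDF (16-bit) writer/reader: one data record per trial ----

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

## format a number into at most 8 ASCII characters (EDF numeric field)
num8 <- function(x) {
  vapply(x, function(v) {
    for (dg in c(6, 5, 4, 3, 2)) {
      s <- formatC(v, digits = dg, format = "g", width = 1)
      if (nchar(s) <= 8) return(s)
    }
    formatC(v, digits = 1, format = "e")
  }, character(1))
}

write_epochs_edf <- function(epochs, path) {
  dm <- dim(epochs$trials)
  n <- dm[1]; d <- dm[2]; s <- dm[3]
  phys_min <- apply(epochs$trials, 2, min)
  phys_max <- apply(epochs$trials, 2, max)
  span <- phys_max - phys_min
  span[span == 0] <- 1
  phys_max <- phys_min + span
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("pathsig epochs", 80), pad("synthetic", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + d), 8), pad("", 44), pad(n, 8),
    pad(format(s / epochs$sample_rate, scientific = FALSE), 8), pad(d, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    pad(substr(epochs$channel_ids, 1, 16), 16),          # label
    pad("", 80)[rep(1, d)],                              # transducer
    pad("uV", 8)[rep(1, d)],                             # physical dim
    pad(num8(phys_min), 8),
    pad(num8(phys_max), 8),
    pad(dig_min, 8)[rep(1, d)],
    pad(dig_max, 8)[rep(1, d)],
    pad("", 80)[rep(1, d)],                              # prefiltering
    pad(s, 8)[rep(1, d)],
    pad("", 32)[rep(1, d)])
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)
  ## physical ranges as actually parsed back (8-char ASCII) define the scaling
  pmin_r <- as.double(num8(phys_min))
  pmax_r <- as.double(num8(phys_max))
  for (i in seq_len(n)) {
    for (j in seq_len(d)) {
      x <- epochs$trials[i, j, ]
      dig <- round((x - pmin_r[j]) / (pmax_r[j] - pmin_r[j]) *
                     (dig_max - dig_min) + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_epochs_edf <- function(path, meta) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr) < 256) stop_invalid("'%s' is not a valid EDF file (short header)", path)
  n <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.double(substr(hdr, 245, 252))
  d <- as.integer(substr(hdr, 253, 256))
  if (is.na(n) || is.na(d) || n < 1 || d < 1) {
    stop_invalid("'%s' has a malformed EDF header (records=%s, signals=%s)",
                 path, n, d)
  }
  sig_hdr <- readChar(con, 256 * d, useBytes = TRUE)
  fld <- function(off, width) {
    vapply(seq_len(d), function(j) {
      substr(sig_hdr, off + (j - 1) * width + 1, off + j * width)
    }, character(1))
  }
  labels <- trimws(fld(0, 16))
  phys_min <- as.double(fld(d * (16 + 80 + 8), 8))
  phys_max <- as.double(fld(d * (16 + 80 + 8 + 8), 8))
  dig_min <- as.double(fld(d * (16 + 80 + 8 + 8 + 8), 8))
  dig_max <- as.double(fld(d * (16 + 80 + 8 + 8 + 8 + 8), 8))
  s <- as.integer(fld(d * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))[1]
  arr <- array(0, c(n, d, s))
  for (i in seq_len(n)) {
    for (j in seq_len(d)) {
      dig <- readBin(con, integer(), n = s, size = 2, endian = "little")
      if (length(dig) != s) {
        stop_invalid("'%s': truncated data record %d, signal %d", path, i, j)
      }
      arr[i, j, ] <- phys_min[j] + (dig - dig_min[j]) /
        (dig_max[j] - dig_min[j]) * (phys_max[j] - phys_min[j])
    }
  }
  sr <- s / rec_dur
  epoch_set(arr, meta$labels, labels, sr, meta$subject_ids)
}

#' Write per-trial feature tables and SPD stacks
#'
#' Signature feature matrices are written as CSV (one row per trial, header
#' = multi-index labels such as `s2_1_2`, plus a `label` column). SPD
#' stacks are written as CSV of flattened upper triangles (row-major within
#' the triangle) with a sidecar JSON recording channel ids and epsilon.
#'
#' @param features output of [extract_features()].
#' @param path output CSV path.
#' @param epsilon recorded in the sidecar for SPD stacks.
#' @return `path` invisibly.
#' @export
write_features <- function(features, path, epsilon = NULL) {
  labels <- attr(features, "labels")
  if (is.array(features) && length(dim(features)) == 3) {
    d <- dim(features)[1]
    up <- which(upper.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
    up <- up[order(up[, 1], up[, 2]), , drop = FALSE]
    mat <- t(apply(features, 3, function(A) A[up]))
    colnames(mat) <- sprintf("a_%d_%d", up[, 1], up[, 2])
    dt <- data.table::data.table(label = as.character(labels), mat)
    data.table::fwrite(dt, path)
    jsonlite::write_json(list(channel_ids = paste0("ch", seq_len(d)),
                              epsilon = epsilon, layout = "upper_triangle_rowmajor"),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    dt <- data.table::data.table(label = as.character(labels), features)
    data.table::fwrite(dt, path)
  }
  invisible(path)
}

#' Serialize fitted Riemannian models to JSON
#'
#' Stores MDM class means or a tangent-space reference as nested lists in a
#' documented JSON container, so fitted geometry can be inspected or reused
#' outside R.
#'
#' @param model an [mdm()] or [tangent_classifier()] fit.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "mdm")) {
    list(type = "mdm", levels = model$levels,
         means = lapply(model$means, function(M) unname(apply(M, 1, as.list))))
  } else if (inherits(model, "tangent_classifier")) {
    list(type = "tangent", levels = model$levels, model = model$model,
         reference = unname(apply(model$reference, 1, as.list)))
  } else {
    stop_invalid("unsupported model class '%s'", class(model)[1])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
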