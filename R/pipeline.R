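#' Zero-phase band-pass filtering of an epoch set
#'
#' Applies an order-4 Butterworth band-pass (design: [signal::butter()] with
#' normalized band edges) forward and backward ([signal::filtfilt()]) to each
#' channel of each trial, so the phase response is zero and lead-lag
#' relations are not distorted. The default 8-30 Hz band covers the mu/alpha
#' and beta rhythms relevant to motor imagery. Trial length is preserved.
#'
#' @param epochs an [epoch_set()].
#' @param low,high band edges in Hz; `high` must stay below the Nyquist
#'   frequency.
#' @return a filtered [epoch_set()].
#' @export
bandpass <- function(epochs, low = 8, high = 30) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$sample_rate / 2
  if (low <= 0 || high <= low || high >= nyq) {
    stop_invalid("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
                 low, high, nyq)
  }
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  out <- epochs
  n <- dim(epochs$trials)[1]
  d <- dim(epochs$trials)[2]
  for (i in seq_len(n)) {
    for (j in seq_len(d)) {
      out$trials[i, j, ] <- signal::filtfilt(bf, epochs$trials[i, j, ])
    }
  }
  out
}

#' Feature specification
#'
#' @param type `"signature"` (flattened truncated signature vector),
#'   `"lead-spd"` (lead-matrix-derived SPD matrix) or `"covariance"`
#'   (sample covariance SPD matrix).
#' @param level signature truncation level (1-4), for `"signature"`.
#' @param cumulative include all levels 1..level (default) or level only.
#' @param epsilon diagonal regularization for `"lead-spd"`.
#' @param shrinkage covariance shrinkage for `"covariance"`.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(type = c("signature", "lead-spd", "covariance"),
                         level = 2L, cumulative = TRUE, epsilon = 0.001,
                         shrinkage = 0) {
  type <- match.arg(type)
  level <- as.integer(level)
  if (type == "signature" && !(level %in% 1:4)) {
    stop_invalid("signature level must be in 1..4")
  }
  if (epsilon <= 0) stop_invalid("epsilon must be positive")
  structure(list(type = type, level = level, cumulative = cumulative,
                 epsilon = epsilon, shrinkage = shrinkage),
            class = "feature_spec")
}

#' Extract per-trial features from an epoch set
#'
#' Runs the configured feature map over every trial. Signature features are
#' fixed-length vectors whatever the trial sample count; SPD features
#' (lead-derived or covariance) are d x d matrices, every one of which is
#' checked positive definite before being returned.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [feature_spec()].
#' @return for `"signature"`: numeric matrix trials x features with
#'   multi-index column names; otherwise a d x d x trials array of SPD
#'   matrices. Both carry attribute `labels` (and `subject_ids` if present).
#' @export
extract_features <- function(epochs, spec) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "feature_spec"))
  n <- dim(epochs$trials)[1]
  d <- dim(epochs$trials)[2]
  if (spec$type == "signature") {
    levels <- if (spec$cumulative) seq_len(spec$level) else spec$level
    out <- matrix(0, n, sum(d^levels))
    colnames(out) <- signature_names(d, levels)
    for (i in seq_len(n)) {
      out[i, ] <- flatten(signature(trial_path(epochs, i), spec$level), levels)
    }
  } else {
    out <- array(0, c(d, d, n))
    for (i in seq_len(n)) {
      p <- trial_path(epochs, i)
      A <- if (spec$type == "lead-spd") {
        lead_spd(lead_matrix(p), spec$epsilon)
      } else {
        sample_covariance(p, spec$shrinkage)
      }
      chk <- assert_spd(A)
      if (!chk$spd) {
        stop_invalid("trial %d produced a non-SPD feature (min eig %.3g)",
                     i, chk$min_eigenvalue)
      }
      out[, , i] <- A
    }
  }
  attr(out, "labels") <- epochs$labels
  attr(out, "subject_ids") <- epochs$subject_ids
  out
}

#' Classifier specification
#'
#' Vector-feature families: `"svm"` (linear, cost 1), `"lda"`, `"logistic"`
#' (ridge), `"rf"` (random forest, 200 trees), `"mlp"` (single hidden layer,
#' size 16, decay 0.01). SPD families: `"mdm"` ([mdm()]) and `"tangent"`
#' ([tangent_classifier()]). Hyperparameters are fixed documented defaults.
#'
#' @param model one of the names above.
#' @param ... overrides: `lambda` (logistic/tangent ridge penalty),
#'   `tangent_model` (linear rule inside `"tangent"`).
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(model = c("logistic", "svm", "lda", "rf", "mlp",
                                      "mdm", "tangent"), ...) {
  model <- match.arg(model)
  opts <- list(...)
  structure(list(model = model,
                 lambda = opts$lambda %||% 0.01,
                 tangent_model = opts$tangent_model %||% "logistic"),
            class = "classifier_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_any <- function(features, idx, labels, spec, seed) {
  if (spec$model %in% c("mdm", "tangent")) {
    if (!is.array(features) || length(dim(features)) != 3) {
      stop_invalid("classifier '%s' needs SPD features", spec$model)
    }
    mats <- as_spd_list(features[, , idx, drop = FALSE])
    if (spec$model == "mdm") {
      mdm(mats, labels[idx])
    } else {
      tangent_classifier(mats, labels[idx], model = spec$tangent_model,
                         lambda = spec$lambda, seed = seed)
    }
  } else {
    if (is.array(features) && length(dim(features)) == 3) {
      stop_invalid("classifier '%s' needs vector features", spec$model)
    }
    fit_linear_model(features[idx, , drop = FALSE], labels[idx],
                     spec$model, lambda = spec$lambda, seed = seed)
  }
}

predict_any <- function(fit, features, idx, levels, spec) {
  if (spec$model %in% c("mdm", "tangent")) {
    predict(fit, as_spd_list(features[, , idx, drop = FALSE]))
  } else {
    predict_linear_model(fit, features[idx, , drop = FALSE], levels)
  }
}

#' Cross-validated classification accuracy
#'
#' Runs seeded stratified k-fold or leave-one-subject-out cross-validation
#' of a classifier on extracted features. Fold assignment is a deterministic
#' function of the seed and the labels (not of trial order); classifier
#' training randomness is re-seeded per fold, so repeated runs with the same
#' inputs are identical.
#'
#' @param features output of [extract_features()] (matrix or SPD array); per
#'   trial labels are taken from `labels` or the `labels` attribute.
#' @param labels optional explicit label vector.
#' @param classifier a [classifier_spec()].
#' @param scheme `"kfold"` or `"loso"` (leave one subject out; requires
#'   subject ids).
#' @param k number of folds for `"kfold"`.
#' @param subject_ids optional explicit subject ids for `"loso"`.
#' @param seed integer seed.
#' @return object of class `cv_report`: per-unit accuracies (`accuracy`),
#'   `mean`, `sd`, `scheme` and `units` (fold or subject names).
#' @export
crossvalidate <- function(features, labels = NULL, classifier,
                          scheme = c("kfold", "loso"), k = 10L,
                          subject_ids = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(classifier, "classifier_spec"))
  labels <- as.factor(labels %||% attr(features, "labels"))
  n <- length(labels)
  if (n == 0) stop_invalid("labels are required")
  if (scheme == "loso") {
    subject_ids <- subject_ids %||% attr(features, "subject_ids")
    if (is.null(subject_ids)) stop_invalid("leave-one-subject-out needs subject ids")
    units <- sort(unique(subject_ids))
    fold_of <- match(subject_ids, units)
  } else {
    k <- as.integer(k)
    if (k < 2) stop_invalid("need at least 2 folds")
    fold_of <- integer(n)
    with_local_seed(derive_seed(seed, 0L), {
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    units <- sprintf("fold%02d", seq_len(k))
  }
  acc <- numeric(length(units))
  for (f in seq_along(units)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    tl <- droplevels(labels[train])
    if (nlevels(tl) < 2) {
      stop_invalid("training split for %s contains a single class", units[f])
    }
    fit <- fit_any(features, train, labels, classifier, derive_seed(seed, f))
    pred <- predict_any(fit, features, test, levels(labels), classifier)
    acc[f] <- mean(pred == labels[test])
  }
  structure(list(accuracy = stats::setNames(acc, units),
                 mean = mean(acc), sd = stats::sd(acc),
                 scheme = scheme, units = units, n_trials = n,
                 classifier = classifier$model),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cv_report> %s, %s over %d units: %.1f%% (%.1f)\n",
              x$classifier, x$scheme, length(x$units),
              100 * x$mean, 100 * x$sd))
  invisible(x)
}

#' Responder split and paired method comparison
#'
#' Splits subjects into less/more responsive groups by their accuracy under
#' a reference method (threshold = chance level 0.5 by default), then
#' compares a second method against the reference within each group with
#' paired t-tests, Bonferroni-corrected over the two groups.
#'
#' @param report_ref,report_alt `cv_report`s with per-subject accuracies for
#'   the same subjects (reference and alternative method).
#' @param threshold accuracy threshold defining the groups.
#' @return list with per-group subject names, paired mean differences
#'   (alternative minus reference), raw and Bonferroni-corrected p-values.
#' @export
responder_split <- function(report_ref, report_alt, threshold = 0.5) {
  a <- report_ref$accuracy
  b <- report_alt$accuracy
  if (!identical(names(a), names(b))) {
    stop_invalid("the two reports must cover the same subjects in the same order")
  }
  lo <- which(a <= threshold)
  hi <- which(a > threshold)
  cmp <- function(idx) {
    if (length(idx) == 0) {
      return(list(n = 0L, mean_diff = NA_real_, p = NA_real_))
    }
    d <- b[idx] - a[idx]
    p <- if (length(idx) >= 2 && stats::sd(d) > 0) {
      stats::t.test(b[idx], a[idx], paired = TRUE)$p.value
    } else NA_real_
    list(n = length(idx), mean_diff = mean(d), p = p)
  }
  lo_c <- cmp(lo)
  hi_c <- cmp(hi)
  raw <- c(less_responsive = lo_c$p, more_responsive = hi_c$p)
  structure(list(
    threshold = threshold,
    less_responsive = names(a)[lo],
    more_responsive = names(a)[hi],
    mean_diff = c(less_responsive = lo_c$mean_diff,
                  more_responsive = hi_c$mean_diff),
    p_raw = raw,
    p_adjusted = stats::p.adjust(raw, method = "bonferroni")
  ), class = "responder_split")
}

#' @export
print.responder_split <- function(x, ...) {
  cat(sprintf("<responder_split> threshold %.2f: %d less / %d more responsive\n",
              x$threshold, length(x$less_responsive), length(x$more_responsive)))
  cat(sprintf("  mean diff (alt - ref): less %.3f, more %.3f\n",
              x$mean_diff[1], x$mean_diff[2]))
  cat(sprintf("  Bonferroni p: less %.3g, more %.3g\n",
              x$p_adjusted[1], x$p_adjusted[2]))
  invisible(x)
}
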