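#' Minimum-distance-to-mean classifier on the SPD manifold
#'
#' Fits one Karcher mean per class under the affine-invariant metric;
#' prediction assigns a matrix to the class whose mean is nearest in
#' [airm_distance()]. Distance ties go to the earliest factor level.
#'
#' @param x list of SPD matrices (or d x d x n array) of training features.
#' @param labels factor (or coercible) of class labels, one per matrix.
#' @param tol,max_iter passed to [geometric_mean()].
#' @return object of class `mdm` with per-class `means`.
#' @seealso [tangent_classifier()] for the tangent-space variant.
#' @export
mdm <- function(x, labels, tol = 1e-8, max_iter = 200L) {
  x <- as_spd_list(x)
  labels <- as.factor(labels)
  if (length(x) != length(labels)) stop_invalid("one label per matrix required")
  if (nlevels(labels) < 2) stop_invalid("need at least 2 classes")
  if (any(table(labels) == 0)) stop_invalid("every class needs at least one sample")
  means <- lapply(levels(labels), function(cl) {
    geometric_mean(x[labels == cl], tol = tol, max_iter = max_iter)
  })
  names(means) <- levels(labels)
  structure(list(means = means, levels = levels(labels)), class = "mdm")
}

#' @export
print.mdm <- function(x, ...) {
  cat(sprintf("<mdm> %d classes (%s), %d x %d SPD means\n",
              length(x$levels), paste(x$levels, collapse = ", "),
              nrow(x$means[[1]]), ncol(x$means[[1]])))
  invisible(x)
}

#' @rdname mdm
#' @param object fitted `mdm` model.
#' @param newdata list of SPD matrices or d x d x n array.
#' @param ... unused.
#' @export
predict.mdm <- function(object, newdata, ...) {
  newdata <- as_spd_list(newdata)
  preds <- vapply(newdata, function(A) {
    dists <- vapply(object$means, function(M) airm_distance(M, A), numeric(1))
    which.min(dists)  # ties -> earliest level
  }, integer(1))
  factor(object$levels[preds], levels = object$levels)
}

#' Tangent-space classifier on the SPD manifold
#'
#' Projects all training features to the tangent space at their Karcher mean
#' via [log_map()], then fits a classical linear classifier on the resulting
#' Euclidean vectors. At prediction time the *training* reference mean is
#' reused. The default linear rule is ridge-regularized logistic regression
#' (handles tangent dimension larger than the sample count); linear SVM and
#' LDA are available alternatives.
#'
#' @param x list of SPD matrices (or d x d x n array).
#' @param labels class labels (factor or coercible).
#' @param model one of `"logistic"`, `"svm"`, `"lda"`.
#' @param reference `"mean"` (Karcher mean of training features, default) or
#'   `"identity"`.
#' @param lambda ridge penalty for the logistic rule.
#' @param seed integer seed controlling any training randomness.
#' @return object of class `tangent_classifier`.
#' @export
tangent_classifier <- function(x, labels, model = c("logistic", "svm", "lda"),
                               reference = c("mean", "identity"),
                               lambda = 0.01, seed = 1L) {
  x <- as_spd_list(x)
  labels <- as.factor(labels)
  model <- match.arg(model)
  reference <- match.arg(reference)
  if (length(x) != length(labels)) stop_invalid("one label per matrix required")
  if (nlevels(labels) < 2) stop_invalid("need at least 2 classes")
  d <- nrow(x[[1]])
  ref <- if (reference == "mean") geometric_mean(x) else diag(d)
  feats <- t(vapply(x, function(A) as.double(log_map(ref, A)),
                    numeric(d * (d + 1) / 2)))
  fit <- fit_linear_model(feats, labels, model, lambda, seed)
  structure(list(reference = ref, model = model, fit = fit,
                 levels = levels(labels), lambda = lambda),
            class = "tangent_classifier")
}

#' @export
print.tangent_classifier <- function(x, ...) {
  cat(sprintf("<tangent_classifier> model = %s, %d classes, reference %d x %d\n",
              x$model, length(x$levels), nrow(x$reference), ncol(x$reference)))
  invisible(x)
}

#' @rdname tangent_classifier
#' @param object fitted `tangent_classifier`.
#' @param newdata list of SPD matrices or d x d x n array.
#' @param ... unused.
#' @export
predict.tangent_classifier <- function(object, newdata, ...) {
  newdata <- as_spd_list(newdata)
  d <- nrow(object$reference)
  feats <- t(vapply(newdata, function(A) as.double(log_map(object$reference, A)),
                    numeric(d * (d + 1) / 2)))
  predict_linear_model(object$fit, feats, object$levels)
}

## ---- shared linear/classical model wrappers (also used for signature
## feature vectors in the cross-validation runner) ----

fit_linear_model <- function(x, labels, model, lambda = 0.01, seed = 1L,
                             mlp_size = 16L) {
  labels <- as.factor(labels)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  with_local_seed(seed, switch(
    model,
    logistic = {
      fam <- if (nlevels(labels) == 2) "binomial" else "multinomial"
      list(kind = "glmnet", lambda = lambda,
           obj = glmnet::glmnet(x, labels, family = fam, alpha = 0,
                                lambda = lambda, standardize = TRUE))
    },
    svm = list(kind = "svm",
               obj = e1071::svm(x, labels, kernel = "linear", cost = 1,
                                scale = apply(x, 2, stats::sd) > 0)),
    lda = list(kind = "lda", obj = suppressWarnings(MASS::lda(x, labels))),
    rf = list(kind = "rf",
              obj = randomForest::randomForest(x, labels, ntree = 200)),
    mlp = {
      cs <- apply(x, 2, stats::sd)
      cs[cs == 0] <- 1
      cm <- colMeans(x)
      xs <- scale(x, center = cm, scale = cs)
      list(kind = "mlp", center = cm, scale = cs,
           obj = nnet::nnet(xs, nnet::class.ind(labels), size = mlp_size,
                            decay = 0.01, maxit = 200, softmax = TRUE,
                            trace = FALSE, MaxNWts = 1e6))
    },
    stop_invalid("unknown classifier model '%s'", model)
  ))
}

predict_linear_model <- function(fit, x, levels) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  pred <- switch(
    fit$kind,
    glmnet = {
      p <- predict(fit$obj, x, s = fit$lambda, type = "class")
      as.character(p)
    },
    svm = as.character(predict(fit$obj, x)),
    lda = as.character(predict(fit$obj, x)$class),
    rf = as.character(predict(fit$obj, x)),
    mlp = {
      xs <- scale(x, center = fit$center, scale = fit$scale)
      p <- predict(fit$obj, xs)
      colnames(p)[max.col(p, ties.method = "first")]
    }
  )
  factor(pred, levels = levels)
}
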