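# The classifier grid: 6 SVM kernels and 6 kNN variants.
#
# SVMs use one-vs-one pairwise voting (10 binary machines for 5 classes) with
# box constraint 1.  Polynomial kernels of degree 1/2/3 play the roles of the
# linear/quadratic/cubic presets; the Gaussian presets use kernel scales
# sqrt(P)/4 (fine), sqrt(P) (medium) and 4*sqrt(P) (coarse) for P predictors,
# in strict ratio 1:4:16.  kNN variants: fine (k=1), medium (k=10), coarse
# (k=100) Euclidean; cosine (k=10); cubic distance (Minkowski p=3, k=10);
# weighted (k=10, inverse-squared-distance vote weights).  All classifiers
# consume z-scored features; the standardization statistics are frozen from
# the training rows and reapplied at prediction time.

SVM_KERNELS <- c("linear", "quadratic", "cubic",
                 "gauss_fine", "gauss_medium", "gauss_coarse")
KNN_VARIANTS <- c("fine", "medium", "coarse", "cosine", "cubic_distance", "weighted")

#' Classifier specification
#'
#' @param family `"svm"` or `"knn"`.
#' @param kernel for SVMs, one of linear, quadratic, cubic, gauss_fine,
#'   gauss_medium, gauss_coarse.
#' @param variant for kNN, one of fine (k=1), medium (k=10), coarse (k=100),
#'   cosine (k=10), cubic_distance (k=10, Minkowski p=3), weighted (k=10,
#'   inverse-squared-distance weights).
#' @param standardize z-score features inside the model (default TRUE).
#' @param class_weights optional named class-weight vector for SVMs (defaults
#'   off: no rebalancing despite the transition-heavy class prior).
#' @param seed integer seed stored with the spec (training is deterministic;
#'   the seed is consumed by resampling protocols such as [kfold_cv()]).
#' @return A list of class `classifier_spec`.
#' @examples
#' classifier_spec("svm", kernel = "cubic")
#' classifier_spec("knn", variant = "weighted")
#' @export
classifier_spec <- function(family = c("svm", "knn"), kernel = NULL,
                            variant = NULL, standardize = TRUE,
                            class_weights = NULL, seed = 1L) {
  family <- match.arg(family)
  if (family == "svm") {
    if (!is.null(variant)) stop("variant applies to knn, not svm")
    kernel <- match.arg(kernel %||% "cubic", SVM_KERNELS)
  } else {
    if (!is.null(kernel)) stop("kernel applies to svm, not knn")
    variant <- match.arg(variant %||% "fine", KNN_VARIANTS)
  }
  structure(list(family = family, kernel = kernel, variant = variant,
                 standardize = standardize, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s (%s)\n", x$family,
              if (x$family == "svm") x$kernel else x$variant))
  invisible(x)
}

#' Short identifier of a classifier spec
#' @param spec a [classifier_spec()].
#' @return e.g. `"svm_cubic"` or `"knn_weighted"`.
#' @export
spec_id <- function(spec) {
  paste(spec$family, if (spec$family == "svm") spec$kernel else spec$variant,
        sep = "_")
}

knn_params <- function(variant) {
  switch(variant,
         fine = list(k = 1L, metric = "euclidean", weighted = FALSE),
         medium = list(k = 10L, metric = "euclidean", weighted = FALSE),
         coarse = list(k = 100L, metric = "euclidean", weighted = FALSE),
         cosine = list(k = 10L, metric = "cosine", weighted = FALSE),
         cubic_distance = list(k = 10L, metric = "minkowski3", weighted = FALSE),
         weighted = list(k = 10L, metric = "euclidean", weighted = TRUE))
}

#' Gaussian kernel scale presets
#'
#' With `p` predictors the fine/medium/coarse Gaussian presets use kernel
#' scales `sqrt(p)/4`, `sqrt(p)` and `4*sqrt(p)` (ratio 1:4:16).  The radial
#' kernel `exp(-|u - v|^2 / (2 s^2))` translates to the libsvm `gamma`
#' `1/(2 s^2)`.
#'
#' @param kernel one of gauss_fine, gauss_medium, gauss_coarse.
#' @param p number of predictors.
#' @return The kernel scale `s`.
#' @export
gaussian_kernel_scale <- function(kernel, p) {
  switch(kernel,
         gauss_fine = sqrt(p) / 4,
         gauss_medium = sqrt(p),
         gauss_coarse = 4 * sqrt(p),
         stop("not a gaussian kernel: ", kernel))
}

#' Train a classifier on a feature matrix
#'
#' Fits one model of the SVM/kNN grid.  Standardization statistics are
#' computed from the training rows only and frozen into the returned object;
#' prediction applies the same transform.  Training is deterministic for a
#' given spec and data.
#'
#' @param spec a [classifier_spec()].
#' @param fm a [feature_matrix()] with at least 2 classes present and no
#'   missing values.
#' @return An object of class `wod_classifier` with [predict()] support.
#' @export
train_classifier <- function(spec, fm) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(fm, "feature_matrix"))
  if (!nrow(fm$values)) stop("empty training matrix")
  if (anyNA(fm$values)) stop("training matrix contains missing values")
  y <- droplevels(fm$label)
  if (nlevels(y) < 2) stop("training data must contain at least 2 classes")
  st <- if (spec$standardize) standardize(fm$values) else
    list(matrix = fm$values, stats = NULL)
  X <- st$matrix
  fit <- if (spec$family == "svm") {
    p <- ncol(X)
    args <- list(x = X, y = y, scale = FALSE, cost = 1, fitted = FALSE)
    args <- c(args, switch(spec$kernel,
      linear = list(kernel = "linear"),
      quadratic = list(kernel = "polynomial", degree = 2, gamma = 1, coef0 = 1),
      cubic = list(kernel = "polynomial", degree = 3, gamma = 1, coef0 = 1),
      list(kernel = "radial",
           gamma = 1 / (2 * gaussian_kernel_scale(spec$kernel, p)^2))))
    if (!is.null(spec$class_weights)) args$class.weights <- spec$class_weights
    do.call(e1071::svm, args)
  } else {
    c(knn_params(spec$variant), list(X = X, y = y))
  }
  structure(list(spec = spec, fit = fit, stats = st$stats,
                 classes = levels(y), columns = colnames(fm$values)),
            class = "wod_classifier")
}

#' @export
print.wod_classifier <- function(x, ...) {
  cat(sprintf("<wod_classifier> %s: %d features, classes {%s}\n",
              spec_id(x$spec), length(x$columns),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict window classes
#'
#' Returns one label per row plus a per-class score matrix whose row-wise
#' argmax equals the predicted label.  Scores are signed one-vs-rest
#' aggregated pairwise-voting margins for SVMs and (possibly weighted)
#' neighbor vote fractions for kNN; both are monotone in class likelihood
#' and suitable for one-vs-rest ROC analysis.
#'
#' @param object a trained `wod_classifier`.
#' @param fm a [feature_matrix()] (or numeric matrix) whose columns match
#'   the training columns.
#' @param ... unused.
#' @return A list with `label` (factor over the training classes) and
#'   `scores` (numeric matrix, one column per class).
#' @export
predict.wod_classifier <- function(object, fm, ...) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (!identical(colnames(X), object$columns))
    stop("prediction columns do not match the training columns")
  if (!is.null(object$stats)) X <- standardize(X, object$stats)$matrix
  cl <- object$classes
  if (object$spec$family == "svm") {
    pr <- stats::predict(object$fit, X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    scores <- matrix(0, nrow(X), length(cl), dimnames = list(NULL, cl))
    for (nm in colnames(dv)) {
      pair <- strsplit(nm, "/", fixed = TRUE)[[1]]
      scores[, pair[1]] <- scores[, pair[1]] + dv[, nm]
      scores[, pair[2]] <- scores[, pair[2]] - dv[, nm]
    }
    lab <- factor(as.character(pr), levels = cl)
  } else {
    sc <- knn_scores(object$fit, X)
    scores <- sc
    lab <- factor(cl[max.col(sc, ties.method = "first")], levels = cl)
  }
  list(label = lab, scores = scores)
}

# vote-fraction score matrix for the kNN variants; ties in distance are
# broken by training-row order, ties in votes by class order
knn_scores <- function(fit, X) {
  Tr <- fit$X; y <- fit$y; k <- min(fit$k, nrow(Tr))
  cl <- levels(y)
  D2 <- switch(fit$metric,
    euclidean = {
      # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
      d <- outer(rowSums(X^2), rowSums(Tr^2), `+`) - 2 * tcrossprod(X, Tr)
      pmax(d, 0)
    },
    cosine = {
      nx <- sqrt(rowSums(X^2)); nt <- sqrt(rowSums(Tr^2))
      cs <- tcrossprod(X, Tr) / (pmax(nx, 1e-300) %o% pmax(nt, 1e-300))
      1 - cs
    },
    minkowski3 = {
      d <- matrix(0, nrow(X), nrow(Tr))
      tT <- t(Tr)
      for (i in seq_len(nrow(X)))
        d[i, ] <- colSums(abs(tT - X[i, ])^3)^(1 / 3)
      d
    })
  scores <- matrix(0, nrow(X), length(cl), dimnames = list(NULL, cl))
  yi <- as.integer(y)
  for (i in seq_len(nrow(X))) {
    nb <- order(D2[i, ])[seq_len(k)]
    w <- if (fit$weighted) {
      dd <- D2[i, nb]
      if (fit$metric == "euclidean") dd <- sqrt(dd)
      1 / pmax(dd, 1e-12)^2
    } else rep(1, k)
    v <- vapply(seq_along(cl), function(m) sum(w[yi[nb] == m]), 0)
    scores[i, ] <- v / sum(v)
  }
  scores
}

#' Number of binary machines in a one-vs-one SVM
#' @param model a trained `wod_classifier` with `family == "svm"`.
#' @return Integer count of pairwise binary SVMs (`choose(n_classes, 2)`).
#' @export
n_binary_machines <- function(model) {
  stopifnot(model$spec$family == "svm")
  length(model$fit$labels) * (length(model$fit$labels) - 1L) / 2L
}
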