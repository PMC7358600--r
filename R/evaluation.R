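# Confusion matrices, per-class metrics, one-vs-rest ROC/AUC, stratified
# k-fold cross-validation (Stage 1) and the leave-one-subject-out protocol on
# the workout-simulation set (Stage 2).

#' Confusion matrix of window classifications
#'
#' Rows are true classes, columns predicted classes, in the fixed order
#' C&J, AS, BJ, BP, TRANS.
#'
#' @param true,pred label vectors of equal length (values in
#'   [drill_levels()]).
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true, pred) {
  if (length(true) != length(pred))
    stop("true and pred must have the same length")
  t <- as_drill_factor(true); p <- as_drill_factor(pred)
  cm <- table(true = t, predicted = p)
  out <- matrix(as.integer(cm), 5, 5,
                dimnames = list(true = drill_levels(), predicted = drill_levels()))
  class(out) <- c("confusion_matrix", class(out))
  out
}

as_confusion <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 5, ncol(m) == 5, all(m >= 0))
  dimnames(m) <- list(true = drill_levels(), predicted = drill_levels())
  class(m) <- c("confusion_matrix", class(unclass(m)))
  m
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  tot <- sum(x)
  cat("Confusion matrix (true rows x predicted columns), n =", tot, "\n")
  m <- unclass(x)
  disp <- matrix(sprintf(paste0("%d (%.", digits, "f%%)"), m, 100 * m / tot),
                 5, 5, dimnames = dimnames(m))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Per-class one-vs-rest metrics
#'
#' Collapses the confusion matrix one-vs-rest for the given class and
#' reports TP/TN/FP/FN counts with accuracy `ACC = (TP+TN)/(TP+TN+FP+FN)`,
#' precision `PPV = TP/(TP+FP)`, sensitivity `TPR = TP/(TP+FN)`, plus
#' `FNR = 1 - TPR` and `FPR = FP/(FP+TN)`.  A zero denominator yields 0 for
#' the affected rate, with `degenerate = TRUE` flagged.
#'
#' @param cm a [confusion()] matrix.
#' @param class one of [drill_levels()].
#' @return A list of counts and rates.
#' @export
class_metrics <- function(cm, class) {
  cm <- as_confusion(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  i <- match(class, drill_levels())
  if (is.na(i)) stop("unknown class: ", class)
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  rate <- function(num, den) if (den > 0) num / den else 0
  degenerate <- (tp + fp == 0) || (tp + fn == 0) || (fp + tn == 0)
  list(class = class, TP = tp, TN = tn, FP = fp, FN = fn,
       ACC = (tp + tn) / sum(cm),
       PPV = rate(tp, tp + fp),
       TPR = rate(tp, tp + fn),
       FNR = if (tp + fn > 0) 1 - tp / (tp + fn) else 0,
       FPR = rate(fp, fp + tn),
       degenerate = degenerate)
}

#' Overall accuracy of a confusion matrix
#' @param cm a [confusion()] matrix.
#' @return trace / total, a proportion in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  cm <- as_confusion(cm)
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Per-class metric table
#'
#' [class_metrics()] for every class, as a data frame (proportions, not
#' percentages).
#'
#' @param cm a [confusion()] matrix.
#' @return A `data.frame` with one row per class.
#' @export
metrics_table <- function(cm) {
  rows <- lapply(drill_levels(), function(cl) {
    m <- class_metrics(cm, cl)
    data.frame(class = cl, TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
               ACC = m$ACC, PPV = m$PPV, TPR = m$TPR, FNR = m$FNR, FPR = m$FPR)
  })
  do.call(rbind, rows)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps a threshold over the unique scores of the positive class and
#' reports (FPR, TPR) points plus the trapezoid-rule AUC.  With only one
#' class present in the truth the curve is undefined and the result is
#' flagged.
#'
#' @param scores numeric vector (or one column of the score matrix from
#'   [predict.wod_classifier()]): higher means more likely positive.
#' @param true label vector.
#' @param class the positive class.
#' @return A list with `curve` (`data.frame` of threshold/FPR/TPR), `auc`,
#'   and `defined` (FALSE when truth is single-class, in which case `auc`
#'   is `NA`).
#' @export
roc_ovr <- function(scores, true, class) {
  stopifnot(length(scores) == length(true), all(is.finite(scores)))
  pos <- as_drill_factor(true) == class
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0)
    return(list(curve = NULL, auc = NA_real_, defined = FALSE))
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores[pos] >= t) / np, 0)
  fpr <- vapply(th, function(t) sum(scores[!pos] >= t) / nn, 0)
  curve <- data.frame(threshold = c(Inf, th), FPR = c(0, fpr), TPR = c(0, tpr))
  if (curve$FPR[nrow(curve)] < 1 || curve$TPR[nrow(curve)] < 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, FPR = 1, TPR = 1))
  auc <- sum(diff(curve$FPR) * (head(curve$TPR, -1) + tail(curve$TPR, -1)) / 2)
  list(curve = curve, auc = auc, defined = TRUE)
}

#' Evaluation report
#'
#' Bundles the pooled confusion matrix, per-class metrics, overall accuracy
#' and one-vs-rest ROC/AUC of one evaluation protocol run.
#'
#' @param cm pooled [confusion()] matrix.
#' @param rocs optional named list of [roc_ovr()] results, one per class.
#' @param protocol descriptor list (stage, windowing, sensor subset,
#'   classifier spec, ...), carried verbatim for provenance.
#' @param extra additional fields (e.g. per-iteration accuracies).
#' @return An object of class `evaluation_report`.
#' @export
evaluation_report <- function(cm, rocs = NULL, protocol = list(), extra = list()) {
  cm <- as_confusion(cm)
  structure(c(list(confusion = cm,
                   metrics = metrics_table(cm),
                   overall_accuracy = overall_accuracy(cm),
                   auc = if (!is.null(rocs))
                     vapply(rocs, `[[`, 0, "auc") else NULL,
                   rocs = rocs, protocol = protocol),
              extra),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report>%s overall accuracy %.1f%% (n = %d windows)\n",
              if (length(x$protocol)) paste0(" [", paste(unlist(x$protocol), collapse = ", "), "]") else "",
              100 * x$overall_accuracy, sum(x$confusion)))
  m <- x$metrics
  cat(sprintf("  %-6s ACC %5.1f  PPV %5.1f  TPR %5.1f\n",
              m$class, 100 * m$ACC, 100 * m$PPV, 100 * m$TPR), sep = "")
  invisible(x)
}

# pooled one-vs-rest ROCs from stacked scores/truth
pooled_rocs <- function(scores, true) {
  out <- lapply(drill_levels(), function(cl) {
    if (cl %in% colnames(scores)) roc_ovr(scores[, cl], true, cl)
    else list(curve = NULL, auc = NA_real_, defined = FALSE)
  })
  names(out) <- drill_levels()
  out
}

#' Stratified k-fold cross-validation
#'
#' Stage-1 assessment: rows are partitioned into `k` folds stratified by
#' class with a seeded shuffle; each fold is predicted by a model trained on
#' the remaining folds and the pooled confusion matrix is reported.
#'
#' @param fm a [feature_matrix()].
#' @param spec a [classifier_spec()].
#' @param k number of folds (default 5); every class must have at least `k`
#'   members.
#' @param seed integer seed for the fold assignment.
#' @return An [evaluation_report()] with a `folds` element (per-row fold id).
#' @export
kfold_cv <- function(fm, spec, k = 5, seed = 1L) {
  y <- fm$label
  cnt <- table(droplevels(y))
  if (any(cnt < k))
    stop("class rarer than k folds: ",
         paste(names(cnt)[cnt < k], collapse = ", "))
  n <- length(y)
  fold <- integer(n)
  set.seed(seed)
  for (cl in levels(droplevels(y))) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  truth <- character(0); predd <- character(0)
  scores <- NULL
  for (f in seq_len(k)) {
    test <- fold == f
    model <- train_classifier(spec, subset_rows(fm, !test))
    pr <- predict(model, subset_rows(fm, test))
    truth <- c(truth, as.character(y[test]))
    predd <- c(predd, as.character(pr$label))
    sc <- matrix(0, sum(test), 5, dimnames = list(NULL, drill_levels()))
    sc[, colnames(pr$scores)] <- pr$scores
    scores <- rbind(scores, sc)
  }
  cm <- confusion(truth, predd)
  evaluation_report(cm, rocs = pooled_rocs(scores, truth),
                    protocol = list(stage = "kfold", k = k,
                                    classifier = spec_id(spec), seed = seed),
                    extra = list(folds = fold))
}

#' Leave-one-subject-out evaluation
#'
#' Stage-2 assessment of the study protocol: for each participant, a model
#' is trained on the training sets (set1 and set3) of all *other*
#' participants and tested on the held-out participant's workout-simulation
#' set (set2).  The pooled confusion matrix across iterations is reported,
#' together with the per-iteration overall accuracies and their mean.
#'
#' @param fm a cohort [feature_matrix()] carrying `participant_id` and
#'   `set_id` per row (e.g. from [cohort_features()]); must contain set1,
#'   set2 and set3 rows for every participant.
#' @param spec a [classifier_spec()].
#' @param train_sets,test_sets which sets feed training and testing.
#' @return An [evaluation_report()] with `per_iteration` (data.frame of
#'   participant and accuracy) and `mean_iteration_accuracy` elements.
#' @export
loso_evaluate <- function(fm, spec, train_sets = c("set1", "set3"),
                          test_sets = "set2") {
  pids <- unique(fm$participant_id)
  if (length(pids) < 2) stop("LOSO needs at least 2 participants")
  for (p in pids) {
    have <- unique(fm$set_id[fm$participant_id == p])
    miss <- setdiff(c(train_sets, test_sets), have)
    if (length(miss))
      stop("participant ", p, " lacks set(s): ", paste(miss, collapse = ", "))
  }
  truth <- character(0); predd <- character(0); scores <- NULL
  per <- data.frame(participant_id = pids, accuracy = NA_real_, n = NA_integer_)
  for (j in seq_along(pids)) {
    p <- pids[j]
    tr <- fm$participant_id != p & fm$set_id %in% train_sets
    te <- fm$participant_id == p & fm$set_id %in% test_sets
    model <- train_classifier(spec, subset_rows(fm, tr))
    pr <- predict(model, subset_rows(fm, te))
    t_j <- as.character(fm$label[te]); p_j <- as.character(pr$label)
    per$accuracy[j] <- mean(t_j == p_j)
    per$n[j] <- sum(te)
    truth <- c(truth, t_j); predd <- c(predd, p_j)
    sc <- matrix(0, sum(te), 5, dimnames = list(NULL, drill_levels()))
    sc[, colnames(pr$scores)] <- pr$scores
    scores <- rbind(scores, sc)
  }
  cm <- confusion(truth, predd)
  evaluation_report(cm, rocs = pooled_rocs(scores, truth),
                    protocol = list(stage = "loso", classifier = spec_id(spec)),
                    extra = list(per_iteration = per,
                                 mean_iteration_accuracy = mean(per$accuracy)))
}
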