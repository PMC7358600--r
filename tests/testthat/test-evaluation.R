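test_that("confusion matrices tally truth against prediction", {
  lv <- drill_levels()
  cm <- confusion(lv, lv)
  expect_equal(unclass(cm), diag(1L, 5),
               ignore_attr = TRUE)
  cm <- confusion("C&J", "TRANS")
  expect_equal(cm["C&J", "TRANS"], 1L)
  expect_equal(sum(cm), 1L)
  expect_error(confusion(c("C&J", "AS"), "C&J"), "length")
  # 200 random pairs against an independent tally
  set.seed(21)
  t <- sample(lv, 200, TRUE); p <- sample(lv, 200, TRUE)
  cm <- confusion(t, p)
  for (i in lv) for (j in lv)
    expect_equal(cm[i, j], sum(t == i & p == j))
})

test_that("per-class metrics implement the one-vs-rest count identities", {
  cm <- confusion(drill_levels(), drill_levels())
  for (cl in drill_levels()) {
    m <- class_metrics(cm, cl)
    expect_equal(m$ACC, 1); expect_equal(m$PPV, 1); expect_equal(m$TPR, 1)
    expect_equal(m$FNR, 0); expect_equal(m$FPR, 0)
  }
  expect_error(class_metrics(cm, "squat"), "unknown class")
  # identities on a random matrix
  set.seed(22)
  M <- matrix(sample(0:30, 25, TRUE), 5, 5)
  for (cl in drill_levels()) {
    i <- match(cl, drill_levels())
    m <- class_metrics(M, cl)
    expect_equal(m$TP, M[i, i])
    expect_equal(m$FP, sum(M[, i]) - M[i, i])
    expect_equal(m$FN, sum(M[i, ]) - M[i, i])
    expect_equal(m$TP + m$TN + m$FP + m$FN, sum(M))
    expect_equal(m$ACC, (m$TP + m$TN) / sum(M))
    expect_equal(m$FNR, 1 - m$TPR)
  }
  # per-class TPs sum to the trace
  tps <- vapply(drill_levels(), function(cl) class_metrics(M, cl)$TP, 0)
  expect_equal(sum(tps), sum(diag(M)))
})

test_that("overall accuracy is trace over total", {
  expect_equal(overall_accuracy(confusion(drill_levels(), drill_levels())), 1)
  set.seed(23)
  M <- matrix(sample(0:20, 25, TRUE), 5, 5)
  expect_equal(overall_accuracy(M), sum(diag(M)) / sum(M))
  expect_error(overall_accuracy(matrix(0, 5, 5)), "empty")
})

test_that("ROC/AUC agrees with the rank-statistic oracle", {
  # perfect separation
  r <- roc_ovr(c(5, 4, 1, 0), c("AS", "AS", "TRANS", "TRANS"), "AS")
  expect_equal(r$auc, 1)
  # uninformative scores
  r <- roc_ovr(rep(2, 6), rep(c("AS", "TRANS"), 3), "AS")
  expect_equal(r$auc, 0.5)
  # 6-point toy with a tie, against pair counting
  sc <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  tr <- c("BJ", "BJ", "TRANS", "BJ", "TRANS", "TRANS")
  expect_equal(roc_ovr(sc, tr, "BJ")$auc,
               auc_pair_oracle(sc, tr == "BJ"))
  # random small instances
  set.seed(24)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    sc <- round(runif(n), 1)
    tr <- sample(c("C&J", "TRANS"), n, TRUE)
    if (length(unique(tr)) < 2) next
    expect_equal(roc_ovr(sc, tr, "C&J")$auc,
                 auc_pair_oracle(sc, tr == "C&J"))
  }
  # single-class truth is flagged, not computed
  r <- roc_ovr(1:3, rep("AS", 3), "AS")
  expect_false(r$defined)
  expect_true(is.na(r$auc))
})

test_that("stratified k-fold pools a sensible confusion matrix", {
  fm <- toy_separable(n_per = 25)
  rep1 <- kfold_cv(fm, classifier_spec("svm", kernel = "linear"), seed = 3)
  expect_equal(rep1$overall_accuracy, 1)
  # folds are stratified: every fold holds both classes
  expect_true(all(table(rep1$folds, droplevels(fm$label)) > 0))
  # determinism
  rep2 <- kfold_cv(fm, classifier_spec("svm", kernel = "linear"), seed = 3)
  expect_equal(rep1$confusion, rep2$confusion)
  expect_equal(rep1$folds, rep2$folds)
  # permuted labels collapse to chance (majority prevalence)
  set.seed(31)
  fmp <- feature_matrix(fm$values, fm$columns, sample(as.character(fm$label)))
  repp <- kfold_cv(fmp, classifier_spec("knn", variant = "medium"), seed = 3)
  prev <- max(table(fmp$label)) / length(fmp$label)
  expect_lt(repp$overall_accuracy, prev + 0.25)
  # class rarer than k errors
  rare <- subset_rows(fm, c(1:3, 26:50))
  expect_error(kfold_cv(rare, classifier_spec("svm"), k = 5), "rarer")
})

test_that("LOSO holds out each participant's whole session", {
  # protocol-disjointness oracle: labels are participant-specific, so any
  # leakage of the held-out participant's training sets would lift accuracy
  # above zero; a clean protocol scores exactly zero here
  mk <- function(pid, flip, offset = 0) {
    v <- cbind(rep(c(0, 1), each = 6) + offset)
    lab <- rep(if (flip) c("AS", "C&J") else c("C&J", "AS"), each = 6)
    feature_matrix(v, data.frame(site = "wrist", quantity = "accel",
                                 axis = "x", feature = "mean"),
                   lab, participant_id = pid,
                   set_id = rep(c("set1", "set2", "set3"), 4))
  }
  # participant b's own rows (offset 0.1) are nearer to each other than to
  # a's, so any leakage of b's training sets would score 1, not 0
  fm <- rbind_features(mk("a", FALSE), mk("b", TRUE, offset = 0.1))
  rep <- loso_evaluate(fm, classifier_spec("knn", variant = "fine"))
  expect_equal(rep$overall_accuracy, 0)
  expect_equal(nrow(rep$per_iteration), 2)
  # two identical participants: LOSO equals within-participant holdout
  fm2 <- rbind_features(mk("a", FALSE), mk("b", FALSE))
  rep2 <- loso_evaluate(fm2, classifier_spec("knn", variant = "fine"))
  tr <- subset_rows(fm2, fm2$participant_id == "a" & fm2$set_id != "set2")
  te <- subset_rows(fm2, fm2$participant_id == "a" & fm2$set_id == "set2")
  m <- train_classifier(classifier_spec("knn", variant = "fine"), tr)
  hold <- mean(as.character(predict(m, te)$label) ==
               as.character(te$label))
  expect_equal(rep2$overall_accuracy, hold)
  # missing sets are rejected
  bad <- subset_rows(fm, !(fm$participant_id == "a" & fm$set_id == "set2"))
  expect_error(loso_evaluate(bad, classifier_spec("knn", variant = "fine")),
               "set2")
  expect_error(loso_evaluate(subset_rows(fm, fm$participant_id == "a"),
                             classifier_spec("knn", variant = "fine")),
               "2 participants")
})

test_that("confusion percentages and report fields are coherent", {
  set.seed(25)
  t <- sample(drill_levels(), 300, TRUE)
  p <- sample(drill_levels(), 300, TRUE)
  rep <- evaluation_report(confusion(t, p))
  expect_equal(sum(rep$confusion) , 300)
  expect_equal(rep$overall_accuracy, mean(t == p))
  expect_equal(sum(rep$confusion / sum(rep$confusion)), 1)
})
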