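# Shipped benchmark results for the reference pipeline configuration
# (cubic-kernel SVM, 600 ms windows, 10% overlap, all five sensors).

#' Benchmark confusion matrices and metrics
#'
#' The package ships the reference confusion matrices reported for the
#' cubic-kernel SVM pipeline (600 ms windows, 10% overlap, five sensors)
#' evaluated on a 14-participant functional-fitness dataset: Stage 1 is a
#' 5-fold cross-validation of the training sets, Stage 2 the
#' leave-one-subject-out validation on the workout-simulation set.  Feeding
#' these matrices through [class_metrics()] reproduces the published
#' per-class ACC/PPV/TPR table ([benchmark_metrics()]) -- a worked example
#' of the metric arithmetic that runs without any simulation.
#'
#' @param stage `"stage1"` or `"stage2"`.
#' @return `benchmark_confusion()`: a [confusion()] matrix of window counts.
#'   `benchmark_metrics()`: a `data.frame` of the published per-class
#'   ACC/PPV/TPR percentages for both stages.
#' @examples
#' cm <- benchmark_confusion("stage1")
#' round(100 * overall_accuracy(cm), 1)  # 97.8
#' @export
benchmark_confusion <- function(stage = c("stage1", "stage2")) {
  stage <- match.arg(stage)
  path <- system.file("extdata", paste0("benchmark_confusion_", stage, ".csv"),
                      package = "wodrec", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- df$true
  stopifnot(identical(rownames(m), drill_levels()),
            identical(colnames(m), drill_levels()))
  as_confusion(m)
}

#' @rdname benchmark_confusion
#' @export
benchmark_metrics <- function() {
  path <- system.file("extdata", "benchmark_metrics.csv",
                      package = "wodrec", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
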