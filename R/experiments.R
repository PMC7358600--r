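# Experiment grids: classifier family x window length x overlap, sensor
# subsets, and feature-reduced (mRMR top-K) configurations.

#' Default sensor subsets of the sensitivity analysis
#'
#' The full five-sensor configuration, the five singles, and the seven pairs
#' examined in the sensitivity analysis (wrist paired with ankle, lumbar,
#' thigh and upper arm; upper arm paired with ankle, lumbar and thigh).
#'
#' @param which `"all"`, `"full"`, `"singles"` or `"pairs"`.
#' @return Named list of site character vectors.
#' @export
default_sensor_subsets <- function(which = c("all", "full", "singles", "pairs")) {
  which <- match.arg(which)
  full <- list(all5 = sensor_sites())
  singles <- list(W = "wrist", UA = "upper_arm", T = "thigh",
                  A = "ankle", L = "lumbar")
  pairs <- list(`W+A` = c("wrist", "ankle"), `W+L` = c("wrist", "lumbar"),
                `W+T` = c("wrist", "thigh"), `W+UA` = c("wrist", "upper_arm"),
                `UA+A` = c("upper_arm", "ankle"), `UA+L` = c("upper_arm", "lumbar"),
                `UA+T` = c("upper_arm", "thigh"))
  switch(which, full = full, singles = singles, pairs = pairs,
         all = c(full, singles, pairs))
}

#' Default classifier grid
#'
#' The 12 classifiers of the study grid: 6 SVM kernels (linear, quadratic,
#' cubic, fine/medium/coarse Gaussian) and 6 kNN variants (fine, medium,
#' coarse, cosine, cubic distance, weighted).
#'
#' @return Named list of [classifier_spec()]s.
#' @export
default_classifier_grid <- function() {
  specs <- c(lapply(SVM_KERNELS, function(k) classifier_spec("svm", kernel = k)),
             lapply(KNN_VARIANTS, function(v) classifier_spec("knn", variant = v)))
  stats::setNames(specs, vapply(specs, spec_id, ""))
}

#' Experiment grid definition
#'
#' @param window_ms,overlap_pct windowing grid (defaults: 300/400/500/600 ms
#'   x 0/10/20%).
#' @param classifiers named list of [classifier_spec()]s.
#' @param subsets named list of site vectors ([default_sensor_subsets()]).
#' @param feature_mode `"all"` or `"top20"` (mRMR-reduced).
#' @param n_top features kept in `"top20"` mode.
#' @return A list of class `experiment_grid`.
#' @export
experiment_grid <- function(window_ms = c(300, 400, 500, 600),
                            overlap_pct = c(0, 10, 20),
                            classifiers = default_classifier_grid(),
                            subsets = default_sensor_subsets("full"),
                            feature_mode = c("all", "top20"),
                            n_top = 20) {
  feature_mode <- match.arg(feature_mode)
  structure(list(window_ms = window_ms, overlap_pct = overlap_pct,
                 classifiers = classifiers, subsets = subsets,
                 feature_mode = feature_mode, n_top = n_top),
            class = "experiment_grid")
}

# per-cell seed derived from the master seed and the cell coordinates, so any
# cell can be re-run in isolation
cell_seed <- function(master_seed, ...) {
  key <- paste(..., sep = "|")
  h <- sum(utf8ToInt(key) * (31^(seq_len(nchar(key)) %% 7)))
  as.integer((as.numeric(master_seed) * 131071 + h) %% 2147483629) + 1L
}

#' Run an experiment grid
#'
#' Evaluates every (windowing x classifier x sensor subset) cell of the grid
#' under the chosen protocol stage: `"kfold"` (stratified 5-fold CV on the
#' training sets, set1 + set3) or `"loso"` (leave-one-subject-out on set2).
#' Features are extracted once per windowing spec with all required sites
#' and sliced per subset.  In `"top20"` mode the mRMR ranking is computed on
#' the standardized training rows and the top `n_top` columns are kept
#' before model fitting.  A cell whose training data cannot support the
#' protocol (e.g. a class rarer than the folds) is recorded as `NA` rather
#' than failing the run.
#'
#' @param cohort a [generate_cohort()] result (or compatible list).
#' @param grid an [experiment_grid()].
#' @param stage `"kfold"` or `"loso"`.
#' @param seed master seed; per-cell seeds are derived from it.
#' @param k folds for the kfold stage.
#' @return A list of class `grid_results`: `table` (one row per cell with
#'   overall accuracy, in percent) and `reports` (named list of
#'   [evaluation_report()]s).
#' @export
run_grid <- function(cohort, grid, stage = c("kfold", "loso"), seed = 1L, k = 5) {
  stage <- match.arg(stage)
  all_sites <- Reduce(union, grid$subsets)
  rows <- list(); reports <- list()
  for (wms in grid$window_ms) for (ov in grid$overlap_pct) {
    wspec <- windowing_spec(wms, ov)
    feats <- cohort_features(cohort, wspec, sites = all_sites)
    for (sn in names(grid$subsets)) {
      fsub <- select_sites(feats, grid$subsets[[sn]])
      for (cn in names(grid$classifiers)) {
        spec <- grid$classifiers[[cn]]
        cseed <- cell_seed(seed, wms, ov, sn, cn, stage)
        cell <- paste(cn, paste0(wms, "ms"), paste0(ov, "pct"), sn, sep = "_")
        rep <- tryCatch({
          fm <- fsub
          if (grid$feature_mode == "top20") {
            tr_rows <- fm$set_id %in% c("set1", "set3")
            z <- standardize(subset_rows(fm, tr_rows))
            rk <- mrmr_rank(z$matrix)
            fm <- select_columns(fm, select_top(rk, grid$n_top))
          }
          if (stage == "kfold") {
            kfold_cv(subset_rows(fm, fm$set_id %in% c("set1", "set3")),
                     spec, k = k, seed = cseed)
          } else {
            loso_evaluate(fm, spec)
          }
        }, error = function(e) e)
        ok <- inherits(rep, "evaluation_report")
        rows[[length(rows) + 1L]] <- data.frame(
          cell = cell, classifier = cn, window_ms = wms, overlap_pct = ov,
          subset = sn, feature_mode = grid$feature_mode, stage = stage,
          accuracy_pct = if (ok) 100 * rep$overall_accuracy else NA_real_,
          note = if (ok) "" else conditionMessage(rep),
          stringsAsFactors = FALSE)
        if (ok) {
          rep$protocol <- c(rep$protocol,
                            list(window_ms = wms, overlap_pct = ov, subset = sn,
                                 feature_mode = grid$feature_mode))
          reports[[cell]] <- rep
        }
      }
    }
  }
  structure(list(table = do.call(rbind, rows), reports = reports),
            class = "grid_results")
}

#' @export
print.grid_results <- function(x, ...) {
  cat("<grid_results>", nrow(x$table), "cells\n")
  print(utils::head(x$table[order(-x$table$accuracy_pct),
                            c("cell", "accuracy_pct")], 10), row.names = FALSE)
  invisible(x)
}

#' Format grid results
#'
#' Renders the accuracy table as CSV (and optionally markdown) with the best
#' and worst cells flagged.  Pure formatting: reading the CSV back gives the
#' same table.
#'
#' @param results a [run_grid()] result (or its `table`).
#' @param csv_path,md_path optional output paths.
#' @return Invisibly, the annotated `data.frame` (with a `flag` column:
#'   `"best"` / `"worst"` / `""`).
#' @export
report_grid <- function(results, csv_path = NULL, md_path = NULL) {
  tab <- if (inherits(results, "grid_results")) results$table else results
  tab <- as.data.frame(tab)
  if (nrow(tab)) {
    acc <- tab$accuracy_pct
    flag <- rep("", nrow(tab))
    if (any(!is.na(acc))) {
      flag[which(acc == max(acc, na.rm = TRUE))] <- "best"
      flag[which(acc == min(acc, na.rm = TRUE))] <-
        ifelse(flag[which(acc == min(acc, na.rm = TRUE))] == "best",
               "best+worst", "worst")
    }
    tab$flag <- flag
  } else tab$flag <- character(0)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(md_path)) {
    hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    body <- apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, body), md_path)
  }
  invisible(tab)
}
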