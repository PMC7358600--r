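# Minimum-redundancy maximum-relevance (mRMR) feature ranking.
#
# Relevance and redundancy are plug-in mutual-information estimates (bits)
# on discretized features; the greedy step maximizes
# MI(feature; label) - mean MI(feature; already-selected)   (MID criterion).

#' Plug-in mutual information of two discrete series
#'
#' Estimated in bits from the joint frequency table:
#' `sum p(a,b) log2( p(a,b) / (p(a) p(b)) )`.  Symmetric; zero for the
#' columns of an exact product table.
#'
#' @param a,b vectors of equal length (treated as categorical).
#' @return Nonnegative mutual information in bits.
#' @examples
#' mutual_information(rep(0:1, 50), rep(0:1, 50))  # 1 bit
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have the same length")
  .mi_codes(as.integer(factor(a)), as.integer(factor(b)))
}

# mutual information from integer codes 1..ka, 1..kb
.mi_codes <- function(ai, bi, ka = max(ai), kb = max(bi)) {
  n <- length(ai)
  joint <- tabulate((ai - 1L) * kb + bi, ka * kb) / n
  pa <- tabulate(ai, ka) / n
  pb <- tabulate(bi, kb) / n
  ex <- rep(pa, each = kb) * rep.int(pb, ka)  # matches (a-1)*kb + b layout
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / ex[nz]))
}

# equal-frequency discretization of continuous columns into <= n_bins bins;
# duplicate quantile cut points collapse (heavy ties give fewer bins)
discretize_columns <- function(X, n_bins = 10) {
  apply(X, 2, function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                 type = 7, names = FALSE))
    if (length(br) < 2) return(rep.int(1L, length(x)))
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  })
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance ranking of a (standardized)
#' feature matrix against the class label.  Continuous features are
#' discretized into `n_bins` equal-frequency bins; relevance is
#' MI(feature; label) and redundancy the mean MI with the already-selected
#' features.  The difference criterion (MID) is used; ties break toward the
#' lower column index, making the ranking deterministic.
#'
#' @param fm a [feature_matrix()] (standardize first for the canonical
#'   pipeline) or plain numeric matrix.
#' @param labels class labels (taken from `fm` when omitted).
#' @param n_top how many features to rank (default: all).
#' @param n_bins discretization bins (default 10).
#' @return A list of class `feature_ranking` with `order` (column indices in
#'   selection order), `score` (relevance minus redundancy at each step) and
#'   `relevance` (per-feature MI with the label).
#' @export
mrmr_rank <- function(fm, labels = NULL, n_top = NULL, n_bins = 10) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (is.null(labels)) {
    if (!inherits(fm, "feature_matrix")) stop("labels required for a plain matrix")
    labels <- fm$label
  }
  if (!nrow(X) || !ncol(X)) stop("empty feature matrix")
  y <- as.integer(factor(labels))
  if (max(y) < 2) stop("at least 2 classes required")
  p <- ncol(X)
  n_top <- min(n_top %||% p, p)
  D <- discretize_columns(X, n_bins)
  kb <- apply(D, 2, max)
  rel <- vapply(seq_len(p), function(j) .mi_codes(y, D[, j], max(y), kb[j]), 0)
  selected <- integer(0)
  score <- numeric(0)
  red_sum <- numeric(p)                 # running sum of MI with selected
  remaining <- seq_len(p)
  for (step in seq_len(n_top)) {
    crit <- if (length(selected) == 0) rel[remaining]
            else rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(crit)]  # which.max -> lowest index on ties
    score <- c(score, max(crit))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j)
          .mi_codes(D[, pick], D[, j], kb[pick], kb[j]), 0)
  }
  structure(list(order = selected, score = score, relevance = rel,
                 n_bins = n_bins,
                 columns = if (inherits(fm, "feature_matrix")) fm$columns else NULL),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat("<feature_ranking>", length(x$order), "features ranked; top", n, ":\n")
  top <- head(x$order, n)
  nm <- if (!is.null(x$columns))
    apply(x$columns[top, ], 1, paste, collapse = "|") else paste0("col", top)
  cat(sprintf("  %2d. %-40s score %.4f\n", seq_along(top), nm,
              head(x$score, n)), sep = "")
  invisible(x)
}

#' Keep the top-K ranked features
#'
#' @param ranking a [mrmr_rank()] result.
#' @param K how many features to keep (default 20, the reduced
#'   configuration of the study design).
#' @return Integer column indices, in ranking order.
#' @export
select_top <- function(ranking, K = 20) {
  if (K < 1) stop("K must be at least 1")
  if (K > length(ranking$order))
    stop("K = ", K, " exceeds the ", length(ranking$order), " ranked features")
  ranking$order[seq_len(K)]
}

#' Summarize a ranking by feature domain and quantity
#'
#' Reporting helper: counts how many of the top-K features are time- vs
#' frequency-domain and accelerometer- vs gyroscope-derived, and per site.
#'
#' @inheritParams select_top
#' @return A list of count tables.
#' @export
ranking_profile <- function(ranking, K = 20) {
  if (is.null(ranking$columns)) stop("ranking has no column provenance")
  top <- ranking$columns[select_top(ranking, K), ]
  domain <- ifelse(top$feature %in% TIME_FEATURE_NAMES, "time", "frequency")
  list(domain = table(domain), quantity = table(top$quantity),
       site = table(top$site))
}
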