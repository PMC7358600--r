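# Time- and frequency-domain features per channel window, and assembly of the
# N x F feature matrix.
#
# Every channel (site x quantity x axis) contributes 18 features per window:
# 11 time-domain (mean, sd, RMS, mean absolute deviation, max, min, kurtosis,
# skewness, 25th/50th/75th percentiles) and 7 frequency-domain (spectral mean
# value, power, higher/lower frequency, median frequency, mean frequency,
# spectral entropy).  With 5 sensors x 2 quantities x 3 axes that is 540
# features; 108 per single sensor, 216 per sensor pair.

TIME_FEATURE_NAMES <- c("mean", "sd", "rms", "mad", "max", "min",
                        "kurtosis", "skewness", "q25", "q50", "q75")
FREQ_FEATURE_NAMES <- c("spec_mean", "power", "f_upper", "f_lower",
                        "f_median", "f_mean", "spec_entropy")

#' Feature name vocabularies
#' @return Character vector of per-channel feature names, in canonical column
#'   order (time-domain first, then frequency-domain).
#' @export
feature_names <- function() c(TIME_FEATURE_NAMES, FREQ_FEATURE_NAMES)

# ---- time domain -------------------------------------------------------------

#' Time-domain features of one window
#'
#' Computes the 11 time-domain summary statistics of a single channel window:
#' mean, standard deviation (n-1 denominator), root mean square, mean
#' absolute deviation about the mean, max, min, kurtosis, skewness, and the
#' 25th/50th/75th percentiles (linear interpolation between closest ranks).
#'
#' Kurtosis is the non-excess moment estimator `m4/m2^2` (a normal signal
#' gives ~3); set `excess = TRUE` for the excess convention.  On a constant
#' window the second moment vanishes and skewness and kurtosis are defined
#' as 0.
#'
#' @param x numeric vector, length >= 2.
#' @param excess logical; subtract 3 from kurtosis.
#' @return Named numeric vector of length 11.
#' @examples
#' time_features(c(1, 2, 3, 4))
#' @export
time_features <- function(x, excess = FALSE) {
  if (length(x) < 2) stop("window must hold at least 2 samples")
  out <- .time_features_mat(matrix(as.numeric(x), ncol = 1), excess = excess)
  stats::setNames(out[1, ], TIME_FEATURE_NAMES)
}

# windows in columns: W is window_samples x n_windows
.time_features_mat <- function(W, excess = FALSE) {
  n <- nrow(W); m <- ncol(W)
  mu <- colMeans(W)
  C <- W - rep(mu, each = n)
  m2 <- colMeans(C^2)
  msq <- colMeans(W^2)
  sdv <- sqrt(m2 * n / (n - 1))
  rms <- sqrt(msq)
  mad_ <- colMeans(abs(C))
  mx <- apply(W, 2, max)
  mn <- apply(W, 2, min)
  # degenerate (constant) windows: second moment numerically zero
  degen <- m2 <= .Machine$double.eps * pmax(1, msq)
  m3 <- colMeans(C^3); m4 <- colMeans(C^4)
  skw <- ifelse(degen, 0, m3 / m2^1.5)
  krt <- ifelse(degen, 0, m4 / m2^2 - if (excess) 3 else 0)
  qs <- apply(W, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              type = 7, names = FALSE)
  if (m == 1L) qs <- matrix(qs, nrow = 3)
  out <- cbind(mu, sdv, rms, mad_, mx, mn, krt, skw, qs[1, ], qs[2, ], qs[3, ])
  colnames(out) <- TIME_FEATURE_NAMES
  out
}

# ---- frequency domain --------------------------------------------------------

#' Frequency-domain features of one window
#'
#' Features are computed from the one-sided periodogram of the raw
#' (unfiltered, un-tapered) window with the DC bin excluded, so a constant
#' offset (gravity) does not pin the frequency-located features at 0 Hz.
#' With `n` samples there are `K = floor(n/2)` bins at frequencies
#' `f_k = k * fs / n`, `k = 1..K`.  The one-sided power is
#' `P_k = 2 |X_k|^2 / n^2` (the Nyquist bin, when present, is not doubled),
#' so that for a zero-mean window `sum(P_k)` equals the population variance
#' (Parseval).
#'
#' * spectral mean value: mean of the one-sided amplitude spectrum
#' * power: `sum(P_k)`
#' * higher / lower frequency: extreme `f_k` with `P_k >= peak_frac * max(P)`
#' * median frequency: smallest `f_k` whose cumulative power reaches half the
#'   total
#' * mean frequency: power-weighted mean `sum(f_k P_k) / sum(P_k)`
#' * spectral entropy: `-sum(p_k log p_k) / log(K)` with `p_k = P_k/sum(P)`,
#'   normalized to `[0, 1]` so values are comparable across window lengths
#'
#' A zero-power (constant) window returns 0 for all seven features by
#' convention.
#'
#' @param x numeric vector, length >= 4.
#' @param fs sampling rate in Hz.
#' @param peak_frac band-edge threshold as a fraction of the peak power
#'   (default 0.05).
#' @return Named numeric vector of length 7.
#' @examples
#' t <- seq(0, 1 - 1 / 64, by = 1 / 64)
#' freq_features(sin(2 * pi * 8 * t), fs = 64)  # all located features at 8 Hz
#' @export
freq_features <- function(x, fs, peak_frac = 0.05) {
  if (length(x) < 4) stop("window must hold at least 4 samples")
  out <- .freq_features_mat(matrix(as.numeric(x), ncol = 1), fs, peak_frac)
  stats::setNames(out[1, ], FREQ_FEATURE_NAMES)
}

.freq_features_mat <- function(W, fs, peak_frac = 0.05) {
  n <- nrow(W); m <- ncol(W)
  K <- n %/% 2L
  X <- stats::mvfft(W)
  sel <- 2:(K + 1L)                       # DC excluded; Nyquist included if n even
  f <- (1:K) * fs / n
  mag2 <- Mod(X[sel, , drop = FALSE])^2
  scale2 <- rep(2, K)
  if (n %% 2L == 0L) scale2[K] <- 1       # Nyquist bin is its own conjugate
  P <- mag2 * (scale2 / n^2)
  A <- sqrt(mag2) * (scale2 / n)          # one-sided amplitude spectrum
  tot <- colSums(P)
  msq <- colMeans(W^2)
  live <- tot > 1e-20 * pmax(1, msq)      # zero-power convention guard
  spec_mean <- colMeans(A)
  f_upper <- f_lower <- f_median <- f_mean <- ent <- numeric(m)
  pk <- apply(P, 2, max)
  for (j in seq_len(m)) {
    if (!live[j]) next
    Pj <- P[, j]
    band <- which(Pj >= peak_frac * pk[j])
    f_lower[j] <- f[band[1]]
    f_upper[j] <- f[band[length(band)]]
    # half-power point; epsilon guards exact-equality splits (two equal tones)
    f_median[j] <- f[which(cumsum(Pj) >= tot[j] * (0.5 - 1e-12))[1]]
    f_mean[j] <- sum(f * Pj) / tot[j]
    p <- Pj / tot[j]
    p <- p[p > 0]
    ent[j] <- -sum(p * log(p)) / log(K)
  }
  spec_mean[!live] <- 0
  out <- cbind(spec_mean, tot * live, f_upper, f_lower, f_median, f_mean, ent)
  colnames(out) <- FREQ_FEATURE_NAMES
  out
}

# ---- feature matrix ----------------------------------------------------------

#' Construct a feature matrix
#'
#' @param values numeric matrix, one row per window, one column per feature.
#' @param columns `data.frame` of per-column provenance with columns `site`,
#'   `quantity`, `axis`, `feature`.
#' @param label factor of window labels.
#' @param participant_id,set_id character vectors (recycled if scalar).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, columns, label,
                           participant_id = "p1", set_id = "set1") {
  values <- as.matrix(values)
  stopifnot(nrow(columns) == ncol(values),
            all(c("site", "quantity", "axis", "feature") %in% names(columns)))
  if (length(label) != nrow(values)) stop("one label per row required")
  colnames(values) <- paste(columns$site, columns$quantity, columns$axis,
                            columns$feature, sep = "|")
  structure(list(values = values,
                 columns = as.data.frame(columns)[c("site", "quantity", "axis", "feature")],
                 label = as_drill_factor(label),
                 participant_id = rep_len(as.character(participant_id), nrow(values)),
                 set_id = rep_len(as.character(set_id), nrow(values))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%d site(s)); classes: %s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$columns$site)),
              paste(sprintf("%s=%d", levels(x$label), tabulate(x$label, 5)),
                    collapse = " ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Extract features for all windows of a recording
#'
#' Computes the 18 per-channel features on every window and assembles the
#' N x F matrix.  Column order is deterministic: sites in canonical order
#' ([sensor_sites()]), then quantity (accel, gyro), axis (x, y, z), and the
#' 18 features in [feature_names()] order.
#'
#' @param windows a `labeled_windows` frame from [segment_and_label()] (or
#'   window positions from [make_windows()] plus a `label` column).
#' @param rec the [recording()] the windows were cut from.
#' @param sites subset of sites to extract (default: all present).  A
#'   requested site missing from the recording is an error.
#' @param excess kurtosis convention, see [time_features()].
#' @param peak_frac band-edge threshold, see [freq_features()].
#' @return A [feature_matrix()].
#' @export
extract_matrix <- function(windows, rec, sites = NULL, excess = FALSE,
                           peak_frac = 0.05) {
  stopifnot(inherits(rec, "recording"))
  have <- recording_sites(rec)
  if (is.null(sites)) sites <- have
  sites <- intersect(sensor_sites(), sites)   # canonical order
  miss <- setdiff(sites, have)
  if (length(miss)) stop("recording lacks requested site(s): ",
                         paste(miss, collapse = ", "))
  n_win <- nrow(windows)
  w <- if (n_win) windows$end_sample[1] - windows$start_sample[1] else 0L
  idx <- if (n_win) outer(0:(w - 1L), windows$start_sample, `+`) else NULL
  blocks <- list(); cols <- list(); b <- 0L
  for (site in sites) for (q in sensor_quantities()) {
    key <- paste(site, q, sep = "_")
    if (!key %in% names(rec$streams))
      stop("recording lacks stream ", key)
    dat <- rec$streams[[key]]$data
    for (ax in sensor_axes()) {
      b <- b + 1L
      if (n_win) {
        Wm <- matrix(dat[, ax][idx], nrow = w)
        blocks[[b]] <- cbind(.time_features_mat(Wm, excess = excess),
                             .freq_features_mat(Wm, rec$fs, peak_frac))
      } else {
        blocks[[b]] <- matrix(numeric(), 0, 18)
      }
      cols[[b]] <- data.frame(site = site, quantity = q, axis = ax,
                              feature = feature_names())
    }
  }
  vals <- do.call(cbind, blocks)
  lab <- if ("label" %in% names(windows)) windows$label else rep("TRANS", n_win)
  pid <- if ("participant_id" %in% names(windows)) windows$participant_id else rec$participant_id
  sid <- if ("set_id" %in% names(windows)) windows$set_id else rec$set_id
  feature_matrix(vals, do.call(rbind, cols), lab,
                 participant_id = pid, set_id = sid)
}

#' Bind feature matrices by row
#'
#' Rows of all matrices stacked; column provenance must match exactly.
#' @param ... `feature_matrix` objects (or a single list of them).
#' @return A [feature_matrix()].
#' @export
rbind_features <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && !inherits(ms[[1]], "feature_matrix")) ms <- ms[[1]]
  ref <- ms[[1]]
  for (m in ms[-1]) {
    if (!identical(colnames(m$values), colnames(ref$values)))
      stop("feature matrices have mismatched column provenance")
  }
  feature_matrix(do.call(rbind, lapply(ms, `[[`, "values")), ref$columns,
                 unlist(lapply(ms, function(m) as.character(m$label))),
                 unlist(lapply(ms, `[[`, "participant_id")),
                 unlist(lapply(ms, `[[`, "set_id")))
}

#' Subset a feature matrix
#'
#' `select_sites()` keeps the columns whose provenance site is in `sites`
#' (slicing an already-extracted matrix, e.g. the full 540-column matrix,
#' rather than re-extracting).  `subset_rows()` keeps the given window rows.
#' `select_columns()` keeps columns by index, preserving order (used with
#' [mrmr_rank()] / [select_top()]).
#'
#' @param fm a [feature_matrix()].
#' @param sites character vector of sites.
#' @return A [feature_matrix()].
#' @export
select_sites <- function(fm, sites) {
  sites <- match.arg(sites, sensor_sites(), several.ok = TRUE)
  keep <- fm$columns$site %in% sites
  if (!any(keep)) stop("no columns for site(s): ", paste(sites, collapse = ", "))
  feature_matrix(fm$values[, keep, drop = FALSE], fm$columns[keep, ],
                 fm$label, fm$participant_id, fm$set_id)
}

#' @rdname select_sites
#' @param rows integer or logical row index.
#' @export
subset_rows <- function(fm, rows) {
  feature_matrix(fm$values[rows, , drop = FALSE], fm$columns,
                 fm$label[rows], fm$participant_id[rows], fm$set_id[rows])
}

#' @rdname select_sites
#' @param cols integer column indices (order preserved).
#' @export
select_columns <- function(fm, cols) {
  feature_matrix(fm$values[, cols, drop = FALSE], fm$columns[cols, ],
                 fm$label, fm$participant_id, fm$set_id)
}

# ---- standardization ---------------------------------------------------------

#' Column-wise z-score standardization
#'
#' Standardizes each feature column to zero mean and unit variance.  When
#' `stats` is omitted the means and standard deviations are computed from the
#' input (training data) and returned for reuse on test data; constant
#' columns (sd 0) map to all-zero output.
#'
#' @param fm a [feature_matrix()] or plain numeric matrix.
#' @param stats optional list with `mean` and `sd` vectors (one per column),
#'   as returned by a previous call.
#' @return A list with elements `matrix` (same class as the input) and
#'   `stats`.
#' @export
standardize <- function(fm, stats = NULL) {
  vals <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (is.null(stats)) {
    stats <- list(mean = colMeans(vals),
                  sd = apply(vals, 2, stats::sd))
  }
  if (length(stats$mean) != ncol(vals) || length(stats$sd) != ncol(vals))
    stop("standardization stats have ", length(stats$mean),
         " columns; matrix has ", ncol(vals))
  s <- ifelse(stats$sd > 0, stats$sd, 1)
  z <- sweep(sweep(vals, 2, stats$mean), 2, s, `/`)
  z[, stats$sd == 0] <- 0
  out <- if (inherits(fm, "feature_matrix")) {
    feature_matrix(z, fm$columns, fm$label, fm$participant_id, fm$set_id)
  } else z
  list(matrix = out, stats = stats)
}

# ---- feature matrix CSV ------------------------------------------------------

#' Write / read a feature matrix as CSV
#'
#' One metadata header per value column (`site|quantity|axis|feature`), plus
#' `label`, `participant_id` and `set_id` columns.  The round trip
#' `read_feature_matrix(write_feature_matrix(m))` preserves values to within
#' 1e-12 and labels exactly.
#'
#' @param fm a non-empty [feature_matrix()].
#' @param path output path.
#' @return `write_feature_matrix()` invisibly returns `path`;
#'   `read_feature_matrix()` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!nrow(fm$values) || !ncol(fm$values)) stop("feature matrix is empty")
  df <- as.data.frame(fm$values, check.names = FALSE)
  df$label <- as.character(fm$label)
  df$participant_id <- fm$participant_id
  df$set_id <- fm$set_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("label", "participant_id", "set_id")
  vcols <- setdiff(names(df), meta)
  parts <- strsplit(vcols, "|", fixed = TRUE)
  bad <- vcols[lengths(parts) != 4L]
  if (length(bad)) stop("malformed feature column header: ", bad[1])
  cols <- data.frame(site = vapply(parts, `[`, "", 1),
                     quantity = vapply(parts, `[`, "", 2),
                     axis = vapply(parts, `[`, "", 3),
                     feature = vapply(parts, `[`, "", 4))
  feature_matrix(as.matrix(df[vcols]), cols, df$label,
                 df$participant_id, df$set_id)
}
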