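# Sliding-window segmentation and majority labeling.

#' Windowing specification
#'
#' Fixed-duration windows slide across the continuous recording.  The study
#' grid uses lengths of 300--600 ms (100 ms increments) and overlaps of 0, 10
#' and 20%, but any positive length and overlap in [0, 100) are accepted.
#'
#' The realized window length is `window_samples = floor(window_ms/1000 * fs)`
#' (never exceeding the nominal duration; 600 ms at 148.15 Hz gives 88
#' samples) and the hop is `step_samples = round(window_samples * (1 -
#' overlap_pct/100))` with ties rounded half away from zero.
#'
#' @param window_ms window duration, milliseconds.
#' @param overlap_pct percentage overlap between consecutive windows, in
#'   `[0, 100)`.
#' @param fs sampling rate in Hz.
#' @return A list of class `windowing_spec` with elements `window_ms`,
#'   `overlap_pct`, `fs`, `window_samples`, `step_samples`.
#' @examples
#' windowing_spec(600, 10)  # 88-sample windows, 79-sample hop
#' @export
windowing_spec <- function(window_ms = 600, overlap_pct = 10, fs = default_fs()) {
  stopifnot(window_ms > 0, overlap_pct >= 0, overlap_pct < 100, fs > 0)
  w <- floor(window_ms / 1000 * fs)
  if (w < 2) stop("window of ", window_ms, " ms at ", fs, " Hz holds fewer than 2 samples")
  step <- floor(w * (1 - overlap_pct / 100) + 0.5)  # half away from zero (args positive)
  step <- max(step, 1L)
  structure(list(window_ms = window_ms, overlap_pct = overlap_pct, fs = fs,
                 window_samples = as.integer(w), step_samples = as.integer(step)),
            class = "windowing_spec")
}

#' @export
print.windowing_spec <- function(x, ...) {
  cat(sprintf("<windowing_spec> %g ms / %g%% overlap @ %.2f Hz -> %d samples, step %d\n",
              x$window_ms, x$overlap_pct, x$fs, x$window_samples, x$step_samples))
  invisible(x)
}

#' Cut a recording into window positions
#'
#' Returns the ordered window positions (half-open sample spans, 1-based
#' start) without labels.  The number of windows is
#' `floor((n_samples - window_samples)/step_samples) + 1`; trailing samples
#' that cannot fill a complete window are discarded.  A recording shorter
#' than one window yields zero windows with a warning.
#'
#' @param rec a [recording()] (or an integer sample count).
#' @param spec a [windowing_spec()].
#' @return A `data.frame` with columns `start_sample`, `end_sample`
#'   (half-open: the window covers samples `start_sample` to
#'   `end_sample - 1`).
#' @export
make_windows <- function(rec, spec) {
  n <- if (inherits(rec, "recording")) rec$n_samples else as.integer(rec)
  w <- spec$window_samples; s <- spec$step_samples
  if (n < w) {
    warning("recording of ", n, " samples is shorter than one ", w, "-sample window")
    return(data.frame(start_sample = integer(), end_sample = integer()))
  }
  k <- floor((n - w) / s) + 1L
  starts <- 1L + (seq_len(k) - 1L) * s
  data.frame(start_sample = starts, end_sample = starts + w)
}

# per-sample labels (integer codes into drill_levels()) from a tiled track;
# sample i (1-based) sits at time (i-1)/fs and belongs to [start_s, end_s)
sample_labels <- function(annotations, n_samples, fs) {
  tiled <- tile_annotations(annotations, n_samples / fs)
  lab <- rep.int(match("TRANS", drill_levels()), n_samples)
  for (i in seq_len(nrow(tiled))) {
    lo <- ceiling(tiled$start_s[i] * fs - 1e-9) + 1L
    hi <- ceiling(tiled$end_s[i] * fs - 1e-9)
    lo <- max(lo, 1L); hi <- min(hi, n_samples)
    if (hi >= lo) lab[lo:hi] <- match(as.character(tiled$label[i]), drill_levels())
  }
  lab
}

#' Label one window by the majority criterion
#'
#' A window receives a movement label only if that movement covers strictly
#' more than `majority_frac` of the window's samples; otherwise it is a
#' transition (`TRANS`).  The published rule ("more than 66%") is read as
#' two-thirds; set `majority_frac = 0.66` to reproduce the literal reading.
#' Because no two movements can each exceed two-thirds, the rule is
#' unambiguous; windows straddling back-to-back drills fall to TRANS.
#'
#' @param start_sample,end_sample half-open sample span of the window.
#' @param annotations a [label_intervals()] track.
#' @param fs sampling rate in Hz.
#' @param n_samples recording length (for TRANS gap-filling).
#' @param majority_frac coverage threshold, default `2/3`.
#' @return A factor label in [drill_levels()].
#' @export
label_window <- function(start_sample, end_sample, annotations, fs,
                         n_samples = end_sample - 1L, majority_frac = 2 / 3) {
  lab <- sample_labels(annotations, n_samples, fs)
  majority_from_codes(lab[start_sample:(end_sample - 1L)], majority_frac)
}

majority_from_codes <- function(codes, majority_frac) {
  lev <- drill_levels()
  n <- length(codes)
  out <- "TRANS"
  for (m in seq_len(4L)) {            # movement classes only; TRANS is the fallback
    if (sum(codes == m) / n > majority_frac) { out <- lev[m]; break }
  }
  factor(out, levels = lev)
}

#' Segment a recording and label every window
#'
#' Composition of [make_windows()] and the majority-labeling rule, vectorized
#' over windows.
#'
#' @inheritParams make_windows
#' @inheritParams label_window
#' @return A `data.frame` of class `labeled_windows` with columns
#'   `start_sample`, `end_sample`, `label`, `participant_id`, `set_id`.
#' @export
segment_and_label <- function(rec, spec, majority_frac = 2 / 3) {
  stopifnot(inherits(rec, "recording"))
  win <- make_windows(rec, spec)
  lev <- drill_levels()
  if (!nrow(win)) {
    out <- data.frame(win, label = factor(character(), levels = lev),
                      participant_id = character(), set_id = character())
    class(out) <- c("labeled_windows", "data.frame")
    return(out)
  }
  codes <- sample_labels(rec$annotations, rec$n_samples, rec$fs)
  w <- spec$window_samples
  # cumulative per-class counts -> coverage of each window by each movement
  lab <- character(nrow(win))
  cum <- sapply(seq_len(4L), function(m) cumsum(codes == m))
  cum <- rbind(0, cum)
  cov <- (cum[win$end_sample, , drop = FALSE] - cum[win$start_sample, , drop = FALSE]) / w
  best <- max.col(cov, ties.method = "first")
  take <- cov[cbind(seq_len(nrow(cov)), best)] > majority_frac
  lab <- ifelse(take, lev[best], "TRANS")
  out <- data.frame(win, label = factor(lab, levels = lev),
                    participant_id = rec$participant_id, set_id = rec$set_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_windows", "data.frame")
  out
}
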