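# Recording container and CSV I/O.
#
# A recording bundles the synchronized streams of one participant-session
# (one workout set): up to 5 sensor sites x 2 kinematic quantities x 3 axes,
# all sharing the same sampling rate and length, plus the ground-truth
# annotation track of movement intervals.

#' Construct a sensor stream
#'
#' One sensor's tri-axial timeseries for a single kinematic quantity.
#' Acceleration is expressed in g (gravity included), angular velocity in
#' deg/s.  Values outside the physical sensor range are saturated to it.
#'
#' @param site sensor site, one of [sensor_sites()].
#' @param quantity `"accel"` or `"gyro"`.
#' @param x,y,z numeric series of identical length.
#' @param fs sampling rate in Hz (default 148.15).
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(site, quantity, x, y, z, fs = default_fs()) {
  site <- match.arg(site, sensor_sites())
  quantity <- match.arg(quantity, sensor_quantities())
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("axis series of ", site, "_", quantity, " have unequal lengths")
  rng <- sensor_range(quantity)
  dat <- cbind(x = pmin(pmax(as.numeric(x), rng[1]), rng[2]),
               y = pmin(pmax(as.numeric(y), rng[1]), rng[2]),
               z = pmin(pmax(as.numeric(z), rng[1]), rng[2]))
  structure(list(site = site, quantity = quantity, data = dat, fs = fs,
                 n_samples = n),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s %s: %d samples @ %.2f Hz\n",
              x$site, x$quantity, x$n_samples, x$fs))
  invisible(x)
}

#' Construct an annotation track of labeled intervals
#'
#' Intervals are half-open `[start_s, end_s)` in seconds from recording
#' start.  Intervals must be non-overlapping; any span of the recording not
#' covered by an interval is implicitly a transition (`TRANS`) -- see
#' [tile_annotations()].
#'
#' @param start_s,end_s numeric vectors, seconds.
#' @param label character vector of class labels ([drill_levels()]).
#' @return A `data.frame` with class `label_intervals`, ordered by start.
#' @export
label_intervals <- function(start_s = numeric(), end_s = numeric(), label = character()) {
  if (length(start_s) != length(end_s) || length(start_s) != length(label))
    stop("start_s, end_s and label must have the same length")
  lab <- as_drill_factor(label)
  bad <- which(!(end_s > start_s))
  if (length(bad))
    stop("annotation row ", bad[1], ": end_s (", end_s[bad[1]],
         ") must exceed start_s (", start_s[bad[1]], ")")
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]; lab <- lab[o]
  if (length(start_s) > 1L) {
    ov <- which(start_s[-1] < end_s[-length(end_s)])
    if (length(ov))
      stop("annotation rows ", ov[1], " and ", ov[1] + 1L,
           " overlap (intervals must be disjoint)")
  }
  structure(data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                       label = lab, stringsAsFactors = FALSE),
            class = c("label_intervals", "data.frame"))
}

#' Fill annotation gaps with transition intervals
#'
#' Returns intervals that exactly tile `[0, duration_s)`: every span not
#' covered by an annotated movement becomes a `TRANS` interval.  Adjacent
#' intervals with identical labels are left as-is (window labeling is
#' invariant to such splits).
#'
#' @param annotations a [label_intervals()] object.
#' @param duration_s recording duration in seconds.
#' @return A `label_intervals` tiling of the recording.
#' @export
tile_annotations <- function(annotations, duration_s) {
  stopifnot(duration_s > 0)
  a <- annotations[annotations$start_s < duration_s, , drop = FALSE]
  if (nrow(a)) a$end_s <- pmin(a$end_s, duration_s)
  starts <- numeric(); ends <- numeric(); labs <- character()
  cur <- 0
  if (nrow(a)) {
    for (i in seq_len(nrow(a))) {
      if (a$start_s[i] > cur) {
        starts <- c(starts, cur); ends <- c(ends, a$start_s[i]); labs <- c(labs, "TRANS")
      }
      starts <- c(starts, a$start_s[i]); ends <- c(ends, a$end_s[i])
      labs <- c(labs, as.character(a$label[i]))
      cur <- a$end_s[i]
    }
  }
  if (cur < duration_s) {
    starts <- c(starts, cur); ends <- c(ends, duration_s); labs <- c(labs, "TRANS")
  }
  label_intervals(starts, ends, labs)
}

#' Construct a recording
#'
#' @param participant_id non-empty identifier string.
#' @param set_id `"set1"`, `"set2"` or `"set3"` (training / workout-simulation
#'   / training sets of the protocol).
#' @param streams list of [sensor_stream()] objects sharing `fs` and length.
#' @param annotations a [label_intervals()] track (movement intervals;
#'   uncovered spans are implicitly TRANS).
#' @return An object of class `recording`.
#' @export
recording <- function(participant_id, set_id, streams, annotations = label_intervals()) {
  if (!nzchar(participant_id)) stop("participant_id must be non-empty")
  set_id <- match.arg(set_id, c("set1", "set2", "set3"))
  if (!length(streams)) stop("a recording needs at least one stream")
  fs <- streams[[1]]$fs; n <- streams[[1]]$n_samples
  for (s in streams) {
    if (!inherits(s, "sensor_stream")) stop("streams must be sensor_stream objects")
    if (s$fs != fs || s$n_samples != n)
      stop("all streams must share fs and n_samples (", s$site, "_", s$quantity,
           " differs)")
  }
  keys <- vapply(streams, function(s) paste(s$site, s$quantity, sep = "_"), "")
  if (anyDuplicated(keys)) stop("duplicate stream: ", keys[duplicated(keys)][1])
  names(streams) <- keys
  structure(list(participant_id = participant_id, set_id = set_id,
                 streams = streams, annotations = annotations,
                 fs = fs, n_samples = n),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> participant %s, %s: %d streams, %d samples (%.1f s @ %.2f Hz), %d annotated intervals\n",
              x$participant_id, x$set_id, length(x$streams), x$n_samples,
              x$n_samples / x$fs, x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Sites present in a recording
#' @param rec a [recording()].
#' @return character vector of sites, in canonical order.
#' @export
recording_sites <- function(rec) {
  sites <- unique(vapply(rec$streams, function(s) s$site, ""))
  intersect(sensor_sites(), sites)
}

#' Recording duration in seconds
#' @param rec a [recording()].
#' @export
recording_duration <- function(rec) rec$n_samples / rec$fs

# parse "<site>_<quantity>_<axis>" channel headers
parse_channel_name <- function(nm) {
  m <- regmatches(nm, regexec("^(ankle|lumbar|thigh|upper_arm|wrist)_(accel|gyro)_([xyz])$", nm))[[1]]
  if (length(m) != 4L)
    stop("unknown channel column '", nm,
         "' (expected <site>_<quantity>_<axis> with site in {",
         paste(sensor_sites(), collapse = ", "), "}, quantity in {accel, gyro}, axis in {x, y, z})")
  list(site = m[2], quantity = m[3], axis = m[4])
}

#' Read a recording from CSV files
#'
#' The signal CSV must have a header `time_s` followed by one column per
#' channel named `<site>_<quantity>_<axis>` (axis x/y/z); one row per sample.
#' The time column is informative only -- sample index and `fs` are
#' authoritative.  The annotation CSV has header `start_s,end_s,label`;
#' a file with zero rows labels the entire recording TRANS.  Signals are
#' clipped to the sensor ranges on ingest.
#'
#' @param signal_path path to the signal CSV.
#' @param annotation_path path to the annotation CSV (optional; `NULL` means
#'   no annotated movements, i.e. all TRANS).
#' @param participant_id,set_id identity of the recording.
#' @param fs sampling rate in Hz.
#' @return A [recording()].
#' @export
read_recording <- function(signal_path, annotation_path = NULL,
                           participant_id = "p1", set_id = "set1",
                           fs = default_fs()) {
  sig <- utils::read.csv(signal_path, check.names = FALSE)
  if (!nrow(sig)) stop("signal file ", signal_path, " has no rows")
  if (names(sig)[1] != "time_s") stop("first signal column must be time_s")
  tt <- sig[[1]]
  if (is.unsorted(tt, strictly = TRUE)) {
    bad <- which(diff(tt) <= 0)[1] + 1L
    stop("time_s column is not strictly increasing at row ", bad)
  }
  chans <- names(sig)[-1]
  if (!length(chans)) stop("signal file has no channel columns")
  meta <- lapply(chans, parse_channel_name)
  key <- vapply(meta, function(m) paste(m$site, m$quantity, sep = "_"), "")
  streams <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    ax <- vapply(meta[idx], function(m) m$axis, "")
    if (!setequal(ax, c("x", "y", "z")))
      stop("channel group ", k, " must have exactly axes x, y, z (found: ",
           paste(sort(ax), collapse = ", "), ")")
    cols <- chans[idx][match(c("x", "y", "z"), ax)]
    for (cl in cols) if (anyNA(sig[[cl]])) stop("missing values in column ", cl)
    streams[[k]] <- sensor_stream(meta[[idx[1]]]$site, meta[[idx[1]]]$quantity,
                                  sig[[cols[1]]], sig[[cols[2]]], sig[[cols[3]]],
                                  fs = fs)
  }
  ann <- label_intervals()
  if (!is.null(annotation_path)) {
    adf <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
    need <- c("start_s", "end_s", "label")
    if (!all(need %in% names(adf)))
      stop("annotation file must have columns start_s,end_s,label")
    if (nrow(adf)) ann <- label_intervals(adf$start_s, adf$end_s, adf$label)
  }
  recording(participant_id, set_id, streams, ann)
}

#' Write a recording to CSV files
#'
#' Inverse of [read_recording()]: wide signal CSV (`time_s` + one column per
#' channel) and annotation CSV (`start_s,end_s,label`).
#'
#' @param rec a [recording()].
#' @param signal_path,annotation_path output paths.
#' @return Invisibly, `signal_path`.
#' @export
write_recording <- function(rec, signal_path, annotation_path = NULL) {
  cols <- list(time_s = (seq_len(rec$n_samples) - 1) / rec$fs)
  for (site in recording_sites(rec)) for (q in sensor_quantities()) {
    k <- paste(site, q, sep = "_")
    if (!k %in% names(rec$streams)) next
    d <- rec$streams[[k]]$data
    for (ax in sensor_axes()) cols[[paste(k, ax, sep = "_")]] <- d[, ax]
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), signal_path,
                   row.names = FALSE)
  if (!is.null(annotation_path)) {
    a <- rec$annotations
    utils::write.csv(data.frame(start_s = a$start_s, end_s = a$end_s,
                                label = as.character(a$label)),
                     annotation_path, row.names = FALSE)
  }
  invisible(signal_path)
}
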