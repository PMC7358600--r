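# Shared fixtures, built in code.  Expensive objects are cached for the run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a minimal recording built from raw axis data (one or more site-quantity
# channels), default fs chosen so times are simple
toy_recording <- function(n = 100, fs = 100,
                          sites = "wrist", quantities = c("accel", "gyro"),
                          annotations = label_intervals(),
                          participant_id = "p1", set_id = "set1",
                          signal = function(i) sin(2 * pi * 5 * (i - 1) / fs)) {
  streams <- list()
  base <- signal(seq_len(n))
  for (s in sites) for (q in quantities)
    streams[[paste(s, q, sep = "_")]] <-
      sensor_stream(s, q, base, base / 2, base / 3, fs = fs)
  recording(participant_id, set_id, streams, annotations)
}

# small 2-feature separable training set: two Gaussian blobs far apart
toy_separable <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per, 0, 0.3), ncol = 2),
             matrix(rnorm(2 * n_per, 5, 0.3), ncol = 2))
  cols <- data.frame(site = "wrist", quantity = "accel", axis = c("x", "y"),
                     feature = c("mean", "sd"))
  feature_matrix(X, cols, rep(c("C&J", "TRANS"), each = n_per))
}

# XOR pattern: four tight clusters at the corners, diagonal classes
toy_xor <- function(n_per = 10, seed = 2) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  lab <- rep(c("C&J", "C&J", "AS", "AS"), each = n_per)
  X <- do.call(rbind, lapply(1:4, function(i)
    cbind(rnorm(n_per, centers[i, 1], 0.05), rnorm(n_per, centers[i, 2], 0.05))))
  cols <- data.frame(site = "wrist", quantity = "accel", axis = c("x", "y"),
                     feature = c("mean", "sd"))
  feature_matrix(X, cols, lab)
}

small_cohort <- function() memo("cohort3", generate_cohort(3, master_seed = 7))

small_features <- function() memo("features3",
  cohort_features(small_cohort(), windowing_spec(600, 10)))

# independent AUC oracle: P(score_pos > score_neg) + 0.5 P(tie) by pair counting
auc_pair_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# independent MI oracle via the entropy identity H(a) + H(b) - H(a,b), bits
mi_entropy_oracle <- function(a, b) {
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  H(a) + H(b) - H(paste(a, b, sep = "\r"))
}
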