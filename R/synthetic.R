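# Seeded synthetic-workout simulator.
#
# The real dataset behind this pipeline is not publicly deposited, so the
# simulator emulates its structure: 5 sensor sites x (tri-axial accelerometer
# in g + tri-axial gyroscope in deg/s) at 148.15 Hz; three workout sets per
# participant (set1/set3: 3 repetitions of each of the 4 drills; set2: rounds
# of 1, 2, 3, 4 repetitions of each drill, 40 executions in total);
# back-to-back repetitions separated only by short transition phases; and
# inter-/intra-subject variability in tempo and amplitude.
#
# Each drill has a kinematic signature: a sum of Gaussian-windowed sinusoid
# bursts (amplitude, center and width as fractions of the repetition
# duration, carrier frequency in the 1-8 Hz band) on a drill-specific subset
# of channels.  This is the simplest signal model that gives the four drills
# distinct envelopes and spectra across sites -- e.g. box jumps put sharp
# high-frequency impact bursts on the ankle and thigh, swings put sustained
# periodic activity on the lumbar spine and arm, the clean & jerk is biphasic
# on the arm, and burpees spread broadband bursts over the whole body.
# Gravity appears as a per-site constant accelerometer offset with slow
# orientation drift; transitions are low-amplitude correlated noise plus
# posture drift; white measurement noise is added everywhere and signals are
# clipped to the sensor ranges.

burst <- function(site, quantity, axis, amp, center, width, freq) {
  data.frame(site = site, quantity = quantity, axis = axis,
             amp = amp, center = center, width = width, freq = freq,
             stringsAsFactors = FALSE)
}

#' Default drill templates
#'
#' Templates hold each drill's repetition-duration distribution (lognormal,
#' truncated to `[0.8, 6]` s) and its burst signature.  The duration medians
#' (C&J 3.0 s, AS 1.6 s, BJ 2.2 s, BP 3.2 s) and all signature parameters
#' are simulator defaults chosen to give plausible, well-separated drill
#' dynamics; they are free parameters of the generator, not measured values.
#'
#' @param separability global multiplier on every burst amplitude.  1 is the
#'   default separable regime; 0 makes drills indistinguishable from
#'   transition noise (the degenerate control).
#' @return Named list of templates, one per movement class.
#' @export
default_drill_templates <- function(separability = 1) {
  tpl <- list(
    "C&J" = list(
      dur_median = 3.0, dur_sdlog = 0.15,
      bursts = rbind(
        burst("wrist", "accel", "y", 2.5, 0.25, 0.10, 2.0),
        burst("wrist", "accel", "y", 2.0, 0.70, 0.08, 2.5),
        burst("wrist", "gyro", "z", 250, 0.25, 0.10, 2.0),
        burst("wrist", "gyro", "z", 200, 0.70, 0.09, 2.2),
        burst("upper_arm", "accel", "y", 1.8, 0.25, 0.12, 1.8),
        burst("upper_arm", "accel", "y", 1.5, 0.70, 0.10, 2.2),
        burst("upper_arm", "gyro", "x", 180, 0.28, 0.10, 2.0),
        burst("wrist", "gyro", "y", 150, 0.50, 0.30, 1.8),
        burst("upper_arm", "accel", "z", 1.2, 0.50, 0.30, 2.0),
        burst("thigh", "accel", "z", 1.2, 0.20, 0.10, 2.0),
        burst("lumbar", "accel", "y", 1.0, 0.25, 0.15, 1.5),
        burst("lumbar", "gyro", "z", 120, 0.50, 0.30, 1.6))),
    "AS" = list(
      dur_median = 1.6, dur_sdlog = 0.15,
      bursts = rbind(
        burst("lumbar", "accel", "y", 1.8, 0.50, 0.35, 1.4),
        burst("lumbar", "gyro", "x", 220, 0.50, 0.35, 1.4),
        burst("wrist", "accel", "x", 2.2, 0.50, 0.30, 1.4),
        burst("upper_arm", "gyro", "y", 260, 0.50, 0.30, 1.4),
        burst("thigh", "gyro", "x", 120, 0.45, 0.30, 1.4))),
    "BJ" = list(
      dur_median = 2.2, dur_sdlog = 0.15,
      bursts = rbind(
        burst("ankle", "accel", "z", 3.5, 0.30, 0.04, 7.0),
        burst("ankle", "accel", "z", 4.0, 0.55, 0.04, 7.5),
        burst("ankle", "accel", "z", 2.5, 0.90, 0.05, 6.0),
        burst("ankle", "gyro", "y", 300, 0.30, 0.05, 6.0),
        burst("thigh", "accel", "z", 2.5, 0.30, 0.05, 6.5),
        burst("thigh", "accel", "z", 2.8, 0.55, 0.05, 7.0),
        burst("thigh", "gyro", "x", 250, 0.55, 0.06, 5.0),
        burst("thigh", "gyro", "y", 150, 0.50, 0.25, 3.0),
        burst("ankle", "gyro", "x", 120, 0.50, 0.30, 3.5),
        burst("lumbar", "accel", "z", 1.5, 0.55, 0.06, 5.0))),
    "BP" = list(
      dur_median = 3.2, dur_sdlog = 0.15,
      bursts = rbind(
        burst("wrist", "accel", "z", 2.0, 0.35, 0.12, 3.5),
        burst("wrist", "gyro", "x", 220, 0.80, 0.10, 4.5),
        burst("upper_arm", "accel", "x", 1.6, 0.40, 0.15, 3.0),
        burst("thigh", "accel", "y", 1.8, 0.60, 0.12, 4.0),
        burst("ankle", "accel", "x", 1.6, 0.75, 0.10, 5.0),
        burst("lumbar", "gyro", "y", 200, 0.50, 0.25, 2.5),
        burst("upper_arm", "gyro", "z", 180, 0.50, 0.30, 2.8),
        burst("thigh", "gyro", "z", 150, 0.50, 0.28, 3.2),
        burst("lumbar", "accel", "x", 1.5, 0.30, 0.20, 2.0))))
  for (nm in names(tpl)) tpl[[nm]]$bursts$amp <- tpl[[nm]]$bursts$amp * separability
  tpl
}

DUR_TRUNC <- c(0.8, 6)     # repetition durations truncated to this range, s
TRANS_TRUNC <- c(0.5, 3)   # transition durations, s

rlnorm_trunc <- function(n, median, sdlog, trunc) {
  x <- stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
  pmin(pmax(x, trunc[1]), trunc[2])
}

#' Participant profile
#'
#' Per-participant variability: a tempo scale multiplying all durations,
#' per-site amplitude scales, a carrier-frequency jitter factor, and the
#' participant's randomized drill order (drill order is randomized between
#' participants, and fixed within one participant's session).
#'
#' @param participant_id identifier.
#' @param tempo_scale,freq_scale positive scalars.
#' @param amp_scale named positive vector, one entry per site.
#' @param drill_order permutation of the four movement classes.
#' @return A list of class `participant_profile`.
#' @export
participant_profile <- function(participant_id,
                                tempo_scale = 1,
                                amp_scale = stats::setNames(rep(1, 5), sensor_sites()),
                                freq_scale = 1,
                                drill_order = movement_levels()) {
  stopifnot(tempo_scale > 0, all(amp_scale > 0), freq_scale > 0,
            setequal(drill_order, movement_levels()))
  structure(list(participant_id = participant_id, tempo_scale = tempo_scale,
                 amp_scale = amp_scale, freq_scale = freq_scale,
                 drill_order = drill_order),
            class = "participant_profile")
}

#' Workout protocol specification
#'
#' The session structure: set1 and set3 (training sets) hold 3 consecutive
#' repetitions of each drill; set2 (the workout simulation) holds 4 rounds
#' of 1, 2, 3 and 4 repetitions of each drill -- 12, 40 and 12 drill
#' executions respectively, performed back to back with only short
#' transitions in between.
#'
#' @param trans_median,trans_sdlog transition-duration lognormal parameters
#'   (seconds; truncated to `[0.5, 3]` s).
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(trans_median = 1.2, trans_sdlog = 0.3) {
  structure(list(set_reps = list(set1 = list(rounds = list(c(3, 3, 3, 3))),
                                 set2 = list(rounds = lapply(1:4, function(r) rep(r, 4))),
                                 set3 = list(rounds = list(c(3, 3, 3, 3)))),
                 trans_median = trans_median, trans_sdlog = trans_sdlog),
            class = "protocol_spec")
}

# ordered event labels of one set: within each round, all repetitions of each
# drill in the participant's order, drills back to back
set_event_labels <- function(protocol, set_id, drill_order) {
  rounds <- protocol$set_reps[[set_id]]$rounds
  unlist(lapply(rounds, function(reps)
    unlist(mapply(rep, drill_order, reps, SIMPLIFY = FALSE))), use.names = FALSE)
}

# per-site gravity direction (unit-ish vectors, g); slight per-site tilt
GRAVITY_DIR <- list(ankle = c(0.10, 0.15, 0.98), lumbar = c(0.05, 0.10, 0.99),
                    thigh = c(0.20, 0.05, 0.97), upper_arm = c(0.25, 0.20, 0.94),
                    wrist = c(0.30, 0.25, 0.92))

# AR(1) correlated noise, unit marginal sd
ar1_noise <- function(n, phi = 0.97) {
  x <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(x, phi, method = "recursive"))
}

#' Generate one participant's annotated workout session
#'
#' Simulates the three workout sets of one participant as continuous
#' multi-sensor recordings with exact ground-truth movement intervals.
#' Identical seed, profile and parameters give identical output.
#'
#' @param profile a [participant_profile()].
#' @param protocol a [protocol_spec()].
#' @param templates drill templates ([default_drill_templates()]).
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param sites sites to simulate (default all five).
#' @param accel_noise_sd,gyro_noise_sd white measurement-noise sd (g, deg/s).
#' @param trans_accel_amp,trans_gyro_amp marginal sd of the correlated
#'   transition-movement noise (g, deg/s).
#' @return Named list of three [recording()]s (`set1`, `set2`, `set3`).
#' @export
generate_participant <- function(profile, protocol = protocol_spec(),
                                 templates = default_drill_templates(),
                                 fs = default_fs(), seed = 1L,
                                 sites = sensor_sites(),
                                 accel_noise_sd = 0.05, gyro_noise_sd = 8,
                                 trans_accel_amp = 0.12, trans_gyro_amp = 12) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(protocol, "protocol_spec"))
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (!setequal(names(templates), movement_levels()))
    stop("templates must cover all four drills")
  if (!length(protocol$set_reps)) stop("empty protocol")
  set.seed(as.integer(seed))
  out <- list()
  for (set_id in names(protocol$set_reps)) {
    labs <- set_event_labels(protocol, set_id, profile$drill_order)
    n_ev <- length(labs)
    drill_dur <- vapply(labs, function(l)
      rlnorm_trunc(1, templates[[l]]$dur_median * profile$tempo_scale,
                   templates[[l]]$dur_sdlog, DUR_TRUNC), 0)
    trans_dur <- rlnorm_trunc(n_ev + 1L, protocol$trans_median * profile$tempo_scale,
                              protocol$trans_sdlog, TRANS_TRUNC)
    # sample-aligned event grid: transitions interleaved with drills
    ev_lab <- character(2 * n_ev + 1L)
    ev_dur <- numeric(2 * n_ev + 1L)
    ev_lab[seq(1, 2 * n_ev + 1, by = 2)] <- "TRANS"
    ev_dur[seq(1, 2 * n_ev + 1, by = 2)] <- trans_dur
    ev_lab[seq(2, 2 * n_ev, by = 2)] <- labs
    ev_dur[seq(2, 2 * n_ev, by = 2)] <- drill_dur
    ev_n <- pmax(round(ev_dur * fs), 2L)
    ev_end <- cumsum(ev_n)
    ev_start <- ev_end - ev_n + 1L
    n <- ev_end[length(ev_end)]
    tloc <- lapply(seq_along(ev_n), function(i) (seq_len(ev_n[i]) - 1) / fs)
    streams <- list()
    for (site in sites) for (q in sensor_quantities()) {
      noise_sd <- if (q == "accel") accel_noise_sd else gyro_noise_sd
      trans_amp <- if (q == "accel") trans_accel_amp else trans_gyro_amp
      dat <- matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3,
                    dimnames = list(NULL, sensor_axes()))
      # low-frequency posture/movement noise over the whole set
      for (ax in 1:3) dat[, ax] <- dat[, ax] + trans_amp * ar1_noise(n)
      if (q == "accel") {
        g0 <- GRAVITY_DIR[[site]]
        tt <- (seq_len(n) - 1) / fs
        for (ax in 1:3) {
          drift_f <- stats::runif(1, 0.03, 0.1)
          drift_a <- stats::runif(1, 0.02, 0.06)
          dat[, ax] <- dat[, ax] + g0[ax] +
            drift_a * sin(2 * pi * drift_f * tt + stats::runif(1, 0, 2 * pi))
        }
      }
      for (i in seq_along(ev_lab)) {
        if (ev_lab[i] == "TRANS") next
        bs <- templates[[ev_lab[i]]]$bursts
        bs <- bs[bs$site == site & bs$quantity == q, , drop = FALSE]
        if (!nrow(bs)) next
        D <- ev_n[i] / fs
        t <- tloc[[i]]
        span <- ev_start[i]:ev_end[i]
        for (b in seq_len(nrow(bs))) {
          f <- bs$freq[b] * profile$freq_scale * exp(stats::rnorm(1, 0, 0.04))
          amp <- bs$amp[b] * profile$amp_scale[[site]] * exp(stats::rnorm(1, 0, 0.08))
          ph <- stats::runif(1, 0, 2 * pi)
          ax <- match(bs$axis[b], sensor_axes())
          dat[span, ax] <- dat[span, ax] +
            amp * exp(-(t - bs$center[b] * D)^2 / (2 * (bs$width[b] * D)^2)) *
            sin(2 * pi * f * t + ph)
        }
      }
      streams[[paste(site, q, sep = "_")]] <-
        sensor_stream(site, q, dat[, 1], dat[, 2], dat[, 3], fs = fs)
    }
    drill_idx <- which(ev_lab != "TRANS")
    ann <- label_intervals((ev_start[drill_idx] - 1) / fs,
                           ev_end[drill_idx] / fs,
                           ev_lab[drill_idx])
    out[[set_id]] <- recording(profile$participant_id, set_id, streams, ann)
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws seeded per-participant profiles (tempo, per-site amplitude and
#' frequency scales; randomized drill order) and simulates the full
#' three-set session for each participant.  The default cohort size matches
#' the fourteen-participant study design this simulator emulates.
#'
#' @param n_participants cohort size, at least 2 (LOSO is undefined below
#'   that).
#' @param master_seed integer; drives the profile draws and each
#'   participant's simulation seed.
#' @param tempo_sdlog,amp_sdlog,freq_sdlog inter-subject variability
#'   (lognormal sd of the respective scales; 0 gives identical profiles).
#' @param ... passed on to [generate_participant()] (templates, protocol,
#'   fs, noise levels, sites).
#' @return A list of class `cohort`: one element per participant, each a
#'   named list of three [recording()]s.
#' @export
generate_cohort <- function(n_participants = 14, master_seed = 1L,
                            tempo_sdlog = 0.08, amp_sdlog = 0.12,
                            freq_sdlog = 0.05, ...) {
  if (n_participants < 2) stop("a cohort needs at least 2 participants")
  set.seed(as.integer(master_seed))
  ids <- sprintf("p%02d", seq_len(n_participants))
  profiles <- lapply(ids, function(id) {
    participant_profile(
      id,
      tempo_scale = stats::rlnorm(1, 0, tempo_sdlog),
      amp_scale = stats::setNames(stats::rlnorm(5, 0, amp_sdlog), sensor_sites()),
      freq_scale = stats::rlnorm(1, 0, freq_sdlog),
      drill_order = sample(movement_levels()))
  })
  seeds <- sample.int(2^31 - 2, n_participants)
  out <- lapply(seq_len(n_participants), function(i)
    generate_participant(profiles[[i]], seed = seeds[i], ...))
  names(out) <- ids
  structure(out, class = "cohort", profiles = profiles)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants x %d recordings\n",
              length(x), length(x[[1]])))
  invisible(x)
}

#' Segment and extract features for a whole cohort
#'
#' Runs [segment_and_label()] and [extract_matrix()] on every recording of
#' the cohort and stacks the results into one feature matrix carrying
#' participant and set identity per row.  Extract once with all sites and
#' slice subsets with [select_sites()] rather than re-extracting.
#'
#' @param cohort a [generate_cohort()] result (or any list of lists of
#'   recordings).
#' @param spec a [windowing_spec()].
#' @param sites site subset (default: all present).
#' @param majority_frac window-labeling threshold, see [label_window()].
#' @return A [feature_matrix()].
#' @export
cohort_features <- function(cohort, spec = windowing_spec(), sites = NULL,
                            majority_frac = 2 / 3) {
  ms <- list()
  for (p in cohort) for (rec in p) {
    win <- segment_and_label(rec, spec, majority_frac = majority_frac)
    ms[[length(ms) + 1L]] <- extract_matrix(win, rec, sites = sites)
  }
  rbind_features(ms)
}
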