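test_that("window geometry follows the floor/round conventions", {
  spec <- windowing_spec(600, 10)              # default acquisition rate
  expect_equal(spec$window_samples, 88)        # floor(0.6 * 148.15)
  expect_equal(spec$step_samples, 79)          # round(88 * 0.9)
  expect_equal(windowing_spec(600, 0)$step_samples, 88)
  expect_equal(windowing_spec(600, 20)$step_samples, 70)
})

test_that("window counts match the closed form on the worked cases", {
  spec <- windowing_spec(600, 0, fs = 148.15)
  expect_equal(nrow(make_windows(88L, spec)), 1)          # exact fit
  expect_warning(w0 <- make_windows(87L, spec), "shorter")
  expect_equal(nrow(w0), 0)
  spec10 <- windowing_spec(600, 10, fs = 148.15)
  w <- make_windows(1000L, spec10)
  expect_equal(nrow(w), 12)
  expect_equal(w$start_sample, 1 + 79 * (0:11))           # starts 0,79,...,869
})

test_that("window count equals brute-force enumeration over a parameter grid", {
  for (n in c(10, 37, 88, 100, 257)) {
    for (wms in c(300, 400, 500, 600)) {
      for (ov in c(0, 10, 20, 50)) {
        spec <- windowing_spec(wms, ov, fs = 148.15)
        if (n < spec$window_samples) next
        got <- make_windows(as.integer(n), spec)
        # oracle: enumerate starts directly
        starts <- seq(1L, n, by = spec$step_samples)
        starts <- starts[starts + spec$window_samples - 1L <= n]
        expect_equal(got$start_sample, starts)
        expect_true(all(got$end_sample - 1L <= n))
      }
    }
  }
})

test_that("increasing overlap never decreases the window count", {
  for (n in c(100, 500, 1000)) {
    counts <- vapply(c(0, 10, 20, 40, 60, 80), function(ov)
      nrow(make_windows(as.integer(n), windowing_spec(400, ov))), 0L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("majority labeling requires strict two-thirds coverage", {
  fs <- 100
  n <- 100
  # 70% C&J coverage -> C&J
  ann <- label_intervals(0, 0.70, "C&J")
  expect_equal(as.character(label_window(1L, 101L, ann, fs, n_samples = n)),
               "C&J")
  # 50/50 split with TRANS -> TRANS
  ann <- label_intervals(0, 0.50, "AS")
  expect_equal(as.character(label_window(1L, 101L, ann, fs, n_samples = n)),
               "TRANS")
  # back-to-back drills, no single movement above 2/3 -> TRANS
  ann <- label_intervals(c(0, 0.5), c(0.5, 1), c("C&J", "AS"))
  expect_equal(as.character(label_window(1L, 101L, ann, fs, n_samples = n)),
               "TRANS")
  # exact two-thirds is NOT a majority (strict inequality)
  ann <- label_intervals(0, 0.66, "BJ")
  w <- label_window(1L, 100L, ann, fs, n_samples = 99L)  # 66 of 99 samples
  expect_equal(as.character(w), "TRANS")
  # one sample above two-thirds flips it
  ann <- label_intervals(0, 0.67, "BJ")
  w <- label_window(1L, 100L, ann, fs, n_samples = 99L)  # 67 of 99
  expect_equal(as.character(w), "BJ")
})

test_that("labeling is invariant to splitting an interval with equal labels", {
  fs <- 100; n <- 200
  whole <- label_intervals(0.2, 1.6, "BP")
  split <- label_intervals(c(0.2, 0.7, 1.1), c(0.7, 1.1, 1.6), rep("BP", 3))
  for (st in c(1L, 21L, 61L, 101L)) {
    expect_equal(label_window(st, st + 100L, whole, fs, n_samples = n),
                 label_window(st, st + 100L, split, fs, n_samples = n))
  }
})

test_that("segment_and_label composes windowing and labeling", {
  fs <- 100
  rec <- toy_recording(n = 1000, fs = fs)               # no annotations
  win <- segment_and_label(rec, windowing_spec(600, 0, fs = fs))
  expect_true(all(win$label == "TRANS"))
  # one 3 s drill inside 10 s of transition: several windows carry the label
  ann <- label_intervals(3.5, 6.5, "AS")
  rec <- toy_recording(n = 1000, fs = fs, annotations = ann)
  win <- segment_and_label(rec, windowing_spec(600, 10, fs = fs))
  expect_gte(sum(win$label == "AS"), 3)
  expect_true(all(win$label %in% c("AS", "TRANS")))
  expect_equal(win$participant_id[1], "p1")
})

test_that("a synthetic training set yields windows of all five classes", {
  rec <- small_cohort()[[1]]$set1
  win <- segment_and_label(rec, windowing_spec(600, 10))
  expect_setequal(as.character(unique(win$label)), drill_levels())
  expect_false(is.unsorted(win$start_sample))
})
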