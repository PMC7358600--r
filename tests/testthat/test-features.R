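test_that("time features are exact on constant and small hand-computed windows", {
  # constant window: degenerate-case conventions
  tf <- time_features(rep(3, 10))
  expect_equal(unname(tf[c("mean", "sd", "rms", "mad", "max", "min",
                           "kurtosis", "skewness", "q25", "q50", "q75")]),
               c(3, 0, 3, 0, 3, 3, 0, 0, 3, 3, 3))
  expect_equal(unname(time_features(rep(-2, 5))["rms"]), 2)
  # x = 1..4, checked against direct arithmetic
  tf <- time_features(1:4)
  expect_equal(unname(tf["mean"]), 2.5)
  expect_equal(unname(tf["sd"]), sd(1:4), tolerance = 1e-6)       # 1.290994
  expect_equal(unname(tf["rms"]), sqrt(mean((1:4)^2)), tolerance = 1e-6)  # 2.738613
  expect_equal(unname(tf["mad"]), 1.0)
  expect_equal(unname(tf["max"]), 4)
  expect_equal(unname(tf["min"]), 1)
  expect_equal(unname(tf[c("q25", "q50", "q75")]),
               unname(quantile(1:4, c(.25, .5, .75), type = 7)))
  # moment features against direct central-moment arithmetic
  set.seed(4)
  x <- rnorm(50)
  m <- mean(x); cm <- x - m
  expect_equal(unname(time_features(x)["skewness"]),
               mean(cm^3) / mean(cm^2)^1.5)
  expect_equal(unname(time_features(x)["kurtosis"]),
               mean(cm^4) / mean(cm^2)^2)
  expect_equal(unname(time_features(x, excess = TRUE)["kurtosis"]),
               mean(cm^4) / mean(cm^2)^2 - 3)
})

test_that("negating the signal transforms time features by symmetry", {
  set.seed(11)
  x <- rnorm(64) + 0.5
  a <- time_features(x); b <- time_features(-x)
  expect_equal(b["mean"], -a["mean"], ignore_attr = TRUE)
  expect_equal(b["skewness"], -a["skewness"], ignore_attr = TRUE)
  for (f in c("sd", "rms", "mad", "kurtosis"))
    expect_equal(b[f], a[f], ignore_attr = TRUE)
  expect_equal(unname(b["max"]), -unname(a["min"]))
  expect_equal(unname(b["min"]), -unname(a["max"]))
})

test_that("a bin-aligned tone concentrates all located frequencies at f0", {
  fs <- 64; n <- 64
  t <- (0:(n - 1)) / fs
  ff <- freq_features(sin(2 * pi * 8 * t), fs)
  expect_equal(unname(ff["f_median"]), 8)
  expect_equal(unname(ff["f_mean"]), 8, tolerance = 1e-9)
  expect_equal(unname(ff["f_upper"]), 8)
  expect_equal(unname(ff["f_lower"]), 8)
  expect_lt(unname(ff["spec_entropy"]), 0.01)
  # one-sided amplitude of a unit sinusoid is 1 at its bin
  expect_equal(unname(ff["spec_mean"]), 1 / (n / 2), tolerance = 1e-9)
})

test_that("two equal tones give closed-form mean/lower/upper frequencies", {
  fs <- 64; n <- 128
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 4 * t) + sin(2 * pi * 12 * t)
  ff <- freq_features(x, fs)
  expect_equal(unname(ff["f_mean"]), (4 + 12) / 2, tolerance = 1e-9)
  expect_equal(unname(ff["f_lower"]), 4)
  expect_equal(unname(ff["f_upper"]), 12)
  # median: smallest bin reaching half the total power = the lower tone
  expect_equal(unname(ff["f_median"]), 4)
})

test_that("constant (zero-power) windows return the all-zero convention", {
  ff <- freq_features(rep(5, 32), fs = 100)
  expect_equal(unname(ff), rep(0, 7))
})

test_that("white noise has near-flat spectral entropy", {
  set.seed(9)
  ff <- freq_features(rnorm(512), fs = 148.15)
  expect_gt(unname(ff["spec_entropy"]), 0.9)
  expect_lte(unname(ff["spec_entropy"]), 1)
})

test_that("periodogram power matches time-domain variance (Parseval)", {
  set.seed(10)
  for (n in c(64, 88, 101)) {
    x <- rnorm(n)
    x <- x - mean(x)
    expect_equal(unname(freq_features(x, 100)["power"]), mean(x^2),
                 tolerance = 1e-10)
  }
})

test_that("features of a periodic signal are invariant to period shifts", {
  fs <- 100
  t <- (0:999) / fs
  x <- sin(2 * pi * 5 * t) + 0.3 * sin(2 * pi * 10 * t)
  period <- fs / 5   # 20 samples
  w <- 100           # 5 full periods
  a <- c(time_features(x[1:w]), freq_features(x[1:w], fs))
  b <- c(time_features(x[(1 + 2 * period):(w + 2 * period)]),
         freq_features(x[(1 + 2 * period):(w + 2 * period)], fs))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("feature counts follow 18 x 6 x sites for every configuration", {
  ann <- label_intervals(0, 0.5, "C&J")
  rec <- toy_recording(n = 300, fs = 100, sites = sensor_sites(),
                       annotations = ann)
  win <- segment_and_label(rec, windowing_spec(600, 10, fs = 100))
  full <- extract_matrix(win, rec)
  expect_equal(ncol(full$values), 540)
  expect_equal(ncol(extract_matrix(win, rec, sites = "upper_arm")$values), 108)
  expect_equal(ncol(extract_matrix(win, rec,
                                   sites = c("upper_arm", "thigh"))$values), 216)
  expect_error(extract_matrix(win, toy_recording(n = 300, fs = 100),
                              sites = "thigh"), "thigh")
  # column order: site blocks in canonical order, 18 features per channel
  expect_equal(unique(full$columns$site), sensor_sites())
  expect_equal(full$columns$feature[1:18], feature_names())
  # slicing the full matrix equals direct extraction
  expect_equal(select_sites(full, "upper_arm")$values,
               extract_matrix(win, rec, sites = "upper_arm")$values)
})

test_that("all features are finite on saturated and constant windows", {
  clipped <- sensor_stream("ankle", "accel",
                           rep(c(20, -20), 50), rep(0, 100), rep(1, 100),
                           fs = 100)
  still <- sensor_stream("ankle", "gyro",
                         rep(0, 100), rep(0, 100), rep(4, 100), fs = 100)
  rec <- recording("p1", "set1", list(clipped, still))
  win <- segment_and_label(rec, windowing_spec(600, 0, fs = 100))
  fm <- extract_matrix(win, rec)
  expect_true(all(is.finite(fm$values)))
})

test_that("standardization freezes training statistics for reuse", {
  set.seed(3)
  tr <- matrix(rnorm(60, mean = 10, sd = 2), ncol = 3)
  z <- standardize(tr)
  expect_equal(colMeans(z$matrix), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z$matrix, 2, sd), rep(1, 3), tolerance = 1e-12)
  # constant column guard
  zc <- standardize(cbind(tr[, 1], 7))
  expect_equal(zc$matrix[, 2], rep(0, 20))
  # train stats applied to shifted test data leave a visible mean shift
  te <- tr + 1
  zt <- standardize(te, z$stats)$matrix
  expect_equal(colMeans(zt), 1 / z$stats$sd, tolerance = 1e-10)
  expect_error(standardize(tr[, 1:2], z$stats), "columns")
})
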