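test_that("mutual information matches the entropy-identity oracle", {
  # perfectly dependent balanced binary pair carries exactly 1 bit
  a <- rep(0:1, 50)
  expect_equal(mutual_information(a, a), 1)
  # independent product table has zero MI
  a <- rep(c("u", "v"), each = 6)
  b <- rep(c("p", "q", "r"), 4)
  expect_equal(mutual_information(a, b), 0, tolerance = 1e-12)
  # 3x3 joint table against the direct plug-in formula
  a <- c(1, 1, 1, 2, 2, 3, 3, 3, 3)
  b <- c(1, 2, 2, 2, 3, 1, 1, 3, 3)
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  direct <- 0
  for (i in 1:3) for (j in 1:3)
    if (joint[i, j] > 0)
      direct <- direct + joint[i, j] * log2(joint[i, j] / (pa[i] * pb[j]))
  expect_equal(mutual_information(a, b), unname(direct))
  # random small tables against the entropy identity
  set.seed(41)
  for (i in 1:25) {
    a <- sample(1:3, 30, TRUE); b <- sample(1:4, 30, TRUE)
    expect_equal(mutual_information(a, b), mi_entropy_oracle(a, b),
                 tolerance = 1e-12)
  }
  expect_gte(mutual_information(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE)), 0)
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("mRMR ranks relevance first and penalizes redundancy", {
  set.seed(42)
  n <- 200
  y <- rep(c("C&J", "TRANS"), each = n / 2)
  informative <- ifelse(y == "C&J", 1, -1) + rnorm(n, 0, 0.3)
  noise <- matrix(rnorm(n * 6), ncol = 6)
  X <- cbind(noise[, 1:3], informative, noise[, 4:6])
  rk <- mrmr_rank(X, labels = y)
  expect_equal(rk$order[1], 4)
  expect_equal(which.max(rk$relevance), 4L)
  # an exact duplicate of the winner is not picked second while any other
  # feature has positive relevance
  weak <- ifelse(y == "C&J", 1, -1) + rnorm(n, 0, 2)
  X2 <- cbind(informative, informative, weak, noise[, 1])
  rk2 <- mrmr_rank(X2, labels = y)
  expect_equal(rk2$order[1], 1)
  expect_false(rk2$order[2] == 2)
})

test_that("the greedy trace matches a brute-force mRMR oracle", {
  set.seed(43)
  n <- 120
  y <- sample(c("AS", "BJ", "TRANS"), n, TRUE)
  X <- cbind(as.integer(y == "AS") + rnorm(n, 0, 0.5),
             rnorm(n),
             as.integer(y == "BJ") + rnorm(n, 0, 0.7),
             as.integer(y == "AS") + rnorm(n, 0, 0.6))
  n_bins <- 4
  rk <- mrmr_rank(X, labels = y, n_bins = n_bins)
  # oracle: same discretization, explicit greedy MID loop on MI tables
  disc <- apply(X, 2, function(x) {
    br <- unique(quantile(x, seq(0, 1, length.out = n_bins + 1), names = FALSE))
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  })
  rel <- vapply(1:4, function(j) mi_entropy_oracle(y, disc[, j]), 0)
  sel <- integer(0); rem <- 1:4
  while (length(rem)) {
    crit <- vapply(rem, function(j) {
      red <- if (length(sel)) mean(vapply(sel, function(s)
        mi_entropy_oracle(disc[, s], disc[, j]), 0)) else 0
      rel[j] - red
    }, 0)
    pick <- rem[which.max(crit)]
    sel <- c(sel, pick); rem <- setdiff(rem, pick)
  }
  expect_equal(rk$order, sel)
  expect_equal(rk$relevance, rel, tolerance = 1e-12)
})

test_that("ranking is equivariant under column permutation", {
  set.seed(44)
  n <- 150
  y <- rep(c("BP", "TRANS"), each = n / 2)
  X <- cbind(ifelse(y == "BP", 2, 0) + rnorm(n),
             rnorm(n, sd = 2),
             ifelse(y == "BP", 0, 1) + rnorm(n, 0, 0.5),
             rnorm(n))
  perm <- c(3, 1, 4, 2)
  r1 <- mrmr_rank(X, labels = y)
  r2 <- mrmr_rank(X[, perm], labels = y)
  expect_equal(perm[r2$order], r1$order)
})

test_that("select_top slices the ranking head", {
  rk <- structure(list(order = 5:1, score = rep(0, 5)), class = "feature_ranking")
  expect_equal(select_top(rk, 5), 5:1)
  expect_equal(select_top(rk, 2), c(5L, 4L))
  expect_error(select_top(rk, 0), "at least 1")
  expect_error(select_top(rk, 6), "exceeds")
})

test_that("top-20 of a 108-column single-sensor matrix recovers class structure", {
  fm <- small_features()
  ua <- select_sites(fm, "upper_arm")
  expect_equal(ncol(ua$values), 108)
  tr <- subset_rows(ua, ua$set_id %in% c("set1", "set3"))
  z <- standardize(tr)
  rk <- mrmr_rank(z$matrix)
  top <- select_top(rk, 20)
  expect_length(top, 20)
  expect_equal(anyDuplicated(top), 0)
  # the selected features should be far more label-informative than the rest
  rest <- setdiff(seq_len(108), top)
  expect_gt(mean(rk$relevance[top]), mean(rk$relevance[rest]))
  prof <- ranking_profile(rk, 20)
  expect_equal(sum(prof$domain), 20)
})
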