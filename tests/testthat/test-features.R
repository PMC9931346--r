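test_that("inertia decomposition matches the brute-force double sums", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  labels <- sample.int(2, 20, replace = TRUE)
  dec <- inertia_decomposition(X, labels)
  oracle <- brute_inertia(X, labels)
  expect_equal(unname(dec$T), oracle$T, tolerance = 1e-12)
  expect_equal(unname(dec$B), oracle$B, tolerance = 1e-12)
  expect_equal(unname(dec$W), oracle$W, tolerance = 1e-12)
})

test_that("degenerate partitions split inertia as expected", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  one <- inertia_decomposition(X, rep(1, 10))
  expect_equal(unname(one$B), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(one$W), unname(one$T), tolerance = 1e-12)
  singletons <- inertia_decomposition(X, seq_len(10))
  expect_equal(unname(singletons$W), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(singletons$B), unname(singletons$T), tolerance = 1e-12)
  expect_error(inertia_decomposition(X, c(rep(1, 10))[c(1:9, NA)]), ".")
})

test_that("Huygens-Steiner holds on random instances", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:40, 1); m <- sample(2:6, 1); K <- sample(2:4, 1)
    X <- matrix(rnorm(n * m), n, m)
    labels <- sample.int(K, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    dec <- inertia_decomposition(X, labels)
    expect_true(all(abs(dec$T - (dec$B + dec$W)) < 1e-8))
    expect_true(all(dec$B >= -1e-12 & dec$W >= -1e-12))
  }
})

test_that("quality indices normalize and respect invariances", {
  set.seed(4)
  X <- matrix(rnorm(90), 30, 3)
  labels <- sample.int(3, 30, replace = TRUE)
  qi <- quality_indices(inertia_decomposition(X, labels))
  expect_true(all(qi$Q >= 0 & qi$Q <= 1))
  expect_equal(sum(qi$Qprime), 1, tolerance = 1e-12)
  # per-feature affine rescaling leaves Q unchanged
  X2 <- sweep(sweep(X, 2, c(2, 0.5, 10), "*"), 2, c(1, -3, 7), "+")
  qi2 <- quality_indices(inertia_decomposition(X2, labels))
  expect_equal(qi$Q, qi2$Q, tolerance = 1e-10)
  # a constant variable is flagged
  X3 <- cbind(X, 5)
  expect_warning(qi3 <- quality_indices(inertia_decomposition(X3, labels)),
                 "constant")
  expect_true(is.na(qi3$Q[4]))
  # only feature 1 separates the clusters
  Y <- cbind(c(rep(0, 10), rep(5, 10)), rnorm(20, 0, 1e-8))
  qY <- quality_indices(inertia_decomposition(Y, rep(1:2, each = 10)))
  expect_gt(qY$Qprime[1], 0.999)
})

test_that("merging identical clusters leaves Q unchanged", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 3), 20, 2))
  lab_merged <- rep(1:2, each = 20)
  lab_split <- c(rep(1, 10), rep(3, 10), rep(2, 20))
  # cluster 3 duplicates cluster 1's distribution; compare via cluster means
  X[11:20, ] <- X[1:10, ]
  q1 <- quality_indices(inertia_decomposition(X, lab_merged))
  q2 <- quality_indices(inertia_decomposition(X, lab_split))
  expect_equal(q1$Q, q2$Q, tolerance = 1e-10)
})

test_that("the variation test keys on separation and pair counts", {
  set.seed(6)
  n <- 200
  # feature 1 hugely separated, feature 2 identical
  X <- cbind(c(rnorm(n), rnorm(n, 10)), rnorm(2 * n))
  labels <- rep(1:2, each = n)
  sel1 <- variation_test(X, labels, delta = 0.01, min_pairs = 1)
  expect_true(sel1[1])
  expect_false(sel1[2])
  # only one pair exists with two clusters: min_pairs = 2 deselects
  sel2 <- variation_test(X, labels, delta = 0.01, min_pairs = 2)
  expect_false(sel2[1])
  # monotone in separation
  X3 <- X; X3[labels == 2, 1] <- X3[labels == 2, 1] + 10
  sel3 <- variation_test(X3, labels, delta = 0.01, min_pairs = 1)
  expect_true(sel3[1])
  w <- capture_warnings(
    variation_test(rbind(X, c(0, 0)), c(labels, 3), min_pairs = 1))
  expect_true(all(grepl("size 1", w)) && length(w) >= 1)
})

test_that("tiers count the selecting methods", {
  set.seed(7)
  # three separated clusters in 4 informative + 6 noise features
  n <- 120
  centers <- rbind(c(0, 0, 0, 0), c(6, 6, 0, 0), c(0, 0, 6, 6))
  lab <- rep(1:3, each = n / 3)
  X <- cbind(centers[lab, ] + matrix(rnorm(n * 4, 0, 0.5), n, 4),
             matrix(rnorm(n * 6), n, 6))
  colnames(X) <- paste0("f", 1:10)
  rk <- rank_and_tier(X, lab, k = 4, min_pairs = 1)
  tab <- rk$table
  expect_true(all(tab$tier[tab$variable %in% paste0("f", 1:4)] >= 2))
  expect_true(all(tab$tier >= 0 & tab$tier <= 3))
  expect_warning(rank_and_tier(X, lab, k = 99), "clamped")
})
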