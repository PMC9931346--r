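test_that("polytope vertices reproduce the data exactly", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(0.3, 0.3), c(0.1, 0.6))
  fit <- fit_archetypes(X, K = 3, seed = 1)
  expect_lt(fit$rss, 1e-10)
  perm <- sepstates:::match_archetypes(fit$Z, X[1:3, ])
  expect_lt(max(abs(fit$Z[perm, ] - X[1:3, ])), 1e-6)
  # alpha and beta rows on the simplex, Z = beta X exactly
  expect_true(all(fit$alpha >= -1e-12))
  expect_true(all(abs(rowSums(fit$alpha) - 1) < 1e-8))
  expect_true(all(fit$beta >= -1e-12))
  expect_true(all(abs(rowSums(fit$beta) - 1) < 1e-8))
  expect_lt(max(abs(fit$Z - fit$beta %*% X)), 1e-12)
})

test_that("K = 1 matches a brute-force search over the convex hull", {
  set.seed(2)
  X <- matrix(rnorm(8), 4, 2)
  fit <- fit_archetypes(X, K = 1, seed = 1, tol = 1e-14, max_iter = 5000)
  # oracle: grid over simplex weights on the 4 points
  grid <- seq(0, 1, by = 0.02)
  best <- Inf
  for (a in grid) for (b in grid) for (cc in grid) {
    d <- 1 - a - b - cc
    if (d < -1e-12) next
    z <- a * X[1, ] + b * X[2, ] + cc * X[3, ] + max(d, 0) * X[4, ]
    rss <- sum(sweep(X, 2L, z, "-")^2)
    if (rss < best) best <- rss
  }
  # both are approximate: the grid to its resolution, the solver to its tol
  expect_lt(abs(fit$rss - best), 5e-3)
  # the fitted archetype stays in the convex hull (beta on the simplex)
  expect_true(all(fit$beta >= -1e-12))
  expect_equal(sum(fit$beta), 1, tolerance = 1e-8)
})

test_that("planted archetypes are recovered from pure noise-free data", {
  cfg <- cohort_config(seed = 4, n_patients = 30, K_true = 4, noise_sd = 0,
                       mixture_concentration = Inf, missing_rate = 1)
  set.seed(9)
  obs <- simulate_observations(cfg, 400)
  fit <- fit_archetypes(obs$X, 4, max_iter = 500, seed = 1)
  perm <- sepstates:::match_archetypes(fit$Z, cfg$archetype_matrix)
  rel <- sqrt(rowSums((cfg$archetype_matrix - fit$Z[perm, ])^2)) /
    sqrt(rowSums(cfg$archetype_matrix^2))
  expect_lt(max(rel), 1e-3)
})

test_that("objective decreases monotonically and rss matches the matrices", {
  set.seed(3)
  X <- matrix(rnorm(600), 100, 6)
  fit <- fit_archetypes(X, 3, max_iter = 200, seed = 2)
  expect_true(all(diff(fit$objective_path) <= 1e-9))
  expect_equal(fit$rss,
               sum((X - fit$alpha %*% fit$beta %*% X)^2), tolerance = 1e-8)
})

test_that("row permutation permutes alpha and preserves archetypes", {
  set.seed(6)
  X <- matrix(rnorm(300), 50, 6)
  p <- sample(50)
  f1 <- fit_archetypes(X, 3, max_iter = 300, seed = 1)
  f2 <- fit_archetypes(X[p, ], 3, max_iter = 300, seed = 1)
  perm <- sepstates:::match_archetypes(f2$Z, f1$Z)
  expect_lt(max(abs(f2$Z[perm, ] - f1$Z)), 1e-6)
  expect_lt(max(abs(f2$alpha[order(p), perm] - f1$alpha)), 1e-4)
})

test_that("projection onto fixed archetypes has the stated geometry", {
  Z <- rbind(c(0, 0), c(10, 0), c(0, 10))
  a1 <- project_alpha(rbind(Z[2, ]), Z)
  expect_equal(unname(a1[1, ]), c(0, 1, 0), tolerance = 1e-10)
  mid <- rbind((Z[1, ] + Z[2, ]) / 2)
  a2 <- project_alpha(mid, Z)
  expect_equal(unname(a2[1, ]), c(0.5, 0.5, 0), tolerance = 1e-8)
  expect_error(project_alpha(matrix(0, 1, 3), Z), "dimension")
  # fixed point: reprojecting training rows reproduces alpha
  set.seed(7)
  X <- matrix(rnorm(200), 50, 4)
  fit <- fit_archetypes(X, 3, max_iter = 300, seed = 1)
  a <- project_alpha(X, fit$Z)
  f_re <- sum((X - a %*% fit$Z)^2)
  expect_lte(f_re, fit$rss + 1e-8)
})

test_that("state assignment is the argmax with lowest-index ties", {
  a <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.5, 0.0), c(0.1, 0.2, 0.7))
  lab <- assign_state(a)
  expect_equal(as.integer(lab), c(1L, 1L, 3L))
  expect_equal(attr(lab, "ties"), 2L)
  set.seed(8)
  W <- sepstates:::rdirichlet(200, c(1, 1, 1, 1))
  expect_equal(as.integer(assign_state(W)), apply(W, 1, which.max))
})

test_that("elbow selection finds the planted order and handles edge cases", {
  cfg <- cohort_config(seed = 10, n_patients = 30, K_true = 4,
                       noise_sd = 0.05, mixture_concentration = Inf,
                       missing_rate = 1, m = 20)
  set.seed(11)
  obs <- simulate_observations(cfg, 300)
  curve <- select_K_elbow(obs$X, 2:6, max_iter = 200, seed = 1)
  expect_equal(curve$chosen_K, 4L)
  expect_true(all(diff(curve$rss) <= 1e-6))
  expect_equal(select_K_elbow(obs$X, 3, max_iter = 50, seed = 1)$chosen_K, 3L)
  # strictly linear residual curve has no elbow
  expect_true(is.na(sepstates:::elbow_point(1:5, seq(10, 2, by = -2))))
})

test_that("generalizability metrics are near-perfect on easy data", {
  cfg <- cohort_config(seed = 12, n_patients = 30, K_true = 3,
                       noise_sd = 0.05, mixture_concentration = Inf,
                       missing_rate = 1, m = 10)
  set.seed(13)
  obs <- simulate_observations(cfg, 400)
  sofa <- rnorm(400, 5)
  pat <- sample(paste0("p", 1:40), 400, replace = TRUE)
  died <- setNames(runif(40) < 0.2, paste0("p", 1:40))
  rep <- evaluate_generalizability(obs$X, K = 3, n_repetitions = 3, seed = 2,
                                   max_iter = 300, sofa = sofa, sirs = sofa,
                                   patient = pat, died = died)
  expect_gt(rep$accuracy, 0.95)
  expect_lt(rep$relative_error, 0.1)
  expect_true(all(rep$reps$accuracy >= 0 & rep$reps$accuracy <= 1))
  expect_true(all(rep$reps$sofa_error >= 0))
  expect_error(evaluate_generalizability(obs$X, K = 3, split_fraction = 1),
               "empty")
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_archetypes(X, 11), "exceed")
  X[1, 1] <- NA
  expect_error(fit_archetypes(X, 2), "finite")
})
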