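make_dataset <- function(seqs, X_by_stay = NULL, patient_id = NULL,
                         died = NULL) {
  traces <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    X <- X_by_stay[[i]] %||%
      matrix(0, length(s), 2, dimnames = list(NULL, c("v1", "v2")))
    list(time = seq_along(s), X = X, states = as.integer(s))
  })
  names(traces) <- as.character(seq_along(seqs))
  structure(list(traces = traces,
                 patient_id = patient_id %||%
                   setNames(paste0("p", seq_along(seqs)),
                            names(traces)),
                 died = died),
            class = "trajectory_dataset")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("trajectories preserve stays, order and labels", {
  X <- matrix(rnorm(12), 6, 2)
  attr(X, "stay") <- rep(c("s1", "s2"), each = 3)
  attr(X, "bin") <- c(3, 1, 2, 1, 2, 3)
  labels <- c(2, 1, 1, 1, 1, 2)
  td <- build_trajectories(X, labels)
  expect_equal(length(td$traces), 2L)
  expect_equal(td$traces[["s1"]]$states, c(1L, 1L, 2L))  # time-sorted
  expect_equal(td$traces[["s1"]]$time, 1:3)
  expect_error(build_trajectories(X, c(labels[-6], NA)), "missing")
})

test_that("first-order estimates equal direct pair counting", {
  td <- make_dataset(list(rep(1:2, 10)))
  t1 <- fit_markov(td, order = 1)
  expect_equal(unname(t1$prob["1", ]), c(0, 1))
  expect_equal(unname(t1$prob["2", ]), c(1, 0))
  # all self-transitions give the identity matrix
  td2 <- make_dataset(list(rep(1, 8), rep(2, 5), rep(3, 4)))
  t2 <- fit_markov(td2, order = 1, K = 3)
  expect_equal(unname(t2$prob), diag(3))
  # random traces against an independent pair-count oracle
  set.seed(3)
  seqs <- replicate(40, sample.int(3, sample(3:12, 1), replace = TRUE),
                    simplify = FALSE)
  t3 <- fit_markov(make_dataset(seqs), order = 1, K = 3)
  from <- unlist(lapply(seqs, function(s) s[-length(s)]))
  to <- unlist(lapply(seqs, function(s) s[-1]))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(unname(t3$prob[as.character(i), j]),
                 sum(from == i & to == j) / sum(from == i))
  }
  expect_error(fit_markov(make_dataset(list(c(1, 2))), order = 5), "longer")
})

test_that("marginalizing second-order contexts reproduces first order", {
  set.seed(4)
  seqs <- replicate(30, sample.int(3, sample(4:15, 1), replace = TRUE),
                    simplify = FALSE)
  # drop the first element of each trace so both orders see the same windows
  t1 <- fit_markov(make_dataset(lapply(seqs, function(s) s[-1])), 1, K = 3)
  t2 <- fit_markov(make_dataset(seqs), 2, K = 3)
  # sum the order-2 counts over the older state in the context
  agg <- matrix(0, 3, 3, dimnames = dimnames(t1$counts))
  for (ctx in rownames(t2$counts)) {
    last <- as.integer(strsplit(ctx, "|", fixed = TRUE)[[1]][2])
    agg[last, ] <- agg[last, ] + t2$counts[ctx, ]
  }
  expect_equal(agg, t1$counts)
})

test_that("the de Bruijn graph has overlap-consistent valued edges", {
  set.seed(5)
  seqs <- replicate(25, sample.int(2, 10, replace = TRUE), simplify = FALSE)
  died <- setNames(runif(25) < 0.3, paste0("p", 1:25))
  td <- make_dataset(seqs, died = died)
  tn <- fit_markov(td, order = 2, K = 2)
  g <- debruijn_graph(tn, td)
  expect_lte(nrow(g$vertices), 4L)
  expect_lte(nrow(g$edges), 8L)
  for (i in seq_len(nrow(g$edges))) {
    src <- strsplit(g$edges$from[i], "|", fixed = TRUE)[[1]]
    tgt <- strsplit(g$edges$to[i], "|", fixed = TRUE)[[1]]
    expect_equal(src[-1], tgt[-length(tgt)])
  }
  # per-context probabilities sum to one over emitted edges
  for (v in unique(g$edges$from)) {
    expect_equal(sum(g$edges$probability[g$edges$from == v]), 1,
                 tolerance = 1e-12)
  }
  # vertex mortality equals the pass-through rate of the context
  v11 <- g$vertices[g$vertices$context == "1|1", ]
  if (nrow(v11)) {
    has11 <- vapply(seqs, function(s)
      any(s[-length(s)] == 1 & s[-1] == 1), TRUE)
    expect_equal(v11$mortality, mean(died[paste0("p", which(has11))]))
  }
})

test_that("first-order edges carry hand-checkable treatment summaries", {
  td <- make_dataset(list(c(1, 2), c(1, 2)), patient_id = c(`1` = "p1",
                                                            `2` = "p2"))
  treatments <- data.frame(stay_id = c(1, 1, 2, 2), bin = c(1, 2, 1, 2),
                           fluids = c(100, 200, 300, 400),
                           vasopressor = c(0.1, 0.4, 0.2, 0.3),
                           ventilator = c(0, 1, 0, 0))
  tn <- fit_markov(td, order = 1, K = 2)
  g <- debruijn_graph(tn, td, treatments)
  e <- g$edges[g$edges$from == "1" & g$edges$next_state == 2, ]
  expect_equal(e$mean_fluids, mean(c(mean(c(100, 200)), mean(c(300, 400)))))
  expect_equal(e$max_vasopressor, mean(c(0.4, 0.3)))
  expect_equal(e$ventilator_prob, 0.5)
})

test_that("gradient extraction matches direct enumeration", {
  X1 <- matrix(c(0, 0, 1, 0, 1, 2), 3, 2, byrow = TRUE,
               dimnames = list(NULL, c("v1", "v2")))
  td <- make_dataset(list(c(1, 2, 2)), X_by_stay = list(X1))
  gd <- gradient_dataset(td)
  expect_equal(nrow(gd$G), 1L)       # only the 1 -> 2 change
  expect_equal(unname(gd$G[1, ]), c(1, 0))
  expect_equal(gd$from, 1L); expect_equal(gd$to, 2L)
  gd_all <- gradient_dataset(td, include_self = TRUE)
  expect_equal(nrow(gd_all$G), 2L)
  # constant trace yields nothing
  td0 <- make_dataset(list(rep(1, 5)))
  expect_equal(nrow(gradient_dataset(td0)$G), 0L)
  # count oracle on random traces
  set.seed(6)
  seqs <- replicate(20, sample.int(3, 8, replace = TRUE), simplify = FALSE)
  Xs <- lapply(seqs, function(s) matrix(rnorm(length(s) * 2), length(s), 2))
  gd2 <- gradient_dataset(make_dataset(seqs, Xs))
  hand <- sum(vapply(seqs, function(s) sum(diff(s) != 0), 0))
  expect_equal(nrow(gd2$G), hand)
})

test_that("pure gradient directions are recovered as groups with markers", {
  set.seed(7)
  dirs <- rbind(c(4, 0, 0, 0), c(0, 4, 0, 0), c(0, 0, 4, 0))
  # traces engineered so transition (1->2) moves along dirs[1], etc.
  seqs <- list(); Xs <- list()
  for (i in 1:60) {
    kind <- (i - 1) %% 3 + 1
    s <- c(1, 2, 2)
    if (kind == 2) s <- c(1, 3, 3)
    if (kind == 3) s <- c(2, 3, 3)
    X <- matrix(0, 3, 4)
    X[2, ] <- dirs[kind, ]
    X[3, ] <- dirs[kind, ]
    colnames(X) <- paste0("v", 1:4)
    seqs[[i]] <- s; Xs[[i]] <- X
  }
  gd <- gradient_dataset(make_dataset(seqs, Xs))
  gg <- gradient_archetypes(gd, K = 3, seed = 1, max_iter = 300)
  # three groups, each pure in one (from,to) pair
  H <- transition_histogram(gg)
  expect_equal(nrow(H), 3L)
  expect_true(all(abs(rowSums(H) - 1) < 1e-12))
  expect_true(all(apply(H, 1, max) == 1))
  mk <- transition_marker_zscores(gd, gg$groups)
  # each group's dominant component has a positive z
  for (g in 1:3) {
    grp_mean <- colMeans(gd$G[gg$groups == unique(gg$groups)[g], , drop = FALSE])
    j <- which.max(grp_mean)
    expect_gt(mk$z[j, paste0("G", unique(gg$groups)[g])], 0)
  }
})
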