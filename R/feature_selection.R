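#' Per-variable inertia decomposition (Huygens-Steiner)
#'
#' For a partition of observations into clusters, decomposes each
#' variable's total inertia `T_j = sum_i (x_ij - g_j)^2` into
#' inter-cluster inertia `B_j = sum_k n_k (g_kj - g_j)^2` and
#' within-cluster inertia `W_j = sum_k sum_{i in C_k} (x_ij - g_kj)^2`,
#' with `T_j = B_j + W_j` exactly.
#'
#' @param X observation matrix.
#' @param labels cluster label per row (every named cluster nonempty).
#' @return object of class `"inertia_decomposition"`: vectors `T`, `B`,
#'   `W`, matrix `cluster_means`, vector `grand_mean`, `n_k`.
#' @export
inertia_decomposition <- function(X, labels) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_input("X must be finite")
  ks <- sort(unique(labels))
  n_k <- vapply(ks, function(k) sum(labels == k), 0L)
  if (any(n_k == 0L)) stop_input("empty cluster")
  g <- colMeans(X)
  Tj <- colSums(sweep(X, 2L, g, "-")^2)
  G <- do.call(rbind, lapply(ks, function(k)
    colMeans(X[labels == k, , drop = FALSE])))
  Bj <- colSums(n_k * sweep(G, 2L, g, "-")^2)
  Wj <- Tj - Bj
  Wj_direct <- colSums((X - G[match(labels, ks), , drop = FALSE])^2)
  structure(list(T = Tj, B = Bj, W = Wj_direct, W_identity = Wj,
                 cluster_means = G, grand_mean = g, n_k = n_k,
                 clusters = ks),
            class = "inertia_decomposition")
}

#' Variable quality indices from an inertia decomposition
#'
#' `Q_j = B_j / T_j` (the share of variable j's dispersion explained by
#' the clustering, in `[0, 1]`) and `Q'_j = B_j / sum_i B_i` (variable
#' j's share of the total inter-cluster inertia, summing to 1).
#'
#' @param decomp an [inertia_decomposition()].
#' @return data.frame `variable`, `Q`, `Qprime`. Constant variables
#'   (`T_j = 0`) yield `NA` for `Q` with a warning.
#' @export
quality_indices <- function(decomp) {
  Tj <- decomp$T; Bj <- decomp$B
  Q <- ifelse(Tj > 0, Bj / Tj, NA_real_)
  if (any(Tj == 0)) warning("constant variable(s); Q reported missing")
  sB <- sum(Bj)
  Qp <- if (sB > 0) Bj / sB else rep(NA_real_, length(Bj))
  if (sB == 0) warning("no inter-cluster inertia; Q' reported missing")
  data.frame(variable = names(Tj) %||% paste0("V", seq_along(Tj)),
             Q = unname(Q), Qprime = unname(Qp))
}

#' Variation test for cluster-separating features
#'
#' Feature `j` is selected when at least `min_pairs` unordered cluster
#' pairs `(i, l)` exhibit a mean difference at `j` exceeding a threshold
#' `theta` with probability at least `1 - delta` under the normal
#' approximation of the sampled mean difference:
#' `|D| > theta` where `D ~ N(mean_i - mean_l, s_i^2/n_i + s_l^2/n_l)`.
#' The threshold is `theta = sigma_ij` (the SD of feature `j` in cluster
#' `i`); both orderings of a pair are evaluated and either sufficing
#' counts the pair once.
#'
#' @param X observation matrix.
#' @param labels cluster label per row.
#' @param delta significance level (default 0.05).
#' @param min_pairs minimum number of qualifying cluster pairs
#'   (default 2).
#' @return logical vector per feature with attribute `pair_counts`
#'   (qualifying pair count per feature).
#' @export
variation_test <- function(X, labels, delta = 0.05, min_pairs = 2L) {
  X <- as.matrix(X)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop_input("need at least two clusters")
  mlist <- lapply(ks, function(k) X[labels == k, , drop = FALSE])
  ns <- vapply(mlist, nrow, 0L)
  mu <- lapply(mlist, colMeans)
  sdv <- lapply(mlist, function(Mk) apply(Mk, 2L, stats::sd))
  p_exceeds <- function(i, l, theta) {
    d <- mu[[i]] - mu[[l]]
    se <- sqrt(sdv[[i]]^2 / ns[i] + sdv[[l]]^2 / ns[l])
    se[se == 0] <- .Machine$double.eps
    stats::pnorm((-theta - d) / se) + stats::pnorm((theta - d) / se,
                                                   lower.tail = FALSE)
  }
  nfeat <- ncol(X)
  counts <- integer(nfeat)
  for (i in seq_along(ks)[-length(ks)]) {
    for (l in (i + 1L):length(ks)) {
      if (ns[i] < 2L || ns[l] < 2L) {
        warning("cluster of size 1; pair skipped")
        next
      }
      ok <- p_exceeds(i, l, sdv[[i]]) >= 1 - delta |
            p_exceeds(l, i, sdv[[l]]) >= 1 - delta
      counts <- counts + as.integer(ok)
    }
  }
  sel <- counts >= min_pairs
  names(sel) <- colnames(X) %||% paste0("V", seq_len(nfeat))
  attr(sel, "pair_counts") <- counts
  sel
}

#' Rank features and assign overlap tiers
#'
#' Combines the three selectors: top-`k` by `Q_j`, top-`k` by `Q'_j`, and
#' the variation-test set. Each feature's tier is the number of methods
#' (0-3) that selected it.
#'
#' @param X observation matrix.
#' @param labels cluster label per row.
#' @param k list size for the quality indices (default 15; clamped to the
#'   feature count with a warning).
#' @param delta,min_pairs passed to [variation_test()].
#' @return object of class `"feature_ranking"`: data.frame `table`
#'   (variable, Q, Qprime, variation_selected, tier) plus the top-k sets.
#' @export
rank_and_tier <- function(X, labels, k = 15L, delta = 0.05, min_pairs = 2L) {
  X <- as.matrix(X)
  if (k > ncol(X)) {
    warning("k exceeds feature count; clamped")
    k <- ncol(X)
  }
  dec <- inertia_decomposition(X, labels)
  qi <- quality_indices(dec)
  vt <- variation_test(X, labels, delta = delta, min_pairs = min_pairs)
  top_Q <- qi$variable[order(-qi$Q)][seq_len(k)]
  top_Qp <- qi$variable[order(-qi$Qprime)][seq_len(k)]
  tier <- (qi$variable %in% top_Q) + (qi$variable %in% top_Qp) +
          unname(vt[qi$variable])
  tab <- data.frame(variable = qi$variable, Q = qi$Q, Qprime = qi$Qprime,
                    variation_selected = unname(vt[qi$variable]),
                    tier = tier)
  tab <- tab[order(-tab$tier, -tab$Q), ]
  rownames(tab) <- NULL
  structure(list(table = tab, top_Q = top_Q, top_Qprime = top_Qp,
                 variation_set = names(vt)[vt], k = k),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  n3 <- sum(x$table$tier == 3); n2 <- sum(x$table$tier == 2)
  n1 <- sum(x$table$tier == 1)
  cat("Feature ranking: ", n3, " features selected by all three methods, ",
      n2, " by two, ", n1, " by one\n", sep = "")
  print(utils::head(x$table, 10), ...)
  invisible(x)
}
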