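#' Fit archetypes by alternating simplex-constrained least squares
#'
#' Finds `K` archetypes `Z = beta %*% X` (each archetype a convex
#' combination of data points) and per-observation convex coefficients
#' `alpha` (rows on the simplex) minimizing the residual sum of squares
#' `||X - alpha beta X||_F^2`. Each half-step solves a simplex-constrained
#' least-squares problem by projected-gradient descent with backtracking
#' (the objective is nonincreasing at every iteration); at convergence the
#' coefficients are polished by exact penalized non-negative least
#' squares. Initialization uses a furthest-sum heuristic over data points,
#' plus random restarts.
#'
#' @param X numeric matrix, observations in rows (`n >= K`).
#' @param K number of archetypes.
#' @param max_iter maximum alternating iterations (default 1000).
#' @param n_restarts number of initializations; the best fit is returned.
#' @param seed optional integer seed for the restart draws.
#' @param tol relative objective-decrease tolerance for convergence.
#' @param standardize z-score the columns before fitting (parameters are
#'   stored and used by [project_alpha()]).
#' @return object of class `"archetype_model"`: `Z` (K x m), `alpha`
#'   (n x K), `beta` (K x n), `rss`, `n_iter`, `converged`,
#'   `objective_path`, `center`, `scale`.
#' @examples
#' X <- rbind(c(0, 0), c(1, 0), c(0, 1))
#' fit <- fit_archetypes(X, K = 3, seed = 1)
#' fit$rss  # ~0: the three vertices reproduce the data exactly
#' @export
fit_archetypes <- function(X, K, max_iter = 1000L, n_restarts = 1L,
                           seed = NULL, tol = 1e-8, standardize = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_input("X must be finite")
  n <- nrow(X)
  if (K > n) stop_input("K must not exceed the number of observations")
  if (K < 1L) stop_input("K must be >= 1")
  center <- scale_ <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    X <- sweep(sweep(X, 2L, center, "-"), 2L, scale_, "/")
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) furthest_sum_init(X, K) else
      sample.int(n, K)
    fit <- aa_solve(X, K, init, max_iter, tol)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  best$center <- center
  best$scale <- scale_
  best$K <- K
  class(best) <- "archetype_model"
  best
}

#' @export
print.archetype_model <- function(x, ...) {
  cat("Archetype model: K =", x$K, ", rss =", format(x$rss, digits = 6),
      ",", x$n_iter, "iterations",
      if (isTRUE(x$converged)) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

furthest_sum_init <- function(X, K) {
  n <- nrow(X)
  mu <- colMeans(X)
  d0 <- rowSums(sweep(X, 2L, mu, "-")^2)
  idx <- which.max(d0)
  if (K > 1L) {
    dsum <- rep(0, n)
    for (k in 2L:K) {
      last <- X[idx[k - 1L], ]
      dsum <- dsum + sqrt(rowSums(sweep(X, 2L, last, "-")^2))
      cand <- dsum
      cand[idx] <- -Inf
      idx <- c(idx, which.max(cand))
    }
  }
  idx
}

aa_objective <- function(X, A, BX) sum((X - A %*% BX)^2)

aa_solve <- function(X, K, init_idx, max_iter, tol) {
  n <- nrow(X)
  B <- matrix(0, K, n)
  B[cbind(seq_len(K), init_idx)] <- 1
  Z <- B %*% X
  A <- exact_alpha(X, Z)
  f <- aa_objective(X, A, Z)
  path <- f
  mu_a <- 1; mu_b <- 1e-3
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    f_prev <- f
    # alpha half-step: projected gradient with backtracking
    R <- A %*% Z - X
    G <- R %*% t(Z)
    repeat {
      A_new <- project_simplex_rows(A - mu_a * G)
      f_new <- aa_objective(X, A_new, Z)
      if (f_new <= f || mu_a < 1e-14) break
      mu_a <- mu_a / 2
    }
    if (f_new <= f) { A <- A_new; f <- f_new; mu_a <- mu_a * 1.2 }
    # beta half-step
    R <- A %*% Z - X
    G <- crossprod(A, R) %*% t(X)
    repeat {
      B_new <- project_simplex_rows(B - mu_b * G)
      Z_new <- B_new %*% X
      f_new <- aa_objective(X, A, Z_new)
      if (f_new <= f || mu_b < 1e-18) break
      mu_b <- mu_b / 2
    }
    if (f_new <= f) { B <- B_new; Z <- Z_new; f <- f_new; mu_b <- mu_b * 1.2 }
    path <- c(path, f)
    if (f_prev - f <= tol * max(1, f_prev)) { converged <- TRUE; break }
  }
  A <- exact_alpha(X, Z)
  f <- aa_objective(X, A, Z)
  path <- c(path, f)
  structure(list(Z = Z, alpha = A, beta = B, rss = f, n_iter = iter,
                 converged = converged, objective_path = path), class = "list")
}

exact_alpha <- function(X, Z) {
  At <- t(Z)
  A <- t(apply(X, 1L, function(x) simplex_lsq(At, x)))
  if (nrow(Z) == 1L) A <- matrix(A, ncol = 1L)
  A
}

#' Project new observations onto fixed archetypes
#'
#' Per-row simplex-constrained least squares of `X_new` against a fitted
#' archetype matrix (training standardization applied when the model
#' carries it).
#'
#' @param X_new matrix of new observations (original scale if the model
#'   was fitted with `standardize = TRUE`).
#' @param model an `"archetype_model"`, or a bare `K x m` archetype
#'   matrix.
#' @return `nrow(X_new) x K` matrix of simplex coefficients.
#' @export
project_alpha <- function(X_new, model) {
  if (inherits(model, "archetype_model")) {
    Z <- model$Z
    if (!is.null(model$center)) {
      X_new <- sweep(sweep(X_new, 2L, model$center, "-"), 2L, model$scale, "/")
    }
  } else {
    Z <- as.matrix(model)
  }
  if (ncol(X_new) != ncol(Z)) stop_input("dimension mismatch: X_new has ",
    ncol(X_new), " columns, archetypes have ", ncol(Z))
  exact_alpha(as.matrix(X_new), Z)
}

#' Assign each observation to its dominant archetype
#'
#' The state label is the index of the largest convex coefficient; exact
#' ties resolve to the lowest index (tied rows are reported in the
#' `"ties"` attribute).
#'
#' @param alpha an `"archetype_model"` or a coefficient matrix.
#' @return integer label vector with attribute `ties`.
#' @export
assign_state <- function(alpha) {
  if (inherits(alpha, "archetype_model")) alpha <- alpha$alpha
  lab <- max.col(alpha, ties.method = "first")
  mx <- alpha[cbind(seq_len(nrow(alpha)), lab)]
  ties <- which(rowSums(alpha == mx) > 1L)
  attr(lab, "ties") <- ties
  lab
}

#' Choose the number of archetypes by the elbow rule
#'
#' Fits every `K` in `K_range`, records the residual Frobenius norm, and
#' picks the `K` maximizing the perpendicular distance to the chord
#' joining the curve endpoints (both axes min-max normalized first). If
#' the curve is exactly linear (all distances ~0) the smallest `K` is
#' returned with a warning.
#'
#' @param X observation matrix.
#' @param K_range increasing integer vector of candidate K.
#' @param ... solver parameters passed to [fit_archetypes()].
#' @return object of class `"elbow_curve"`: `K`, `rss` (residual
#'   Frobenius norms), `chosen_K`, `models`.
#' @export
select_K_elbow <- function(X, K_range, ...) {
  K_range <- sort(unique(as.integer(K_range)))
  if (!length(K_range)) stop_input("K_range must be nonempty")
  models <- lapply(K_range, function(K) fit_archetypes(X, K, ...))
  rss <- vapply(models, function(mdl) sqrt(mdl$rss), 0)
  chosen <- elbow_point(K_range, rss)
  if (is.na(chosen)) {
    warning("residual curve has no elbow; returning smallest K")
    chosen <- K_range[1L]
  }
  structure(list(K = K_range, rss = rss, chosen_K = chosen, models = models),
            class = "elbow_curve")
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat("Elbow curve over K =", paste(x$K, collapse = ", "),
      "; chosen K =", x$chosen_K, "\n")
  invisible(x)
}

elbow_point <- function(K, rss) {
  if (length(K) == 1L) return(K)
  xs <- (K - K[1L]) / max(K[length(K)] - K[1L], 1)
  rng <- max(rss) - min(rss)
  ys <- if (rng > 0) (rss - min(rss)) / rng else rss * 0
  x1 <- c(xs[1L], ys[1L]); x2 <- c(xs[length(xs)], ys[length(ys)])
  v <- x2 - x1
  v <- v / sqrt(sum(v^2))
  d2 <- vapply(seq_along(xs), function(i) {
    w <- c(xs[i], ys[i]) - x1
    max(sum(w^2) - sum(w * v)^2, 0)
  }, 0)
  if (max(d2) <= 1e-12) return(NA_integer_)
  K[which.max(d2)]
}

#' Train/test generalizability protocol for archetypes
#'
#' Reference archetypes are fitted on the full data and every observation
#' is labeled by its dominant coefficient. For each repetition the data
#' are split into a training part (default 90%) and a test part; archetypes
#' refitted on the training part are matched to the reference by
#' minimum-cost assignment on Euclidean distances, and the protocol
#' reports (i) the summed per-archetype relative error
#' `sum_k ||A_k - A_k^train|| / ||A_k||`, (ii) the test-set assignment
#' accuracy of training-archetype projection against the reference labels,
#' and (iii) absolute per-state errors of mean SOFA, mean SIRS and
#' pass-through mortality on the test set (when those inputs are given).
#'
#' @param X observation matrix.
#' @param split_fraction training fraction (default 0.9).
#' @param n_repetitions number of random splits (default 20).
#' @param K number of archetypes.
#' @param seed integer seed controlling splits and restarts.
#' @param sofa,sirs optional numeric per-row severity scores.
#' @param patient optional per-row patient id, `died` a named logical per
#'   patient; both needed for the mortality error.
#' @param reference optional prefitted `"archetype_model"` on the full
#'   data (refitted when `NULL`).
#' @param ... solver parameters passed to [fit_archetypes()].
#' @return object of class `"generalizability_report"`: per-repetition
#'   data.frame `reps` and the averages `relative_error`, `accuracy`,
#'   `sofa_error`, `sirs_error`, `mortality_error`.
#' @export
evaluate_generalizability <- function(X, K, split_fraction = 0.9,
                                      n_repetitions = 20L, seed = 1L,
                                      sofa = NULL, sirs = NULL,
                                      patient = NULL, died = NULL,
                                      reference = NULL, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (floor(n * (1 - split_fraction)) < 1L)
    stop_input("test set would be empty")
  set.seed(seed)
  if (is.null(reference)) reference <- fit_archetypes(X, K, ...)
  if (is.null(reference)) stop_input("reference fit failed")
  ref_labels <- assign_state(reference)
  reps <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    train <- sort(sample.int(n, round(n * split_fraction)))
    test <- setdiff(seq_len(n), train)
    fit <- fit_archetypes(X[train, , drop = FALSE], K, ...)
    perm <- match_archetypes(fit$Z, reference$Z)
    Ztr <- fit$Z[perm, , drop = FALSE]
    rel_err <- sum(sqrt(rowSums((reference$Z - Ztr)^2)) /
                   sqrt(rowSums(reference$Z^2)))
    a_test <- project_alpha(X[test, , drop = FALSE], Ztr)
    lab_test <- assign_state(a_test)
    acc <- mean(lab_test == ref_labels[test])
    sofa_err <- sirs_err <- mort_err <- NA_real_
    if (!is.null(sofa))
      sofa_err <- per_state_abs_err(sofa[test], ref_labels[test], lab_test, K)
    if (!is.null(sirs))
      sirs_err <- per_state_abs_err(sirs[test], ref_labels[test], lab_test, K)
    if (!is.null(patient) && !is.null(died)) {
      m_ref <- per_state_mortality_rows(ref_labels[test], patient[test], died, K)
      m_tr <- per_state_mortality_rows(lab_test, patient[test], died, K)
      mort_err <- mean(abs(m_ref - m_tr), na.rm = TRUE)
    }
    reps[[r]] <- data.frame(rep = r, relative_error = rel_err, accuracy = acc,
                            sofa_error = sofa_err, sirs_error = sirs_err,
                            mortality_error = mort_err)
  }
  reps <- do.call(rbind, reps)
  structure(list(reps = reps,
                 relative_error = mean(reps$relative_error),
                 accuracy = mean(reps$accuracy),
                 sofa_error = mean(reps$sofa_error),
                 sirs_error = mean(reps$sirs_error),
                 mortality_error = mean(reps$mortality_error)),
            class = "generalizability_report")
}

#' @export
print.generalizability_report <- function(x, ...) {
  cat(sprintf(paste0("Generalizability over %d repetitions: relative error ",
                     "%.4f, accuracy %.2f%%\n"),
              nrow(x$reps), x$relative_error, 100 * x$accuracy))
  invisible(x)
}

per_state_abs_err <- function(v, lab_ref, lab_new, K) {
  errs <- vapply(seq_len(K), function(k) {
    a <- mean(v[lab_ref == k]); b <- mean(v[lab_new == k])
    abs(a - b)
  }, 0)
  mean(errs, na.rm = TRUE)
}

per_state_mortality_rows <- function(labels, patient, died, K) {
  vapply(seq_len(K), function(k) {
    p <- unique(as.character(patient[labels == k]))
    if (!length(p)) return(NA_real_)
    mean(died[p])
  }, 0)
}
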