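#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

#' Project rows of a matrix onto the probability simplex
#'
#' Euclidean projection of each row onto \{w : w >= 0, sum(w) = 1\} using the
#' sort-and-threshold algorithm.
#'
#' @param W numeric matrix (rows are projected independently).
#' @return matrix of the same shape with rows on the simplex.
#' @keywords internal
project_simplex_rows <- function(W) {
  n <- nrow(W); K <- ncol(W)
  if (K == 1L) return(matrix(1, n, 1L))
  if (K > 32L) {
    # few long rows (e.g. beta over data points): per-row projection
    return(t(apply(W, 1L, proj_simplex_vec)))
  }
  # row-wise decreasing sort and cumulative sums, fully vectorized
  U <- matrix(W[order(row(W), -W)], n, K, byrow = TRUE)
  css <- U %*% upper.tri(diag(K), diag = TRUE)
  j <- matrix(seq_len(K), n, K, byrow = TRUE)
  rho <- rowSums(U + (1 - css) / j > 0)
  theta <- (1 - css[cbind(seq_len(n), rho)]) / rho
  pmax(W + theta, 0)
}

proj_simplex_vec <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  pmax(v + (1 - css[rho]) / rho, 0)
}

#' Dirichlet sampler
#' @keywords internal
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

#' Simplex-constrained least squares
#'
#' Solves min ||y - A w||^2 subject to w >= 0, sum(w) = 1 exactly by a
#' primal active-set method on the equivalent quadratic program (KKT
#' system solved on the current support; indices enter on negative
#' reduced cost and leave at the boundary). Intended for small K (the
#' number of archetypes).
#'
#' @param A numeric matrix (d x K).
#' @param y numeric vector length d.
#' @param tol numerical tolerance.
#' @return weight vector of length K on the simplex.
#' @keywords internal
simplex_lsq <- function(A, y, tol = 1e-10) {
  K <- ncol(A)
  if (K == 1L) return(1)
  G <- crossprod(A)
  cc <- drop(crossprod(A, y))
  scal <- max(diag(G), 1)
  w <- rep(1 / K, K)
  S <- seq_len(K)
  solve_S <- function(S) {
    nS <- length(S)
    Kmat <- rbind(cbind(G[S, S, drop = FALSE], 1), c(rep(1, nS), 0))
    rhs <- c(cc[S], 1)
    sol <- tryCatch(solve(Kmat, rhs), error = function(e) {
      Kmat[seq_len(nS), seq_len(nS)] <-
        Kmat[seq_len(nS), seq_len(nS)] + diag(1e-10 * scal, nS)
      solve(Kmat, rhs)
    })
    list(w = sol[seq_len(nS)], lambda = sol[nS + 1L])
  }
  for (it in seq_len(100L * K)) {
    sol <- solve_S(S)
    wS <- sol$w
    if (all(wS >= -tol)) {
      w[] <- 0
      w[S] <- pmax(wS, 0)
      grad <- drop(G %*% w) - cc
      mu <- grad + sol$lambda
      outside <- setdiff(seq_len(K), S)
      if (!length(outside) || min(mu[outside]) >= -tol * scal) break
      S <- sort(c(S, outside[which.min(mu[outside])]))
    } else {
      # partial step to the boundary, drop the blocking index
      cur <- w[S]
      d <- wS - cur
      bad <- which(wS < -tol)
      alpha <- min(cur[bad] / (cur[bad] - wS[bad]))
      w[] <- 0
      w[S] <- pmax(cur + alpha * d, 0)
      S <- S[w[S] > tol]
      if (!length(S)) { S <- which.max(cc); w[] <- 0; w[S] <- 1 }
    }
  }
  w / sum(w)
}

#' Exact minimum-cost archetype matching
#'
#' Matches rows of `Zhat` to rows of `Zref` minimizing the total Euclidean
#' distance. Exact (permutation enumeration) for K <= 8, greedy otherwise.
#'
#' @param Zhat,Zref K x m matrices.
#' @return integer permutation `p` such that `Zhat[p[k], ]` matches
#'   `Zref[k, ]`.
#' @keywords internal
match_archetypes <- function(Zhat, Zref) {
  K <- nrow(Zref)
  D <- as.matrix(stats::dist(rbind(Zref, Zhat)))[seq_len(K), K + seq_len(K), drop = FALSE]
  if (K <= 8L) {
    perms <- permutations_all(K)
    costs <- apply(perms, 1L, function(p) sum(D[cbind(seq_len(K), p)]))
    perms[which.min(costs), ]
  } else {
    p <- integer(K)
    used <- rep(FALSE, K)
    for (k in order(apply(D, 1L, min))) {
      j <- which.min(replace(D[k, ], used, Inf))
      p[k] <- j
      used[j] <- TRUE
    }
    p
  }
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  out
}
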