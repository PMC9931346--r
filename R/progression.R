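#' Build per-stay trajectories
#'
#' One trace per stay: time-ordered (bin time, clinical vector, state
#' label) triples plus the patient's outcome.
#'
#' @param X pooled observation matrix with `stay`/`bin` attributes (see
#'   [grid_matrix()]), or a plain matrix with `stay` and `bin` given.
#' @param labels integer state label per row.
#' @param stay,bin row provenance (default from attributes of `X`).
#' @param patient_id named map stay -> patient (optional).
#' @param died named logical per patient (optional).
#' @return object of class `"trajectory_dataset"`: list `traces` (per
#'   stay: `time`, `X`, `states`), `patient_id`, `died`.
#' @export
build_trajectories <- function(X, labels, stay = attr(X, "stay"),
                               bin = attr(X, "bin"), patient_id = NULL,
                               died = NULL) {
  if (is.null(stay) || is.null(bin))
    stop_input("stay/bin provenance required")
  if (anyNA(labels)) stop_input("missing state label")
  stays <- unique(stay)
  traces <- lapply(stays, function(s) {
    rows <- which(stay == s)
    rows <- rows[order(bin[rows])]
    list(time = bin[rows], X = X[rows, , drop = FALSE],
         states = as.integer(labels[rows]))
  })
  names(traces) <- as.character(stays)
  keep <- lengths(lapply(traces, `[[`, "states")) > 0L
  if (any(!keep)) warning("empty stay(s) excluded")
  structure(list(traces = traces[keep], patient_id = patient_id,
                 died = died), class = "trajectory_dataset")
}

#' Maximum-likelihood l-th order Markov transition estimates
#'
#' Conditional next-state frequencies per length-`l` context (oldest
#' state first). Contexts never observed carry zero counts and `NA`
#' probabilities (no smoothing by default; add-lambda smoothing optional
#' for downstream simulation).
#'
#' @param dataset a `"trajectory_dataset"` (or list of integer state
#'   vectors).
#' @param order chain order `l >= 1`.
#' @param K number of states (default: maximum observed).
#' @param smoothing add-lambda smoothing constant (default 0 = none).
#' @return object of class `"transition_tensor"`: `prob` and `counts`
#'   (`K^l x K` matrices, context row names `"s1|...|sl"`), `order`, `K`.
#' @export
fit_markov <- function(dataset, order = 1L, K = NULL, smoothing = 0) {
  seqs <- if (inherits(dataset, "trajectory_dataset"))
    lapply(dataset$traces, `[[`, "states") else dataset
  if (order < 1L) stop_input("order must be >= 1")
  if (is.null(K)) K <- max(unlist(seqs))
  if (!any(lengths(seqs) > order))
    stop_input("no trace longer than the chain order")
  ctx <- all_contexts(K, order)
  counts <- matrix(0, length(ctx), K, dimnames = list(ctx, seq_len(K)))
  for (s in seqs) {
    n <- length(s)
    if (n <= order) next
    for (t in (order + 1L):n) {
      counts[context_key(s[(t - order):(t - 1L)]), s[t]] <-
        counts[context_key(s[(t - order):(t - 1L)]), s[t]] + 1
    }
  }
  tot <- rowSums(counts) + K * smoothing
  prob <- (counts + smoothing) / tot
  prob[tot == 0, ] <- NA_real_
  structure(list(prob = prob, counts = counts, order = as.integer(order),
                 K = as.integer(K)), class = "transition_tensor")
}

#' @export
print.transition_tensor <- function(x, ...) {
  cat("Order-", x$order, " Markov transition tensor over ", x$K,
      " states (", sum(rowSums(x$counts) > 0), "/", nrow(x$prob),
      " contexts observed)\n", sep = "")
  invisible(x)
}

#' Valued de Bruijn transition graph
#'
#' Vertices are the observed length-`l` state contexts; each edge
#' `(s1,...,sl) -> (s2,...,sl,j)` carries the estimated transition
#' probability (source suffix and target prefix overlap in `l-1`
#' states). Each vertex carries the pass-through mortality among
#' patients whose trace contains the context (each patient counted
#' once). For first-order graphs each edge additionally carries treatment
#' summaries over the transitions realizing it: mean fluid volume, mean
#' per-transition maximum vasopressor dose, and ventilator-use
#' probability.
#'
#' @param tensor a `"transition_tensor"`.
#' @param dataset a `"trajectory_dataset"` with `patient_id` and `died`
#'   set (for mortality; optional).
#' @param treatments optional data.frame `stay_id`, `bin`, `fluids`,
#'   `vasopressor`, `ventilator` (used when `tensor$order == 1`).
#' @return object of class `"debruijn_graph"`: `graph` (igraph),
#'   `vertices` data.frame (context, n_patients, mortality), `edges`
#'   data.frame (from, to, probability, count, and treatment columns for
#'   `l = 1`).
#' @export
debruijn_graph <- function(tensor, dataset = NULL, treatments = NULL) {
  l <- tensor$order; K <- tensor$K
  observed <- rownames(tensor$prob)[rowSums(tensor$counts) > 0]
  edges <- NULL
  for (v in observed) {
    s <- as.integer(strsplit(v, "|", fixed = TRUE)[[1L]])
    for (j in seq_len(K)) {
      if (tensor$counts[v, j] > 0) {
        tgt <- context_key(c(s[-1L], j))
        edges <- rbind(edges, data.frame(
          from = v, to = tgt, next_state = j,
          probability = tensor$prob[v, j],
          count = tensor$counts[v, j]))
      }
    }
  }
  verts <- unique(c(observed, edges$to))
  vert_df <- data.frame(context = verts, n_patients = NA_integer_,
                        mortality = NA_real_)
  if (!is.null(dataset) && !is.null(dataset$patient_id) &&
      !is.null(dataset$died)) {
    pat_by_ctx <- stats::setNames(vector("list", length(verts)), verts)
    for (nm in names(dataset$traces)) {
      s <- dataset$traces[[nm]]$states
      p <- as.character(dataset$patient_id[[nm]])
      n <- length(s)
      if (n < l) next
      for (t in seq_len(n - l + 1L)) {
        ctx <- context_key(s[t:(t + l - 1L)])
        if (ctx %in% verts)
          pat_by_ctx[[ctx]] <- union(pat_by_ctx[[ctx]], p)
      }
    }
    vert_df$n_patients <- vapply(pat_by_ctx[verts], length, 0L)
    vert_df$mortality <- vapply(pat_by_ctx[verts], function(p)
      if (length(p)) mean(dataset$died[p]) else NA_real_, 0)
  }
  if (l == 1L && !is.null(treatments) && !is.null(dataset)) {
    tr_key <- paste(treatments$stay_id, treatments$bin)
    agg <- list()
    for (nm in names(dataset$traces)) {
      tra <- dataset$traces[[nm]]
      n <- length(tra$states)
      if (n < 2L) next
      for (t in seq_len(n - 1L)) {
        ekey <- paste(tra$states[t], tra$states[t + 1L], sep = "->")
        rows <- match(paste(nm, tra$time[c(t, t + 1L)]), tr_key)
        rows <- rows[!is.na(rows)]
        if (!length(rows)) next
        agg[[ekey]] <- rbind(agg[[ekey]], data.frame(
          fluids = mean(treatments$fluids[rows]),
          vaso_max = max(treatments$vasopressor[rows]),
          vent = as.integer(any(treatments$ventilator[rows] > 0))))
      }
    }
    ekeys <- paste(edges$from, edges$next_state, sep = "->")
    edges$mean_fluids <- vapply(ekeys, function(k)
      if (!is.null(agg[[k]])) mean(agg[[k]]$fluids) else NA_real_, 0)
    edges$max_vasopressor <- vapply(ekeys, function(k)
      if (!is.null(agg[[k]])) mean(agg[[k]]$vaso_max) else NA_real_, 0)
    edges$ventilator_prob <- vapply(ekeys, function(k)
      if (!is.null(agg[[k]])) mean(agg[[k]]$vent) else NA_real_, 0)
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vert_df)
  structure(list(graph = g, vertices = vert_df, edges = edges,
                 order = l, K = K), class = "debruijn_graph")
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat("de Bruijn graph B(", x$K, ",", x$order, "): ",
      nrow(x$vertices), " vertices, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Export a de Bruijn graph
#'
#' @param graph a `"debruijn_graph"`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return invisibly, `path`.
#' @export
write_debruijn <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(graph$graph, path, format = format)
  invisible(path)
}

#' Gradients of clinical measurements at state transitions
#'
#' For each consecutive pair of points in each trace with a state change
#' (self-transitions optional), the gradient is the difference of the two
#' standardized clinical vectors, labeled with its (from, to) states.
#'
#' @param dataset a `"trajectory_dataset"` whose `X` blocks are on the
#'   standardized scale.
#' @param include_self include self-transitions (default `FALSE`).
#' @return object of class `"gradient_dataset"`: `G` (gradient matrix),
#'   `from`, `to`, `stay`.
#' @export
gradient_dataset <- function(dataset, include_self = FALSE) {
  Gs <- list(); from <- to <- integer(0); stay <- character(0)
  for (nm in names(dataset$traces)) {
    tra <- dataset$traces[[nm]]
    n <- length(tra$states)
    if (n < 2L) next
    for (t in seq_len(n - 1L)) {
      if (!include_self && tra$states[t] == tra$states[t + 1L]) next
      Gs[[length(Gs) + 1L]] <- tra$X[t + 1L, ] - tra$X[t, ]
      from <- c(from, tra$states[t])
      to <- c(to, tra$states[t + 1L])
      stay <- c(stay, nm)
    }
  }
  G <- if (length(Gs)) do.call(rbind, Gs) else
    matrix(0, 0L, ncol(dataset$traces[[1L]]$X))
  structure(list(G = G, from = from, to = to, stay = stay),
            class = "gradient_dataset")
}

#' Archetypes of state-transition gradients
#'
#' Fits archetypes to the gradient rows (reusing the archetype solver)
#' and labels each gradient with its dominant archetype, defining the
#' gradient groups G1..GK. `K` may be a single value or a range for
#' elbow selection.
#'
#' @param gradients a `"gradient_dataset"`.
#' @param K number of gradient archetypes, or a range for
#'   [select_K_elbow()].
#' @param ... solver parameters for [fit_archetypes()].
#' @return object of class `"gradient_groups"`: `model`, `groups`
#'   (label per gradient), `K`, plus `elbow` when a range was given.
#' @export
gradient_archetypes <- function(gradients, K, ...) {
  G <- gradients$G
  if (nrow(G) < max(K)) stop_input("fewer gradients than archetypes")
  elbow <- NULL
  if (length(K) > 1L) {
    elbow <- select_K_elbow(G, K, ...)
    model <- elbow$models[[match(elbow$chosen_K, elbow$K)]]
    K <- elbow$chosen_K
  } else {
    model <- fit_archetypes(G, K, ...)
  }
  groups <- assign_state(model)
  structure(list(model = model, groups = as.integer(groups), K = K,
                 elbow = elbow, from = gradients$from, to = gradients$to),
            class = "gradient_groups")
}

#' Transition-marker z-scores of gradient groups
#'
#' For gradient component `j` and group `i`:
#' `z_ji = (mu_ji - mu_j) / sigma_j` with `mu_j`/`sigma_j` the
#' population mean/SD of the component over all gradients and `mu_ji`
#' the group mean. P-values from two-sample t tests of each group
#' against the population per component.
#'
#' @param gradients a `"gradient_dataset"`.
#' @param groups integer group label per gradient (e.g. from
#'   [gradient_archetypes()]).
#' @return list with matrices `z` and `p` (components x groups).
#' @export
transition_marker_zscores <- function(gradients, groups) {
  G <- gradients$G
  ks <- sort(unique(groups))
  mu <- colMeans(G)
  sigma <- sqrt(colMeans(sweep(G, 2L, mu, "-")^2))
  z <- p <- matrix(NA_real_, ncol(G), length(ks),
                   dimnames = list(colnames(G), paste0("G", ks)))
  for (i in seq_along(ks)) {
    sub <- G[groups == ks[i], , drop = FALSE]
    z[, i] <- ifelse(sigma > 0, (colMeans(sub) - mu) / sigma, NA_real_)
    if (nrow(sub) >= 2L) {
      for (j in seq_len(ncol(G))) {
        p[j, i] <- tryCatch(stats::t.test(sub[, j], G[, j])$p.value,
                            error = function(e) NA_real_)
      }
    }
  }
  list(z = z, p = p)
}

#' Per-group transition histograms
#'
#' Empirical distribution of (from, to) state pairs within each gradient
#' group; each group's histogram sums to 1.
#'
#' @param groups a `"gradient_groups"` (or an integer label vector with
#'   `from`/`to` supplied).
#' @param from,to transition endpoints per gradient.
#' @return matrix (groups x observed transition pairs), rows summing
#'   to 1.
#' @export
transition_histogram <- function(groups, from = NULL, to = NULL) {
  if (inherits(groups, "gradient_groups")) {
    from <- groups$from; to <- groups$to; groups <- groups$groups
  }
  pair <- paste(from, to, sep = "->")
  ks <- sort(unique(groups))
  pairs <- sort(unique(pair))
  H <- matrix(0, length(ks), length(pairs),
              dimnames = list(paste0("G", ks), pairs))
  for (i in seq_along(ks)) {
    tab <- table(pair[groups == ks[i]])
    H[i, names(tab)] <- as.numeric(tab) / sum(tab)
  }
  H
}
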