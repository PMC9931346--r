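#' Remove implausible measurements
#'
#' Drops events whose value lies outside the variable's plausibility
#' bounds (for example weight above 300 kg, or negative blood pressures),
#' and logs the removal count per variable.
#'
#' @param events long-format data.frame `stay_id`, `time_hours`,
#'   `variable`, `value`.
#' @param catalog a [variable_catalog()].
#' @return the filtered events, with attribute `"removed"` (named count
#'   per variable).
#' @export
filter_outliers <- function(events, catalog) {
  idx <- match(events$variable, catalog$name)
  if (anyNA(idx))
    stop_input("unknown variable(s): ",
               paste(unique(events$variable[is.na(idx)]), collapse = ", "))
  lo <- ifelse(is.na(catalog$plausible_low[idx]), -Inf, catalog$plausible_low[idx])
  hi <- ifelse(is.na(catalog$plausible_high[idx]), Inf, catalog$plausible_high[idx])
  bad <- events$value < lo | events$value > hi
  removed <- table(factor(events$variable[bad], levels = catalog$name))
  out <- events[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(removed)
  out
}

#' Assign events to 4-hour bins around onset
#'
#' Events are placed into half-open 4-hour bins covering the peri-onset
#' window from 24 h before to 48 h after onset (18 bins; onset sits at the
#' left edge of bin 7). Within a bin, multiple measurements of the same
#' variable are aggregated by the catalog rule: vitals are averaged,
#' vasopressor-like variables take the maximum, fluid/urine volumes
#' accumulate, demographics keep the latest value. Events outside the
#' window are dropped; empty bins are masked missing.
#'
#' @param events long-format events (see [filter_outliers()]).
#' @param onset named numeric vector of onset hours, names are stay ids.
#' @param catalog a [variable_catalog()].
#' @param bins number of bins (default 18).
#' @param window_start hours relative to onset at which bin 1 starts
#'   (default -24).
#' @return object of class `"cohort_grid"`: list with `values`
#'   (stay x bin x variable array, `NA` where missing), `mask` (logical
#'   array, `TRUE` where observed), `stay_ids`, `onset`, `bin_hours`.
#' @export
bin_events <- function(events, onset, catalog, bins = 18L, window_start = -24) {
  stay_ids <- names(onset)
  if (is.null(stay_ids)) {
    stay_ids <- as.character(sort(unique(events$stay_id)))
    names(onset) <- stay_ids
  }
  vars <- catalog$name
  vals <- array(NA_real_, c(length(stay_ids), bins, length(vars)),
                dimnames = list(stay_ids, NULL, vars))
  ev <- events[as.character(events$stay_id) %in% stay_ids, , drop = FALSE]
  rel <- ev$time_hours - onset[as.character(ev$stay_id)]
  b <- floor((rel - window_start) / 4) + 1L
  ok <- b >= 1L & b <= bins & ev$variable %in% vars
  ev <- ev[ok, , drop = FALSE]; b <- b[ok]
  agg <- catalog$aggregation[match(ev$variable, catalog$name)]
  key <- paste(ev$stay_id, b, ev$variable, sep = "\r")
  ord <- order(key, ev$time_hours)
  ev <- ev[ord, , drop = FALSE]; b <- b[ord]; agg <- agg[ord]; key <- key[ord]
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  agg_fun <- function(v, a) switch(a,
    mean = mean(v), max = max(v), sum = sum(v), last = v[length(v)],
    stop_input("unknown aggregation rule: ", a))
  val <- vapply(split(seq_along(grp), grp), function(ix)
    agg_fun(ev$value[ix], agg[ix[1L]]), 0)
  si <- match(as.character(ev$stay_id[first]), stay_ids)
  vi <- match(ev$variable[first], vars)
  vals[cbind(si, b[first], vi)] <- val
  structure(list(values = vals, mask = !is.na(vals), stay_ids = stay_ids,
                 onset = onset, bin_hours = 4,
                 window_start = window_start),
            class = "cohort_grid")
}

#' @export
print.cohort_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("Cohort grid:", d[1], "stays x", d[2], "bins x", d[3], "variables;",
      sprintf("%.1f%% observed\n", 100 * mean(x$mask)))
  invisible(x)
}

#' Pool a cohort grid into an observation matrix
#'
#' Stacks all (stay, bin) cells as rows, the form in which archetypes are
#' fitted (states are per-bin).
#'
#' @param grid a `"cohort_grid"`.
#' @return numeric matrix with attributes `stay` and `bin` (row
#'   provenance).
#' @export
grid_matrix <- function(grid) {
  d <- dim(grid$values)
  X <- matrix(aperm(grid$values, c(2L, 1L, 3L)), d[1] * d[2], d[3])
  colnames(X) <- dimnames(grid$values)[[3]]
  attr(X, "stay") <- rep(grid$stay_ids, each = d[2])
  attr(X, "bin") <- rep(seq_len(d[2]), d[1])
  X
}

#' Impute a binned cohort grid
#'
#' Three deterministic stages: (1) time-limited sample-and-hold — each
#' variable's last observation is carried forward up to its catalog
#' maximum hold time; (2) linear interpolation in time across interior
#' gaps bounded by observed or held values; (3) k-nearest-neighbour
#' imputation across all (stay, bin) rows, with distances computed as the
#' mean squared difference over shared available variables on the
#' standardized scale. The output grid has no missing cells; the original
#' missingness mask is preserved for audit.
#'
#' @param grid a `"cohort_grid"` from [bin_events()].
#' @param catalog a [variable_catalog()].
#' @param k_neighbors neighbours for stage 3 (default 5).
#' @return the completed `"cohort_grid"` (field `mask` still marks the
#'   originally observed cells).
#' @export
impute_grid <- function(grid, catalog, k_neighbors = 5L) {
  vals <- grid$values
  d <- dim(vals)
  vars <- dimnames(vals)[[3]]
  hold_bins <- floor(catalog$max_hold_hours[match(vars, catalog$name)] /
                     grid$bin_hours)
  # stage 1: time-limited forward fill
  for (v in seq_len(d[3])) {
    hb <- hold_bins[v]
    if (hb < 1) next
    for (s in seq_len(d[1])) {
      x <- vals[s, , v]
      obs <- which(!is.na(x))
      if (!length(obs)) next
      last_obs <- NA_integer_
      for (b in seq_len(d[2])) {
        if (!is.na(x[b])) {
          last_obs <- b
        } else if (!is.na(last_obs) && (b - last_obs) <= hb) {
          x[b] <- x[last_obs]
        }
      }
      vals[s, , v] <- x
    }
  }
  # stage 2: linear interpolation across bounded interior gaps
  for (v in seq_len(d[3])) {
    for (s in seq_len(d[1])) {
      x <- vals[s, , v]
      obs <- which(!is.na(x))
      if (length(obs) >= 2L && anyNA(x[min(obs):max(obs)])) {
        x <- stats::approx(obs, x[obs], xout = seq_len(d[2]),
                           method = "linear", rule = 1)$y
        vals[s, , v] <- ifelse(is.na(vals[s, , v]), x, vals[s, , v])
      }
    }
  }
  # stage 3: kNN across stay-bin rows
  X <- matrix(aperm(vals, c(2L, 1L, 3L)), d[1] * d[2], d[3])
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    sdv <- apply(X, 2L, stats::sd, na.rm = TRUE)
    if (anyNA(mu) || any(!is.finite(mu)))
      stop_input("variable(s) entirely missing: ",
                 paste(vars[!is.finite(mu)], collapse = ", "))
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
    need <- which(rowSums(is.na(X)) > 0L)
    for (i in need) {
      miss <- which(is.na(X[i, ]))
      diffs <- sweep(Z, 2L, Z[i, ], "-")
      d2 <- rowMeans(diffs^2, na.rm = TRUE)
      d2[i] <- Inf
      for (j in miss) {
        cand <- which(!is.na(X[, j]))
        if (!length(cand)) stop_input("variable entirely missing: ", vars[j])
        ord <- cand[order(d2[cand])]
        nb <- ord[seq_len(min(k_neighbors, length(ord)))]
        X[i, j] <- mean(X[nb, j])
      }
    }
    vals <- aperm(array(X, c(d[2], d[1], d[3])), c(2L, 1L, 3L))
    dimnames(vals) <- dimnames(grid$values)
  }
  grid$values <- vals
  grid
}
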