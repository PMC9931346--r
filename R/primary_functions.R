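#' Biomarker-to-primary-function map
#'
#' Maps selected biomarkers to the seven organ-system "primary functions"
#' (nervous system; inflammation and infection; liver; kidney;
#' coagulation; respiratory; cardiovascular). Each biomarker carries a
#' confidence weight equal to the number of feature-selection methods
#' (1-3) that chose it, and inherits its normal-range boundaries and
#' abnormality direction from the [variable_catalog()]. The assignment
#' ships as the editable data file `extdata/primary_functions.csv`.
#'
#' @param catalog a [variable_catalog()].
#' @return data.frame `fn`, `biomarker`, `weight`, `normal_low`,
#'   `normal_high`, `direction`.
#' @export
primary_function_map <- function(catalog = variable_catalog()) {
  map <- read_bands("primary_functions.csv")
  idx <- match(map$biomarker, catalog$name)
  if (anyNA(idx))
    stop_input("biomarker(s) not in catalog: ",
               paste(map$biomarker[is.na(idx)], collapse = ", "))
  map$normal_low <- catalog$normal_low[idx]
  map$normal_high <- catalog$normal_high[idx]
  map$direction <- catalog$direction[idx]
  map
}

#' Distance from a state mean to the normal-range boundary
#'
#' Zero inside the normal range; otherwise the distance to the nearer
#' violated boundary on the biomarker's unit scale. Only the lower
#' boundary generates distance for low-is-abnormal markers (e.g. GCS),
#' only the upper for high-is-abnormal markers.
#'
#' @param value state mean value(s) of the biomarker, in clinical units.
#' @param normal_low,normal_high normal-range boundaries (either may be
#'   `NA` for one-sided markers, but not both).
#' @param direction `"low_is_abnormal"`, `"high_is_abnormal"` or
#'   `"two_sided"`.
#' @return nonnegative distance(s).
#' @examples
#' boundary_distance(20.7, 4.5, 11.0, "two_sided")  # WBC: 9.7
#' boundary_distance(15, 15, 15, "low_is_abnormal") # GCS at normal: 0
#' @export
boundary_distance <- function(value, normal_low, normal_high, direction) {
  if (all(is.na(c(normal_low, normal_high))))
    stop_input("missing normal range")
  below <- if (!is.na(normal_low)) pmax(0, normal_low - value) else 0
  above <- if (!is.na(normal_high)) pmax(0, value - normal_high) else 0
  switch(direction,
         low_is_abnormal = below,
         high_is_abnormal = above,
         two_sided = pmax(below, above),
         stop_input("unknown direction: ", direction))
}

#' Per-state expression scores of the seven primary functions
#'
#' For each (function, state): every mapped biomarker's boundary distance
#' is normalized by its maximum across states, the function's raw score
#' is the confidence-weighted sum of normalized distances, and each
#' function is linearly rescaled to the 0-10 range. `rescale =
#' "zero_anchored"` (default) anchors zero distance at 0 and the maximal
#' state at 10 (so an all-normal state scores 0); `rescale = "minmax"`
#' maps the minimal state to 0 instead.
#'
#' @param state_means `K x m` matrix of per-state biomarker means in
#'   clinical units (columns named; e.g. `summarize_states(...)$mean`
#'   after unit mapping).
#' @param map a [primary_function_map()].
#' @param rescale `"zero_anchored"` or `"minmax"`.
#' @return object of class `"expression_scores"`: `scores` (`K x 7`
#'   matrix in `[0, 10]`), `raw`, `distances` (per-biomarker).
#' @export
expression_scores <- function(state_means, map = primary_function_map(),
                              rescale = c("zero_anchored", "minmax")) {
  rescale <- match.arg(rescale)
  missing_bm <- setdiff(map$biomarker, colnames(state_means))
  if (length(missing_bm))
    stop_input("state means missing biomarker(s): ",
               paste(missing_bm, collapse = ", "))
  K <- nrow(state_means)
  fns <- unique(map$fn)
  D <- matrix(0, K, nrow(map),
              dimnames = list(rownames(state_means),
                              paste(map$fn, map$biomarker, sep = ":")))
  for (b in seq_len(nrow(map))) {
    D[, b] <- boundary_distance(state_means[, map$biomarker[b]],
                                map$normal_low[b], map$normal_high[b],
                                map$direction[b])
  }
  raw <- matrix(0, K, length(fns), dimnames = list(rownames(state_means), fns))
  for (fn in fns) {
    cols <- which(map$fn == fn)
    acc <- rep(0, K)
    for (b in cols) {
      mx <- max(D[, b])
      if (mx > 0) acc <- acc + map$weight[b] * D[, b] / mx
    }
    raw[, fn] <- acc
  }
  scores <- raw
  for (fn in fns) {
    mx <- max(raw[, fn])
    if (mx == 0) {
      warning("all states within normal range for function: ", fn)
      next
    }
    scores[, fn] <- if (rescale == "zero_anchored") {
      10 * raw[, fn] / mx
    } else {
      mn <- min(raw[, fn])
      if (mx > mn) 10 * (raw[, fn] - mn) / (mx - mn) else raw[, fn] * 0
    }
  }
  structure(list(scores = scores, raw = raw, distances = D,
                 rescale = rescale), class = "expression_scores")
}

#' @export
print.expression_scores <- function(x, ...) {
  cat("Primary-function expression scores (0-10):\n")
  print(round(x$scores, 2))
  invisible(x)
}
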