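#' Seeded 2-D ordination for visualization exports
#'
#' Deterministic two-dimensional embedding of the observation matrix by
#' classical multidimensional scaling on Euclidean distances (computed
#' via principal components, to which it is equivalent). Used only for
#' plot-ready exports; no downstream computation depends on the
#' coordinates. The seed is accepted for interface stability and to pin
#' any future stochastic backend.
#'
#' @param X numeric matrix (`n >= 4`).
#' @param seed integer seed.
#' @return `n x 2` coordinate matrix.
#' @export
embed_2d <- function(X, seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_input("X must be finite")
  if (nrow(X) < 4L) stop_input("need at least 4 observations to embed")
  set.seed(seed)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)
  Y <- pc$x[, 1:2, drop = FALSE]
  colnames(Y) <- c("dim1", "dim2")
  Y
}

#' Run the full sepsis-state analysis pipeline
#'
#' Executes all stages end to end on a synthetic cohort: simulate,
#' select the cohort (onset detection, inclusion rules, Sepsis-3
#' reclassification), preprocess (outlier filtering, 4-hour binning,
#' hold/interpolate/kNN imputation), score severity (SOFA, SIRS),
#' fit archetypes (fixed `K` or elbow selection) and assign states,
#' validate states (pairwise multivariate tests), select discriminative
#' features, score primary-function expression, profile comorbidity
#' enrichment, model progression (higher-order Markov chains, de Bruijn
#' graph, gradient archetypes and transition markers), and embed for
#' visualization. Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @param K number of archetypes, or `NULL` to choose by elbow over
#'   `K_range`.
#' @param K_range candidate K for elbow selection.
#' @param markov_orders Markov chain orders to fit (default `1:3`).
#' @param gradient_K gradient-archetype count (default: same as the
#'   chosen `K`).
#' @param max_iter,n_restarts archetype solver parameters.
#' @param outdir optional directory; when given, stage artifacts are
#'   written as CSV/JSON/GraphML files.
#' @return object of class `"sepsis_pipeline"` with one element per
#'   stage.
#' @export
run_sepsis_pipeline <- function(config = cohort_config(), K = NULL,
                                K_range = 2:8, markov_orders = 1:3,
                                gradient_K = NULL, max_iter = 300L,
                                n_restarts = 1L, outdir = NULL) {
  catalog <- config$catalog
  clin <- catalog[catalog$group != "treatment", , drop = FALSE]
  cohort <- generate_cohort(config)

  # --- cohort selection ---------------------------------------------------
  meta <- cohort$metadata
  onset <- vapply(seq_len(nrow(meta)), function(i)
    detect_onset(meta$antibiotic_time[i], meta$culture_time[i]), 0)
  names(onset) <- as.character(meta$stay_id)
  has_onset <- !is.na(onset)

  # --- preprocessing ------------------------------------------------------
  events <- filter_outliers(cohort$events, clin)
  grid <- bin_events(events, onset[has_onset], clin, bins = config$bins)
  grid <- impute_grid(grid, clin)
  scores <- score_grid(grid, cohort$treatments)

  # selection report with per-stay SOFA series (times relative to admission)
  sofa_by_stay <- split(
    data.frame(time_hours = onset[scores$stay_id] - 24 +
                 4 * (scores$bin - 0.5),
               sofa = scores$sofa),
    scores$stay_id)
  selection <- select_cohort(meta, sofa_by_stay)
  included <- selection$stay_id[selection$included]
  keep_stay <- grid$stay_ids %in% as.character(included)
  grid$values <- grid$values[keep_stay, , , drop = FALSE]
  grid$mask <- grid$mask[keep_stay, , , drop = FALSE]
  grid$stay_ids <- grid$stay_ids[keep_stay]
  scores <- scores[scores$stay_id %in% as.character(included), ]

  # --- archetypes ---------------------------------------------------------
  X_unit <- grid_matrix(grid)
  X_std <- unit_to_std(X_unit, clin)
  elbow <- NULL
  if (is.null(K)) {
    elbow <- select_K_elbow(X_std, K_range, max_iter = max_iter,
                            n_restarts = n_restarts, seed = config$seed)
    K <- elbow$chosen_K
    model <- elbow$models[[match(K, elbow$K)]]
  } else {
    model <- fit_archetypes(X_std, K, max_iter = max_iter,
                            n_restarts = n_restarts, seed = config$seed)
  }
  labels <- assign_state(model)

  # --- validation, features, primary functions ----------------------------
  validation <- tryCatch(pairwise_state_tests(X_std, labels),
                         error = function(e) NULL)
  features <- rank_and_tier(X_std, labels)
  state_stats <- summarize_states(X_unit, labels, K = K)
  expression <- tryCatch(
    expression_scores(state_stats$mean, primary_function_map(clin)),
    warning = function(w) suppressWarnings(
      expression_scores(state_stats$mean, primary_function_map(clin))))

  # --- severity / outcome characterization --------------------------------
  stay_of_row <- attr(X_unit, "stay")
  state_seq <- lapply(split(seq_along(labels), stay_of_row)[
    unique(stay_of_row)], function(ix) labels[ix])
  pat_of_stay <- stats::setNames(as.character(meta$patient_id),
                                 as.character(meta$stay_id))
  patient_id <- pat_of_stay[names(state_seq)]
  died <- stats::setNames(
    cohort$metadata$died[!duplicated(cohort$metadata$patient_id)],
    as.character(cohort$metadata$patient_id[
      !duplicated(cohort$metadata$patient_id)]))
  com_count <- rowSums(cohort$comorbidities[, -1L])
  demographics <- data.frame(
    patient_id = cohort$comorbidities$patient_id,
    age = meta$age[match(cohort$comorbidities$patient_id, meta$patient_id)],
    gender = meta$gender[match(cohort$comorbidities$patient_id,
                               meta$patient_id)],
    comorbidity_count = com_count)
  characterization <- characterize_states(scores, labels, state_seq,
                                          patient_id, died, demographics, K)

  # --- comorbidity enrichment ---------------------------------------------
  pt <- passthrough_sets(state_seq, patient_id, K)
  pt <- pt[lengths(pt) > 0L]
  comorbidity <- if (length(pt) >= 1L)
    comorbidity_zscores(cohort$comorbidities, pt) else NULL

  # --- progression --------------------------------------------------------
  trajectories <- build_trajectories(X_std, labels,
                                     patient_id = patient_id, died = died)
  markov <- lapply(markov_orders, function(l)
    tryCatch(fit_markov(trajectories, order = l, K = K),
             error = function(e) NULL))
  names(markov) <- paste0("order_", markov_orders)
  graphs <- lapply(markov, function(tn) if (!is.null(tn))
    debruijn_graph(tn, trajectories, cohort$treatments) else NULL)
  gradients <- gradient_dataset(trajectories)
  gradient_groups <- NULL
  markers <- NULL
  gK <- gradient_K %||% K
  if (nrow(gradients$G) >= gK + 2L) {
    gradient_groups <- gradient_archetypes(gradients, gK,
                                           max_iter = max_iter,
                                           seed = config$seed)
    markers <- transition_marker_zscores(gradients, gradient_groups$groups)
  }

  embedding <- embed_2d(X_std, seed = config$seed)

  out <- structure(list(
    cohort = cohort, selection = selection, grid = grid, scores = scores,
    X_std = X_std, elbow = elbow, model = model, labels = labels, K = K,
    validation = validation, features = features,
    state_stats = state_stats, expression = expression,
    characterization = characterization, comorbidity = comorbidity,
    trajectories = trajectories, markov = markov, graphs = graphs,
    gradients = gradients, gradient_groups = gradient_groups,
    markers = markers, embedding = embedding), class = "sepsis_pipeline")
  if (!is.null(outdir)) export_pipeline(out, outdir)
  out
}

#' @export
print.sepsis_pipeline <- function(x, ...) {
  cat("Sepsis-state pipeline: ", length(unique(attr(x$X_std, "stay"))),
      " included stays, K = ", x$K, " states\n", sep = "")
  print(x$characterization, digits = 3)
  invisible(x)
}

#' Write pipeline artifacts to disk
#'
#' Exports each stage's result as plain-text files (CSV/JSON/GraphML)
#' under `dir`.
#'
#' @param pipeline a `"sepsis_pipeline"`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
export_pipeline <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  w(pipeline$selection, "selection.csv")
  w(pipeline$scores, "scores.csv")
  w(data.frame(stay_id = attr(pipeline$X_std, "stay"),
               bin = attr(pipeline$X_std, "bin"),
               state = pipeline$labels), "labels.csv")
  w(pipeline$features$table, "feature_ranking.csv")
  w(pipeline$characterization, "state_characterization.csv")
  if (!is.null(pipeline$validation)) {
    w(pipeline$validation$pairwise, "pairwise_tests.csv")
    w(pipeline$validation$per_variable, "per_variable_tests.csv")
  }
  if (!is.null(pipeline$comorbidity)) {
    utils::write.csv(pipeline$comorbidity$masked,
                     file.path(dir, "comorbidity_masked_z.csv"))
  }
  utils::write.csv(pipeline$expression$scores,
                   file.path(dir, "expression_scores.csv"))
  jsonlite::write_json(list(K = pipeline$K,
                            Z = pipeline$model$Z,
                            rss = pipeline$model$rss),
                       file.path(dir, "archetypes.json"), digits = NA)
  for (nm in names(pipeline$graphs)) {
    if (!is.null(pipeline$graphs[[nm]]))
      write_debruijn(pipeline$graphs[[nm]],
                     file.path(dir, paste0("debruijn_", nm, ".graphml")))
  }
  utils::write.csv(pipeline$embedding, file.path(dir, "embedding.csv"))
  invisible(dir)
}
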