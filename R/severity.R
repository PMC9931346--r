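.band_env <- new.env(parent = emptyenv())

read_bands <- function(file) {
  if (is.null(.band_env[[file]])) {
    path <- system.file("extdata", file, package = "sepstates")
    if (path == "") path <- file.path("inst", "extdata", file)
    .band_env[[file]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .band_env[[file]]
}

#' SOFA band table
#'
#' The Sequential Organ Failure Assessment bands used by [sofa_score()],
#' read from the editable data file `extdata/sofa_bands.csv`. A value `v`
#' of a measure receives the score of the band with `low <= v < high`; a
#' component with several measures (cardiovascular: MAP and vasopressor
#' dose; renal: creatinine and 24-h urine) takes the worst applicable
#' band. The respiratory bands follow the PaO2/FiO2 anchors (at or above
#' 400 scores 0; 300-400, 200-300, 100-200 and below 100 score 1-4).
#' Vasopressor support is a single norepinephrine-equivalent dose
#' (mcg/kg/min): any positive dose up to 0.1 scores 3, above 0.1 scores 4.
#'
#' @return data.frame `component`, `measure`, `low`, `high`, `score`.
#' @export
sofa_bands <- function() read_bands("sofa_bands.csv")

band_score <- function(bands, measure, value) {
  b <- bands[bands$measure == measure, , drop = FALSE]
  out <- rep(NA_real_, length(value))
  for (i in seq_len(nrow(b))) {
    hit <- !is.na(value) & value >= b$low[i] & value < b$high[i]
    out[hit] <- pmax(out[hit], b$score[i], na.rm = TRUE)
  }
  out
}

#' Compute the SOFA score
#'
#' Six organ components (respiration, coagulation, liver, cardiovascular,
#' central nervous system, renal), each 0-4, summed to a 0-24 total.
#' Bands are encoded in [sofa_bands()]. Vectorized over observations.
#'
#' @param pao2_fio2 PaO2/FiO2 ratio (mmHg); alternatively supply `pao2`
#'   and `fio2`.
#' @param platelets platelet count (1e9/L).
#' @param bilirubin total bilirubin (mg/dL).
#' @param map mean arterial pressure (mmHg).
#' @param vasopressor norepinephrine-equivalent dose (mcg/kg/min; 0 = no
#'   support).
#' @param gcs Glasgow Coma Scale (3-15).
#' @param creatinine serum creatinine (mg/dL).
#' @param urine_24h optional 24-h urine output (mL).
#' @param pao2,fio2 optionally used to form the ratio; `fio2 = 0` is an
#'   error.
#' @return data.frame with the six components and `total`.
#' @examples
#' sofa_score(pao2_fio2 = 150, platelets = 250, bilirubin = 0.5,
#'            map = 80, vasopressor = 0, gcs = 15, creatinine = 0.9)$total  # 3
#' @export
sofa_score <- function(pao2_fio2 = NULL, platelets = NA, bilirubin = NA,
                       map = NA, vasopressor = 0, gcs = NA, creatinine = NA,
                       urine_24h = NA, pao2 = NULL, fio2 = NULL) {
  if (is.null(pao2_fio2)) {
    if (is.null(pao2) || is.null(fio2))
      stop_input("supply pao2_fio2, or both pao2 and fio2")
    if (any(fio2 == 0, na.rm = TRUE))
      stop_input("FiO2 = 0: PaO2/FiO2 ratio undefined")
    pao2_fio2 <- pao2 / fio2
  }
  bands <- sofa_bands()
  n <- max(lengths(list(pao2_fio2, platelets, bilirubin, map, vasopressor,
                        gcs, creatinine, urine_24h)))
  rec <- function(x) rep_len(x, n)
  resp <- band_score(bands, "pao2_fio2", rec(pao2_fio2))
  coag <- band_score(bands, "platelets", rec(platelets))
  liver <- band_score(bands, "bilirubin", rec(bilirubin))
  cardio <- pmax(band_score(bands, "map", rec(map)),
                 band_score(bands, "vasopressor", rec(vasopressor)),
                 na.rm = TRUE)
  cns <- band_score(bands, "gcs", rec(gcs))
  renal <- pmax(band_score(bands, "creatinine", rec(creatinine)),
                band_score(bands, "urine_24h", rec(urine_24h)), na.rm = TRUE)
  comp <- data.frame(respiration = resp, coagulation = coag, liver = liver,
                     cardiovascular = cardio, cns = cns, renal = renal)
  comp[is.na(comp)] <- 0
  comp$total <- rowSums(comp)
  comp
}

#' Compute the SIRS score
#'
#' One point for each met criterion: temperature outside 36-38 C, heart
#' rate above 90/min, respiratory (respiratory rate above 20/min or PaCO2
#' below 32 mmHg), and white-cell count outside 4-12 x 1e9/L. Thresholds
#' are encoded in `extdata/sirs_thresholds.csv`. The sepsis flag is
#' `score >= threshold` (default 2).
#'
#' @param hr heart rate (bpm).
#' @param temp temperature (Celsius).
#' @param rr respiratory rate (bpm).
#' @param paco2 PaCO2 (mmHg).
#' @param wbc white blood cell count (1e9/L).
#' @param threshold flag threshold (default 2).
#' @return data.frame `score` (0-4) and `flag`.
#' @export
sirs_score <- function(hr, temp, rr, paco2, wbc, threshold = 2) {
  th <- read_bands("sirs_thresholds.csv")
  crit <- function(measure, value) {
    b <- th[th$measure == measure, ]
    !is.na(value) & (value < b$low | value > b$high)
  }
  n <- max(lengths(list(hr, temp, rr, paco2, wbc)))
  rec <- function(x) rep_len(x, n)
  s <- as.integer(crit("temp", rec(temp))) +
       as.integer(crit("hr", rec(hr))) +
       as.integer(crit("rr", rec(rr)) | crit("paco2", rec(paco2))) +
       as.integer(crit("wbc", rec(wbc)))
  data.frame(score = s, flag = s >= threshold)
}

#' Score every (stay, bin) cell of a completed grid
#'
#' Computes SOFA and SIRS per bin from the grid's clinical variables (and
#' the per-bin vasopressor dose when a treatments table is given).
#'
#' @param grid a completed `"cohort_grid"` (see [impute_grid()]).
#' @param treatments optional data.frame `stay_id`, `bin`, `vasopressor`.
#' @return data.frame `stay_id`, `bin`, `sofa`, `sirs`, `sirs_flag`.
#' @export
score_grid <- function(grid, treatments = NULL) {
  X <- grid_matrix(grid)
  stay <- attr(X, "stay"); bin <- attr(X, "bin")
  vaso <- rep(0, nrow(X))
  if (!is.null(treatments)) {
    idx <- match(paste(stay, bin), paste(treatments$stay_id, treatments$bin))
    vaso <- ifelse(is.na(idx), 0, treatments$vasopressor[idx])
  }
  sofa <- sofa_score(pao2_fio2 = X[, "PaO2_FiO2"],
                     platelets = X[, "Platelets"],
                     bilirubin = X[, "Total_Bilirubin"],
                     map = X[, "MeanBP"], vasopressor = vaso,
                     gcs = X[, "GCS"], creatinine = X[, "Creatinine"])
  sirs <- sirs_score(hr = X[, "HR"], temp = X[, "Temp"], rr = X[, "RR"],
                     paco2 = X[, "PaCO2"], wbc = X[, "WBC"])
  data.frame(stay_id = stay, bin = bin, sofa = sofa$total,
             sirs = sirs$score, sirs_flag = sirs$flag)
}

#' Per-state mortality with unique pass-through counting
#'
#' For each state, the mortality rate is the number of patients who
#' visited the state at least once and died, divided by the number of
#' patients who visited it at least once. Revisits never multiply counts:
#' a patient whose trajectory is A1 -> A2 -> A1 and who dies contributes
#' once to A1 and once to A2.
#'
#' @param state_seq list of per-stay integer state sequences.
#' @param patient_id patient id per stay (parallel to `state_seq`).
#' @param died named logical vector per patient (names are patient ids).
#' @param K number of states.
#' @return data.frame `state`, `n_patients`, `n_died`, `mortality`
#'   (`NA` for never-visited states).
#' @export
state_mortality <- function(state_seq, patient_id, died, K) {
  visits <- lapply(seq_len(K), function(k) character(0))
  for (i in seq_along(state_seq)) {
    p <- as.character(patient_id[i])
    for (k in unique(state_seq[[i]])) visits[[k]] <- union(visits[[k]], p)
  }
  n_pat <- vapply(visits, length, 0L)
  n_died <- vapply(visits, function(p) sum(died[p]), 0L)
  data.frame(state = seq_len(K), n_patients = n_pat, n_died = n_died,
             mortality = ifelse(n_pat > 0, n_died / n_pat, NA_real_))
}

#' Per-state means and SDs of clinical variables
#'
#' Group-by summary of an observation matrix by per-row state label, the
#' per-state analogue of the cohort description table.
#'
#' @param X observation matrix (rows = stay-bins).
#' @param labels integer state label per row.
#' @param K number of states (default `max(labels)`).
#' @return list with `mean` and `sd` (`K x m` matrices) and `n` (rows per
#'   state). Empty states yield `NA` rows with a warning.
#' @export
summarize_states <- function(X, labels, K = max(labels)) {
  m <- ncol(X)
  mu <- sdm <- matrix(NA_real_, K, m, dimnames = list(paste0("A", seq_len(K)),
                                                      colnames(X)))
  n <- integer(K)
  for (k in seq_len(K)) {
    rows <- which(labels == k)
    n[k] <- length(rows)
    if (length(rows)) {
      mu[k, ] <- colMeans(X[rows, , drop = FALSE])
      sdm[k, ] <- apply(X[rows, , drop = FALSE], 2L, stats::sd)
    }
  }
  if (any(n == 0L)) warning("empty state(s): ",
                            paste(which(n == 0L), collapse = ", "))
  list(mean = mu, sd = sdm, n = n)
}

#' Characterize states by severity, outcome and demographics
#'
#' Per-state average SOFA and SIRS over assigned bins, mortality rate with
#' unique pass-through counting, and average age, gender and comorbidity
#' count over the patients who passed through each state.
#'
#' @param scores per-bin score table from [score_grid()].
#' @param labels integer state label per row of `scores`.
#' @param state_seq,patient_id,died as in [state_mortality()].
#' @param demographics data.frame per patient with `patient_id`, `age`,
#'   `gender`, `comorbidity_count`.
#' @param K number of states.
#' @return data.frame, one row per state.
#' @export
characterize_states <- function(scores, labels, state_seq, patient_id, died,
                                demographics, K) {
  mort <- state_mortality(state_seq, patient_id, died, K)
  out <- data.frame(state = seq_len(K),
                    avg_sofa = NA_real_, avg_sirs = NA_real_,
                    mortality = mort$mortality,
                    avg_age = NA_real_, avg_gender = NA_real_,
                    avg_comorbidity = NA_real_)
  rownames(demographics) <- as.character(demographics$patient_id)
  for (k in seq_len(K)) {
    rows <- labels == k
    if (any(rows)) {
      out$avg_sofa[k] <- mean(scores$sofa[rows])
      out$avg_sirs[k] <- mean(scores$sirs[rows])
    }
    pats <- unique(unlist(lapply(seq_along(state_seq), function(i)
      if (k %in% state_seq[[i]]) as.character(patient_id[i]) else NULL)))
    if (length(pats)) {
      dg <- demographics[pats, ]
      out$avg_age[k] <- mean(dg$age)
      out$avg_gender[k] <- mean(dg$gender)
      out$avg_comorbidity[k] <- mean(dg$comorbidity_count)
    }
  }
  out
}
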