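#' Configuration for the synthetic ICU cohort generator
#'
#' Bundles and validates every knob of the generator: cohort size, the
#' planted archetype geometry, the purity of the convex mixture weights,
#' observation noise, the (possibly higher-order) Markov chain driving
#' per-bin state trajectories, missingness/outlier corruption of the raw
#' event stream, and the state-dependent comorbidity and mortality models.
#'
#' @param seed integer seed; identical seeds yield identical cohorts.
#' @param n_patients number of distinct patients.
#' @param n_stays number of ICU stays (`>= n_patients`; extra stays are
#'   assigned to existing patients).
#' @param K_true number of planted archetypes (ground-truth states).
#' @param m number of clinical variables; the default 42 uses the full
#'   [variable_catalog()].
#' @param archetype_matrix optional `K_true x m` matrix of archetypes on
#'   the standardized scale; if `NULL`, a direction-aware block design is
#'   built at the configured `separation`.
#' @param separation magnitude (in within-state SDs) of each archetype's
#'   signature shifts when `archetype_matrix` is sampled.
#' @param mixture_concentration Dirichlet concentration of the dominant
#'   (planted-state) mixture component; `Inf` yields exactly pure unit
#'   weights.
#' @param noise_sd observation noise SD on the standardized scale.
#' @param markov_order order `l >= 1` of the state chain.
#' @param transition_tensor stochastic matrix with `K_true^l` context rows
#'   (row names are contexts `"s1|...|sl"`, oldest first) and `K_true`
#'   columns; rows must sum to 1 within 1e-12. Default: self-transition
#'   probability `self_transition`, remainder uniform.
#' @param self_transition self-transition probability of the default
#'   tensor.
#' @param bins number of 4-hour bins per stay (default 18, i.e. the
#'   -24h..+48h peri-onset window).
#' @param missing_rate per-variable probability that a bin's measurement is
#'   never recorded (scalar or length-`m` vector).
#' @param outlier_rate probability that a recorded value is corrupted into
#'   an implausible outlier (multiplied by 10, or negated when that already
#'   leaves the plausible range).
#' @param comorbidity_logit_shift `30 x K_true` matrix of logit shifts of
#'   comorbidity prevalence per state; default enriches comorbidity `k` in
#'   state `k`.
#' @param comorbidity_base_rate baseline comorbidity prevalence.
#' @param mortality_logit length-`K_true` vector of per-state death
#'   log-odds; default gives the "severe" states (upper half) a markedly
#'   higher rate.
#' @param onset_qualify_prob probability that a stay's antibiotic/culture
#'   pair satisfies the onset rule.
#' @param initial_state_prob distribution of the initial state(s); default
#'   concentrates on state 1.
#' @param catalog the [variable_catalog()] (with treatments) used for unit
#'   mapping.
#' @return an object of class `"cohort_config"`.
#' @export
cohort_config <- function(seed = 1L,
                          n_patients = 150L,
                          n_stays = n_patients,
                          K_true = 6L,
                          m = 42L,
                          archetype_matrix = NULL,
                          separation = 2.5,
                          mixture_concentration = 25,
                          noise_sd = 0.25,
                          markov_order = 1L,
                          transition_tensor = NULL,
                          self_transition = 0.8,
                          bins = 18L,
                          missing_rate = 0.3,
                          outlier_rate = 0.01,
                          comorbidity_logit_shift = NULL,
                          comorbidity_base_rate = 0.15,
                          mortality_logit = NULL,
                          onset_qualify_prob = 1,
                          initial_state_prob = NULL,
                          catalog = variable_catalog(treatments = TRUE)) {
  if (K_true < 2L) stop_input("K_true must be >= 2")
  if (n_stays < n_patients) stop_input("n_stays must be >= n_patients")
  if (K_true > n_patients) stop_input("K_true must not exceed n_patients")
  clin <- catalog[catalog$group != "treatment", , drop = FALSE]
  if (m == nrow(clin)) {
    varnames <- clin$name
  } else {
    varnames <- sprintf("V%02d", seq_len(m))
  }
  if (is.null(archetype_matrix)) {
    archetype_matrix <- default_archetypes(K_true, m, separation,
                                           if (m == nrow(clin)) clin else NULL)
  }
  archetype_matrix <- as.matrix(archetype_matrix)
  if (!all(dim(archetype_matrix) == c(K_true, m)))
    stop_input("archetype_matrix must be K_true x m")
  colnames(archetype_matrix) <- varnames
  dd <- stats::dist(archetype_matrix)
  if (any(dd <= 0)) stop_input("archetype rows must be pairwise distinct")
  if (is.null(transition_tensor)) {
    transition_tensor <- default_transition_tensor(K_true, markov_order,
                                                   self_transition)
  }
  transition_tensor <- as.matrix(transition_tensor)
  if (nrow(transition_tensor) != K_true^markov_order ||
      ncol(transition_tensor) != K_true)
    stop_input("transition_tensor must have K_true^markov_order rows and K_true columns")
  if (any(transition_tensor < 0) ||
      any(abs(rowSums(transition_tensor) - 1) > 1e-12))
    stop_input("transition_tensor rows must be nonnegative and sum to 1")
  if (is.null(rownames(transition_tensor)))
    rownames(transition_tensor) <- all_contexts(K_true, markov_order)
  severe <- seq_len(K_true) > ceiling(K_true / 2)
  if (is.null(mortality_logit))
    mortality_logit <- ifelse(severe, stats::qlogis(0.35), stats::qlogis(0.08))
  if (is.null(comorbidity_logit_shift)) {
    comorbidity_logit_shift <- matrix(0, 30L, K_true)
    for (k in seq_len(min(30L, K_true))) comorbidity_logit_shift[k, k] <- 0.6
  }
  if (!all(dim(comorbidity_logit_shift) == c(30L, K_true)))
    stop_input("comorbidity_logit_shift must be 30 x K_true")
  if (is.null(initial_state_prob))
    initial_state_prob <- {
      p <- rep(0.3 / (K_true - 1), K_true); p[1] <- 0.7; p
    }
  missing_rate <- rep_len(missing_rate, m)
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    n_stays = as.integer(n_stays), K_true = as.integer(K_true),
    m = as.integer(m), varnames = varnames,
    archetype_matrix = archetype_matrix,
    mixture_concentration = mixture_concentration, noise_sd = noise_sd,
    markov_order = as.integer(markov_order),
    transition_tensor = transition_tensor, bins = as.integer(bins),
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    comorbidity_logit_shift = comorbidity_logit_shift,
    comorbidity_base_rate = comorbidity_base_rate,
    mortality_logit = mortality_logit,
    onset_qualify_prob = onset_qualify_prob,
    initial_state_prob = initial_state_prob,
    severe_states = which(severe), catalog = catalog
  ), class = "cohort_config")
}

all_contexts <- function(K, l) {
  grids <- rev(expand.grid(rev(replicate(l, seq_len(K), simplify = FALSE))))
  apply(grids, 1L, paste, collapse = "|")
}

context_key <- function(states) paste(states, collapse = "|")

#' Default planted archetypes
#'
#' Builds `K` archetype rows on the standardized scale. Variables are
#' partitioned round-robin into `K` signature blocks; archetype `k` shifts
#' its block by `separation` in each variable's abnormal direction (so a
#' low-is-abnormal marker such as GCS is shifted down), leaving other
#' variables at the cohort mean. This yields well-separated, clinically
#' signed extreme profiles whose unit-mapped values stay plausible.
#'
#' @keywords internal
default_archetypes <- function(K, m, separation, clin = NULL) {
  sign_of <- rep(1, m)
  lo_z <- rep(-Inf, m); hi_z <- rep(Inf, m)
  if (!is.null(clin)) {
    sign_of <- ifelse(clin$direction == "low_is_abnormal", -1, 1)
    # keep unit-mapped archetypes strictly inside the plausibility bounds
    lo_z <- ifelse(is.na(clin$plausible_low), -Inf,
                   0.95 * (clin$plausible_low - clin$sim_mean) / clin$sim_sd)
    hi_z <- ifelse(is.na(clin$plausible_high), Inf,
                   0.95 * (clin$plausible_high - clin$sim_mean) / clin$sim_sd)
  }
  Z <- matrix(0, K, m)
  block <- (seq_len(m) - 1L) %% K + 1L
  for (k in seq_len(K)) Z[k, block == k] <- separation * sign_of[block == k]
  # severe states share a mild global abnormality so severity scores order them
  severe <- seq_len(K) > ceiling(K / 2)
  Z[severe, ] <- Z[severe, , drop = FALSE] +
    matrix(0.5 * sign_of, sum(severe), m, byrow = TRUE)
  Z <- pmin(pmax(Z, matrix(lo_z, K, m, byrow = TRUE)),
            matrix(hi_z, K, m, byrow = TRUE))
  Z
}

#' Default higher-order transition tensor
#' @keywords internal
default_transition_tensor <- function(K, l = 1L, self = 0.8) {
  ctx <- all_contexts(K, l)
  P <- matrix((1 - self) / (K - 1), length(ctx), K,
              dimnames = list(ctx, seq_len(K)))
  last <- as.integer(vapply(strsplit(ctx, "|", fixed = TRUE),
                            function(s) s[[length(s)]], ""))
  P[cbind(seq_along(ctx), last)] <- self
  P
}

sample_state_sequence <- function(config, bins) {
  K <- config$K_true; l <- config$markov_order
  s <- integer(bins)
  s[seq_len(min(l, bins))] <- sample.int(K, min(l, bins), replace = TRUE,
                                         prob = config$initial_state_prob)
  if (bins > l) {
    for (t in (l + 1L):bins) {
      ctx <- context_key(s[(t - l):(t - 1L)])
      s[t] <- sample.int(K, 1L, prob = config$transition_tensor[ctx, ])
    }
  }
  s
}

draw_weights <- function(states, K, concentration) {
  n <- length(states)
  if (!is.finite(concentration)) {
    W <- matrix(0, n, K)
    W[cbind(seq_len(n), states)] <- 1
    return(W)
  }
  alpha <- matrix(1, n, K)
  alpha[cbind(seq_len(n), states)] <- concentration
  x <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
  x / rowSums(x)
}

#' Simulate standardized observations from planted archetypes
#'
#' Draws `n` observations as convex mixtures of the configured archetypes
#' (weights Dirichlet-concentrated on each observation's state) plus
#' Gaussian noise, on the standardized scale.
#'
#' @param config a [cohort_config()].
#' @param n number of observations.
#' @param states optional state index per observation; default uniform.
#' @return list with `X` (n x m), `states`, `weights` (n x K).
#' @export
simulate_observations <- function(config, n, states = NULL) {
  if (is.null(states)) states <- sample.int(config$K_true, n, replace = TRUE)
  W <- draw_weights(states, config$K_true, config$mixture_concentration)
  X <- W %*% config$archetype_matrix
  if (config$noise_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd), nrow(X))
  colnames(X) <- config$varnames
  list(X = X, states = states, weights = W)
}

#' Generate per-stay antibiotic and culture timestamps
#'
#' Emits one antibiotic/culture pair per stay. With probability
#' `onset_qualify_prob` the pair satisfies the suspicion-of-infection rule
#' (antibiotic-first with the culture within 24 h, or culture-first with
#' the antibiotic within 72 h; both branches exercised) and its earliest
#' event equals the stay's true onset; otherwise the gap falls outside
#' both windows.
#'
#' @param config a [cohort_config()].
#' @param onset_true numeric vector of true onset hours per stay.
#' @return data.frame `stay_id`, `antibiotic_time`, `culture_time`,
#'   `qualifies`.
#' @export
generate_admission_events <- function(config, onset_true) {
  n <- length(onset_true)
  if (n == 0L) stop_input("n_stays must be positive")
  qualifies <- stats::runif(n) < config$onset_qualify_prob
  abx_first <- stats::runif(n) < 0.5
  abx <- cul <- numeric(n)
  gap_q <- ifelse(abx_first, stats::runif(n, 0, 24), stats::runif(n, 0, 72))
  abx[abx_first] <- onset_true[abx_first]
  cul[abx_first] <- onset_true[abx_first] + gap_q[abx_first]
  cul[!abx_first] <- onset_true[!abx_first]
  abx[!abx_first] <- onset_true[!abx_first] + gap_q[!abx_first]
  # non-qualifying: antibiotic first with a gap beyond both windows
  bad <- which(!qualifies)
  abx[bad] <- onset_true[bad]
  cul[bad] <- onset_true[bad] + stats::runif(length(bad), 80, 120)
  data.frame(stay_id = seq_len(n), antibiotic_time = abx, culture_time = cul,
             qualifies = qualifies)
}

#' Generate a synthetic ICU cohort
#'
#' Produces a full synthetic cohort with the structure the analysis
#' pipeline assumes: per-stay state trajectories from the configured
#' (higher-order) Markov chain; per-bin observations as noisy convex
#' mixtures of the planted archetypes, mapped to clinical units and
#' emitted as an irregular long-format event stream with configurable
#' missingness and injected implausible outliers; state-dependent
#' treatment series (fluid volume, vasopressor dose, ventilator use);
#' per-patient comorbidities from a logistic model over visited states;
#' and death flags from per-state mortality. Ground truth (archetypes,
#' state sequences, mixture weights, standardized observations, planted
#' rates) is returned for parameter-recovery testing.
#'
#' @param config a [cohort_config()].
#' @return object of class `"sepsis_cohort"`: list with `events`,
#'   `admission`, `metadata`, `comorbidities`, `treatments`,
#'   `ground_truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_stays <- config$n_stays; bins <- config$bins; m <- config$m
  K <- config$K_true
  clin <- config$catalog[config$catalog$group != "treatment", , drop = FALSE]

  patient_id <- c(seq_len(config$n_patients),
                  if (n_stays > config$n_patients)
                    sample.int(config$n_patients,
                               n_stays - config$n_patients, replace = TRUE))
  onset_true <- 24 + 4 * sample(0:2, n_stays, replace = TRUE)
  admission <- generate_admission_events(config, onset_true)

  state_seq <- lapply(seq_len(n_stays), function(i)
    sample_state_sequence(config, bins))
  states_flat <- unlist(state_seq)
  obs_stay <- rep(seq_len(n_stays), each = bins)
  obs_bin <- rep(seq_len(bins), n_stays)
  sim <- simulate_observations(config, n_stays * bins, states = states_flat)
  X_std <- sim$X

  # unit-mapped event stream at irregular within-bin timestamps
  use_catalog_units <- identical(config$varnames, clin$name)
  if (use_catalog_units) {
    X_unit <- std_to_unit(X_std, config$catalog)
  } else {
    X_unit <- X_std
  }
  bin_start <- onset_true[obs_stay] - 24 + 4 * (obs_bin - 1L)
  n_obs <- nrow(X_std)
  ev <- data.frame(
    stay_id = rep(obs_stay, m),
    time_hours = rep(bin_start, m) + stats::runif(n_obs * m, 0, 4),
    variable = rep(config$varnames, each = n_obs),
    value = as.vector(X_unit),
    stringsAsFactors = FALSE
  )
  keep <- stats::runif(n_obs * m) >= rep(config$missing_rate, each = n_obs)
  ev <- ev[keep, , drop = FALSE]
  if (config$outlier_rate > 0 && nrow(ev) > 0 && use_catalog_units) {
    hit <- which(stats::runif(nrow(ev)) < config$outlier_rate)
    if (length(hit)) {
      spec <- clin[match(ev$variable[hit], clin$name), ]
      v <- ev$value[hit]
      lo <- ifelse(is.na(spec$plausible_low), -Inf, spec$plausible_low)
      hi <- ifelse(is.na(spec$plausible_high), Inf, spec$plausible_high)
      times10 <- v * 10
      out <- ifelse(times10 < lo | times10 > hi, times10, -v)
      ev$value[hit] <- out
    }
  }
  ev <- ev[order(ev$stay_id, ev$time_hours), , drop = FALSE]
  rownames(ev) <- NULL

  # state-dependent treatments, one row per (stay, bin)
  sev <- states_flat %in% config$severe_states
  fluids <- stats::rgamma(n_obs, shape = 2, scale = ifelse(sev, 250, 100))
  vaso <- ifelse(sev,
                 stats::rbinom(n_obs, 1L, 0.7) * stats::runif(n_obs, 0.1, 0.8),
                 stats::rbinom(n_obs, 1L, 0.1) * stats::runif(n_obs, 0.01, 0.15))
  vent <- stats::rbinom(n_obs, 1L, ifelse(sev, 0.6, 0.25))
  treatments <- data.frame(stay_id = obs_stay, bin = obs_bin,
                           fluids = fluids, vasopressor = vaso,
                           ventilator = vent)

  # comorbidities per patient from logistic model over visited states
  visited <- lapply(seq_len(config$n_patients), function(p) {
    sort(unique(unlist(state_seq[patient_id == p])))
  })
  base_logit <- stats::qlogis(config$comorbidity_base_rate)
  com <- matrix(0L, config$n_patients, 30L)
  for (p in seq_len(config$n_patients)) {
    shift <- rowMeans(config$comorbidity_logit_shift[, visited[[p]], drop = FALSE])
    com[p, ] <- stats::rbinom(30L, 1L, stats::plogis(base_logit + shift))
  }
  colnames(com) <- comorbidity_names()
  comorbidities <- data.frame(patient_id = seq_len(config$n_patients), com,
                              check.names = FALSE)

  # mortality: the highest-risk visited state drives the death draw
  p_die <- vapply(visited, function(v)
    stats::plogis(max(config$mortality_logit[v])), 0)
  died_patient <- stats::rbinom(config$n_patients, 1L, p_die) == 1L

  age <- pmax(18, pmin(100, stats::rnorm(config$n_patients, 64.57, 16.67)))
  gender <- stats::rbinom(config$n_patients, 1L, 0.44)
  metadata <- data.frame(
    stay_id = seq_len(n_stays),
    patient_id = patient_id,
    age = age[patient_id],
    gender = gender[patient_id],
    antibiotic_time = admission$antibiotic_time,
    culture_time = admission$culture_time,
    onset_true = onset_true,
    death_documented = TRUE,
    died = died_patient[patient_id],
    treatment_withdrawal = FALSE
  )

  ground_truth <- list(
    archetypes = config$archetype_matrix,
    state_sequence = state_seq,
    mixture_weights = sim$weights,
    X_std = X_std,
    obs_stay = obs_stay,
    obs_bin = obs_bin,
    planted_comorbidity_rates = stats::plogis(
      base_logit + config$comorbidity_logit_shift),
    planted_mortality = stats::plogis(config$mortality_logit),
    severe_states = config$severe_states
  )
  structure(list(events = ev, admission = admission, metadata = metadata,
                 comorbidities = comorbidities, treatments = treatments,
                 ground_truth = ground_truth, config = config),
            class = "sepsis_cohort")
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat("Synthetic sepsis cohort:", x$config$n_stays, "stays,",
      x$config$n_patients, "patients,", x$config$K_true,
      "planted states,", nrow(x$events), "raw events\n")
  invisible(x)
}

#' Names of the 30 comorbidity categories
#' @return character vector of length 30.
#' @export
comorbidity_names <- function() {
  c("Congestive_Heart_Failure", "Cardiac_Arrhythmias", "Valvular_Disease",
    "Pulmonary_Circulation", "Peripheral_Vascular", "Hypertension",
    "Paralysis", "Other_Neurological", "Chronic_Pulmonary",
    "Diabetes_Uncomplicated", "Diabetes_Complicated", "Hypothyroidism",
    "Renal_Failure", "Liver_Disease", "Peptic_Ulcer", "AIDS_HIV",
    "Lymphoma", "Metastatic_Cancer", "Solid_Tumor", "Rheumatoid_Arthritis",
    "Coagulopathy", "Obesity", "Weight_Loss", "Fluid_Electrolyte",
    "Blood_Loss_Anemia", "Deficiency_Anemia", "Alcohol_Abuse", "Drug_Abuse",
    "Psychoses", "Depression")
}

#' Write a synthetic cohort to plain-text files
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    events = file.path(dir, "events.csv"),
    metadata = file.path(dir, "stay_metadata.csv"),
    comorbidities = file.path(dir, "comorbidities.csv"),
    treatments = file.path(dir, "treatments.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  utils::write.csv(cohort$events, paths["events"], row.names = FALSE)
  utils::write.csv(cohort$metadata, paths["metadata"], row.names = FALSE)
  utils::write.csv(cohort$comorbidities, paths["comorbidities"], row.names = FALSE)
  utils::write.csv(cohort$treatments, paths["treatments"], row.names = FALSE)
  gt <- cohort$ground_truth
  gt$X_std <- NULL  # bulky; regenerate from the seed instead
  jsonlite::write_json(gt, paths["ground_truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
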