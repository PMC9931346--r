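#' Detect the onset of suspected infection
#'
#' The onset is the earliest event satisfying either branch of the
#' suspicion-of-infection rule: (i) an antibiotic administration followed
#' by a microbiological culture within 24 hours, or (ii) a culture
#' followed by an antibiotic within 72 hours. Ties between simultaneous
#' qualifying events resolve to the antibiotic branch.
#'
#' @param antibiotic_times,culture_times numeric vectors of event hours
#'   (nonnegative, relative to ICU admission); either may be empty.
#' @param abx_window hours a culture may follow an antibiotic (default 24).
#' @param culture_window hours an antibiotic may follow a culture
#'   (default 72).
#' @return the onset hour, or `NA_real_` if no pair qualifies.
#' @examples
#' detect_onset(10, 20)  # antibiotic first, gap 10 h -> onset 10
#' detect_onset(70, 5)   # culture first, gap 65 h -> onset 5
#' detect_onset(10, 40)  # gap exceeds both windows -> NA
#' @export
detect_onset <- function(antibiotic_times, culture_times,
                         abx_window = 24, culture_window = 72) {
  if (any(antibiotic_times < 0, na.rm = TRUE) ||
      any(culture_times < 0, na.rm = TRUE))
    stop_input("event times must be nonnegative")
  antibiotic_times <- sort(antibiotic_times[is.finite(antibiotic_times)])
  culture_times <- sort(culture_times[is.finite(culture_times)])
  best <- Inf
  for (a in antibiotic_times) {
    if (any(culture_times >= a & culture_times <= a + abx_window)) {
      best <- min(best, a)
    }
  }
  for (cu in culture_times) {
    if (any(antibiotic_times >= cu & antibiotic_times <= cu + culture_window)) {
      best <- min(best, cu)
    }
  }
  if (is.finite(best)) best else NA_real_
}

#' Apply the cohort inclusion rules to one stay
#'
#' A stay is included iff (in this order of reporting): age >= 18,
#' organ dysfunction (any SOFA total at or above `sofa_threshold` within
#' the window from 48 h before to 24 h after onset), documented mortality
#' status, and no withdrawal of treatment.
#'
#' @param meta one-row stay metadata (fields `age`, `death_documented`,
#'   `treatment_withdrawal`).
#' @param sofa_series data.frame with `time_hours` and `sofa` columns.
#' @param onset onset hour from [detect_onset()].
#' @param sofa_threshold organ-dysfunction threshold (default `>= 2`,
#'   the Sepsis-3 convention).
#' @return list with `included` flag and `reason` (`"included"` or the
#'   first failed rule).
#' @export
include_stay <- function(meta, sofa_series, onset, sofa_threshold = 2) {
  if (is.na(onset)) return(list(included = FALSE, reason = "no onset"))
  if (meta$age < 18) return(list(included = FALSE, reason = "age"))
  if (is.null(sofa_series) || nrow(sofa_series) == 0L)
    return(list(included = FALSE, reason = "no SOFA available"))
  w <- sofa_series$time_hours >= onset - 48 & sofa_series$time_hours <= onset + 24
  if (!any(w & sofa_series$sofa >= sofa_threshold, na.rm = TRUE))
    return(list(included = FALSE, reason = "organ dysfunction"))
  if (!isTRUE(meta$death_documented))
    return(list(included = FALSE, reason = "mortality not documented"))
  if (isTRUE(meta$treatment_withdrawal))
    return(list(included = FALSE, reason = "treatment withdrawal"))
  list(included = TRUE, reason = "included")
}

#' Reclassify a stay under strict Sepsis-3 criteria
#'
#' Sepsis-3 requires a rise of at least 2 in the SOFA score over baseline.
#' Baseline is the minimum observed SOFA in the 48 h before onset
#' (half-open window, onset excluded), assumed zero when no pre-onset
#' value exists; the post value is the maximum observed SOFA within 24 h
#' after onset (closed window). `delta = max_post - baseline`. Labels:
#' `"sepsis3"` when `delta >= 2` can be established; `"non_sepsis3"` only
#' when both windows have observed values and `delta < 2`; `"unknown"`
#' otherwise (a window is empty and `delta >= 2` cannot be established).
#'
#' @param sofa_series data.frame with `time_hours`, `sofa`.
#' @param onset onset hour.
#' @return list with `label`, `baseline_sofa`, `baseline_assumed_zero`,
#'   `max_post_sofa`, `delta`.
#' @export
classify_sepsis3 <- function(sofa_series, onset) {
  pre <- sofa_series$sofa[sofa_series$time_hours >= onset - 48 &
                          sofa_series$time_hours < onset]
  post <- sofa_series$sofa[sofa_series$time_hours >= onset &
                           sofa_series$time_hours <= onset + 24]
  pre <- pre[!is.na(pre)]; post <- post[!is.na(post)]
  baseline_assumed <- length(pre) == 0L
  baseline <- if (baseline_assumed) 0 else min(pre)
  max_post <- if (length(post)) max(post) else NA_real_
  delta <- if (is.na(max_post)) NA_real_ else max_post - baseline
  label <- if (!is.na(delta) && delta >= 2) {
    "sepsis3"
  } else if (!is.na(delta) && !baseline_assumed) {
    "non_sepsis3"
  } else {
    "unknown"
  }
  list(label = label, baseline_sofa = baseline,
       baseline_assumed_zero = baseline_assumed,
       max_post_sofa = max_post, delta = delta)
}

#' Cohort-level selection report
#'
#' Runs [detect_onset()], [include_stay()] and [classify_sepsis3()] over a
#' stay metadata table and per-stay SOFA series.
#'
#' @param metadata data.frame with one row per stay (fields of
#'   [include_stay()] plus `stay_id`, `antibiotic_time`, `culture_time`).
#' @param sofa_by_stay named list of per-stay SOFA series data.frames
#'   (names are stay ids), or `NULL` to skip the SOFA-based rules.
#' @inheritParams include_stay
#' @return data.frame `stay_id`, `onset`, `included`, `reason`,
#'   `sepsis3_label`, `baseline_sofa`, `delta`.
#' @export
select_cohort <- function(metadata, sofa_by_stay = NULL, sofa_threshold = 2) {
  out <- lapply(seq_len(nrow(metadata)), function(i) {
    meta <- metadata[i, ]
    onset <- detect_onset(meta$antibiotic_time, meta$culture_time)
    sofa <- sofa_by_stay[[as.character(meta$stay_id)]]
    inc <- include_stay(meta, sofa, onset, sofa_threshold)
    s3 <- if (!is.na(onset) && !is.null(sofa) && nrow(sofa)) {
      classify_sepsis3(sofa, onset)
    } else {
      list(label = "unknown", baseline_sofa = NA_real_, delta = NA_real_)
    }
    data.frame(stay_id = meta$stay_id, onset = onset,
               included = inc$included, reason = inc$reason,
               sepsis3_label = s3$label, baseline_sofa = s3$baseline_sofa,
               delta = s3$delta)
  })
  do.call(rbind, out)
}
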