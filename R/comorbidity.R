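#' Z-score enrichment of comorbidities per sepsis state
#'
#' For each comorbidity `j` and state `i`:
#' `z_ji = (w_ji - mu_j) / sigma_j`, where `mu_j` is the cohort
#' prevalence, `sigma_j` its cohort SD, and `w_ji` the prevalence among
#' patients who passed through state `i`. Significance comes from a
#' two-sample test of the binary indicator between the pass-through group
#' and the full cohort (Welch t by default, a two-sample proportion test
#' as an alternative); the masked matrix zeroes entries with `p > 0.05`.
#'
#' @param comorbidities data.frame: `patient_id` plus one binary column
#'   per comorbidity.
#' @param passthrough named list per state of patient ids who visited the
#'   state.
#' @param mask_alpha significance cutoff for the masked matrix
#'   (default 0.05).
#' @param test `"t"` (Welch, as stated) or `"prop"` (two-sample
#'   proportion test).
#' @param exclude_state_from_cohort compare against the cohort without
#'   the state's own patients instead of the full cohort.
#' @param p_adjust optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); `"none"` by default, matching the
#'   raw-p masking rule.
#' @return object of class `"comorbidity_z"`: matrices `z`, `p`,
#'   `masked` (comorbidities x states), `prevalence` (`w_ji`), vectors
#'   `mu`, `sigma`. Degenerate comorbidities (cohort SD 0) yield `NA`.
#' @export
comorbidity_zscores <- function(comorbidities, passthrough,
                                mask_alpha = 0.05, test = c("t", "prop"),
                                exclude_state_from_cohort = FALSE,
                                p_adjust = "none") {
  test <- match.arg(test)
  stopifnot(all(lengths(passthrough) >= 1L))
  ids <- as.character(comorbidities$patient_id)
  M <- as.matrix(comorbidities[, setdiff(colnames(comorbidities), "patient_id"),
                               drop = FALSE])
  rownames(M) <- ids
  mu <- colMeans(M)
  # population SD: for a binary indicator, sqrt(p (1 - p))
  sigma <- sqrt(colMeans(sweep(M, 2L, mu, "-")^2))
  states <- names(passthrough) %||% paste0("A", seq_along(passthrough))
  z <- p <- w <- matrix(NA_real_, ncol(M), length(passthrough),
                        dimnames = list(colnames(M), states))
  for (i in seq_along(passthrough)) {
    grp <- as.character(passthrough[[i]])
    sub <- M[grp, , drop = FALSE]
    ref <- if (exclude_state_from_cohort)
      M[setdiff(ids, grp), , drop = FALSE] else M
    w[, i] <- colMeans(sub)
    z[, i] <- ifelse(sigma > 0, (w[, i] - mu) / sigma, NA_real_)
    for (j in seq_len(ncol(M))) {
      p[j, i] <- if (test == "t") {
        tryCatch(stats::t.test(sub[, j], ref[, j])$p.value,
                 error = function(e) NA_real_)
      } else {
        tryCatch(stats::prop.test(c(sum(sub[, j]), sum(ref[, j])),
                                  c(nrow(sub), nrow(ref)))$p.value,
                 error = function(e) NA_real_)
      }
    }
  }
  if (p_adjust != "none") p[] <- stats::p.adjust(p, method = p_adjust)
  masked <- z
  masked[is.na(p) | p > mask_alpha] <- 0
  structure(list(z = z, p = p, masked = masked, prevalence = w,
                 mu = mu, sigma = sigma), class = "comorbidity_z")
}

#' @export
print.comorbidity_z <- function(x, ...) {
  sig <- sum(x$masked != 0, na.rm = TRUE)
  cat("Comorbidity z-score matrix:", nrow(x$z), "comorbidities x",
      ncol(x$z), "states;", sig, "significant entries\n")
  invisible(x)
}

#' Pass-through patient sets per state
#'
#' @param state_seq list of per-stay state sequences.
#' @param patient_id patient id per stay.
#' @param K number of states.
#' @return named list (`A1`..`AK`) of unique patient ids per state.
#' @export
passthrough_sets <- function(state_seq, patient_id, K) {
  out <- stats::setNames(vector("list", K), paste0("A", seq_len(K)))
  for (k in seq_len(K)) out[[k]] <- character(0)
  for (i in seq_along(state_seq)) {
    p <- as.character(patient_id[i])
    for (k in unique(state_seq[[i]])) out[[k]] <- union(out[[k]], p)
  }
  out
}
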