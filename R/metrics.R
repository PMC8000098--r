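#' Accuracy of (genomic) EBVs
#'
#' Pearson correlation between estimated and true breeding values over the
#' candidate cohort.
#'
#' @param ebv,tbv numeric vectors over the candidates.
#' @return correlation coefficient.
#' @export
gebv_accuracy <- function(ebv, tbv) {
  stopifnot(length(ebv) == length(tbv))
  if (stats::sd(ebv) == 0 || stats::sd(tbv) == 0) {
    stop("gebv_accuracy: zero variance in EBV or TBV")
  }
  stats::cor(ebv, tbv)
}

#' Response to selection
#'
#' Mean TBV of the top `n_selected` candidates by EBV minus the mean TBV of
#' the whole candidate cohort (trait units; kits for litter size). Ties are
#' broken by candidate id.
#'
#' @param tbv true breeding values of the candidates.
#' @param ebv estimated breeding values used for ranking.
#' @param n_selected selected candidates.
#' @param ids candidate ids for tie-breaking (defaults to position).
#' @return selection response in trait units.
#' @export
selection_response <- function(tbv, ebv, n_selected = 150,
                               ids = seq_along(tbv)) {
  stopifnot(length(tbv) == length(ebv), n_selected <= length(tbv))
  top <- order(-ebv, ids)[seq_len(n_selected)]
  mean(tbv[top]) - mean(tbv)
}

#' Percentage of candidates correctly selected
#'
#' Overlap between the EBV-top-n and the TBV-top-n sets, as a percentage of
#' n; under random ranking the expectation is the hypergeometric baseline
#' `100 * n / N`.
#'
#' @param ebv,tbv ranking vectors over the candidates.
#' @param n_selected size of the selected set.
#' @param ids candidate ids for tie-breaking.
#' @return percentage in \[0, 100\].
#' @export
percent_correctly_selected <- function(ebv, tbv, n_selected = 150,
                                       ids = seq_along(tbv)) {
  stopifnot(length(tbv) == length(ebv), n_selected <= length(tbv))
  top_e <- order(-ebv, ids)[seq_len(n_selected)]
  top_t <- order(-tbv, ids)[seq_len(n_selected)]
  100 * length(intersect(top_e, top_t)) / n_selected
}

#' Summarise scenario outcomes over replicates
#'
#' Per-scenario means and standard errors of the endpoint metrics, the
#' accuracy difference to the pedigree-BLUP control within each replicate,
#' and the fraction of replicates in which each scenario beats BLUP.
#'
#' @param outcomes data.frame of per-replicate scenario outcomes (from
#'   [run_experiment()]): columns `scenario`, `replicate`, `qtn_model`,
#'   `accuracy`, `response`, `pct_correct`, `mean_ia`, `mean_yield`, `cost`.
#' @return list with `summary` (per scenario: mean and SE columns; SE is NA
#'   with a single replicate), `delta_accuracy` (per replicate, scenario
#'   minus BLUP) and `beats_blup` (fraction of replicates).
#' @export
summarize_outcomes <- function(outcomes) {
  stopifnot(nrow(outcomes) > 0)
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  agg <- function(d) {
    data.frame(scenario = d$scenario[1],
               n_replicates = nrow(d),
               accuracy = mean(d$accuracy, na.rm = TRUE),
               accuracy_se = se(d$accuracy),
               response = mean(d$response, na.rm = TRUE),
               response_se = se(d$response),
               pct_correct = mean(d$pct_correct, na.rm = TRUE),
               pct_correct_se = se(d$pct_correct),
               mean_ia = mean(d$mean_ia, na.rm = TRUE),
               mean_yield = mean(d$mean_yield, na.rm = TRUE),
               cost = mean(d$cost, na.rm = TRUE))
  }
  summ <- do.call(rbind, lapply(split(outcomes, outcomes$scenario), agg))
  rownames(summ) <- NULL
  blup <- outcomes[outcomes$scenario == "BLUP",
                   c("replicate", "qtn_model", "accuracy")]
  delta <- NULL
  beats <- NULL
  if (nrow(blup) > 0) {
    names(blup)[3] <- "accuracy_blup"
    delta <- merge(outcomes[outcomes$scenario != "BLUP", ], blup,
                   by = c("replicate", "qtn_model"))
    delta$delta_accuracy <- delta$accuracy - delta$accuracy_blup
    delta <- delta[, c("replicate", "qtn_model", "scenario",
                       "delta_accuracy")]
    beats <- vapply(split(delta, delta$scenario),
                    function(d) mean(d$delta_accuracy > 0), numeric(1))
  }
  list(summary = summ, delta_accuracy = delta, beats_blup = beats)
}
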