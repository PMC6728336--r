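# Behavioral analyses: choice-RT summaries with the 1500 ms cutoff,
# verbal-test eligibility, and the consistency score for nonpredictive
# predictions.

#' Choice-RT summary with cutoff exclusion
#'
#' Trials with missing RT or RT above the cutoff are excluded; the boundary
#' value (RT equal to the cutoff) is included, matching the (0, 1500] ms
#' response-window convention.
#'
#' @param trials data.frame with columns `rt` (ms; NA for missed trials),
#'   `timescale`, `predictiveness`.
#' @param cutoff_ms exclusion cutoff in milliseconds.
#' @return data.frame per condition: `timescale`, `predictiveness`,
#'   `mean_rt`, `n`, `n_excluded`.
#' @export
rt_summary <- function(trials, cutoff_ms = 1500) {
  stopifnot(all(c("rt", "timescale", "predictiveness") %in% names(trials)))
  groups <- unique(trials[, c("timescale", "predictiveness")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- trials$timescale == groups$timescale[i] &
      trials$predictiveness == groups$predictiveness[i]
    rt <- trials$rt[sel]
    keep <- !is.na(rt) & rt <= cutoff_ms
    if (!any(keep)) {
      stop(sprintf("all trials excluded in condition %s",
                   cond_key(groups$timescale[i], groups$predictiveness[i])),
           call. = FALSE)
    }
    data.frame(timescale = groups$timescale[i],
               predictiveness = groups$predictiveness[i],
               mean_rt = mean(rt[keep]), n = sum(keep),
               n_excluded = sum(!keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Verbal-test eligibility
#'
#' A participant is eligible for the scan only with 100% accuracy on
#' predictive sequences in every required verbal test; a failed test may be
#' repeated once, and the retake replaces the original.
#'
#' @param verbal list of verbal test results (as in `bc_behavior$verbal`):
#'   each with `trials` (columns `predictiveness`, `response`,
#'   `correct_outcome`) and `attempts`.
#' @param required timepoints that must be present and passed.
#' @return TRUE iff every required test's (final-attempt) predictive
#'   responses are all correct with at most one retake.
#' @export
eligibility <- function(verbal,
                        required = c("train1", "train2", "prescan_set1",
                                     "prescan_set2")) {
  have <- vapply(verbal, function(v) v$timepoint, character(1))
  missing <- setdiff(required, have)
  if (length(missing)) {
    stop("missing verbal test(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  all(vapply(verbal[match(required, have)], function(v) {
    tr <- v$trials
    pred <- tr$predictiveness == "predictive"
    v$attempts <= 2L && all(tr$response[pred] == tr$correct_outcome[pred])
  }, logical(1)))
}

#' Consistency of verbal predictions for nonpredictive actions
#'
#' For each of the four nonpredictive cue-action combinations of one
#' timescale, the pre- and post-scan tests contribute two responses each
#' (four in total); the combination's consistency is the modal-outcome
#' proportion `max(k, 4 - k) / 4`, and the score is the mean over the four
#' combinations. A participant is fully consistent iff every combination
#' maps to a single outcome on all four responses.
#'
#' @param pre_test,post_test verbal test results for the same stimulus set
#'   (pre- and post-scan).
#' @return Object of class `bc_consistency`: `timescale`, `value` (in
#'   `[0.5, 1]`), `fully_consistent`, and the per-combination table.
#' @export
consistency_score <- function(pre_test, post_test) {
  tr <- rbind(
    pre_test$trials[pre_test$trials$predictiveness == "nonpredictive", ],
    post_test$trials[post_test$trials$predictiveness == "nonpredictive", ])
  if (!is.null(pre_test$set) && !is.null(post_test$set) &&
      pre_test$set != post_test$set) {
    stop("pre and post tests cover different stimulus sets", call. = FALSE)
  }
  combos <- unique(tr[, c("cue", "action")])
  per_combo <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- tr$cue == combos$cue[i] & tr$action == combos$action[i]
    resp <- tr$response[sel]
    if (length(resp) != 4L || anyNA(resp)) {
      stop(sprintf("expected 4 responses for combination %s/%s",
                   combos$cue[i], combos$action[i]), call. = FALSE)
    }
    k <- max(table(resp))
    data.frame(cue = combos$cue[i], action = combos$action[i],
               modal_proportion = max(k, 4 - k) / 4,
               stringsAsFactors = FALSE)
  })
  per_combo <- do.call(rbind, per_combo)
  if (nrow(per_combo) != 4L) {
    stop("expected 4 nonpredictive cue-action combinations", call. = FALSE)
  }
  value <- mean(per_combo$modal_proportion)
  structure(list(timescale = pre_test$timescale, value = value,
                 fully_consistent = all(per_combo$modal_proportion == 1),
                 per_combo = per_combo),
            class = "bc_consistency")
}
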