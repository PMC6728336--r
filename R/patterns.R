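# Multivoxel pattern similarity between cue-outcome transitions: within-cue
# (same cue, different outcomes) vs across-cue (disjoint stimuli), with
# trial-count balancing and the resampled split control.

# Transition label of each trial under a labeling scheme. In the primary
# ("averaged") scheme predictive transitions keep (cue, action) identity
# while nonpredictive transitions collapse across actions to (cue, outcome)
# identity, which balances the observation counts per pattern. The "split"
# scheme resolves nonpredictive transitions by action and splits predictive
# trials into random partitions so both conditions are estimated from ~2.5
# trials per run.
transition_label <- function(trials, scheme = c("averaged", "split"),
                             partition = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "averaged") {
    ifelse(trials$predictiveness == "predictive",
           paste(trials$cue, trials$action, sep = "."),
           trials$outcome)
  } else {
    if (is.null(partition)) stop("'partition' required for the split scheme")
    ifelse(trials$predictiveness == "predictive",
           paste(trials$cue, trials$action, partition, sep = "."),
           paste(trials$cue, trials$action, trials$outcome, sep = "."))
  }
}

# Random a/b partition of the predictive trials of one run, per (cue,
# action); redrawn (bounded retries) if a partition would be empty.
split_partition <- function(trials, max_retries = 20L) {
  part <- rep(NA_character_, nrow(trials))
  pred <- which(trials$predictiveness == "predictive" &
                  !(!is.na(trials$predicted) & !trials$predicted))
  combos <- unique(trials[pred, c("cue", "action")])
  for (i in seq_len(nrow(combos))) {
    rows <- pred[trials$cue[pred] == combos$cue[i] &
                   trials$action[pred] == combos$action[i]]
    for (try in seq_len(max_retries)) {
      p <- sample(c("a", "b"), length(rows), replace = TRUE)
      if (length(rows) < 2L || length(unique(p)) == 2L) break
      if (try == max_retries) {
        stop("could not draw a non-empty partition", call. = FALSE)
      }
    }
    part[rows] <- p
  }
  part
}

# Label metadata for one stimulus set under a scheme.
label_meta <- function(design, set, scheme = c("averaged", "split")) {
  scheme <- match.arg(scheme)
  cues <- design$cues[design$cues$set == set, ]
  rows <- list()
  for (i in seq_len(nrow(cues))) {
    cu <- cues$cue[i]
    pr <- cues$predictiveness[i]
    if (scheme == "averaged") {
      if (pr == "predictive") {
        for (a in c("left", "right")) {
          rows[[length(rows) + 1L]] <- data.frame(
            label = paste(cu, a, sep = "."), cue = cu, predictiveness = pr,
            action = a, outcome = dominant_outcome(cu, a),
            partition = NA_character_, stringsAsFactors = FALSE)
        }
      } else {
        for (o in c(cues$outcome1[i], cues$outcome2[i])) {
          rows[[length(rows) + 1L]] <- data.frame(
            label = o, cue = cu, predictiveness = pr, action = NA_character_,
            outcome = o, partition = NA_character_, stringsAsFactors = FALSE)
        }
      }
    } else {
      if (pr == "predictive") {
        for (a in c("left", "right")) for (p in c("a", "b")) {
          rows[[length(rows) + 1L]] <- data.frame(
            label = paste(cu, a, p, sep = "."), cue = cu,
            predictiveness = pr, action = a,
            outcome = dominant_outcome(cu, a), partition = p,
            stringsAsFactors = FALSE)
        }
      } else {
        for (a in c("left", "right")) {
          for (o in c(cues$outcome1[i], cues$outcome2[i])) {
            rows[[length(rows) + 1L]] <- data.frame(
              label = paste(cu, a, o, sep = "."), cue = cu,
              predictiveness = pr, action = a, outcome = o,
              partition = NA_character_, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Average beta patterns across runs
#'
#' Run-wise parameter estimates for each transition are averaged into one
#' voxel pattern per transition before similarity is computed.
#'
#' @param beta_list list of `bc_betas` (one per run of the same stimulus
#'   set).
#' @param meta label metadata (as built internally from the design); rows
#'   define the patterns to keep.
#' @param require_all_runs if TRUE, a label absent from any run is excluded
#'   with a warning; if FALSE, a label is averaged over the runs where it
#'   was estimable.
#' @return Object of class `bc_patterns`: `patterns` (labels x voxels),
#'   `meta`, `counts` (mean trials per run contributing to each pattern).
#' @export
average_betas <- function(beta_list, meta, require_all_runs = TRUE) {
  stopifnot(length(beta_list) >= 1L)
  labels <- meta$label
  present <- sapply(beta_list, function(b) labels %in% rownames(b$betas))
  present <- matrix(present, nrow = length(labels))
  keep <- if (require_all_runs) rowSums(present) == ncol(present) else
    rowSums(present) > 0L
  if (any(!keep)) {
    warning("excluding pattern(s) missing from ",
            if (require_all_runs) "some run(s): " else "all runs: ",
            paste(labels[!keep], collapse = ", "))
  }
  labels <- labels[keep]
  n_vox <- ncol(beta_list[[1]]$betas)
  patterns <- matrix(0, length(labels), n_vox,
                     dimnames = list(labels, NULL))
  counts <- stats::setNames(numeric(length(labels)), labels)
  for (li in seq_along(labels)) {
    lab <- labels[li]
    have <- which(vapply(beta_list,
                         function(b) lab %in% rownames(b$betas), logical(1)))
    patterns[li, ] <- colMeans(do.call(rbind, lapply(
      beta_list[have], function(b) b$betas[lab, , drop = FALSE])))
    counts[li] <- mean(vapply(beta_list[have],
                              function(b) as.numeric(b$counts[[lab]]),
                              numeric(1)))
  }
  structure(list(patterns = patterns, meta = meta[keep, , drop = FALSE],
                 counts = counts),
            class = "bc_patterns")
}

pattern_cor <- function(p1, p2) {
  if (sd(p1) == 0 || sd(p2) == 0) {
    stop("zero-variance pattern", call. = FALSE)
  }
  clipped_fisher(cor(p1, p2))
}

#' Within-cue pattern similarity
#'
#' Fisher-z correlation across voxels between the two transition patterns
#' that share a cue but end in different outcomes, averaged over cues, per
#' predictiveness level.
#'
#' @param patterns a `bc_patterns` (primary averaged scheme).
#' @return Named vector `c(predictive=, nonpredictive=)`.
#' @export
within_cue_similarity <- function(patterns) {
  stopifnot(inherits(patterns, "bc_patterns"))
  meta <- patterns$meta
  out <- vapply(PREDICTIVENESS, function(pr) {
    cues <- unique(meta$cue[meta$predictiveness == pr])
    z <- vapply(cues, function(cu) {
      rows <- which(meta$cue == cu)
      if (length(rows) != 2L) {
        warning("cue ", cu, " lacks two alternative patterns; skipped")
        return(NA_real_)
      }
      pattern_cor(patterns$patterns[rows[1], ], patterns$patterns[rows[2], ])
    }, numeric(1))
    if (all(is.na(z)) && length(z)) {
      stop("expected two alternative patterns per cue (", pr, ")",
           call. = FALSE)
    }
    mean(z, na.rm = TRUE)
  }, numeric(1))
  names(out) <- PREDICTIVENESS
  out
}

#' Across-cue pattern similarity
#'
#' Fisher-z correlation between transition patterns with completely distinct
#' cue and outcome stimuli (and, for predictive actions, different button
#' presses, mirroring the within-cue comparison), averaged over pairings.
#'
#' @param patterns a `bc_patterns` (primary averaged scheme).
#' @return Named vector `c(predictive=, nonpredictive=)` with the pairing
#'   table in attribute `"pairs"`.
#' @export
across_cue_similarity <- function(patterns) {
  stopifnot(inherits(patterns, "bc_patterns"))
  meta <- patterns$meta
  all_pairs <- list()
  out <- vapply(PREDICTIVENESS, function(pr) {
    sub <- meta[meta$predictiveness == pr, , drop = FALSE]
    cues <- unique(sub$cue)
    if (length(cues) == 0L) return(NA_real_)
    if (length(cues) != 2L) {
      stop("across-cue similarity needs exactly two cues per level",
           call. = FALSE)
    }
    a <- sub[sub$cue == cues[1], , drop = FALSE]
    b <- sub[sub$cue == cues[2], , drop = FALSE]
    # pair each pattern of cue 1 with the cue-2 pattern that differs in
    # outcome identity and (for predictive actions) in action
    pairs <- list()
    if (nrow(a) >= 1L && nrow(b) >= 2L) {
      pairs <- c(pairs, list(c(a$label[1], b$label[2])))
    }
    if (nrow(a) >= 2L && nrow(b) >= 1L) {
      pairs <- c(pairs, list(c(a$label[2], b$label[1])))
    }
    all_pairs[[pr]] <<- pairs
    if (!length(pairs)) return(NA_real_)
    z <- vapply(pairs, function(p) {
      pattern_cor(patterns$patterns[p[1], ], patterns$patterns[p[2], ])
    }, numeric(1))
    mean(z)
  }, numeric(1))
  names(out) <- PREDICTIVENESS
  attr(out, "pairs") <- all_pairs
  out
}

# Per-run event table for the pattern GLM.
pattern_events <- function(design, run_index, scheme = "averaged",
                           rt = NULL, partition = NULL) {
  tr <- design$runs[[run_index]]$trials
  ev <- data.frame(
    onset = tr$onset,
    regressor = transition_label(tr, scheme, partition),
    predicted = tr$predicted,
    stringsAsFactors = FALSE
  )
  if (!is.null(rt) && length(rt) == nrow(tr)) ev$rt <- rt
  ev
}

#' Pattern similarity for one ROI of a simulated participant
#'
#' Fits the event-related GLM in every run (8 transition regressors plus
#' temporal derivatives, counter-predicted and missed regressors, motion
#' covariates), averages betas across the runs of each stimulus set, and
#' computes within- and across-cue similarity per condition.
#'
#' @param bold a `bc_bold`.
#' @param roi `"hippocampus"` or `"evc"`.
#' @param behavior optional `bc_behavior`; its scan RTs set trial durations
#'   and missed trials.
#' @param highpass,cutoff drift handling for the GLM confounds.
#' @return Object of class `bc_similarity`: data.frame `cells` with columns
#'   `timescale`, `predictiveness`, `type` (within_cue / across_cue), `z`;
#'   plus `counts` per pattern and `variant = "averaged"`.
#' @export
pattern_similarity <- function(bold, roi = c("hippocampus", "evc"),
                               behavior = NULL, highpass = TRUE,
                               cutoff = 128) {
  roi <- match.arg(roi)
  design <- bold$design
  cfg <- design$config
  betas_by_set <- split_run_betas(bold, roi, behavior, "averaged", NULL,
                                  highpass, cutoff)
  cells <- NULL
  counts <- list()
  for (s in names(betas_by_set)) {
    set <- as.integer(sub("set", "", s))
    ts <- rep(TIMESCALES, length.out = cfg$n_sets)[set]
    meta <- label_meta(design, set, "averaged")
    # a transition occasionally has no trials in one run (random outcomes);
    # average over the runs where it was estimable
    pat <- average_betas(betas_by_set[[s]], meta, require_all_runs = FALSE)
    wi <- within_cue_similarity(pat)
    ac <- across_cue_similarity(pat)
    cells <- rbind(cells,
      data.frame(timescale = ts, predictiveness = PREDICTIVENESS,
                 type = "within_cue", z = as.numeric(wi),
                 stringsAsFactors = FALSE),
      data.frame(timescale = ts, predictiveness = PREDICTIVENESS,
                 type = "across_cue", z = as.numeric(ac),
                 stringsAsFactors = FALSE))
    counts[[s]] <- pat$counts
  }
  structure(list(cells = cells, counts = counts, variant = "averaged"),
            class = "bc_similarity")
}

# Fit the event GLM for every run, grouped by stimulus set.
split_run_betas <- function(bold, roi, behavior, scheme, partitions,
                            highpass, cutoff) {
  design <- bold$design
  cfg <- design$config
  out <- list()
  for (r in seq_along(bold$runs)) {
    run_des <- design$runs[[r]]
    rt <- NULL
    if (!is.null(behavior)) {
      sc <- behavior$scan
      rt <- sc$rt[sc$run == r]
    }
    ev <- pattern_events(design, r, scheme, rt,
                         if (is.null(partitions)) NULL else partitions[[r]])
    confounds <- if (highpass) {
      dct_basis(cfg$n_timepoints, cfg$TR, cutoff)
    } else NULL
    meta <- label_meta(design, run_des$set, scheme)
    b <- fit_event_glm(bold$runs[[r]][[roi]], ev, cfg,
                       nuisance = as.matrix(
                         bold$runs[[r]]$nuisance[, 1:6]),
                       confounds = confounds, labels = meta$label)
    key <- paste0("set", run_des$set)
    out[[key]] <- c(out[[key]], list(b))
  }
  out
}

#' Resampled split-control pattern similarity
#'
#' Control analysis in which nonpredictive transitions are modeled per
#' (cue, action, outcome) sequence and predictive trials are randomly
#' resampled into two partitions, so each pattern rests on ~2.5 trials per
#' run in both conditions. Within-cue similarity is then measured between
#' sequences sharing a cue but differing in both action and outcome
#' (nonpredictive), and within each partition across actions (predictive),
#' averaging correlations afterwards.
#'
#' @param bold a `bc_bold`.
#' @param roi `"hippocampus"` or `"evc"`.
#' @param seed seed for the random partitions.
#' @param behavior optional `bc_behavior` for RTs/missed trials.
#' @param highpass,cutoff drift handling.
#' @return Object of class `bc_similarity` with `variant = "split"` and
#'   within-cue cells only.
#' @export
resampled_split_similarity <- function(bold, roi = c("hippocampus", "evc"),
                                       seed = 1L, behavior = NULL,
                                       highpass = TRUE, cutoff = 128) {
  roi <- match.arg(roi)
  design <- bold$design
  cfg <- design$config
  partitions <- with_seed(seed, {
    lapply(design$runs, function(run) split_partition(run$trials))
  })
  betas_by_set <- split_run_betas(bold, roi, behavior, "split", partitions,
                                  highpass, cutoff)
  cells <- NULL
  counts <- list()
  for (s in names(betas_by_set)) {
    set <- as.integer(sub("set", "", s))
    ts <- rep(TIMESCALES, length.out = cfg$n_sets)[set]
    meta <- label_meta(design, set, "split")
    pat <- average_betas(betas_by_set[[s]], meta, require_all_runs = FALSE)
    m <- pat$meta

    z_nonpred <- local({
      cues <- unique(m$cue[m$predictiveness == "nonpredictive"])
      zz <- unlist(lapply(cues, function(cu) {
        sub <- m[m$cue == cu, , drop = FALSE]
        pairs <- list()
        for (i in seq_len(nrow(sub))) for (j in seq_len(nrow(sub))) {
          if (i < j && sub$action[i] != sub$action[j] &&
              sub$outcome[i] != sub$outcome[j]) {
            pairs <- c(pairs, list(c(sub$label[i], sub$label[j])))
          }
        }
        vapply(pairs, function(p) {
          pattern_cor(pat$patterns[p[1], ], pat$patterns[p[2], ])
        }, numeric(1))
      }))
      mean(zz)
    })

    z_pred <- local({
      cues <- unique(m$cue[m$predictiveness == "predictive"])
      zz <- unlist(lapply(cues, function(cu) {
        vapply(c("a", "b"), function(p) {
          rows <- which(m$cue == cu & m$partition == p)
          if (length(rows) != 2L) return(NA_real_)
          pattern_cor(pat$patterns[rows[1], ], pat$patterns[rows[2], ])
        }, numeric(1))
      }))
      mean(zz, na.rm = TRUE)
    })

    cells <- rbind(cells, data.frame(
      timescale = ts, predictiveness = PREDICTIVENESS,
      type = "within_cue", z = c(z_pred, z_nonpred),
      stringsAsFactors = FALSE))
    counts[[s]] <- pat$counts
  }
  structure(list(cells = cells, counts = counts, variant = "split",
                 seed = seed),
            class = "bc_similarity")
}
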