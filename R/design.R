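#' Configuration of the scanning design
#'
#' Captures every timing and probability parameter of the blocked 2x2 design:
#' cue-action-outcome trials are organized into blocks of a single
#' predictiveness level, blocks alternate within a run, and runs alternate
#' between the two trained stimulus sets (3-day delay vs no delay). Defaults
#' reproduce the study layout: eight 330 s runs (6 s lead-in + 8 blocks of
#' 22.5 s + 18 s fixation) at TR 1.5 s, five trials per block paced every
#' 4.5 s, 95/5 outcome contingencies for predictive actions and 50/50 for
#' nonpredictive actions.
#'
#' @param TR repetition time in seconds.
#' @param n_runs number of scanner runs (must be a multiple of `n_sets`).
#' @param n_sets number of stimulus sets presented in alternating runs.
#' @param blocks_per_run number of blocks per run (even; the two
#'   predictiveness levels alternate).
#' @param trials_per_block trials within each block.
#' @param block_duration block length in seconds.
#' @param fixation_duration fixation period after each block, seconds.
#' @param lead_in rest at the start of each run, seconds.
#' @param p_dominant probability that a predictive action yields its dominant
#'   outcome.
#' @param p_first probability of the first outcome for nonpredictive trials.
#' @param cue_duration,outcome_duration,response_window trial component
#'   durations in seconds.
#' @return An object of class `bc_design_config`.
#' @export
design_config <- function(TR = 1.5, n_runs = 8, n_sets = 2,
                          blocks_per_run = 8, trials_per_block = 5,
                          block_duration = 22.5, fixation_duration = 18,
                          lead_in = 6, p_dominant = 0.95, p_first = 0.5,
                          cue_duration = 1, outcome_duration = 1,
                          response_window = 1.5) {
  for (nm in c("TR", "n_runs", "n_sets", "blocks_per_run", "trials_per_block",
               "block_duration", "fixation_duration", "cue_duration",
               "outcome_duration", "response_window")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (lead_in < 0) stop("'lead_in' must be non-negative", call. = FALSE)
  if (n_runs %% n_sets != 0) {
    stop("'n_runs' must be a multiple of 'n_sets'", call. = FALSE)
  }
  if (blocks_per_run %% 2 != 0) {
    stop("'blocks_per_run' must be even (conditions alternate)", call. = FALSE)
  }
  if (p_dominant <= 0 || p_dominant > 1 || p_first <= 0 || p_first >= 1) {
    stop("outcome probabilities must lie in (0, 1)", call. = FALSE)
  }
  cfg <- list(
    TR = TR, n_runs = as.integer(n_runs), n_sets = as.integer(n_sets),
    blocks_per_run = as.integer(blocks_per_run),
    trials_per_block = as.integer(trials_per_block),
    block_duration = block_duration, fixation_duration = fixation_duration,
    lead_in = lead_in, p_dominant = p_dominant, p_first = p_first,
    cue_duration = cue_duration, outcome_duration = outcome_duration,
    response_window = response_window,
    trial_spacing = block_duration / trials_per_block
  )
  cfg$run_duration <- lead_in +
    blocks_per_run * (block_duration + fixation_duration)
  n_tp <- cfg$run_duration / TR
  if (abs(n_tp - round(n_tp)) > 1e-9) {
    stop("run duration must be an integer number of TRs", call. = FALSE)
  }
  cfg$n_timepoints <- as.integer(round(n_tp))
  structure(cfg, class = "bc_design_config")
}

# Stimulus inventory for one set: two predictive and two nonpredictive cues,
# each with two outcomes (12 images per set).
set_cue_table <- function(set) {
  cue <- sprintf("s%d_%s", set, c("P1", "P2", "N1", "N2"))
  data.frame(
    set = set, cue = cue,
    predictiveness = rep(PREDICTIVENESS, each = 2),
    outcome1 = paste0(cue, "_o1"), outcome2 = paste0(cue, "_o2"),
    stringsAsFactors = FALSE
  )
}

# Dominant outcome of a predictive (cue, action) pairing: left -> outcome1,
# right -> outcome2.
dominant_outcome <- function(cue, action) {
  ifelse(action == "left", paste0(cue, "_o1"), paste0(cue, "_o2"))
}

#' Sample trial outcomes under the trained contingencies
#'
#' Applies the generative outcome rule of the task: predictive actions yield
#' their dominant outcome with probability `p_dominant`, nonpredictive
#' actions yield either outcome of the cue with probability `p_first` /
#' `1 - p_first` irrespective of the action.
#'
#' @param n number of trials to sample.
#' @param predictive logical; predictive or nonpredictive contingency.
#' @param p_dominant,p_first contingency parameters.
#' @param seed optional seed for a self-contained draw.
#' @return Integer vector of outcome indices (1 or 2). For predictive trials
#'   index 1 is the action's dominant outcome.
#' @export
sample_outcomes <- function(n, predictive = FALSE, p_dominant = 0.95,
                            p_first = 0.5, seed = NULL) {
  stopifnot(n >= 1)
  p <- if (predictive) p_dominant else p_first
  draw <- function() ifelse(runif(n) < p, 1L, 2L)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Trials for one run template (shared within a matched run pair). Returns a
# data.frame of trials in presentation order plus the block table.
build_run_template <- function(config, cues_set, timescale) {
  nb <- config$blocks_per_run
  tpb <- config$trials_per_block
  start <- sample(PREDICTIVENESS, 1L)
  block_cond <- rep(c(start, setdiff(PREDICTIVENESS, start)), length.out = nb)
  block_onset <- config$lead_in +
    (seq_len(nb) - 1L) * (config$block_duration + config$fixation_duration)
  blocks <- data.frame(block = seq_len(nb), onset = block_onset,
                       duration = config$block_duration,
                       predictiveness = block_cond, stringsAsFactors = FALSE)

  trials <- vector("list", nb)
  for (cond in PREDICTIVENESS) {
    idx <- which(block_cond == cond)
    if (!length(idx)) next
    n_c <- length(idx) * tpb
    cue_pool <- cues_set$cue[cues_set$predictiveness == cond]
    cue_seq <- sample(rep(cue_pool, length.out = n_c))
    action_seq <- character(n_c)
    for (cu in cue_pool) {
      k <- which(cue_seq == cu)
      action_seq[k] <- sample(rep(c("left", "right"), length.out = length(k)))
    }
    if (cond == "predictive") {
      outcome <- dominant_outcome(cue_seq, action_seq)
      predicted <- rep(TRUE, n_c)
    } else {
      oidx <- sample_outcomes(n_c, predictive = FALSE,
                              p_first = config$p_first)
      outcome <- ifelse(oidx == 1L, paste0(cue_seq, "_o1"),
                        paste0(cue_seq, "_o2"))
      predicted <- rep(NA, n_c)  # undefined for nonpredictive actions
    }
    for (j in seq_along(idx)) {
      b <- idx[j]
      sl <- ((j - 1L) * tpb + 1L):(j * tpb)
      trials[[b]] <- data.frame(
        block = b,
        onset = block_onset[b] + (seq_len(tpb) - 1L) * config$trial_spacing,
        timescale = timescale, predictiveness = cond,
        cue = cue_seq[sl], action = action_seq[sl], outcome = outcome[sl],
        predicted = predicted[sl], stringsAsFactors = FALSE
      )
    }
  }
  trials <- do.call(rbind, trials)
  trials <- trials[order(trials$onset), , drop = FALSE]

  # Exactly one counter-predicted trial per run, inside a predictive block.
  pred_rows <- which(trials$predictiveness == "predictive")
  if (length(pred_rows)) {
    pick <- pred_rows[sample.int(length(pred_rows), 1L)]
    cu <- trials$cue[pick]
    other <- ifelse(trials$action[pick] == "left",
                    paste0(cu, "_o2"), paste0(cu, "_o1"))
    trials$outcome[pick] <- other
    trials$predicted[pick] <- FALSE
  }
  rownames(trials) <- NULL
  list(blocks = blocks, trials = trials)
}

# Training-phase trial lists for one set (exploratory then directed).
build_training_phase <- function(config, cues_set, n_exploratory = 320,
                                 n_directed = 160) {
  one_phase <- function(n, phase) {
    cue <- sample(rep(cues_set$cue, length.out = n))
    pred <- cues_set$predictiveness[match(cue, cues_set$cue)]
    action <- sample(c("left", "right"), n, replace = TRUE)
    oidx <- integer(n)
    is_p <- pred == "predictive"
    if (any(is_p)) {
      oidx[is_p] <- sample_outcomes(sum(is_p), predictive = TRUE,
                                    p_dominant = config$p_dominant)
    }
    if (any(!is_p)) {
      oidx[!is_p] <- sample_outcomes(sum(!is_p), predictive = FALSE,
                                     p_first = config$p_first)
    }
    # For predictive trials index 1 means the dominant outcome of the action.
    outcome <- ifelse(is_p,
      ifelse(oidx == 1L, dominant_outcome(cue, action),
             dominant_outcome(cue, ifelse(action == "left", "right", "left"))),
      ifelse(oidx == 1L, paste0(cue, "_o1"), paste0(cue, "_o2")))
    data.frame(phase = phase, trial = seq_len(n), cue = cue,
               predictiveness = pred, action = action, outcome = outcome,
               stringsAsFactors = FALSE)
  }
  rbind(one_phase(n_exploratory, "exploratory"),
        one_phase(n_directed, "directed"))
}

#' Build the full experimental design
#'
#' Deterministically (given `seed`) generates the trial-level design of the
#' scan task: runs alternate between stimulus sets, blocks of predictive and
#' nonpredictive actions alternate within each run, cue order and actions are
#' randomized and balanced, nonpredictive outcomes are sampled 50/50, and
#' exactly one predictive trial per run receives the counter-predicted
#' outcome. Matched run pairs (consecutive runs of the same set) share block
#' order and trial tables so that evoked responses are identical across the
#' pair. Verbal tests and training-phase trial lists are attached.
#'
#' @param config a [design_config()].
#' @param seed integer seed.
#' @return An object of class `bc_design` with elements `config`, `cues`,
#'   `runs` (each with `$blocks` and `$trials`), `matched_run_pairs`,
#'   `verbal_tests`, `training_phases`, and `seed`.
#' @export
build_design <- function(config = design_config(), seed = 1L) {
  stopifnot(inherits(config, "bc_design_config"))
  seeds <- derive_seeds(seed, c("runs", "verbal"))
  cues <- do.call(rbind, lapply(seq_len(config$n_sets), set_cue_table))

  runs_per_set <- config$n_runs / config$n_sets
  run_set <- ((seq_len(config$n_runs) - 1L) %% config$n_sets) + 1L
  timescale_of_set <- rep(TIMESCALES, length.out = config$n_sets)

  runs <- vector("list", config$n_runs)
  pairs <- list()
  with_seed(seeds[["runs"]], {
    for (s in seq_len(config$n_sets)) {
      set_runs <- which(run_set == s)
      i <- 1L
      while (i <= length(set_runs)) {
        members <- set_runs[i:min(i + 1L, length(set_runs))]
        tmpl <- build_run_template(config, cues[cues$set == s, ],
                                   timescale_of_set[s])
        for (r in members) {
          tr <- tmpl$trials
          tr$run <- r
          runs[[r]] <- list(index = r, set = s,
                            timescale = timescale_of_set[s],
                            blocks = tmpl$blocks, trials = tr)
        }
        if (length(members) == 2L) pairs[[length(pairs) + 1L]] <- members
        i <- i + 2L
      }
    }
  })

  design <- structure(list(
    config = config, cues = cues, runs = runs,
    matched_run_pairs = pairs, verbal_tests = NULL,
    training_phases = NULL, seed = seed
  ), class = "bc_design")

  with_seed(seeds[["verbal"]], {
    design$verbal_tests <- build_verbal_tests(design)
    design$training_phases <- lapply(seq_len(config$n_sets), function(s) {
      build_training_phase(config, cues[cues$set == s, ])
    })
    names(design$training_phases) <- timescale_of_set
  })
  design
}

#' @export
print.bc_design <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<bc_design> %d runs x %d blocks x %d trials (%d total), TR %.2g s\n",
    cfg$n_runs, cfg$blocks_per_run, cfg$trials_per_block,
    cfg$n_runs * cfg$blocks_per_run * cfg$trials_per_block, cfg$TR))
  cat(sprintf("  block %.1f s + fixation %.1f s, run %.0f s (%d TRs)\n",
              cfg$block_duration, cfg$fixation_duration, cfg$run_duration,
              cfg$n_timepoints))
  cat(sprintf("  matched run pairs: %s\n",
              paste(vapply(x$matched_run_pairs,
                           function(p) paste(p, collapse = "-"), ""),
                    collapse = ", ")))
  invisible(x)
}

#' All scan trials of a design as one table
#'
#' @param design a `bc_design`.
#' @return data.frame with one row per trial across runs.
#' @export
design_trials <- function(design) {
  stopifnot(inherits(design, "bc_design"))
  out <- do.call(rbind, lapply(design$runs, function(r) r$trials))
  rownames(out) <- NULL
  out
}

#' Build verbal outcome-identification tests
#'
#' Each test covers one stimulus set with 16 trials: two trials for every
#' cue-action sequence (4 cues x 2 actions), predictive and nonpredictive
#' intermixed in random order. Six tests span the study timeline: one during
#' each training session, and pre-/post-scan tests for each set.
#'
#' @param design a `bc_design`.
#' @return List of `bc_verbal_test` objects (fields `timepoint`, `set`,
#'   `timescale`, `trials`).
#' @export
build_verbal_tests <- function(design) {
  stopifnot(inherits(design, "bc_design"))
  cues <- design$cues
  timescale_of_set <- rep(TIMESCALES, length.out = design$config$n_sets)
  for (s in unique(cues$set)) {
    cs <- cues[cues$set == s, ]
    if (sum(cs$predictiveness == "predictive") != 2L ||
        sum(cs$predictiveness == "nonpredictive") != 2L) {
      stop("cue inventory must contain 2 predictive and 2 nonpredictive ",
           "cues per set", call. = FALSE)
    }
  }
  one_test <- function(timepoint, s) {
    cs <- cues[cues$set == s, ]
    grid <- expand.grid(cue = cs$cue, action = c("left", "right"),
                        rep = 1:2, stringsAsFactors = FALSE)
    grid$predictiveness <- cs$predictiveness[match(grid$cue, cs$cue)]
    grid$correct_outcome <- ifelse(grid$predictiveness == "predictive",
                                   dominant_outcome(grid$cue, grid$action),
                                   NA_character_)
    top_first <- runif(nrow(grid)) < 0.5
    grid$top_outcome <- ifelse(top_first, paste0(grid$cue, "_o1"),
                               paste0(grid$cue, "_o2"))
    grid$bottom_outcome <- ifelse(top_first, paste0(grid$cue, "_o2"),
                                  paste0(grid$cue, "_o1"))
    grid$rep <- NULL
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    rownames(grid) <- NULL
    structure(list(timepoint = timepoint, set = s,
                   timescale = timescale_of_set[s], trials = grid),
              class = "bc_verbal_test")
  }
  sets <- seq_len(design$config$n_sets)
  tests <- list()
  for (s in sets) tests[[paste0("train", s)]] <- one_test(paste0("train", s), s)
  for (s in sets) {
    tests[[paste0("prescan_set", s)]] <- one_test(paste0("prescan_set", s), s)
  }
  for (s in sets) {
    tests[[paste0("postscan_set", s)]] <-
      one_test(paste0("postscan_set", s), s)
  }
  tests
}
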