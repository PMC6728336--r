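#' Behavioral generator parameters
#'
#' @param rt_mean per-condition mean choice RT in ms (named by condition key
#'   or scalar). Defaults encode the study's behavioral profile: equal RTs
#'   immediately after training, faster predictive than nonpredictive RTs
#'   after the 3-day delay.
#' @param rt_sd trial-level RT standard deviation in ms.
#' @param training_slowdown ms added to training-session RTs (self-paced,
#'   not limited by the 1500 ms response window).
#' @param miss_prob probability of failing to respond within the window on a
#'   scanner trial.
#' @param verbal_accuracy probability of a correct verbal response for
#'   predictive sequences.
#' @param consistency per-timescale propensity to give the participant's
#'   preferred outcome for a nonpredictive cue-action combination (named
#'   `day3`, `nodelay`).
#' @return An object of class `bc_behavior_params`.
#' @export
behavior_params <- function(rt_mean = c(day3.predictive = 680,
                                        day3.nonpredictive = 770,
                                        nodelay.predictive = 725,
                                        nodelay.nonpredictive = 720),
                            rt_sd = 150, training_slowdown = 120,
                            miss_prob = 0.02, verbal_accuracy = 1,
                            consistency = c(day3 = 0.88, nodelay = 0.95)) {
  rt_mean <- cond_vector(rt_mean, "rt_mean")
  if (rt_sd < 0) stop("'rt_sd' must be non-negative", call. = FALSE)
  if (miss_prob < 0 || miss_prob >= 1) {
    stop("'miss_prob' must lie in [0, 1)", call. = FALSE)
  }
  if (verbal_accuracy < 0 || verbal_accuracy > 1) {
    stop("'verbal_accuracy' must lie in [0, 1]", call. = FALSE)
  }
  if (!all(TIMESCALES %in% names(consistency))) {
    stop("'consistency' must be named with: ",
         paste(TIMESCALES, collapse = ", "), call. = FALSE)
  }
  if (any(consistency < 0 | consistency > 1)) {
    stop("'consistency' propensities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(rt_mean = rt_mean, rt_sd = rt_sd,
                 training_slowdown = training_slowdown,
                 miss_prob = miss_prob, verbal_accuracy = verbal_accuracy,
                 consistency = as.numeric(consistency[TIMESCALES]) |>
                   stats::setNames(TIMESCALES)),
            class = "bc_behavior_params")
}

# One verbal test attempt given the participant's nonpredictive preferences.
verbal_attempt <- function(test, params, prefs) {
  tr <- test$trials
  response <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    o1 <- paste0(tr$cue[i], "_o1")
    o2 <- paste0(tr$cue[i], "_o2")
    if (tr$predictiveness[i] == "predictive") {
      correct <- tr$correct_outcome[i]
      other <- setdiff(c(o1, o2), correct)
      response[i] <- if (runif(1) < params$verbal_accuracy) correct else other
    } else {
      key <- paste(tr$cue[i], tr$action[i], sep = ".")
      pref <- prefs[[key]]
      other <- setdiff(c(o1, o2), pref)
      p <- params$consistency[[test$timescale]]
      response[i] <- if (runif(1) < p) pref else other
    }
  }
  tr$response <- response
  tr
}

#' Simulate choice RTs and verbal-test responses
#'
#' Scanner RTs are drawn per condition and truncated to the response window
#' (0, 1500] ms, with occasional missed trials; training RTs are self-paced
#' (no truncation) so the 1500 ms analysis cutoff has work to do. Verbal
#' responses are always correct for predictive sequences when
#' `verbal_accuracy = 1`; nonpredictive responses follow a participant-level
#' preferred outcome for each cue-action combination with the per-timescale
#' consistency propensity. A test with a predictive error is repeated once
#' (retake), mirroring the eligibility rule.
#'
#' @param design a `bc_design`.
#' @param params a [behavior_params()].
#' @param seed integer seed.
#' @return An object of class `bc_behavior`: `scan` (per-trial RT table),
#'   `training` (per-set RT tables), `verbal` (per-test response tables with
#'   attempt counts), `preferences`, `params`, `seed`.
#' @export
simulate_behavior <- function(design, params = behavior_params(), seed = 1L) {
  stopifnot(inherits(design, "bc_design"),
            inherits(params, "bc_behavior_params"))
  cfg <- design$config
  window_ms <- cfg$response_window * 1000
  with_seed(seed, {
    scan <- design_trials(design)
    key <- cond_key(scan$timescale, scan$predictiveness)
    raw <- rnorm(nrow(scan), mean = params$rt_mean[key], sd = params$rt_sd)
    rt <- pmin(pmax(raw, 1), window_ms)
    rt[runif(nrow(scan)) < params$miss_prob] <- NA_real_
    scan$rt <- rt

    training <- lapply(names(design$training_phases), function(ts) {
      tp <- design$training_phases[[ts]]
      key <- cond_key(ts, tp$predictiveness)
      tp$timescale <- ts
      tp$rt <- rnorm(nrow(tp), mean = params$rt_mean[key] +
                       params$training_slowdown, sd = params$rt_sd)
      tp$rt <- pmax(tp$rt, 1)
      tp
    })
    names(training) <- names(design$training_phases)

    # stable per-participant preferred outcome for each nonpredictive combo
    np <- design$cues[design$cues$predictiveness == "nonpredictive", ]
    combos <- expand.grid(cue = np$cue, action = c("left", "right"),
                          stringsAsFactors = FALSE)
    prefs <- stats::setNames(
      ifelse(runif(nrow(combos)) < 0.5, paste0(combos$cue, "_o1"),
             paste0(combos$cue, "_o2")),
      paste(combos$cue, combos$action, sep = "."))

    verbal <- lapply(design$verbal_tests, function(test) {
      tr <- verbal_attempt(test, params, prefs)
      attempts <- 1L
      failed <- with(tr, any(predictiveness == "predictive" &
                               response != correct_outcome))
      if (failed) {  # one retake allowed; it replaces the original
        tr <- verbal_attempt(test, params, prefs)
        attempts <- 2L
      }
      list(timepoint = test$timepoint, set = test$set,
           timescale = test$timescale, trials = tr, attempts = attempts)
    })

    structure(list(scan = scan, training = training, verbal = verbal,
                   preferences = prefs, params = params, seed = seed),
              class = "bc_behavior")
  })
}

#' Cohort-level parameter variation
#'
#' Standard deviations of the participant-level jitter applied to the
#' ground-truth template when simulating a cohort.
#'
#' @param rho_sd SD of per-participant coupling jitter (correlation units).
#' @param evoked_sd SD of evoked-amplitude jitter (percent points).
#' @param rt_sd SD of a participant RT intercept (ms).
#' @param consistency_sd SD of consistency-propensity jitter.
#' @param overlap_sd SD of pattern-overlap jitter.
#' @return A list of class `bc_cohort_variation`.
#' @export
cohort_variation <- function(rho_sd = 0.06, evoked_sd = 0.1, rt_sd = 60,
                             consistency_sd = 0.04, overlap_sd = 0.05) {
  structure(list(rho_sd = rho_sd, evoked_sd = evoked_sd, rt_sd = rt_sd,
                 consistency_sd = consistency_sd, overlap_sd = overlap_sd),
            class = "bc_cohort_variation")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Per-participant plan: jittered truth/behavior parameters plus sub-seeds.
cohort_plan <- function(n_participants, config, truth, behavior, seed,
                        variation) {
  if (n_participants < 2) {
    stop("a cohort needs at least 2 participants (group statistics are ",
         "undefined otherwise)", call. = FALSE)
  }
  seeds <- derive_seeds(seed, c("jitter", paste0("p", seq_len(n_participants))))
  jit <- with_seed(seeds[["jitter"]], {
    lapply(seq_len(n_participants), function(i) {
      list(rho = rnorm(4, 0, variation$rho_sd),
           evoked = rnorm(4, 0, variation$evoked_sd),
           rt = rnorm(1, 0, variation$rt_sd),
           consistency = rnorm(2, 0, variation$consistency_sd),
           overlap = rnorm(4, 0, variation$overlap_sd))
    })
  })
  lapply(seq_len(n_participants), function(i) {
    tr <- truth
    tr$rho <- clip(truth$rho + jit[[i]]$rho, -0.95, 0.95)
    tr$evoked_amplitude <- pmax(truth$evoked_amplitude + jit[[i]]$evoked, 0)
    tr$pattern_overlap <- clip(truth$pattern_overlap + jit[[i]]$overlap,
                               -0.95, 0.95)
    bp <- behavior
    bp$rt_mean <- behavior$rt_mean + jit[[i]]$rt
    bp$consistency <- clip(behavior$consistency + jit[[i]]$consistency, 0, 1)
    sub <- derive_seeds(seeds[[paste0("p", i)]],
                        c("design", "bold", "behavior", "resample"))
    list(id = i, config = config, truth = tr, behavior = bp, seeds = sub)
  })
}

# Materialize one participant of a cohort plan.
simulate_participant <- function(plan_i) {
  design <- build_design(plan_i$config, seed = plan_i$seeds[["design"]])
  bold <- simulate_bold(design, plan_i$truth,
                        seed = plan_i$seeds[["bold"]])
  behav <- simulate_behavior(design, plan_i$behavior,
                             seed = plan_i$seeds[["behavior"]])
  structure(list(id = plan_i$id, design = design, truth = plan_i$truth,
                 bold = bold, behavior = behav, seeds = plan_i$seeds),
            class = "bc_participant")
}

#' Simulate a cohort of participants
#'
#' Derives per-participant seeds and parameter jitter reproducibly from a
#' master seed and materializes a full dataset (design, BOLD, behavior) for
#' each participant.
#'
#' @param n_participants number of participants (at least 2).
#' @param config a [design_config()].
#' @param truth template [ground_truth()].
#' @param behavior template [behavior_params()].
#' @param variation a [cohort_variation()]; use SDs of 0 for identical
#'   participants.
#' @param seed master seed.
#' @return List of `bc_participant` objects.
#' @export
simulate_cohort <- function(n_participants, config = design_config(),
                            truth = ground_truth(),
                            behavior = behavior_params(),
                            variation = cohort_variation(), seed = 1L) {
  plan <- cohort_plan(n_participants, config, truth, behavior, seed,
                      variation)
  lapply(plan, simulate_participant)
}
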