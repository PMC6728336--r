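#' Ground-truth parameters for the BOLD simulator
#'
#' The generator realizes the linear-superposition premise of background
#' connectivity: each voxel's signal is a baseline plus (i) a deterministic
#' stimulus-evoked component locked to block onsets, (ii) an intrinsic latent
#' fluctuation whose inter-ROI correlation is condition dependent, (iii)
#' event-locked multivoxel pattern signal, (iv) nuisance contamination
#' (motion, white matter, ventricles), and (v) AR(1)-plus-white voxel noise.
#'
#' The hippocampal latent `g_hip` is an AR(1) process with unit marginal
#' variance; inside the analysis window of a condition-`c` block the EVC
#' latent is `rho[c] * g_hip(t - lag) + sqrt(1 - rho[c]^2) * eta(t)` with
#' `eta` an independent ROI-wide fluctuation, so the latent cross-correlation
#' equals `rho[c]` exactly; between windows the latents are uncoupled.
#'
#' @param evoked_amplitude per-condition evoked amplitude, percent of
#'   baseline (named by condition key, or scalar).
#' @param rho per-condition target inter-ROI latent correlation.
#' @param lag integer TRs by which the EVC latent trails the hippocampal
#'   latent (0 or 1).
#' @param latent_phi AR(1) coefficient of the intrinsic latents.
#' @param latent_gain amplitude of the latent component in signal units.
#' @param ar1_phi AR(1) coefficient of the private voxel noise.
#' @param noise_sd total SD of the voxel noise (split evenly between AR(1)
#'   and white parts).
#' @param baseline mean signal level.
#' @param nuisance_gain SD of the per-voxel nuisance mixing weights.
#' @param evoked_tau time constant (s) of the saturating-exponential evoked
#'   shape.
#' @param pattern_amplitude amplitude of the event-locked pattern signal,
#'   percent of baseline.
#' @param pattern_overlap per-condition correlation between the two outcome
#'   patterns of a cue (the "pattern separation" dial: lower = more
#'   differentiated).
#' @param pattern_common correlation of every pattern with a cue-independent
#'   common component (induces across-cue similarity).
#' @param n_voxels named vector `c(hippocampus=, evc=)`.
#' @param evc_dims optional 3D grid dimensions for the EVC voxels (product
#'   must equal `n_voxels["evc"]`); a near-cubic grid is derived when the
#'   count is a perfect cube, otherwise a flat `c(V, 1, 1)` grid is used.
#' @param coupling_profile `"uniform"` (every EVC voxel carries the coupled
#'   latent equally) or `"localizer"` (coupled loading concentrated on voxels
#'   with high localizer scores, while the private EVC fluctuation stays
#'   uniform; used to probe ROI-dilation specificity).
#' @param coupling_window_s length (s) of the per-block window over which the
#'   condition's coupling holds; defaults to block duration + 12 s, capped at
#'   the block + fixation cycle.
#' @return An object of class `bc_ground_truth`.
#' @export
ground_truth <- function(evoked_amplitude = 1,
                         rho = c(day3.predictive = 0.35,
                                 day3.nonpredictive = 0.15,
                                 nodelay.predictive = 0.25,
                                 nodelay.nonpredictive = 0.25),
                         lag = 0L, latent_phi = 0.4, latent_gain = 0.5,
                         ar1_phi = 0.3, noise_sd = 1, baseline = 100,
                         nuisance_gain = 0.3, evoked_tau = 4.5,
                         pattern_amplitude = 0.8,
                         pattern_overlap = c(day3.predictive = 0.2,
                                             day3.nonpredictive = 0.6,
                                             nodelay.predictive = 0.4,
                                             nodelay.nonpredictive = 0.6),
                         pattern_common = 0,
                         n_voxels = c(hippocampus = 200, evc = 1000),
                         evc_dims = NULL,
                         coupling_profile = c("uniform", "localizer"),
                         coupling_window_s = NULL) {
  rho <- cond_vector(rho, "rho")
  evoked_amplitude <- cond_vector(evoked_amplitude, "evoked_amplitude")
  pattern_overlap <- cond_vector(pattern_overlap, "pattern_overlap")
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  if (abs(latent_phi) >= 1 || abs(ar1_phi) >= 1) {
    stop("AR(1) coefficients must have |phi| < 1", call. = FALSE)
  }
  if (noise_sd <= 0) stop("'noise_sd' must be positive", call. = FALSE)
  if (!lag %in% c(0L, 1L)) stop("'lag' must be 0 or 1", call. = FALSE)
  if (any(abs(pattern_overlap) >= 1) || abs(pattern_common) >= 1) {
    stop("pattern correlations must have magnitude < 1", call. = FALSE)
  }
  if (!all(c("hippocampus", "evc") %in% names(n_voxels))) {
    stop("'n_voxels' must name 'hippocampus' and 'evc'", call. = FALSE)
  }
  V_evc <- as.integer(n_voxels[["evc"]])
  if (is.null(evc_dims)) {
    cube <- round(V_evc^(1 / 3))
    evc_dims <- if (cube^3 == V_evc) rep(cube, 3L) else c(V_evc, 1L, 1L)
  }
  if (prod(evc_dims) != V_evc) {
    stop("prod(evc_dims) must equal n_voxels['evc']", call. = FALSE)
  }
  structure(list(
    evoked_amplitude = evoked_amplitude, rho = rho, lag = as.integer(lag),
    latent_phi = latent_phi, latent_gain = latent_gain, ar1_phi = ar1_phi,
    noise_sd = noise_sd, baseline = baseline, nuisance_gain = nuisance_gain,
    evoked_tau = evoked_tau, pattern_amplitude = pattern_amplitude,
    pattern_overlap = pattern_overlap, pattern_common = pattern_common,
    n_voxels = c(hippocampus = as.integer(n_voxels[["hippocampus"]]),
                 evc = V_evc),
    evc_dims = as.integer(evc_dims),
    coupling_profile = match.arg(coupling_profile),
    coupling_window_s = coupling_window_s
  ), class = "bc_ground_truth")
}

# AR(1) series with unit marginal variance.
ar1_series <- function(n, phi) {
  if (abs(phi) < 1e-12) return(rnorm(n))
  innov <- c(rnorm(1), rnorm(n - 1) * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Matrix of independent AR(1)+white noise rows (voxels x time), total SD sd.
noise_matrix <- function(n_voxels, n_time, phi, sd) {
  innov <- matrix(rnorm(n_time * n_voxels), n_time, n_voxels)
  innov[-1, ] <- innov[-1, , drop = FALSE] * sqrt(1 - phi^2)
  ar <- stats::filter(innov, phi, method = "recursive")
  white <- matrix(rnorm(n_time * n_voxels), n_time, n_voxels)
  t(sd * (sqrt(0.5) * ar + sqrt(0.5) * white))
}

#' Evoked response kernel of the generator
#'
#' The per-block evoked shape: a saturating exponential rise
#' `amplitude * (1 - exp(-t / tau))` over the block, decaying exponentially
#' over the fixation period, sampled at the TR. The kernel spans one
#' block + fixation cycle, so it is exactly representable by the FIR basis.
#'
#' @param amplitude evoked amplitude (percent of baseline).
#' @param config a [design_config()].
#' @param tau time constant in seconds.
#' @return Numeric vector of length `(block + fixation) / TR`.
#' @export
evoked_kernel <- function(amplitude, config, tau = 4.5) {
  n_bins <- round((config$block_duration + config$fixation_duration) /
                    config$TR)
  tt <- (seq_len(n_bins) - 1L) * config$TR
  peak <- 1 - exp(-config$block_duration / tau)
  shape <- ifelse(tt < config$block_duration,
                  1 - exp(-tt / tau),
                  peak * exp(-(tt - config$block_duration) / tau))
  amplitude * shape
}

#' Condition-evoked timecourse of one run (percent of baseline)
#'
#' @param run one element of `design$runs`.
#' @param config the design configuration.
#' @param amplitudes named per-condition amplitudes (percent).
#' @param tau kernel time constant (s).
#' @return Numeric vector of length `config$n_timepoints`.
#' @export
evoked_series <- function(run, config, amplitudes, tau = 4.5) {
  amplitudes <- cond_vector(amplitudes, "amplitudes")
  out <- numeric(config$n_timepoints)
  for (b in seq_len(nrow(run$blocks))) {
    key <- cond_key(run$timescale, run$blocks$predictiveness[b])
    kern <- evoked_kernel(amplitudes[[key]], config, tau)
    start <- round(run$blocks$onset[b] / config$TR)  # 0-based sample index
    idx <- start + seq_along(kern)
    keep <- idx <= config$n_timepoints
    out[idx[keep]] <- out[idx[keep]] + kern[keep]
  }
  out
}

# Per-block coupling state of one run: integer vector over timepoints, with
# the condition key of the block whose analysis window covers each sample
# (NA between windows). `window_len` in samples.
coupling_state <- function(run, config, window_len) {
  state <- rep(NA_character_, config$n_timepoints)
  for (b in seq_len(nrow(run$blocks))) {
    start <- round(run$blocks$onset[b] / config$TR)
    idx <- start + seq_len(window_len)
    idx <- idx[idx <= config$n_timepoints]
    state[idx] <- cond_key(run$timescale, run$blocks$predictiveness[b])
  }
  state
}

# Ground-truth multivoxel patterns, one column per outcome (= transition)
# for every cue of every set: within a cue the two outcome patterns correlate
# at pattern_overlap[condition]; all patterns share a common component at
# pattern_common.
draw_patterns <- function(cues, timescale_of_set, n_vox, overlap, common) {
  labels <- c(rbind(cues$outcome1, cues$outcome2))
  q <- matrix(NA_real_, n_vox, length(labels),
              dimnames = list(NULL, labels))
  shared <- rnorm(n_vox)
  for (i in seq_len(nrow(cues))) {
    key <- cond_key(timescale_of_set[cues$set[i]], cues$predictiveness[i])
    ov <- overlap[[key]]
    # target total within-cue correlation ov, accounting for the common part
    ov_res <- (ov - common^2) / (1 - common^2)
    ov_res <- max(min(ov_res, 1 - 1e-9), -(1 - 1e-9))
    z1 <- rnorm(n_vox)
    z2 <- ov_res * z1 + sqrt(1 - ov_res^2) * rnorm(n_vox)
    q[, cues$outcome1[i]] <- common * shared + sqrt(1 - common^2) * z1
    q[, cues$outcome2[i]] <- common * shared + sqrt(1 - common^2) * z2
  }
  q
}

#' Simulate multi-run BOLD data for one participant
#'
#' Generates voxels-by-time arrays for the two ROIs in every run, plus the
#' nuisance set (6 motion, white-matter and ventricle series) and per-voxel
#' localizer scores for EVC. The construction is strictly additive, so
#' simulations differing only in `evoked_amplitude` differ exactly by the
#' deterministic evoked component ([evoked_series()]).
#'
#' @param design a `bc_design`.
#' @param truth a [ground_truth()].
#' @param seed integer seed; the output is bit-identical for equal inputs.
#' @return An object of class `bc_bold`: list with `runs` (each holding
#'   `hippocampus` and `evc` voxel-by-time matrices and a `nuisance`
#'   data.frame), `localizer_scores`, ground-truth `patterns` per ROI,
#'   `design`, `truth`, and `seed`.
#' @export
simulate_bold <- function(design, truth = ground_truth(), seed = 1L) {
  stopifnot(inherits(design, "bc_design"), inherits(truth, "bc_ground_truth"))
  cfg <- design$config
  n_tp <- cfg$n_timepoints
  V_h <- truth$n_voxels[["hippocampus"]]
  V_e <- truth$n_voxels[["evc"]]
  win_s <- truth$coupling_window_s
  if (is.null(win_s)) {
    win_s <- min(cfg$block_duration + 12, cfg$block_duration +
                   cfg$fixation_duration)
  }
  window_len <- round(win_s / cfg$TR)
  timescale_of_set <- rep(TIMESCALES, length.out = cfg$n_sets)

  with_seed(seed, {
    # Participant-level structure: localizer scores, coupling loadings,
    # ground-truth patterns.
    localizer <- rnorm(V_e)
    if (truth$coupling_profile == "localizer") {
      w_evc <- exp(localizer)
      w_evc <- w_evc / mean(w_evc)
    } else {
      w_evc <- rep(1, V_e)
    }
    patterns <- list(
      hippocampus = draw_patterns(design$cues, timescale_of_set, V_h,
                                  truth$pattern_overlap,
                                  truth$pattern_common),
      evc = draw_patterns(design$cues, timescale_of_set, V_e,
                          truth$pattern_overlap, truth$pattern_common)
    )

    runs <- vector("list", cfg$n_runs)
    for (r in seq_len(cfg$n_runs)) {
      run <- design$runs[[r]]
      state <- coupling_state(run, cfg, window_len)

      # latents: hippocampus leads by `lag` TRs inside coupled windows
      g_h <- ar1_series(n_tp, truth$latent_phi)
      eta <- ar1_series(n_tp, truth$latent_phi)
      g_e_coupled <- numeric(n_tp)   # rho-weighted delayed hippocampal part
      g_e_private <- numeric(n_tp)
      for (t in seq_len(n_tp)) {
        t_lead <- t - truth$lag
        s <- if (t_lead >= 1) state[t_lead] else NA_character_
        rho_s <- if (is.na(s)) 0 else truth$rho[[s]]
        g_lead <- if (t_lead >= 1) g_h[t_lead] else 0
        g_e_coupled[t] <- rho_s * g_lead
        g_e_private[t] <- sqrt(1 - rho_s^2) * eta[t]
      }
      # nuisance series and their voxel contamination
      nuis <- cbind(
        sapply(1:6, function(i) ar1_series(n_tp, 0.9)),
        wm = ar1_series(n_tp, 0.5), ventricle = ar1_series(n_tp, 0.5)
      )
      colnames(nuis) <- c(paste0("motion", 1:6), "wm", "ventricle")
      mix_h <- matrix(rnorm(V_h * ncol(nuis), sd = truth$nuisance_gain),
                      V_h, ncol(nuis))
      mix_e <- matrix(rnorm(V_e * ncol(nuis), sd = truth$nuisance_gain),
                      V_e, ncol(nuis))

      # event-locked pattern regressors (one per outcome present in the run)
      trials <- run$trials
      dur <- cfg$cue_duration + 1.4  # cue + transition interval, ~2.4 s
      pat_labels <- colnames(patterns$hippocampus)
      X_pat <- matrix(0, length(pat_labels), n_tp,
                      dimnames = list(pat_labels, NULL))
      for (lab in unique(trials$outcome)) {
        X_pat[lab, ] <- hrf_regressor(trials$onset[trials$outcome == lab],
                                      rep(dur, sum(trials$outcome == lab)),
                                      n_tp, cfg$TR)
      }

      ev <- evoked_series(run, cfg, truth$evoked_amplitude, truth$evoked_tau)
      base_h <- truth$baseline * (1 + rep(1, V_h) %o% ev / 100) +
        truth$baseline / 100 * truth$pattern_amplitude *
          (patterns$hippocampus %*% X_pat)
      base_e <- truth$baseline * (1 + rep(1, V_e) %o% ev / 100) +
        truth$baseline / 100 * truth$pattern_amplitude *
          (patterns$evc %*% X_pat)

      hip <- base_h +
        truth$latent_gain * (rep(1, V_h) %o% g_h) +
        mix_h %*% t(nuis) +
        noise_matrix(V_h, n_tp, truth$ar1_phi, truth$noise_sd)
      evc <- base_e +
        truth$latent_gain * (w_evc %o% g_e_coupled +
                               rep(1, V_e) %o% g_e_private) +
        mix_e %*% t(nuis) +
        noise_matrix(V_e, n_tp, truth$ar1_phi, truth$noise_sd)

      runs[[r]] <- list(index = r, timescale = run$timescale,
                        hippocampus = unname(as.matrix(hip)),
                        evc = unname(as.matrix(evc)),
                        nuisance = as.data.frame(nuis))
    }

    structure(list(design = design, truth = truth, runs = runs,
                   localizer_scores = localizer, patterns = patterns,
                   seed = seed),
              class = "bc_bold")
  })
}

#' @export
print.bc_bold <- function(x, ...) {
  cat(sprintf(
    "<bc_bold> %d runs, hippocampus %d voxels, EVC %d voxels, %d TRs/run\n",
    length(x$runs), x$truth$n_voxels[["hippocampus"]],
    x$truth$n_voxels[["evc"]], x$design$config$n_timepoints))
  invisible(x)
}
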