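# Data orientation throughout: voxels x time matrices; regressions run over
# time. Sample i corresponds to t = (i - 1) * TR (0-based time convention).

as_vox_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

# OLS of Y (T x V) on X (T x p) via QR; rank-deficient designs are handled
# (qr.resid projects onto the column space regardless).
ols_fit <- function(X, Y) {
  qrx <- qr(X)
  coef <- qr.coef(qrx, Y)
  if (is.null(dim(coef))) coef <- matrix(coef, ncol = 1L)
  resid <- qr.resid(qrx, Y)
  list(coef = coef, resid = resid, rank = qrx$rank,
       collinear = qrx$rank < ncol(X))
}

# Single-iteration Cochrane-Orcutt AR(1) prewhitening: estimate the pooled
# lag-1 residual autocorrelation, quasi-difference Y and X, refit.
prewhiten_ar1 <- function(X, Y) {
  fit0 <- ols_fit(X, Y)
  r <- fit0$resid
  num <- sum(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE])
  den <- sum(r[-nrow(r), , drop = FALSE]^2)
  phi <- if (den > 0) num / den else 0
  phi <- max(min(phi, 0.99), -0.99)
  qd <- function(M) M[-1, , drop = FALSE] - phi * M[-nrow(M), , drop = FALSE]
  fit <- ols_fit(qd(X), qd(Y))
  fit$phi <- phi
  fit
}

# Discrete-cosine high-pass basis: components with period > cutoff seconds.
dct_basis <- function(n, TR, cutoff) {
  K <- floor(2 * n * TR / cutoff)
  if (K < 1) return(matrix(numeric(0), n, 0))
  tt <- seq_len(n) - 0.5
  sapply(seq_len(K), function(k) cos(pi * tt * k / n))
}

#' High-pass filter by discrete-cosine projection
#'
#' Removes the mean and all discrete-cosine components with period longer
#' than `cutoff` seconds (the standard fMRI drift model).
#'
#' @param x numeric vector or voxels-by-time matrix.
#' @param TR sampling interval in seconds.
#' @param cutoff cutoff period in seconds (must exceed `2 * TR`).
#' @return Filtered data of the same shape, with the basis attached as
#'   attribute `"dct_basis"` (timepoints x components, without the mean).
#' @export
high_pass <- function(x, TR, cutoff = 128) {
  if (cutoff <= 2 * TR) stop("'cutoff' must exceed 2 * TR", call. = FALSE)
  vec <- is.null(dim(x))
  m <- as_vox_matrix(x)
  n <- ncol(m)
  D <- dct_basis(n, TR, cutoff)
  if (ncol(D) == 0L) {
    warning("series shorter than one cutoff period; removing the mean only")
    out <- m - rowMeans(m)
  } else {
    fit <- ols_fit(cbind(1, D), t(m))
    out <- t(fit$resid)
  }
  if (vec) out <- drop(out)
  attr(out, "dct_basis") <- D
  out
}

#' Regress nuisance signals out of a timeseries
#'
#' Projects out an intercept plus the nuisance columns (6 motion parameters,
#' white-matter and ventricle series). Rank-deficient nuisance columns are
#' dropped with a warning.
#'
#' @param x numeric vector or voxels-by-time matrix.
#' @param nuisance data.frame or matrix (timepoints x regressors).
#' @return Residual data of the same shape; the residuals are orthogonal to
#'   every retained nuisance column.
#' @export
regress_nuisance <- function(x, nuisance) {
  vec <- is.null(dim(x))
  m <- as_vox_matrix(x)
  N <- as.matrix(nuisance)
  if (nrow(N) != ncol(m)) {
    stop("nuisance length must match the timeseries", call. = FALSE)
  }
  Nc <- scale(N, center = TRUE, scale = FALSE)
  qrn <- qr(Nc)
  if (qrn$rank < ncol(Nc)) {
    keep <- qrn$pivot[seq_len(qrn$rank)]
    dropped <- colnames(N)[-keep]
    if (is.null(dropped)) dropped <- paste0("column ", setdiff(
      seq_len(ncol(N)), keep))
    warning("dropping rank-deficient nuisance column(s): ",
            paste(dropped, collapse = ", "))
    Nc <- Nc[, keep, drop = FALSE]
  }
  fit <- ols_fit(cbind(1, Nc), t(m))
  out <- t(fit$resid)
  if (vec) out <- drop(out)
  out
}

#' FIR design matrix for one run
#'
#' One delta regressor per (condition, TR offset from block onset), pooling
#' all blocks of a condition within the run.
#'
#' @param run one element of `design$runs`.
#' @param config the design configuration.
#' @param n_bins number of TR bins per condition (27 spans one
#'   block + fixation cycle under the default timing).
#' @return Matrix (timepoints x conditions*bins) with names like
#'   `"predictive.bin01"`.
#' @export
fir_design <- function(run, config, n_bins = 27) {
  n_tp <- config$n_timepoints
  conds <- unique(run$blocks$predictiveness)
  cols <- list()
  for (cond in conds) {
    onsets <- run$blocks$onset[run$blocks$predictiveness == cond]
    starts <- round(onsets / config$TR)  # 0-based sample indices
    M <- matrix(0, n_tp, n_bins)
    for (b in seq_len(n_bins)) {
      idx <- starts + b  # 1-based sample of bin offset b-1
      idx <- idx[idx >= 1 & idx <= n_tp]
      M[idx, b] <- M[idx, b] + 1
    }
    colnames(M) <- sprintf("%s.bin%02d", cond, seq_len(n_bins))
    cols[[cond]] <- M
  }
  do.call(cbind, cols)
}

#' Fit the FIR deconvolution model
#'
#' Estimates the average timing and shape of the evoked response in every
#' voxel with delta-function regressors (no assumed HRF), and returns the
#' residual ("background") timeseries. When `confounds` are supplied (e.g.,
#' the drift basis and nuisance columns already projected out of `x`), the
#' FIR columns are residualized against them first, so the sequential fit
#' equals the joint GLM projection and FIR-representable signal is removed
#' exactly.
#'
#' @param x voxels-by-time matrix (or vector) for one run.
#' @param run the corresponding element of `design$runs`.
#' @param config the design configuration.
#' @param n_bins FIR bins per condition.
#' @param confounds optional timepoints-by-q matrix of regressors already
#'   removed from `x`.
#' @param prewhiten logical; single-iteration AR(1) prewhitening of the FIR
#'   fit (the residual series itself stays an OLS projection).
#' @return An object of class `bc_fir`: `estimates` (condition x bin x voxel
#'   array), `intercept` (per-voxel), `residuals` (voxels x time),
#'   `collinear` flag, and the design matrix.
#' @export
fit_fir <- function(x, run, config, n_bins = 27, confounds = NULL,
                    prewhiten = FALSE) {
  m <- as_vox_matrix(x)
  n_tp <- ncol(m)
  if (n_tp != config$n_timepoints) {
    stop("timeseries length does not match the design", call. = FALSE)
  }
  conds <- unique(run$blocks$predictiveness)
  if (n_bins * length(conds) >= n_tp) {
    stop("bins x conditions must be fewer than the timepoints", call. = FALSE)
  }
  F_ <- fir_design(run, config, n_bins)
  labels <- colnames(F_)
  if (!is.null(confounds) && NCOL(confounds) > 0) {
    C <- cbind(1, as.matrix(confounds))
    F_ <- qr.resid(qr(C), F_)
    colnames(F_) <- labels
  }
  X <- cbind(`(Intercept)` = 1, F_)
  fit <- ols_fit(X, t(m))
  if (prewhiten) {
    # coefficients from the prewhitened fit; residuals stay the OLS
    # projection so downstream correlations use the full-length series
    fitw <- prewhiten_ar1(X, t(m))
    coef <- fitw$coef
  } else {
    coef <- fit$coef
  }
  coef[is.na(coef)] <- 0
  est <- array(0, dim = c(length(conds), n_bins, nrow(m)),
               dimnames = list(conds, NULL, NULL))
  for (ci in seq_along(conds)) {
    rows <- match(sprintf("%s.bin%02d", conds[ci], seq_len(n_bins)), labels)
    est[ci, , ] <- coef[1L + rows, , drop = FALSE]
  }
  structure(list(estimates = est, conditions = conds,
                 intercept = coef[1L, ], residuals = t(fit$resid),
                 collinear = fit$collinear, design = X,
                 timescale = run$timescale),
            class = "bc_fir")
}

#' Percent signal change of the evoked response
#'
#' Averages the FIR parameter estimates over the peak bins (TRs 5-19 of the
#' block cycle, 1-based: the block duration shifted forward by 6 s of
#' hemodynamic lag), divides by the voxel baseline, and averages across
#' voxels.
#'
#' @param fir a `bc_fir`.
#' @param baseline per-voxel baseline (or scalar); must be positive.
#' @param peak_bins 1-based bin indices to average (default `5:19`).
#' @return Named numeric vector: percent signal change per condition key.
#' @export
evoked_psc <- function(fir, baseline, peak_bins = 5:19) {
  stopifnot(inherits(fir, "bc_fir"))
  if (any(baseline <= 0)) stop("baseline must be positive", call. = FALSE)
  n_vox <- dim(fir$estimates)[3]
  baseline <- rep_len(baseline, n_vox)
  out <- vapply(seq_along(fir$conditions), function(ci) {
    est <- matrix(fir$estimates[ci, peak_bins, , drop = FALSE],
                  nrow = length(peak_bins))  # bins x voxels
    mean(100 * colMeans(est) / baseline)
  }, numeric(1))
  names(out) <- cond_key(fir$timescale, fir$conditions)
  out
}

#' Double-gamma hemodynamic response function
#'
#' Standard parameterization: a gamma density peaking near `peak` seconds
#' minus an undershoot gamma scaled by `1/ratio`.
#'
#' @param t time in seconds (vector).
#' @param peak,undershoot gamma shape parameters (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, scale = 1) -
    stats::dgamma(t, shape = undershoot, scale = 1) / ratio
  h[t < 0] <- 0
  h
}

#' Convolve event boxcars with the double-gamma HRF
#'
#' @param onsets event onsets in seconds.
#' @param durations event durations in seconds (recycled).
#' @param n_tp number of output samples.
#' @param TR sampling interval (s).
#' @param oversample temporal oversampling factor for the convolution grid.
#' @param hrf function of time returning the impulse response.
#' @return Regressor sampled at `t = (i - 1) * TR`.
#' @export
hrf_regressor <- function(onsets, durations, n_tp, TR, oversample = 10,
                          hrf = hrf_double_gamma) {
  if (!length(onsets)) return(numeric(n_tp))
  durations <- rep_len(durations, length(onsets))
  dt <- TR / oversample
  n_fine <- n_tp * oversample + 32 * oversample
  tt <- (seq_len(n_fine) - 1) * dt
  box <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    box <- box + (tt >= onsets[i] & tt < onsets[i] + durations[i])
  }
  h <- hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_fine)] * dt
  conv[seq(1, by = oversample, length.out = n_tp)]
}

#' Event-related GLM for multivoxel pattern estimation
#'
#' Fits one regressor (plus temporal derivative) per transition label, with
#' separate regressors for the counter-predicted trial and for missed
#' trials, motion covariates, and an intercept; amplitudes are estimated by
#' OLS. Boxcar durations default to the cue-to-outcome span implied by the
#' mean response time, clamped to 2188-2643 ms.
#'
#' @param x voxels-by-time matrix for one run.
#' @param events data.frame with columns `onset` (s), `regressor` (transition
#'   label), and optionally `predicted` (FALSE marks the counter-predicted
#'   trial) and `rt` (ms; NA marks a missed trial).
#' @param config the design configuration.
#' @param nuisance optional timepoints-by-q matrix of motion covariates.
#' @param confounds optional additional columns (e.g., drift basis).
#' @param trial_duration boxcar duration in seconds; derived from mean RT
#'   when NULL.
#' @param labels expected transition labels; labels with no surviving trials
#'   are dropped with a warning and reported in `missing`. Defaults to the
#'   labels present in `events`.
#' @param prewhiten logical; single-iteration AR(1) prewhitening.
#' @return An object of class `bc_betas`: `betas` (labels x voxels),
#'   `counts` (trials per label), `missing` (labels dropped for lack of
#'   trials), `duration`, and the design matrix.
#' @export
fit_event_glm <- function(x, events, config, nuisance = NULL,
                          confounds = NULL, trial_duration = NULL,
                          labels = NULL, prewhiten = FALSE) {
  m <- as_vox_matrix(x)
  n_tp <- ncol(m)
  rt <- if ("rt" %in% names(events)) events$rt else rep(NA_real_,
                                                        nrow(events))
  predicted <- if ("predicted" %in% names(events)) {
    events$predicted
  } else rep(TRUE, nrow(events))
  missed <- if ("rt" %in% names(events)) is.na(events$rt) else
    rep(FALSE, nrow(events))
  counter <- !is.na(predicted) & !predicted & !missed
  keep <- !missed & !counter

  if (is.null(trial_duration)) {
    mean_rt <- mean(rt[keep], na.rm = TRUE)
    trial_duration <- if (is.finite(mean_rt)) {
      clip(2000 + mean_rt, 2188, 2643) / 1000
    } else 2.4
  }

  if (is.null(labels)) labels <- unique(events$regressor[keep])
  counts <- vapply(labels, function(l) sum(events$regressor == l & keep),
                   integer(1))
  missing <- labels[counts == 0L]
  if (length(missing)) {
    warning("dropping empty regressor(s): ", paste(missing, collapse = ", "))
    labels <- labels[counts > 0L]
  }
  reg_cols <- list()
  for (lab in labels) {
    on <- events$onset[keep & events$regressor == lab]
    conv <- hrf_regressor(on, trial_duration, n_tp, config$TR)
    reg_cols[[lab]] <- conv
    reg_cols[[paste0(lab, ".deriv")]] <- c(0, diff(conv))
  }
  if (any(counter)) {
    conv <- hrf_regressor(events$onset[counter], trial_duration, n_tp,
                          config$TR)
    reg_cols[["counter"]] <- conv
    reg_cols[["counter.deriv"]] <- c(0, diff(conv))
  }
  if (any(missed)) {
    reg_cols[["missed"]] <- hrf_regressor(events$onset[missed],
                                          trial_duration, n_tp, config$TR)
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, reg_cols))
  if (!is.null(confounds) && NCOL(confounds) > 0) X <- cbind(X, confounds)
  if (!is.null(nuisance) && NCOL(nuisance) > 0) {
    X <- cbind(X, as.matrix(nuisance))
  }
  fit <- if (prewhiten) prewhiten_ar1(X, t(m)) else ols_fit(X, t(m))
  coef <- fit$coef
  coef[is.na(coef)] <- 0
  rows <- match(labels, colnames(X))
  betas <- coef[rows, , drop = FALSE]
  rownames(betas) <- labels
  structure(list(betas = betas, labels = labels,
                 counts = counts[labels], missing = missing,
                 duration = trial_duration, design = X,
                 collinear = fit$collinear),
            class = "bc_betas")
}

#' Residualize a simulated dataset for background connectivity
#'
#' Runs the multistep chain on every run and ROI: discrete-cosine high-pass
#' (optional), nuisance regression (motion + white matter + ventricles, with
#' the nuisance columns themselves high-passed), then FIR removal of the
#' evoked response with the confounds carried along so the projection is
#' joint.
#'
#' @param bold a `bc_bold`.
#' @param highpass logical; apply the 128 s cosine high-pass first.
#' @param cutoff high-pass cutoff (s).
#' @param n_bins FIR bins per condition; NULL skips FIR removal (for
#'   ablation of the evoked-removal step).
#' @param prewhiten logical; AR(1) prewhitening inside the FIR fit.
#' @return An object of class `bc_resid`: per-run list with residual
#'   `hippocampus` / `evc` matrices, per-ROI `bc_fir` fits, and per-voxel
#'   baselines, plus provenance flags.
#' @export
residualize <- function(bold, highpass = TRUE, cutoff = 128, n_bins = 27,
                        prewhiten = FALSE) {
  stopifnot(inherits(bold, "bc_bold"))
  cfg <- bold$design$config
  runs <- lapply(seq_along(bold$runs), function(r) {
    run_dat <- bold$runs[[r]]
    run_des <- bold$design$runs[[r]]
    out <- list(index = r, timescale = run_dat$timescale)
    for (roi in c("hippocampus", "evc")) {
      y <- run_dat[[roi]]
      baseline <- rowMeans(y)
      nuis <- as.matrix(run_dat$nuisance)
      confounds <- NULL
      if (highpass) {
        D <- dct_basis(ncol(y), cfg$TR, cutoff)
        y <- high_pass(y, cfg$TR, cutoff)
        nuis <- high_pass(t(nuis), cfg$TR, cutoff) |> t()
        confounds <- D
      }
      y <- regress_nuisance(y, nuis)
      confounds <- cbind(confounds, scale(nuis, center = TRUE,
                                          scale = FALSE))
      if (!is.null(n_bins)) {
        fir <- fit_fir(y, run_des, cfg, n_bins = n_bins,
                       confounds = confounds, prewhiten = prewhiten)
        out[[roi]] <- fir$residuals
        out[[paste0(roi, "_fir")]] <- fir
      } else {
        out[[roi]] <- y
        out[[paste0(roi, "_fir")]] <- NULL
      }
      out[[paste0(roi, "_baseline")]] <- baseline
    }
    out
  })
  structure(list(runs = runs, design = bold$design,
                 provenance = c(nuisance_removed = TRUE,
                                fir_removed = !is.null(n_bins),
                                highpassed = highpass)),
            class = "bc_resid")
}
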