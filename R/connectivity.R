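# Background-connectivity measurement: z-scored residual series, per-block
# analysis windows, and Fisher-z correlations (within-run, across-run
# control, time-lagged, ROI-dilation, voxelwise variants).

#' Z-score residual timeseries within run
#'
#' @param x numeric vector (one signal) or voxels-by-time matrix for a run.
#' @param label context used in error messages (run/ROI).
#' @return Same shape, each signal with mean 0 and SD 1 over the run.
#' @export
zscore_run <- function(x, label = "series") {
  vec <- is.null(dim(x))
  m <- as_vox_matrix(x)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    stop(sprintf("zero-variance signal in %s (row %s)", label,
                 paste(head(bad, 3L), collapse = ", ")), call. = FALSE)
  }
  out <- (m - mu) / s
  if (vec) out <- drop(out)
  out
}

#' Standardized ROI signals from residualized data
#'
#' Reduces each run's residual voxel array to the ROI-level mean series or
#' keeps per-voxel series, then z-scores within run. A residual series whose
#' variance is numerically zero relative to the voxel baseline (below
#' `tol` times the baseline; this happens only when the model removed the
#' signal exactly, e.g. noiseless simulations) contains no background signal
#' and is returned as an all-zero series, which downstream correlations
#' treat as zero coupling. An exactly constant series is still an error.
#'
#' @param resid a `bc_resid` from [residualize()].
#' @param roi `"hippocampus"` or `"evc"`.
#' @param reduction `"mean_series"` (average across voxels, then z-score) or
#'   `"per_voxel"`.
#' @param tol relative floor distinguishing numerically-empty residuals
#'   from real background fluctuations.
#' @return List over runs of z-scored vectors (or voxels-by-time matrices).
#' @export
zscore_roi <- function(resid, roi = c("hippocampus", "evc"),
                       reduction = c("mean_series", "per_voxel"),
                       tol = 1e-7) {
  stopifnot(inherits(resid, "bc_resid"))
  roi <- match.arg(roi)
  reduction <- match.arg(reduction)
  lapply(resid$runs, function(run) {
    m <- run[[roi]]
    scale_ref <- mean(abs(run[[paste0(roi, "_baseline")]]))
    sig <- if (reduction == "mean_series") colMeans(m) else m
    sm <- as_vox_matrix(sig)
    s <- apply(sm, 1L, sd)
    degenerate <- s > 0 & s < tol * scale_ref
    if (all(degenerate)) {
      out <- sm * 0
      if (is.null(dim(sig))) out <- drop(out)
      return(out)
    }
    z <- zscore_run(sig, label = sprintf("run %d %s", run$index, roi))
    if (any(degenerate)) {
      zm <- as_vox_matrix(z)
      zm[degenerate, ] <- 0
      z <- if (is.null(dim(sig))) drop(zm) else zm
    }
    z
  })
}

#' Extract per-block analysis windows
#'
#' For every block, takes `window_s` seconds of signal from the block onset
#' (i.e., the block plus the first part of the following fixation), shifted
#' by `lag_TRs` samples, and groups windows by condition.
#'
#' @param z list over runs of z-scored signals (vectors or voxels-by-time
#'   matrices), indexed by run number; NULL entries are skipped.
#' @param design the `bc_design`.
#' @param window_s window length in seconds (34.5 spans the block plus 12 s
#'   after the last trial ends).
#' @param lag_TRs integer shift of every window start, in samples.
#' @param window_len window length in samples; defaults to
#'   `round(window_s / TR)`.
#' @return An object of class `bc_windows`: per condition key, a list of
#'   windows with fields `run`, `block`, `samples`.
#' @export
extract_windows <- function(z, design, window_s = 34.5, lag_TRs = 0,
                            window_len = NULL) {
  cfg <- design$config
  if (is.null(window_len)) window_len <- round(window_s / cfg$TR)
  out <- list()
  for (r in seq_along(z)) {
    if (is.null(z[[r]])) next
    run <- design$runs[[r]]
    sig <- z[[r]]
    n_tp <- if (is.null(dim(sig))) length(sig) else ncol(sig)
    for (b in seq_len(nrow(run$blocks))) {
      start <- round(run$blocks$onset[b] / cfg$TR) + lag_TRs
      idx <- start + seq_len(window_len)
      if (min(idx) < 1 || max(idx) > n_tp) {
        stop(sprintf("window for run %d block %d exceeds the run bounds",
                     r, b), call. = FALSE)
      }
      key <- cond_key(run$timescale, run$blocks$predictiveness[b])
      samples <- if (is.null(dim(sig))) sig[idx] else sig[, idx, drop = FALSE]
      out[[key]] <- c(out[[key]], list(list(run = r, block = b,
                                            samples = samples)))
    }
  }
  structure(out, class = "bc_windows", window_len = window_len,
            lag_TRs = lag_TRs)
}

# correlation clipped away from +/-1 before the Fisher transform
clipped_fisher <- function(r) {
  fisher_z(clip(r, -(1 - 1e-12), 1 - 1e-12))
}

# Pearson correlation with the degenerate-signal convention: an all-zero
# (signal-free) side carries no background coupling, so r = 0.
win_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Background connectivity between two window sets
#'
#' For each condition and run, concatenates that condition's windows,
#' computes the Pearson correlation between the two signals, and Fisher
#' transforms; z values are averaged across runs.
#'
#' @param windowsA,windowsB `bc_windows` with identical (run, block)
#'   structure (e.g., the two ROIs of the same runs).
#' @return Named vector of Fisher-z connectivity per condition key, with the
#'   per-run values in attribute `"per_run"`.
#' @export
background_connectivity <- function(windowsA, windowsB) {
  stopifnot(inherits(windowsA, "bc_windows"), inherits(windowsB, "bc_windows"))
  keys <- names(windowsA)
  if (!identical(keys, names(windowsB))) {
    stop("window sets have different condition structure", call. = FALSE)
  }
  per_run <- list()
  out <- numeric(0)
  for (key in keys) {
    wa <- windowsA[[key]]
    wb <- windowsB[[key]]
    ida <- vapply(wa, function(w) c(w$run, w$block), numeric(2))
    idb <- vapply(wb, function(w) c(w$run, w$block), numeric(2))
    if (!identical(ida, idb)) {
      stop("window sets have different (run, block) structure", call. = FALSE)
    }
    runs <- unique(ida[1, ])
    z_run <- vapply(runs, function(r) {
      a <- unlist(lapply(wa[ida[1, ] == r], `[[`, "samples"))
      b <- unlist(lapply(wb[idb[1, ] == r], `[[`, "samples"))
      if (length(a) < 2L) stop("fewer than 2 samples in a window set",
                               call. = FALSE)
      clipped_fisher(win_cor(a, b))
    }, numeric(1))
    per_run[[key]] <- stats::setNames(z_run, paste0("run", runs))
    out[key] <- mean(z_run)
  }
  attr(out, "per_run") <- per_run
  out
}

#' Across-run control correlation for a matched run pair
#'
#' Correlates the background signal of one region in run `i` with the other
#' region in the stimulus- and order-matched run `j` (and vice versa),
#' using the identical window logic. With evoked responses fully removed the
#' across-run correlation has no shared signal left and goes to zero.
#'
#' @param zA,zB lists over runs of z-scored signals for the two regions.
#' @param design the `bc_design`.
#' @param pair integer vector `c(i, j)`; must be one of
#'   `design$matched_run_pairs`.
#' @param window_s window length in seconds.
#' @return Named vector of Fisher-z values per condition key (both
#'   directions averaged).
#' @export
across_run_control <- function(zA, zB, design, pair, window_s = 34.5) {
  ok <- any(vapply(design$matched_run_pairs,
                   function(p) all(sort(p) == sort(pair)), logical(1)))
  if (!ok) {
    stop("runs ", paste(pair, collapse = ", "),
         " are not a matched pair of this design", call. = FALSE)
  }
  keep <- function(z, r) {
    out <- vector("list", length(z))
    out[[r]] <- z[[r]]
    out
  }
  i <- pair[1]
  j <- pair[2]
  wAi <- extract_windows(keep(zA, i), design, window_s)
  wAj <- extract_windows(keep(zA, j), design, window_s)
  wBi <- extract_windows(keep(zB, i), design, window_s)
  wBj <- extract_windows(keep(zB, j), design, window_s)
  cross <- function(w1, w2) {
    keys <- names(w1)
    vapply(keys, function(key) {
      a <- unlist(lapply(w1[[key]], `[[`, "samples"))
      b <- unlist(lapply(w2[[key]], `[[`, "samples"))
      if (length(a) != length(b)) {
        stop("matched runs have inconsistent windows", call. = FALSE)
      }
      clipped_fisher(win_cor(a, b))
    }, numeric(1))
  }
  (cross(wAi, wBj) + cross(wAj, wBi)) / 2
}

#' Time-lagged background connectivity
#'
#' The leader region contributes the window 0-33 s from each block onset
#' (22 samples at TR 1.5), the follower the window 1.5-34.5 s; correlations
#' are computed per block, Fisher transformed, then averaged over blocks and
#' runs per condition.
#'
#' @param zA,zB lists over runs of z-scored region signals.
#' @param design the `bc_design`.
#' @param leader which region leads in time: `"A"` or `"B"`.
#' @param window_s full (unshifted) window length in seconds; the leader and
#'   follower windows are one TR shorter.
#' @param lag_TRs temporal offset of the follower in samples.
#' @return Named vector of Fisher-z values per condition key.
#' @export
lagged_connectivity <- function(zA, zB, design, leader = c("A", "B"),
                                window_s = 34.5, lag_TRs = 1) {
  leader <- match.arg(leader)
  cfg <- design$config
  short_len <- round(window_s / cfg$TR) - lag_TRs
  lead_w <- extract_windows(if (leader == "A") zA else zB, design,
                            lag_TRs = 0, window_len = short_len)
  foll_w <- extract_windows(if (leader == "A") zB else zA, design,
                            lag_TRs = lag_TRs, window_len = short_len)
  keys <- names(lead_w)
  out <- vapply(keys, function(key) {
    wl <- lead_w[[key]]
    wf <- foll_w[[key]]
    runs <- vapply(wl, `[[`, numeric(1), "run")
    z_block <- vapply(seq_along(wl), function(i) {
      clipped_fisher(win_cor(wl[[i]]$samples, wf[[i]]$samples))
    }, numeric(1))
    mean(vapply(unique(runs), function(r) mean(z_block[runs == r]),
                numeric(1)))
  }, numeric(1))
  out
}

#' ROI-dilation connectivity profile
#'
#' Recomputes seed connectivity as the target ROI grows from the `k` voxels
#' most responsive in the localizer to the full voxel set: for each size the
#' target signal is the mean residual series of the top-`k` voxels (ties
#' broken by voxel index), z-scored within run, then passed through the
#' standard window pipeline.
#'
#' @param seed_z list over runs of z-scored seed signals.
#' @param voxel_resid list over runs of residual voxels-by-time matrices for
#'   the target ROI (not yet averaged).
#' @param localizer_scores per-voxel localizer responsiveness.
#' @param design the `bc_design`.
#' @param sizes ROI sizes to evaluate; values above the voxel count are
#'   truncated to "all".
#' @param window_s window length in seconds.
#' @return Matrix sizes x conditions of Fisher-z values; row names give the
#'   effective sizes (the last row is always `"all"`).
#' @export
dilation_profile <- function(seed_z, voxel_resid, localizer_scores, design,
                             sizes = c(50, 100, 500, 1000, 5000),
                             window_s = 34.5) {
  n_vox <- length(localizer_scores)
  ord <- order(-localizer_scores, seq_len(n_vox))  # stable: ties by index
  sizes <- sort(unique(pmin(sizes, n_vox)))
  if (!n_vox %in% sizes) sizes <- c(sizes, n_vox)
  rows <- lapply(sizes, function(k) {
    top <- ord[seq_len(k)]
    zk <- lapply(voxel_resid, function(m) {
      if (is.null(m)) return(NULL)
      zscore_run(colMeans(m[top, , drop = FALSE]))
    })
    background_connectivity(
      extract_windows(seed_z, design, window_s),
      extract_windows(zk, design, window_s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ifelse(sizes == n_vox, "all", as.character(sizes))
  out
}

#' Voxelwise background-connectivity map
#'
#' Fisher-z connectivity of every target voxel with the seed signal, per
#' condition, using the standard concatenated-window computation.
#'
#' @param seed_z list over runs of z-scored seed signals.
#' @param voxel_z list over runs of z-scored voxels-by-time matrices.
#' @param design the `bc_design`.
#' @param window_s window length in seconds.
#' @param dims optional 3D grid dimensions attached to the result.
#' @return Matrix voxels x conditions of Fisher-z values (zero-variance
#'   voxels give NA; their count is in attribute `"n_missing"`), with
#'   attribute `"dims"`.
#' @export
voxelwise_map <- function(seed_z, voxel_z, design, window_s = 34.5,
                          dims = NULL) {
  ws <- extract_windows(seed_z, design, window_s)
  wv <- extract_windows(voxel_z, design, window_s)
  keys <- names(ws)
  out <- NULL
  n_missing <- 0L
  for (key in keys) {
    runs <- vapply(ws[[key]], `[[`, numeric(1), "run")
    z_runs <- lapply(unique(runs), function(r) {
      s <- unlist(lapply(ws[[key]][runs == r], `[[`, "samples"))
      V <- do.call(cbind, lapply(wv[[key]][runs == r], `[[`, "samples"))
      s_c <- s - mean(s)
      V_c <- V - rowMeans(V)
      denom <- sqrt(rowSums(V_c^2) * sum(s_c^2))
      r_vox <- as.numeric(V_c %*% s_c) / denom
      r_vox[!is.finite(r_vox)] <- NA
      clipped_fisher(r_vox)
    })
    z <- Reduce(`+`, z_runs) / length(z_runs)
    n_missing <- max(n_missing, sum(is.na(z)))
    out <- cbind(out, z)
    colnames(out)[ncol(out)] <- key
  }
  attr(out, "dims") <- dims
  attr(out, "n_missing") <- n_missing
  out
}

#' Within-run ROI background connectivity for one participant
#'
#' Convenience wrapper: mean-series reduction, z-scoring, window extraction
#' and concatenated-window correlation between hippocampus and EVC.
#'
#' @param resid a `bc_resid`.
#' @param window_s window length in seconds.
#' @return Named Fisher-z vector over the four condition cells.
#' @export
roi_connectivity <- function(resid, window_s = 34.5) {
  z_h <- zscore_roi(resid, "hippocampus")
  z_e <- zscore_roi(resid, "evc")
  background_connectivity(
    extract_windows(z_h, resid$design, window_s),
    extract_windows(z_e, resid$design, window_s))
}
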