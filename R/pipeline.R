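# End-to-end orchestration: cohort simulation -> residualization -> all
# connectivity and similarity variants -> behavior -> group statistics.

#' Study-level configuration
#'
#' Collects every analysis parameter in one place. Defaults follow the
#' study protocol: TR 1.5 s, 27 FIR bins, 34.5 s block windows, 128 s
#' high-pass, 1500 ms RT cutoff, dilation sizes 50-5000 voxels, 24
#' participants.
#'
#' @param n_participants cohort size.
#' @param design a [design_config()].
#' @param truth a [ground_truth()] template.
#' @param behavior a [behavior_params()] template.
#' @param variation a [cohort_variation()].
#' @param highpass,cutoff drift removal settings.
#' @param n_bins FIR bins per condition.
#' @param fir_removal logical; FALSE ablates the evoked-removal step (for
#'   control analyses).
#' @param window_s analysis window length (s).
#' @param lag_TRs shift used by the time-lagged variant.
#' @param rt_cutoff RT exclusion cutoff (ms).
#' @param dilation_sizes EVC ROI sizes for the specificity profile.
#' @param n_perm permutations for the voxelwise test.
#' @param analyses which optional stages to run.
#' @return A list of class `bc_study_config`.
#' @export
study_config <- function(n_participants = 24, design = design_config(),
                         truth = ground_truth(),
                         behavior = behavior_params(),
                         variation = cohort_variation(),
                         highpass = TRUE, cutoff = 128, n_bins = 27,
                         fir_removal = TRUE, window_s = 34.5, lag_TRs = 1,
                         rt_cutoff = 1500,
                         dilation_sizes = c(50, 100, 500, 1000, 5000),
                         n_perm = 500,
                         analyses = c("evoked", "connectivity", "control",
                                      "lagged", "dilation", "similarity",
                                      "split", "behavior", "voxelwise")) {
  structure(list(n_participants = n_participants, design = design,
                 truth = truth, behavior = behavior, variation = variation,
                 highpass = highpass, cutoff = cutoff, n_bins = n_bins,
                 fir_removal = fir_removal, window_s = window_s,
                 lag_TRs = lag_TRs, rt_cutoff = rt_cutoff,
                 dilation_sizes = dilation_sizes, n_perm = n_perm,
                 analyses = analyses),
            class = "bc_study_config")
}

cells_to_df <- function(z, participant, variant) {
  keys <- strsplit(names(z), ".", fixed = TRUE)
  data.frame(participant = participant,
             timescale = vapply(keys, `[[`, "", 1L),
             predictiveness = vapply(keys, `[[`, "", 2L),
             variant = variant, z = as.numeric(z),
             stringsAsFactors = FALSE)
}

# All analyses for one materialized participant.
participant_analysis <- function(ds, config) {
  an <- config$analyses
  resid <- residualize(ds$bold, highpass = config$highpass,
                       cutoff = config$cutoff,
                       n_bins = if (config$fir_removal) config$n_bins else
                         NULL)
  design <- ds$design
  id <- ds$id
  out <- list(connectivity = NULL, psc = NULL, dilation = NULL,
              similarity = NULL, behavior = NULL, consistency = NULL,
              diff_map = NULL)

  z_h <- zscore_roi(resid, "hippocampus")
  z_e <- zscore_roi(resid, "evc")

  if ("connectivity" %in% an) {
    within <- background_connectivity(
      extract_windows(z_h, design, config$window_s),
      extract_windows(z_e, design, config$window_s))
    out$connectivity <- cells_to_df(within, id, "within_run")
  }
  if ("control" %in% an && length(design$matched_run_pairs)) {
    ctrl_list <- lapply(design$matched_run_pairs, function(p) {
      across_run_control(z_h, z_e, design, p, config$window_s)
    })
    keys <- unique(unlist(lapply(ctrl_list, names)))
    ctrl <- vapply(keys, function(k) {
      mean(unlist(lapply(ctrl_list, function(v) v[names(v) == k])))
    }, numeric(1))
    out$connectivity <- rbind(out$connectivity,
                              cells_to_df(ctrl, id, "across_run"))
  }
  if ("lagged" %in% an) {
    hip_leads <- lagged_connectivity(z_h, z_e, design, leader = "A",
                                     window_s = config$window_s,
                                     lag_TRs = config$lag_TRs)
    evc_leads <- lagged_connectivity(z_h, z_e, design, leader = "B",
                                     window_s = config$window_s,
                                     lag_TRs = config$lag_TRs)
    out$connectivity <- rbind(out$connectivity,
                              cells_to_df(hip_leads, id, "hip_leads"),
                              cells_to_df(evc_leads, id, "evc_leads"))
  }
  if ("evoked" %in% an && config$fir_removal) {
    psc_rows <- list()
    for (roi in c("hippocampus", "evc")) {
      acc <- list()
      for (run in resid$runs) {
        p <- evoked_psc(run[[paste0(roi, "_fir")]],
                        run[[paste0(roi, "_baseline")]])
        for (key in names(p)) acc[[key]] <- c(acc[[key]], p[[key]])
      }
      psc_rows[[roi]] <- data.frame(
        participant = id, roi = roi, condition = names(acc),
        psc = vapply(acc, mean, numeric(1)), stringsAsFactors = FALSE)
    }
    out$psc <- do.call(rbind, psc_rows)
    rownames(out$psc) <- NULL
  }
  if ("dilation" %in% an) {
    evc_resid <- lapply(resid$runs, function(r) r$evc)
    prof <- dilation_profile(z_h, evc_resid, ds$bold$localizer_scores,
                             design, sizes = config$dilation_sizes,
                             window_s = config$window_s)
    out$dilation <- do.call(rbind, lapply(rownames(prof), function(sz) {
      cells_to_df(prof[sz, ], id, "dilation") |>
        transform(size = sz)
    }))
  }
  if ("voxelwise" %in% an) {
    z_ev <- zscore_roi(resid, "evc", reduction = "per_voxel")
    vm <- voxelwise_map(z_h, z_ev, design, config$window_s,
                        dims = ds$truth$evc_dims)
    if (all(c("day3.predictive", "day3.nonpredictive") %in% colnames(vm))) {
      out$diff_map <- vm[, "day3.predictive"] - vm[, "day3.nonpredictive"]
    }
  }
  if ("similarity" %in% an) {
    sims <- list()
    for (roi in c("hippocampus", "evc")) {
      s <- pattern_similarity(ds$bold, roi, behavior = ds$behavior,
                              highpass = config$highpass,
                              cutoff = config$cutoff)
      s$cells$roi <- roi
      s$cells$variant <- "averaged"
      sims[[roi]] <- s$cells
      if ("split" %in% an) {
        sp <- resampled_split_similarity(ds$bold, roi,
                                         seed = ds$seeds[["resample"]],
                                         behavior = ds$behavior,
                                         highpass = config$highpass,
                                         cutoff = config$cutoff)
        sp$cells$roi <- roi
        sp$cells$variant <- "split"
        sims[[paste0(roi, "_split")]] <- sp$cells
      }
    }
    out$similarity <- transform(do.call(rbind, sims), participant = id)
    rownames(out$similarity) <- NULL
  }
  if ("behavior" %in% an) {
    rt <- rt_summary(ds$behavior$scan, cutoff_ms = config$rt_cutoff)
    rt$participant <- id
    out$behavior <- rt
    cons <- lapply(seq_len(design$config$n_sets), function(s) {
      pre <- ds$behavior$verbal[[paste0("prescan_set", s)]]
      post <- ds$behavior$verbal[[paste0("postscan_set", s)]]
      cs <- consistency_score(pre, post)
      data.frame(participant = id, timescale = cs$timescale,
                 value = cs$value, fully_consistent = cs$fully_consistent,
                 stringsAsFactors = FALSE)
    })
    out$consistency <- do.call(rbind, cons)
    out$eligible <- eligibility(ds$behavior$verbal)
  }
  out
}

group_statistics <- function(tabs, n, config, perm_seed) {
  rows <- list()
  notes <- character(0)
  add <- function(test, stat, df1, df2, estimate, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, statistic = stat, df1 = df1, df2 = df2,
      estimate = estimate, p = p, stringsAsFactors = FALSE)
  }
  note <- function(msg) notes <<- c(notes, msg)
  try_anova <- function(df, value, label) {
    tryCatch({
      a <- rm_anova_2x2(df, value = value)
      for (i in seq_len(nrow(a))) {
        add(paste0(label, ": ", a$effect[i]), a$F[i], a$df1[i], a$df2[i],
            NA_real_, a$p[i])
      }
    }, error = function(e) note(paste0(label, " skipped: ", e$message)))
  }

  conn <- tabs$connectivity
  if (!is.null(conn)) {
    for (v in unique(conn$variant)) {
      try_anova(conn[conn$variant == v, ], "z", paste0("connectivity ", v))
    }
    wr <- conn[conn$variant == "within_run", ]
    d3p <- wr$z[wr$timescale == "day3" & wr$predictiveness == "predictive"]
    d3n <- wr$z[wr$timescale == "day3" &
                  wr$predictiveness == "nonpredictive"]
    tryCatch({
      tt <- paired_t(d3p, d3n)
      add("day3 predictive vs nonpredictive connectivity", tt$t, tt$df, NA,
          tt$mean_diff, tt$p)
    }, error = function(e) note(paste0("day3 paired t skipped: ",
                                       e$message)))
    if ("across_run" %in% conn$variant) {
      ar <- conn[conn$variant == "across_run", ]
      for (ts in unique(wr$timescale)) for (pr in unique(wr$predictiveness)) {
        w <- wr$z[wr$timescale == ts & wr$predictiveness == pr]
        a <- ar$z[ar$timescale == ts & ar$predictiveness == pr]
        tryCatch({
          tt <- paired_t(w, a)
          add(sprintf("within vs across run (%s)", cond_key(ts, pr)),
              tt$t, tt$df, NA, tt$mean_diff, tt$p)
        }, error = function(e) note(paste0("within-vs-across skipped: ",
                                           e$message)))
      }
    }
  }
  if (!is.null(tabs$behavior)) {
    try_anova(tabs$behavior, "mean_rt", "choice RT")
  }
  if (!is.null(tabs$psc)) {
    for (roi in unique(tabs$psc$roi)) {
      df <- tabs$psc[tabs$psc$roi == roi, ]
      keys <- strsplit(df$condition, ".", fixed = TRUE)
      df$timescale <- vapply(keys, `[[`, "", 1L)
      df$predictiveness <- vapply(keys, `[[`, "", 2L)
      try_anova(df, "psc", paste0("evoked PSC ", roi))
    }
  }
  if (!is.null(tabs$similarity)) {
    sim <- tabs$similarity
    for (roi in unique(sim$roi)) {
      df <- sim[sim$roi == roi & sim$variant == "averaged" &
                  sim$type == "within_cue", ]
      try_anova(df, "z", paste0("within-cue similarity ", roi))
    }
  }
  if (!is.null(tabs$consistency)) {
    cs <- tabs$consistency
    d3 <- cs$value[cs$timescale == "day3"]
    nd <- cs$value[cs$timescale == "nodelay"]
    tryCatch({
      tt <- paired_t(nd, d3)
      add("consistency nodelay vs day3", tt$t, tt$df, NA, tt$mean_diff,
          tt$p)
    }, error = function(e) note(paste0("consistency t skipped: ",
                                       e$message)))
    if (!is.null(conn) && n >= 3) {
      wr <- conn[conn$variant == "within_run", ]
      x <- wr$z[wr$timescale == "day3" &
                  wr$predictiveness == "nonpredictive"]
      y <- cs$value[cs$timescale == "day3"]
      tryCatch({
        ct <- between_subject_correlation(x, y)
        add("day3 nonpredictive connectivity ~ consistency", ct$r, NA,
            ct$n - 2, ct$r, ct$p)
      }, error = function(e) note(paste0("consistency correlation ",
                                         "skipped: ", e$message)))
      grp <- cs$fully_consistent[cs$timescale == "day3"]
      if (length(unique(grp)) == 2L && min(table(grp)) >= 2L) {
        tryCatch({
          tt <- two_sample_t(x[grp], x[!grp])
          add("day3 nonpredictive connectivity: consistent vs not", tt$t,
              tt$df, NA, tt$mean_diff, tt$p)
        }, error = function(e) note(paste0("consistency group t ",
                                           "skipped: ", e$message)))
      } else {
        note("consistency group comparison skipped: degenerate groups")
      }
    } else if (!is.null(conn)) {
      note("between-subject stages skipped: need at least 3 participants")
    }
  }
  if (!is.null(tabs$similarity) && !is.null(conn) && n >= 3) {
    wr <- conn[conn$variant == "within_run", ]
    sim <- tabs$similarity
    x <- wr$z[wr$timescale == "day3" & wr$predictiveness == "predictive"]
    y <- sim$z[sim$roi == "hippocampus" & sim$variant == "averaged" &
                 sim$type == "within_cue" & sim$timescale == "day3" &
                 sim$predictiveness == "predictive"]
    tryCatch({
      ct <- between_subject_correlation(x, y)
      add("day3 connectivity ~ hippocampal within-cue similarity", ct$r,
          NA, ct$n - 2, ct$r, ct$p)
    }, error = function(e) note(paste0("similarity correlation skipped: ",
                                       e$message)))
  }

  perm <- NULL
  if (!is.null(tabs$diff_maps)) {
    if (n >= 6) {
      M <- do.call(rbind, tabs$diff_maps)
      attr(M, "dims") <- tabs$map_dims
      perm <- signflip_permutation(M, n_perm = config$n_perm,
                                   seed = perm_seed)
      add("voxelwise day3 predictiveness (min FWE p)", max(perm$enhanced),
          NA, NA, NA_real_, min(perm$p_fwe))
    } else {
      note("voxelwise permutation skipped: need at least 6 participants")
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else NULL,
       notes = notes, permutation = perm)
}

#' Run the full synthetic study
#'
#' Simulates a cohort and executes every configured analysis stage per
#' participant (residualization, evoked PSC, all connectivity variants,
#' dilation profile, voxelwise maps, pattern similarity including the
#' resampled split control, RT and consistency summaries), then the group
#' statistics. Fully deterministic given `(config, seed)`.
#'
#' @param config a [study_config()].
#' @param seed master seed; fans out to named stage seeds.
#' @return Object of class `bc_study_report` with the per-participant
#'   tables, group statistics table, skipped-stage notes, configuration
#'   hash, and runtime.
#' @export
run_study <- function(config = study_config(), seed = 1L) {
  stopifnot(inherits(config, "bc_study_config"))
  t0 <- Sys.time()
  seeds <- derive_seeds(seed, c("cohort", "permute"))
  plan <- cohort_plan(config$n_participants, config$design, config$truth,
                      config$behavior, seeds[["cohort"]], config$variation)
  tabs <- list(connectivity = NULL, psc = NULL, dilation = NULL,
               similarity = NULL, behavior = NULL, consistency = NULL,
               diff_maps = list(), map_dims = config$truth$evc_dims)
  eligible <- logical(0)
  for (i in seq_along(plan)) {
    ds <- simulate_participant(plan[[i]])
    res <- tryCatch(participant_analysis(ds, config), error = function(e) {
      stop(sprintf("analysis failed for participant %d: %s", i,
                   conditionMessage(e)), call. = FALSE)
    })
    for (nm in c("connectivity", "psc", "dilation", "similarity",
                 "behavior", "consistency")) {
      if (!is.null(res[[nm]])) tabs[[nm]] <- rbind(tabs[[nm]], res[[nm]])
    }
    if (!is.null(res$diff_map)) {
      tabs$diff_maps[[length(tabs$diff_maps) + 1L]] <- res$diff_map
    }
    if (!is.null(res$eligible)) eligible <- c(eligible, res$eligible)
    rm(ds)
  }
  if (!length(tabs$diff_maps)) tabs$diff_maps <- NULL
  grp <- group_statistics(tabs, config$n_participants, config,
                          seeds[["permute"]])
  structure(list(
    connectivity = tabs$connectivity, psc = tabs$psc,
    dilation = tabs$dilation, similarity = tabs$similarity,
    behavior = tabs$behavior, consistency = tabs$consistency,
    eligible = eligible, group = grp$table, notes = grp$notes,
    permutation = grp$permutation,
    config = config, config_hash = config_hash(config), seed = seed,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "bc_study_report")
}

#' @export
print.bc_study_report <- function(x, ...) {
  cat(sprintf("<bc_study_report> %d participants, seed %s, config %s\n",
              x$config$n_participants, format(x$seed), x$config_hash))
  if (!is.null(x$connectivity)) {
    wr <- x$connectivity[x$connectivity$variant == "within_run", ]
    agg <- stats::aggregate(z ~ timescale + predictiveness, wr, mean)
    cat("mean within-run background connectivity (Fisher z):\n")
    print(agg, row.names = FALSE)
  }
  if (!is.null(x$group)) {
    cat("group statistics:\n")
    print(x$group, row.names = FALSE)
  }
  if (length(x$notes)) cat("notes:\n", paste(" -", x$notes,
                                             collapse = "\n"), "\n")
  cat(sprintf("runtime: %.1f s\n", x$runtime_s))
  invisible(x)
}
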