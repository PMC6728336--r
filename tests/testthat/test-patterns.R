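make_patterns <- function(mat, meta) {
  structure(list(patterns = mat, meta = meta,
                 counts = stats::setNames(rep(5, nrow(meta)), meta$label)),
            class = "bc_patterns")
}

two_cue_meta <- function(pr = "predictive") {
  if (pr == "predictive") {
    data.frame(label = c("c1.left", "c1.right", "c2.left", "c2.right"),
               cue = c("c1", "c1", "c2", "c2"), predictiveness = pr,
               action = c("left", "right", "left", "right"),
               outcome = c("c1_o1", "c1_o2", "c2_o1", "c2_o2"),
               partition = NA_character_, stringsAsFactors = FALSE)
  } else {
    data.frame(label = c("d1_o1", "d1_o2", "d2_o1", "d2_o2"),
               cue = c("d1", "d1", "d2", "d2"), predictiveness = pr,
               action = NA_character_,
               outcome = c("d1_o1", "d1_o2", "d2_o1", "d2_o2"),
               partition = NA_character_, stringsAsFactors = FALSE)
  }
}

test_that("beta averaging across runs preserves equal patterns and counts", {
  meta <- two_cue_meta()
  set.seed(1)
  B <- matrix(rnorm(4 * 30), 4, 30, dimnames = list(meta$label, NULL))
  mk <- function() structure(list(betas = B,
                                  counts = stats::setNames(rep(5L, 4),
                                                           meta$label)),
                             class = "bc_betas")
  avg <- average_betas(list(mk(), mk(), mk()), meta)
  expect_equal(avg$patterns, B)
  expect_true(all(avg$counts == 5))
  # a pattern missing from one run is excluded with a warning
  b2 <- mk()
  b2$betas <- b2$betas[-1, , drop = FALSE]
  b2$counts <- b2$counts[-1]
  expect_warning(avg2 <- average_betas(list(mk(), b2), meta), "missing")
  expect_false("c1.left" %in% rownames(avg2$patterns))
})

test_that("within-cue similarity reflects pattern geometry and is affine-invariant", {
  meta <- two_cue_meta()
  set.seed(2)
  base <- rnorm(50)
  base2 <- rnorm(50)
  mat <- rbind(base, base, base2, base2)
  rownames(mat) <- meta$label
  wi <- within_cue_similarity(make_patterns(mat, meta))
  expect_gt(wi[["predictive"]], 13)  # identical patterns hit the clip
  # orthogonal mean-centered patterns give z ~ 0
  v1 <- rep(c(1, -1), 25)
  v2 <- rep(c(1, 1, -1, -1), length.out = 50)
  mat2 <- rbind(v1, v2, v1, v2)
  rownames(mat2) <- meta$label
  expect_lt(abs(within_cue_similarity(make_patterns(mat2, meta))[[
    "predictive"]]), 1e-10)
  # common affine rescaling of the patterns leaves similarity unchanged
  wi_scaled <- within_cue_similarity(make_patterns(3 * mat2 + 5, meta))
  expect_equal(wi_scaled, within_cue_similarity(make_patterns(mat2, meta)),
               tolerance = 1e-10)
  expect_error(within_cue_similarity(make_patterns(0 * mat2, meta)),
               "zero-variance")
})

test_that("across-cue pairs never share cue or outcome and detect shared components", {
  meta <- two_cue_meta()
  set.seed(3)
  common <- rnorm(80)
  mat <- t(replicate(4, 0.8 * common + 0.6 * rnorm(80)))
  rownames(mat) <- meta$label
  pat <- make_patterns(mat, meta)
  ac <- across_cue_similarity(pat)
  # shared cue-independent component produces positive similarity
  expect_gt(ac[["predictive"]], 0.3)
  for (pairs in attr(ac, "pairs")) {
    for (p in pairs) {
      m1 <- meta[meta$label == p[1], ]
      m2 <- meta[meta$label == p[2], ]
      expect_false(m1$cue == m2$cue)
      expect_false(m1$outcome == m2$outcome)
    }
  }
  # independent patterns give near-zero similarity
  mat0 <- matrix(rnorm(4 * 2000), 4, 2000, dimnames = list(meta$label, NULL))
  ac0 <- across_cue_similarity(make_patterns(mat0, meta))
  expect_lt(max(abs(ac0), na.rm = TRUE), 0.1)
})

test_that("pattern similarity recovers the generator's differentiation ordering", {
  d <- build_design(seed = 3)
  tt <- ground_truth(n_voxels = c(hippocampus = 30, evc = 48),
                     noise_sd = 0.5, pattern_amplitude = 1.5)
  ok <- logical(3)
  for (i in 1:3) {
    b <- simulate_bold(d, tt, seed = 20 + i)
    s <- pattern_similarity(b, "evc")
    cells <- s$cells
    z <- function(ts, pr, ty) cells$z[cells$timescale == ts &
                                        cells$predictiveness == pr &
                                        cells$type == ty]
    ok[i] <- z("day3", "predictive", "within_cue") <
      z("day3", "nonpredictive", "within_cue")
    # across-cue similarity stays near zero (no common component)
    expect_lt(max(abs(cells$z[cells$type == "across_cue"])), 0.25)
  }
  expect_true(all(ok))
})

test_that("within- and across-cue similarity use the identical averaged patterns", {
  d <- build_design(small_config(n_runs = 2), seed = 4)
  tt <- tiny_truth(pattern_amplitude = 1)
  b <- simulate_bold(d, tt, seed = 31)
  betas <- backconn:::split_run_betas(b, "evc", NULL, "averaged", NULL,
                                      TRUE, 128)
  meta <- backconn:::label_meta(d, 1, "averaged")
  pat <- average_betas(betas$set1, meta)
  expect_equal(nrow(pat$patterns), 8)  # 4 predictive + 4 nonpredictive
  wi <- within_cue_similarity(pat)
  ac <- across_cue_similarity(pat)
  expect_true(all(is.finite(c(wi, ac))))
})

test_that("the resampled split control halves trial counts and tracks the primary estimate", {
  d <- build_design(seed = 5)
  tt <- ground_truth(n_voxels = c(hippocampus = 20, evc = 48),
                     noise_sd = 0.3, pattern_amplitude = 3)
  b <- simulate_bold(d, tt, seed = 41)
  sp1 <- suppressWarnings(resampled_split_similarity(b, "evc", seed = 6))
  sp2 <- suppressWarnings(resampled_split_similarity(b, "evc", seed = 6))
  expect_identical(sp1$cells, sp2$cells)  # same seed, same partitions
  counts <- unlist(sp1$counts)
  expect_lt(abs(mean(counts) - 2.5), 0.6)  # ~2.5 trials per run per pattern
  s <- pattern_similarity(b, "evc")
  for (ts in c("day3", "nodelay")) {
    for (pr in c("predictive", "nonpredictive")) {
      z_split <- sp1$cells$z[sp1$cells$timescale == ts &
                               sp1$cells$predictiveness == pr]
      z_full <- s$cells$z[s$cells$timescale == ts &
                            s$cells$predictiveness == pr &
                            s$cells$type == "within_cue"]
      expect_lt(abs(z_split - z_full), 0.25)
    }
  }
})

test_that("trial-count balancing equates estimator variance across conditions", {
  d <- build_design(seed = 6)
  tt <- ground_truth(n_voxels = c(hippocampus = 10, evc = 200),
                     noise_sd = 1, pattern_amplitude = 0)
  b <- simulate_bold(d, tt, seed = 51)
  betas <- backconn:::split_run_betas(b, "evc", NULL, "averaged", NULL,
                                      TRUE, 128)
  meta <- backconn:::label_meta(d, 1, "averaged")
  pat <- average_betas(betas$set1, meta)
  v <- apply(pat$patterns, 1, var)
  v_pred <- mean(v[meta$predictiveness[match(names(v), meta$label)] ==
                     "predictive"])
  v_non <- mean(v[meta$predictiveness[match(names(v), meta$label)] ==
                    "nonpredictive"])
  expect_gt(v_pred / v_non, 0.5)
  expect_lt(v_pred / v_non, 2)
  # observation counts differ only by the excluded counter trial
  c_pred <- mean(pat$counts[meta$predictiveness == "predictive"])
  c_non <- mean(pat$counts[meta$predictiveness == "nonpredictive"])
  expect_lt(abs(c_pred - c_non), 0.5)
})
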