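test_that("within-run z-scoring is exact and affine-invariant", {
  set.seed(5)
  x <- matrix(rnorm(60), 3, 20)
  z <- zscore_run(x)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  expect_equal(zscore_run(3 * x + 2), z, tolerance = 1e-12)
  expect_error(zscore_run(rbind(x, 0 * x[1, ]), label = "run 1 evc"),
               "run 1 evc")
})

test_that("window extraction yields 23 samples per block, 4 per condition per run", {
  d <- build_design(seed = 3)
  z <- lapply(d$runs, function(r) rnorm(d$config$n_timepoints))
  w <- extract_windows(z, d)
  expect_equal(attr(w, "window_len"), 23)  # 34.5 s / 1.5 s
  for (key in names(w)) {
    runs <- vapply(w[[key]], `[[`, numeric(1), "run")
    expect_true(all(table(runs) == 4))
    expect_true(all(lengths(lapply(w[[key]], `[[`, "samples")) == 23))
  }
  # window accounting: 4 x 23 = 92 concatenated samples per condition per run
  key1 <- names(w)[1]
  r1 <- vapply(w[[key1]], `[[`, numeric(1), "run")
  expect_equal(sum(lengths(lapply(w[[key1]][r1 == r1[1]], `[[`,
                                  "samples"))), 92)
  # lag shifts every start index by one sample
  w1 <- extract_windows(z, d, lag_TRs = 1)
  expect_equal(w1[[key1]][[1]]$samples[1:22], w[[key1]][[1]]$samples[2:23])
  # windows beyond the run bounds are refused, naming the block
  expect_error(extract_windows(z, d, window_s = 80, lag_TRs = 10), "block")
})

test_that("connectivity of a signal with itself exercises the clipping path", {
  d <- build_design(small_config(), seed = 1)
  z <- lapply(d$runs, function(r) rnorm(d$config$n_timepoints))
  w <- extract_windows(z, d)
  zz <- background_connectivity(w, w)
  expect_true(all(is.finite(zz)))
  expect_true(all(zz > 13))  # arctanh of the clipped correlation
})

test_that("independent white noise gives null connectivity", {
  d <- build_design(seed = 8)
  set.seed(42)
  zA <- lapply(d$runs, function(r) rnorm(d$config$n_timepoints))
  zB <- lapply(d$runs, function(r) rnorm(d$config$n_timepoints))
  z <- background_connectivity(extract_windows(zA, d),
                               extract_windows(zB, d))
  expect_true(all(abs(z) < 0.15))
})

test_that("Fisher-z averaging equals the per-run oracle", {
  d <- build_design(small_config(), seed = 2)
  set.seed(9)
  zA <- lapply(d$runs, function(r) rnorm(d$config$n_timepoints))
  zB <- lapply(d$runs, function(r) rnorm(d$config$n_timepoints))
  wa <- extract_windows(zA, d)
  wb <- extract_windows(zB, d)
  z <- background_connectivity(wa, wb)
  for (key in names(z)) {
    manual <- vapply(1:2, function(r) {
      runs <- vapply(wa[[key]], `[[`, numeric(1), "run")
      a <- unlist(lapply(wa[[key]][runs == r], `[[`, "samples"))
      b <- unlist(lapply(wb[[key]][runs == r], `[[`, "samples"))
      atanh(cor(a, b))
    }, numeric(1))
    expect_equal(unname(z[[key]]), mean(manual), tolerance = 1e-12)
  }
})

test_that("relabeling conditions permutes the result cells exactly", {
  d <- build_design(small_config(), seed = 4)
  set.seed(2)
  zA <- lapply(d$runs, function(r) rnorm(d$config$n_timepoints))
  zB <- lapply(d$runs, function(r) rnorm(d$config$n_timepoints))
  z1 <- background_connectivity(extract_windows(zA, d),
                                extract_windows(zB, d))
  d_sw <- d
  for (r in seq_along(d_sw$runs)) {
    p <- d_sw$runs[[r]]$blocks$predictiveness
    d_sw$runs[[r]]$blocks$predictiveness <-
      ifelse(p == "predictive", "nonpredictive", "predictive")
  }
  z2 <- background_connectivity(extract_windows(zA, d_sw),
                                extract_windows(zB, d_sw))
  expect_equal(unname(z1[["day3.predictive"]]),
               unname(z2[["day3.nonpredictive"]]), tolerance = 1e-12)
  expect_equal(unname(z1[["day3.nonpredictive"]]),
               unname(z2[["day3.predictive"]]), tolerance = 1e-12)
})

test_that("across-run control is exactly null for removable evoked signal", {
  d <- build_design(small_config(), seed = 5)
  b <- simulate_bold(d, noiseless_truth(evoked_amplitude = 2), seed = 7)
  res <- residualize(b)
  z_h <- zscore_roi(res, "hippocampus")
  z_e <- zscore_roi(res, "evc")
  ctrl <- across_run_control(z_h, z_e, d, d$matched_run_pairs[[1]])
  expect_lt(max(abs(ctrl)), 1e-6)
  expect_error(across_run_control(z_h, z_e, d, c(1, 1)), "matched pair")
})

test_that("skipping FIR removal leaks shared evoked signal into the control", {
  d <- build_design(small_config(), seed = 5)
  tt <- ground_truth(evoked_amplitude = 2, nuisance_gain = 0,
                     pattern_amplitude = 0, latent_gain = 0.2,
                     noise_sd = 0.5,
                     n_voxels = c(hippocampus = 6, evc = 8))
  b <- simulate_bold(d, tt, seed = 7)
  no_fir <- residualize(b, n_bins = NULL)
  ctrl_leak <- across_run_control(zscore_roi(no_fir, "hippocampus"),
                                  zscore_roi(no_fir, "evc"),
                                  d, d$matched_run_pairs[[1]])
  expect_gt(mean(ctrl_leak), 0.2)
  with_fir <- residualize(b)
  ctrl_clean <- across_run_control(zscore_roi(with_fir, "hippocampus"),
                                   zscore_roi(with_fir, "evc"),
                                   d, d$matched_run_pairs[[1]])
  expect_lt(mean(abs(ctrl_clean)), mean(ctrl_leak))
})

test_that("lagged windows span 22 samples and a zero-lag generator is symmetric", {
  d <- build_design(small_config(n_runs = 4), seed = 6)
  tt <- latent_truth(rho = 0.5, noise_sd = 0.2, lag = 0)
  b <- simulate_bold(d, tt, seed = 11)
  z_h <- lapply(b$runs, function(r) zscore_run(colMeans(r$hippocampus)))
  z_e <- lapply(b$runs, function(r) zscore_run(colMeans(r$evc)))
  # leader window sample count: 33 s / 1.5 s
  w <- extract_windows(z_h, d, window_len = 22)
  expect_true(all(lengths(lapply(w[[1]], `[[`, "samples")) == 22))
  hip_leads <- lagged_connectivity(z_h, z_e, d, leader = "A")
  evc_leads <- lagged_connectivity(z_h, z_e, d, leader = "B")
  expect_lt(abs(mean(hip_leads) - mean(evc_leads)), 0.08)
})

test_that("dilation profile is nested, stable under ties, and detects localized coupling", {
  d <- build_design(small_config(n_runs = 4), seed = 7)
  tt <- ground_truth(evoked_amplitude = 0, nuisance_gain = 0,
                     pattern_amplitude = 0, rho = 0.6, noise_sd = 0.4,
                     n_voxels = c(hippocampus = 6, evc = 64),
                     coupling_profile = "localizer")
  b <- simulate_bold(d, tt, seed = 13)
  res <- residualize(b)
  z_h <- zscore_roi(res, "hippocampus")
  evc_res <- lapply(res$runs, function(r) r$evc)
  prof <- dilation_profile(z_h, evc_res, b$localizer_scores, d,
                           sizes = c(8, 32, 5000))
  expect_equal(rownames(prof), c("8", "32", "all"))
  # the full-size row equals the plain ROI-mean computation
  z_all <- background_connectivity(
    extract_windows(z_h, d),
    extract_windows(lapply(evc_res, function(m) zscore_run(colMeans(m))),
                    d))
  expect_equal(as.numeric(prof["all", names(z_all)]), as.numeric(z_all),
               tolerance = 1e-12)
  # coupling loaded on high-localizer voxels dilutes as the ROI grows
  expect_gt(mean(prof["8", ]), mean(prof["all", ]))
  # top-k sets are nested and ties break by voxel index
  scores <- c(3, 1, 1, 2)
  ord <- order(-scores, seq_along(scores))
  expect_equal(ord[1:3], c(1, 4, 2))
})

test_that("voxelwise maps preserve shape and recover the null under misalignment", {
  d <- build_design(small_config(n_runs = 4), seed = 9)
  tt <- latent_truth(rho = 0.4, noise_sd = 0.5)
  b <- simulate_bold(d, tt, seed = 17)
  res <- residualize(b)
  z_h <- zscore_roi(res, "hippocampus")
  z_ev <- zscore_roi(res, "evc", reduction = "per_voxel")
  vm <- voxelwise_map(z_h, z_ev, d, dims = c(2, 2, 2))
  expect_equal(nrow(vm), 8)
  expect_equal(sort(colnames(vm)), sort(all_cond_keys()[grep("day3",
                                                             all_cond_keys())]))
  expect_equal(attr(vm, "dims"), c(2, 2, 2))
  # a voxel identical to the seed maps to the clipped maximum
  z_self <- voxelwise_map(z_h, lapply(z_h, function(v) rbind(v)), d)
  expect_true(all(z_self > 13))
  # circularly shifting the seed by half a run destroys the coupling
  z_shift <- lapply(z_h, function(v) c(tail(v, 110), head(v, 110)))
  vm0 <- voxelwise_map(z_shift, z_ev, d)
  null_bound <- 2 / sqrt(92 - 3)
  expect_gt(mean(abs(vm0) < null_bound), 0.9)
})
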