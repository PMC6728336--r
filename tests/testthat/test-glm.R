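test_that("high-pass projection removes slow components and keeps fast ones", {
  TR <- 1.5
  n <- 220
  tt <- (seq_len(n) - 1) * TR
  expect_equal(max(abs(high_pass(rep(3, n), TR))), 0)

  # amplitude measured by regressing on sine/cosine at the probe frequency
  amp <- function(x, period) {
    X <- cbind(sin(2 * pi * tt / period), cos(2 * pi * tt / period))
    sqrt(sum(ols_oracle(X, x)^2))
  }
  slow <- sin(2 * pi * tt / 330)
  expect_lt(amp(as.numeric(high_pass(slow, TR)), 330), 0.1)  # >90% removed
  fast <- sin(2 * pi * tt / 30)
  expect_gt(amp(as.numeric(high_pass(fast, TR)), 30), 0.95)  # <5% loss

  expect_warning(high_pass(rnorm(20), TR, cutoff = 128), "cutoff")
  expect_error(high_pass(rnorm(20), TR, cutoff = 2), "exceed")
})

test_that("nuisance regression is an exact least-squares projection", {
  set.seed(31)
  n <- 60
  N <- matrix(rnorm(n * 3), n, 3)
  colnames(N) <- c("m1", "m2", "wm")
  # a pure nuisance signal is annihilated
  expect_lt(max(abs(regress_nuisance(2.5 * N[, 1], N))), 1e-10)
  # an orthogonal signal survives up to its mean
  sig <- qr.resid(qr(cbind(1, N)), rnorm(n))
  expect_equal(as.numeric(regress_nuisance(sig + 7, N)), sig,
               tolerance = 1e-10)
  # 10-sample case matches the normal-equations oracle
  X10 <- matrix(rnorm(20), 10, 2)
  y10 <- rnorm(10)
  res_oracle <- y10 - cbind(1, scale(X10, scale = FALSE)) %*%
    ols_oracle(cbind(1, scale(X10, scale = FALSE)), y10)
  expect_equal(as.numeric(regress_nuisance(y10, X10)),
               as.numeric(res_oracle), tolerance = 1e-10)
  # residual orthogonality to every centered nuisance column
  r <- regress_nuisance(rnorm(n), N)
  Nc <- scale(N, scale = FALSE)
  expect_lt(max(abs(crossprod(Nc, as.numeric(r)))) / n, 1e-8)
  # duplicated columns are dropped with a warning
  expect_warning(regress_nuisance(rnorm(n), cbind(N, m1b = N[, 1])),
                 "rank-deficient")
})

test_that("FIR deconvolution spans the block cycle and removes representable signal exactly", {
  d <- build_design(small_config(), seed = 2)
  F_ <- fir_design(d$runs[[1]], d$config)
  expect_equal(ncol(F_), 2 * 27)  # 27 delta bins per condition
  expect_true(all(colSums(F_) %in% c(3, 4)))  # one delta per block, 4 blocks

  tt <- noiseless_truth(evoked_amplitude = 1.2)
  b <- simulate_bold(d, tt, seed = 3)
  fir <- fit_fir(b$runs[[1]]$hippocampus, d$runs[[1]], d$config)
  expect_lt(max(abs(fir$residuals)), 1e-6)
  # residuals orthogonal to every FIR column
  expect_lt(max(abs(fir$design[, -1] |> crossprod(t(fir$residuals)))) /
              d$config$n_timepoints, 1e-8)
  # recovered kernel equals the generator kernel (in signal units)
  kern <- tt$baseline / 100 * evoked_kernel(1.2, d$config)
  for (ci in seq_along(fir$conditions)) {
    expect_equal(unname(fir$estimates[ci, , 1]), kern, tolerance = 1e-6)
  }
  expect_error(fit_fir(b$runs[[1]]$hippocampus, d$runs[[1]], d$config,
                       n_bins = 200), "fewer than")
})

test_that("evoked percent signal change matches the analytic kernel average", {
  d <- build_design(small_config(), seed = 2)
  tt <- noiseless_truth(evoked_amplitude = 1)
  b <- simulate_bold(d, tt, seed = 3)
  fir <- fit_fir(b$runs[[1]]$hippocampus, d$runs[[1]], d$config)
  expect_length(5:19, 15)  # TRs 5-19 inclusive
  psc <- evoked_psc(fir, baseline = tt$baseline)
  analytic <- mean(evoked_kernel(1, d$config)[5:19])
  for (key in names(psc)) {
    expect_lt(abs(psc[[key]] - analytic) / analytic, 0.02)
  }
  # zero evoked amplitude gives zero PSC
  b0 <- simulate_bold(d, noiseless_truth(evoked_amplitude = 0), seed = 3)
  fir0 <- fit_fir(b0$runs[[1]]$hippocampus, d$runs[[1]], d$config)
  expect_lt(max(abs(evoked_psc(fir0, tt$baseline))), 1e-6)
  expect_error(evoked_psc(fir, baseline = 0), "positive")
})

test_that("event GLM recovers per-transition amplitudes in rank order", {
  cfg <- small_config(n_runs = 1)
  TR <- cfg$TR
  n_tp <- cfg$n_timepoints
  labels <- c("A", "B", "C", "D")
  amps <- c(A = 1, B = 2, C = 3, D = 4)
  set.seed(44)
  betas_runs <- lapply(1:4, function(run) {
    onsets <- seq(10, 300, by = 9)
    ev <- data.frame(onset = onsets,
                     regressor = sample(rep(labels, length.out =
                                              length(onsets))))
    y <- numeric(n_tp)
    for (lab in labels) {
      y <- y + amps[[lab]] * hrf_regressor(ev$onset[ev$regressor == lab],
                                           2.4, n_tp, TR)
    }
    y <- y + rnorm(n_tp, sd = 0.2)
    fit_event_glm(y, ev, cfg, trial_duration = 2.4)
  })
  avg <- rowMeans(sapply(betas_runs, function(b) b$betas[labels, 1]))
  expect_equal(order(avg), 1:4)
  expect_equal(unname(avg), unname(amps), tolerance = 0.25)
})

test_that("event GLM handles durations, missed and counter trials, empty regressors", {
  cfg <- small_config(n_runs = 1)
  n_tp <- cfg$n_timepoints
  y <- rnorm(n_tp)
  ev <- data.frame(onset = c(10, 50, 90, 130), regressor = c("A", "A", "B", "B"),
                   predicted = c(TRUE, TRUE, FALSE, TRUE),
                   rt = c(500, NA, 700, 1300))
  b <- fit_event_glm(y, ev, cfg)
  # duration derived from mean kept RT (500, 1300 -> 2900ms, clamped)
  expect_equal(b$duration, 2.643)
  expect_true(all(c("counter", "missed") %in% colnames(b$design)))
  expect_equal(unname(b$counts[c("A", "B")]), c(1L, 1L))
  # clamping low
  ev$rt <- c(100, 120, 90, 110)
  expect_equal(fit_event_glm(y, ev, cfg)$duration, 2.188)
  # no RT information: default 2.4 s
  expect_equal(fit_event_glm(y, ev[, 1:2], cfg)$duration, 2.4)
  # an expected label with no trials is dropped with a warning
  expect_warning(
    b2 <- fit_event_glm(y, ev[, 1:2], cfg, labels = c("A", "B", "C")),
    "empty regressor")
  expect_equal(b2$missing, "C")
  # near-zero input gives near-zero betas
  b3 <- fit_event_glm(rnorm(n_tp, sd = 1e-8), ev[, 1:2], cfg)
  expect_lt(max(abs(b3$betas)), 1e-6)
})

test_that("all estimators match a direct normal-equations solve", {
  set.seed(12)
  X <- cbind(1, matrix(rnorm(36), 12, 3))
  y <- rnorm(12)
  fit <- backconn:::ols_fit(X, matrix(y))
  expect_equal(as.numeric(fit$coef), as.numeric(ols_oracle(X, y)),
               tolerance = 1e-10)
})

test_that("AR(1) prewhitening estimates the residual autocorrelation", {
  set.seed(7)
  n <- 400
  X <- cbind(1, rnorm(n))
  e <- as.numeric(stats::filter(rnorm(n), 0.5, method = "recursive"))
  y <- X %*% c(1, 2) + e
  fit <- backconn:::prewhiten_ar1(X, matrix(y))
  expect_lt(abs(fit$phi - 0.5), 0.12)
  expect_equal(as.numeric(fit$coef), c(1, 2), tolerance = 0.2)
})
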