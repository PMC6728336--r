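test_that("Fisher transform matches its closed form and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  r <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
})

test_that("t-tests follow the classical formulas and refuse degenerate input", {
  # hand-computed two-sample case: means 2.05 vs 1.05, pooled sd 0.1291
  x <- c(2.1, 1.9, 2.0, 2.2)
  y <- c(1.0, 1.2, 0.9, 1.1)
  tt <- two_sample_t(x, y)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(tt$t, t_hand, tolerance = 1e-10)
  expect_equal(tt$df, 6)
  expect_lt(tt$p, 0.001)

  # near-constant differences: huge t, small p
  a <- c(1, 2, 3, 4)
  b <- a + 1 + c(1e-4, -1e-4, 1e-4, -1e-4)
  pt_ <- paired_t(b, a)
  expect_gt(abs(pt_$t), 100)
  expect_lt(pt_$p, 1e-5)
  # constant paired differences are an error, not a number
  expect_error(paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero variance")
  # cross-check against the reference implementation
  set.seed(3)
  u <- rnorm(10); v <- rnorm(10)
  ref <- t.test(u, v, paired = TRUE)
  mine <- paired_t(u, v)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
})

test_that("2x2 repeated-measures ANOVA equals the contrast t^2 and the aov oracle", {
  set.seed(11)
  n <- 10
  df <- expand.grid(participant = seq_len(n),
                    timescale = c("day3", "nodelay"),
                    predictiveness = c("predictive", "nonpredictive"),
                    stringsAsFactors = FALSE)
  df$z <- rnorm(nrow(df)) +
    ifelse(df$timescale == "day3" & df$predictiveness == "predictive",
           0.8, 0)
  a <- rm_anova_2x2(df)
  # F = t^2 for the interaction contrast
  g <- function(ts, pr) df$z[df$timescale == ts & df$predictiveness == pr][
    order(df$participant[df$timescale == ts & df$predictiveness == pr])]
  contrast <- (g("day3", "predictive") - g("day3", "nonpredictive")) -
    (g("nodelay", "predictive") - g("nodelay", "nonpredictive"))
  t_c <- mean(contrast) / (sd(contrast) / sqrt(n))
  expect_equal(a$F[a$effect == "interaction"], t_c^2, tolerance = 1e-10)

  # equality with aov's within-participant strata
  df$ts <- factor(df$timescale); df$pr <- factor(df$predictiveness)
  df$id <- factor(df$participant)
  sm <- summary(aov(z ~ ts * pr + Error(id / (ts * pr)), data = df))
  f_aov <- c(sm[["Error: id:ts"]][[1]]$`F value`[1],
             sm[["Error: id:pr"]][[1]]$`F value`[1],
             sm[["Error: id:ts:pr"]][[1]]$`F value`[1])
  expect_equal(a$F, f_aov, tolerance = 1e-8)
  expect_equal(a$df1, rep(1, 3))
  expect_equal(a$df2, rep(n - 1, 3))

  # exactly additive cells leave a zero-variance interaction contrast
  df_add <- df
  df_add$z <- as.numeric(factor(df_add$timescale)) +
    2 * as.numeric(factor(df_add$predictiveness)) + rep(rnorm(n), 4)
  expect_error(rm_anova_2x2(df_add), "zero variance")
  # near-additive data: main effects dwarf the interaction
  df_add$z <- df_add$z + rnorm(nrow(df_add)) * 1e-4
  a_add <- rm_anova_2x2(df_add)
  expect_gt(a_add$F[a_add$effect == "predictiveness"], 1e4)
  expect_lt(a_add$F[a_add$effect == "interaction"], 30)

  expect_error(rm_anova_2x2(df[-1, ]), "missing cell")
})

test_that("between-subject correlation matches direct arithmetic", {
  expect_equal(between_subject_correlation(1:10, 1:10)$r, 1)
  set.seed(21)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(abs(between_subject_correlation(x, y)$r), 0.08)
  # 5-point hand oracle
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x5 - mean(x5)) * (y5 - mean(y5))) /
    sqrt(sum((x5 - mean(x5))^2) * sum((y5 - mean(y5))^2))
  expect_equal(between_subject_correlation(x5, y5)$r, r_hand,
               tolerance = 1e-12)
  expect_error(between_subject_correlation(1:2, 1:2), "at least 3")
  expect_error(between_subject_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("TFCE matches its closed form and a brute-force oracle", {
  z <- array(0, c(5, 5, 5))
  expect_equal(tfce(z), z)
  # isolated voxel: integral of h^2 dh up to v -> v^3 / 3
  z[3, 3, 3] <- 2
  e <- tfce(z)
  expect_equal(e[3, 3, 3], 8 / 3, tolerance = 0.03)
  expect_equal(sum(e != 0), 1)
  # negative values are enhanced on the negated map
  z[1, 1, 1] <- -2
  e2 <- tfce(z)
  expect_equal(e2[1, 1, 1], -e2[3, 3, 3], tolerance = 1e-10)

  # random map against the plain-R flood-fill oracle
  set.seed(31)
  m <- array(pmax(rnorm(125), 0), c(5, 5, 5))
  expect_equal(tfce(m, n_steps = 20), tfce_oracle(m, n_steps = 20),
               tolerance = 1e-10)
  expect_equal(tfce(m, n_steps = 20, connectivity = 6),
               tfce_oracle(m, n_steps = 20, connectivity = 6),
               tolerance = 1e-10)
  expect_error(tfce(matrix(0, 3, 3)), "3D")
})

test_that("TFCE scales as 2^(H+1) under doubling and is monotone at fixed maximum", {
  set.seed(32)
  m <- array(pmax(rnorm(5 * 5 * 5), 0), c(5, 5, 5))
  expect_equal(tfce(2 * m), 8 * tfce(m), tolerance = 1e-10)
  # raising sub-maximal voxels never decreases any enhancement
  m2 <- m
  sub <- m2 < max(m2) * 0.5
  m2[sub] <- m2[sub] + 0.2 * max(m2)
  expect_true(all(tfce(m2) - tfce(m) > -1e-10))
})

test_that("sign-flip permutation flags a shared focal effect and is reproducible", {
  set.seed(41)
  maps <- lapply(1:16, function(i) {
    a <- array(rnorm(8 * 8 * 4) * 0.05, c(8, 8, 4))
    a[4, 4, 2] <- a[4, 4, 2] + 5
    a
  })
  p1 <- signflip_permutation(maps, n_perm = 200, seed = 7)
  expect_equal(p1$p_fwe[4, 4, 2], 1 / 201)
  expect_equal(which.min(p1$p_fwe), which.max(p1$enhanced))
  p2 <- signflip_permutation(maps, n_perm = 200, seed = 7)
  expect_identical(p1$p_fwe, p2$p_fwe)
  expect_true(all(p1$p_fwe >= 1 / 201 & p1$p_fwe <= 1))
  expect_warning(signflip_permutation(maps, n_perm = 50, seed = 1),
                 "coarse")
  expect_error(signflip_permutation(maps[1:4], n_perm = 200, seed = 1),
               "at least 6")
})
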