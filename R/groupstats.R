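# Group-level inference: Fisher transforms, t-tests, 2x2 repeated-measures
# ANOVA via 1-df contrasts, between-subject correlations, and the voxelwise
# sign-flip permutation test with threshold-free cluster enhancement.

#' Fisher z-transform and its inverse
#'
#' @param r correlation coefficient(s); values outside (-1, 1) are clipped.
#' @param z Fisher-z value(s).
#' @return `fisher_z`: `atanh(r)`; `fisher_z_inv`: `tanh(z)`.
#' @export
fisher_z <- function(r) {
  atanh(clip(r, -1, 1))
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

check_variance <- function(x, what) {
  if (length(x) < 2L || sd(x) == 0) {
    stop("zero variance in ", what, "; t statistic undefined", call. = FALSE)
  }
}

#' Paired-sample t-test
#'
#' @param x,y paired samples.
#' @return List with `t`, `df`, `p` (two-tailed), `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  check_variance(x - y, "paired differences")
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Two-sample t-test (pooled variance)
#'
#' @param x,y independent samples.
#' @return List with `t`, `df`, `p` (two-tailed), `mean_diff`.
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (sd(c(x - mean(x), y - mean(y))) == 0) {
    stop("zero variance in both groups; t statistic undefined",
         call. = FALSE)
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(x) - mean(y))
}

one_sample_f <- function(d, effect) {
  check_variance(d, paste0("the ", effect, " contrast"))
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  data.frame(effect = effect, F = t^2, df1 = 1, df2 = n - 1,
             p = 2 * pt(-abs(t), n - 1), stringsAsFactors = FALSE)
}

#' 2x2 repeated-measures ANOVA
#'
#' Within-participant main effects and interaction computed as 1-df
#' contrasts (for 2x2 cells each effect's F equals the squared paired t of
#' its contrast).
#'
#' @param data data.frame with one row per participant x cell.
#' @param value,id,f1,f2 column names of the response, participant
#'   identifier, and the two within-participant factors (2 levels each).
#' @return Object of class `bc_anova`: data.frame with `effect`, `F`,
#'   `df1`, `df2`, `p` for both main effects and the interaction.
#' @export
rm_anova_2x2 <- function(data, value = "z", id = "participant",
                         f1 = "timescale", f2 = "predictiveness") {
  l1 <- sort(unique(data[[f1]]))
  l2 <- sort(unique(data[[f2]]))
  if (length(l1) != 2L || length(l2) != 2L) {
    stop("both factors must have exactly two levels", call. = FALSE)
  }
  ids <- unique(data[[id]])
  cell <- function(a, b) {
    v <- rep(NA_real_, length(ids))
    sel <- data[[f1]] == a & data[[f2]] == b
    v[match(data[[id]][sel], ids)] <- data[[value]][sel]
    if (anyNA(v)) {
      stop(sprintf("missing cell (%s, %s) for some participant(s)", a, b),
           call. = FALSE)
    }
    v
  }
  y11 <- cell(l1[1], l2[1]); y12 <- cell(l1[1], l2[2])
  y21 <- cell(l1[2], l2[1]); y22 <- cell(l1[2], l2[2])
  res <- rbind(
    one_sample_f((y11 + y12) / 2 - (y21 + y22) / 2, f1),
    one_sample_f((y11 + y21) / 2 - (y12 + y22) / 2, f2),
    one_sample_f((y11 - y12) - (y21 - y22), "interaction"))
  structure(res, class = c("bc_anova", "data.frame"))
}

#' Between-subject Pearson correlation
#'
#' @param x,y per-participant values.
#' @return List with `r`, `p` (two-tailed, from the t transform), `n`.
#' @export
between_subject_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds: each voxel's
#' enhanced value is `sum_h e(h)^E * h^H * dh`, where `e(h)` is the size of
#' the suprathreshold connected component containing the voxel at height
#' `h`. Negative values are enhanced on the negated map separately and
#' returned with a negative sign.
#'
#' @param stat_map 3D numeric array.
#' @param E,H extent and height exponents.
#' @param n_steps number of integration steps (the step is `max/n_steps`,
#'   computed separately for each sign).
#' @param connectivity neighborhood: 6 (faces) or 26 (faces, edges,
#'   corners).
#' @return 3D array of signed enhanced values.
#' @export
tfce <- function(stat_map, E = 0.5, H = 2, n_steps = 100,
                 connectivity = 26) {
  if (length(dim(stat_map)) != 3L) {
    stop("'stat_map' must be a 3D array", call. = FALSE)
  }
  if (!connectivity %in% c(6, 26)) {
    stop("'connectivity' must be 6 or 26", call. = FALSE)
  }
  if (any(!is.finite(stat_map))) {
    stop("'stat_map' must be finite", call. = FALSE)
  }
  dims <- dim(stat_map)
  pos <- tfce_enhance_cpp(pmax(as.numeric(stat_map), 0), dims, E, H,
                          as.integer(n_steps), as.integer(connectivity))
  neg <- tfce_enhance_cpp(pmax(-as.numeric(stat_map), 0), dims, E, H,
                          as.integer(n_steps), as.integer(connectivity))
  array(pos - neg, dim = dims)
}

# Canonicalize participant maps to an n x V matrix plus grid dims.
as_map_matrix <- function(maps) {
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    M <- do.call(rbind, lapply(maps, as.numeric))
  } else if (is.matrix(maps)) {
    dims <- attr(maps, "dims")
    if (is.null(dims)) dims <- c(ncol(maps), 1L, 1L)
    M <- maps
  } else if (length(dim(maps)) == 4L) {
    dims <- dim(maps)[2:4]
    M <- matrix(maps, nrow = dim(maps)[1])
  } else {
    stop("'maps' must be a list of 3D arrays, an n x V matrix, or a 4D ",
         "array", call. = FALSE)
  }
  list(M = M, dims = as.integer(dims))
}

map_tstat <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  s <- sqrt(colSums((M - rep(mu, each = n))^2) / (n - 1))
  t <- mu / (s / sqrt(n))
  t[s == 0 & mu == 0] <- 0
  t[s == 0 & mu != 0] <- sign(mu[s == 0 & mu != 0]) * 1e6
  t
}

abs_enhanced <- function(t_map, dims, E, H, n_steps, connectivity) {
  enh <- tfce(array(t_map, dim = dims), E = E, H = H, n_steps = n_steps,
              connectivity = connectivity)
  abs(as.numeric(enh))
}

#' Sign-flip permutation test with TFCE correction
#'
#' One-sample group test of participant effect maps: the observed voxelwise
#' t map is TFCE-enhanced, a null distribution of the maximum enhanced
#' statistic is built by randomly negating each participant's map, and
#' family-wise-error-corrected p-values are read off the max-statistic
#' distribution (two-tailed via the absolute enhanced value).
#'
#' @param maps participant effect maps: list of 3D arrays, n x V matrix
#'   (with a `"dims"` attribute), or n x X x Y x Z array.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param E,H,n_steps,connectivity TFCE parameters.
#' @param enhance logical; FALSE skips TFCE and uses the raw |t| map.
#' @return Object of class `bc_perm_map`: `observed` (t map), `enhanced`,
#'   `p_fwe`, `max_null`, `n_perm`, `seed`, `dims`.
#' @export
signflip_permutation <- function(maps, n_perm = 1000, seed = 1L, E = 0.5,
                                 H = 2, n_steps = 100, connectivity = 26,
                                 enhance = TRUE) {
  mm <- as_map_matrix(maps)
  M <- mm$M
  n <- nrow(M)
  if (n < 6L) {
    stop("sign-flip permutation needs at least 6 participants",
         call. = FALSE)
  }
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
  enh_fun <- if (enhance) {
    function(t) abs_enhanced(t, mm$dims, E, H, n_steps, connectivity)
  } else {
    function(t) abs(t)
  }
  t_obs <- map_tstat(M)
  e_obs <- enh_fun(t_obs)
  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      max(enh_fun(map_tstat(M * flips)))
    }, numeric(1))
  })
  p_fwe <- (1 + vapply(e_obs, function(e) sum(max_null >= e),
                       numeric(1))) / (n_perm + 1)
  structure(list(observed = array(t_obs, dim = mm$dims),
                 enhanced = array(e_obs, dim = mm$dims),
                 p_fwe = array(p_fwe, dim = mm$dims),
                 max_null = max_null, n_perm = n_perm, seed = seed,
                 dims = mm$dims),
            class = "bc_perm_map")
}
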