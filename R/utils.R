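#' backconn: background connectivity analysis with a ground-truth simulator
#'
#' Measures intrinsic (background) coupling between regions of interest in
#' blocked task fMRI after stimulus-evoked responses and nuisance signals have
#' been regressed out, together with a synthetic BOLD generator in which the
#' evoked and intrinsic components are linearly superimposed with known
#' parameters, so every stage of the pipeline can be validated against ground
#' truth.
#'
#' @useDynLib backconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor aov t.test cor.test pf pt qnorm median
#' @importFrom utils read.delim write.table head tail
#' @keywords internal
"_PACKAGE"

# Condition labels used throughout: timescale refers to when the stimulus set
# was trained (3 days before vs immediately before the scan), predictiveness
# to whether the button press determines the outcome.
TIMESCALES <- c("day3", "nodelay")
PREDICTIVENESS <- c("predictive", "nonpredictive")

#' Condition keys for the 2x2 design
#'
#' @param timescale character vector of timescales.
#' @param predictiveness character vector of predictiveness levels.
#' @return Character keys of the form `"day3.predictive"`.
#' @export
cond_key <- function(timescale, predictiveness) {
  paste(timescale, predictiveness, sep = ".")
}

#' All four condition keys
#' @return Character vector of length 4.
#' @export
all_cond_keys <- function() {
  as.vector(outer(TIMESCALES, PREDICTIVENESS, cond_key))
}

# Validate a named per-condition parameter vector; a scalar is recycled.
cond_vector <- function(x, name) {
  keys <- all_cond_keys()
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), 4L), keys)
  }
  if (!all(keys %in% names(x))) {
    stop(sprintf("'%s' must be named with all of: %s", name,
                 paste(keys, collapse = ", ")), call. = FALSE)
  }
  out <- as.numeric(x[keys])
  names(out) <- keys
  out
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive number", name), call. = FALSE)
  }
}

#' Derive reproducible sub-seeds from a master seed
#'
#' A single master seed fans out to named sub-seeds so that individual stages
#' (design, BOLD, behavior, resampling, permutation) can be rerun in
#' isolation while the full run stays deterministic.
#'
#' @param seed master seed (integer).
#' @param names character vector of stage names.
#' @return Named integer vector of seeds (all below 2^31).
#' @export
derive_seeds <- function(seed, names) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  stats::setNames(s, names)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

# Small stable content hash (polynomial rolling hash over the serialized
# object) used to stamp reports with their configuration; not cryptographic.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
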