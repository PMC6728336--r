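# Shared fixtures: small designs and ground truths so individual tests stay
# fast while exercising the full code paths.

small_config <- function(n_runs = 2, n_sets = 1, ...) {
  design_config(n_runs = n_runs, n_sets = n_sets, ...)
}

tiny_truth <- function(...) {
  ground_truth(n_voxels = c(hippocampus = 6, evc = 8), ...)
}

# latent-dominated truth: no evoked, no nuisance, no pattern signal
latent_truth <- function(rho = 0.6, noise_sd = 0.1, ...) {
  ground_truth(evoked_amplitude = 0, nuisance_gain = 0,
               pattern_amplitude = 0, rho = rho, noise_sd = noise_sd,
               n_voxels = c(hippocampus = 6, evc = 8), ...)
}

# effectively noiseless truth for exact-removal checks (noise_sd must stay
# positive, so use a negligible value)
noiseless_truth <- function(...) {
  ground_truth(noise_sd = 1e-8, latent_gain = 0, nuisance_gain = 0,
               pattern_amplitude = 0,
               n_voxels = c(hippocampus = 3, evc = 3), ...)
}

# hand-built verbal test objects for behavior-module tests
make_verbal_test <- function(responses, timepoint = "prescan_set1",
                             timescale = "day3", set = 1L,
                             predictiveness = "nonpredictive") {
  # responses: named list combo "cue.action" -> character vector of outcomes
  rows <- list()
  for (key in names(responses)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    for (resp in responses[[key]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        cue = parts[1], action = parts[2], predictiveness = predictiveness,
        correct_outcome = NA_character_, response = resp,
        stringsAsFactors = FALSE)
    }
  }
  list(timepoint = timepoint, set = set, timescale = timescale,
       trials = do.call(rbind, rows), attempts = 1L)
}

# independent normal-equations OLS oracle
ols_oracle <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# brute-force TFCE oracle: plain-R flood fill at every integration height
tfce_oracle <- function(map, E = 0.5, H = 2, n_steps = 100,
                        connectivity = 26) {
  dims <- dim(map)
  V <- prod(dims)
  hmax <- max(map)
  if (hmax <= 0) return(array(0, dims))
  dh <- hmax / n_steps
  nb_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb_offsets <- nb_offsets[rowSums(abs(nb_offsets)) > 0, , drop = FALSE]
  if (connectivity == 6) {
    nb_offsets <- nb_offsets[rowSums(abs(nb_offsets)) == 1, , drop = FALSE]
  }
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                  z = seq_len(dims[3])))
  enh <- numeric(V)
  for (k in seq_len(n_steps)) {
    h <- k * dh
    supra <- which(as.numeric(map) >= h)
    lab <- integer(V)
    nxt <- 0L
    for (v0 in supra) {
      if (lab[v0] != 0L) next
      nxt <- nxt + 1L
      comp <- v0
      lab[v0] <- nxt
      frontier <- v0
      while (length(frontier)) {
        new_frontier <- integer(0)
        for (v in frontier) {
          cc <- coords[v, ]
          for (j in seq_len(nrow(nb_offsets))) {
            p <- cc + nb_offsets[j, ]
            if (any(p < 1) || any(p > dims)) next
            w <- p[1] + dims[1] * ((p[2] - 1) + dims[2] * (p[3] - 1))
            if (lab[w] == 0L && as.numeric(map)[w] >= h) {
              lab[w] <- nxt
              comp <- c(comp, w)
              new_frontier <- c(new_frontier, w)
            }
          }
        }
        frontier <- new_frontier
      }
      enh[comp] <- enh[comp] + length(comp)^E * h^H * dh
    }
  }
  array(enh, dims)
}
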