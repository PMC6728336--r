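EVENTS_COLUMNS <- c("onset", "duration", "trial_type", "cue", "action",
                    "outcome", "response_time")

#' Write BIDS-style events tables
#'
#' One tab-separated events file per run with columns `onset`, `duration`,
#' `trial_type`, `cue`, `action`, `outcome`, `response_time`. Onsets and
#' durations are written in seconds with millisecond precision; missing
#' response times are written as `n/a`.
#'
#' @param design a `bc_design`.
#' @param dir output directory (created if needed).
#' @param rt optional data.frame of per-trial response times with columns
#'   `run` and `rt` (milliseconds, NA for missed trials), in trial order.
#' @return Invisibly, the paths written.
#' @export
write_events <- function(design, dir, rt = NULL) {
  stopifnot(inherits(design, "bc_design"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- design$config
  trial_dur <- cfg$cue_duration + cfg$response_window + cfg$outcome_duration
  paths <- character(0)
  for (run in design$runs) {
    tr <- run$trials
    df <- data.frame(
      onset = sprintf("%.3f", tr$onset),
      duration = sprintf("%.3f", trial_dur),
      trial_type = cond_key(tr$timescale, tr$predictiveness),
      cue = tr$cue, action = tr$action, outcome = tr$outcome,
      response_time = "n/a", stringsAsFactors = FALSE
    )
    if (!is.null(rt)) {
      rr <- rt$rt[rt$run == run$index]
      if (length(rr) == nrow(df)) {
        df$response_time <- ifelse(is.na(rr), "n/a", sprintf("%.1f", rr))
      }
    }
    path <- file.path(dir, sprintf("run-%02d_events.tsv", run$index))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a BIDS-style events table
#'
#' @param path path to a tab-separated events file.
#' @return data.frame with numeric `onset`, `duration` and `response_time`
#'   (NA where the file holds `n/a`), plus the condition columns.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "n/a", check.names = FALSE)
  missing <- setdiff(EVENTS_COLUMNS, names(df))
  if (length(missing)) {
    stop("events file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$onset <- as.numeric(df$onset)
  df$duration <- as.numeric(df$duration)
  df$response_time <- as.numeric(df$response_time)
  if (anyNA(df$onset)) stop("non-numeric onset values", call. = FALSE)
  df[, EVENTS_COLUMNS]
}

#' Serialize a design to JSON for provenance
#'
#' @param design a `bc_design`.
#' @param path output path; if NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "bc_design"))
  payload <- list(
    config = unclass(design$config), seed = design$seed,
    cues = design$cues,
    matched_run_pairs = design$matched_run_pairs,
    runs = lapply(design$runs, function(r) {
      list(index = r$index, set = r$set, timescale = r$timescale,
           blocks = r$blocks, trials = r$trials)
    })
  )
  json <- jsonlite::toJSON(payload, dataframe = "columns", digits = NA,
                           auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
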