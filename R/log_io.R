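# event-log schema: column -> storage type in the CSV
LOG_COLUMNS <- c(
  participant_id    = "integer",
  session_id        = "integer",
  block_index       = "integer",
  condition         = "character",
  trial_index       = "integer",
  stimulus          = "integer",
  seq_phase         = "integer",
  is_skip_successor = "logical",
  omitted_stimulus  = "integer",
  response          = "integer",
  rt_ms             = "numeric",
  deadline_ms       = "numeric",
  outcome           = "character",
  action_slip       = "logical"
)

#' Write / read a trial-level event log as CSV
#'
#' One row per trial, header as in the schema (see the package README), NA
#' for absent fields (no response, no RT, non-skip trials). Two leading
#' comment lines carry the configuration fingerprint and the simulation seed;
#' numeric columns are written with explicit decimal formatting (RTs at 0.1
#' ms, deadlines at 0.001 ms) so that \code{read_log(write_log(x))} is a
#' field-exact round trip.
#'
#' @param log an \code{mslt_log} data.frame.
#' @param path CSV file path.
#' @return \code{write_log}: \code{path}, invisibly. \code{read_log}: the
#'   \code{mslt_log}.
#' @export
write_log <- function(log, path) {
  check_log(log)
  miss <- setdiff(names(LOG_COLUMNS), names(log))
  if (length(miss) > 0)
    abort_arg("log is missing column(s): ", paste(miss, collapse = ", "))
  out <- log[names(LOG_COLUMNS)]
  fmt_num <- function(x, fmt) ifelse(is.na(x), "NA", sprintf(fmt, x))
  out$rt_ms <- fmt_num(out$rt_ms, "%.1f")
  out$deadline_ms <- fmt_num(out$deadline_ms, "%.3f")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# mslt event log; fingerprint=",
           if (is.null(attr(log, "fingerprint"))) "unknown" else attr(log, "fingerprint")),
    paste0("# seed=", if (is.null(attr(log, "seed"))) "NA" else attr(log, "seed"))
  ), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  if (!file.exists(path)) abort_arg("no such file: ", path)
  header <- readLines(path, n = 2)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(names(LOG_COLUMNS), names(df))
  if (length(miss) > 0)
    abort_arg("malformed log ", path, ": missing column(s) ",
              paste(miss, collapse = ", "))
  for (cn in names(LOG_COLUMNS)) {
    df[[cn]] <- switch(LOG_COLUMNS[[cn]],
      integer = as.integer(df[[cn]]),
      numeric = as.numeric(df[[cn]]),
      logical = as.logical(df[[cn]]),
      character = as.character(df[[cn]]))
  }
  bad <- which(!df$outcome %in% c("correct", "wrong_key", "too_slow"))
  if (length(bad) > 0)
    abort_arg("malformed log ", path, ": invalid outcome at data row ",
              bad[1])
  bad_ts <- which((df$outcome == "too_slow") != is.na(df$response))
  if (length(bad_ts) > 0)
    abort_arg("malformed log ", path, ": outcome/response mismatch at data row ",
              bad_ts[1])
  df <- df[names(LOG_COLUMNS)]
  fp <- sub("^# mslt event log; fingerprint=", "", header[1])
  sd <- suppressWarnings(as.integer(sub("^# seed=", "", header[2])))
  attr(df, "fingerprint") <- fp
  attr(df, "seed") <- sd
  class(df) <- c("mslt_log", "data.frame")
  df
}

#' Write all logs of a study to a directory
#'
#' @param study an \code{mslt_study}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mslt_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(study$logs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_log(study$logs[[nm]], p)
    p
  }, character(1))
  utils::write.csv(cohort_table(study$cohort),
                   file.path(dir, "cohort_params.csv"), row.names = FALSE)
  invisible(paths)
}

#' Read every event log in a directory
#'
#' @param dir directory containing \code{*.csv} logs written by
#'   \code{\link{write_study}} (the cohort parameter table is skipped).
#' @return named list of \code{mslt_log}s.
#' @export
read_study_logs <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "cohort_params.csv"]
  if (length(files) == 0) abort_arg("no event logs found in ", dir)
  logs <- lapply(files, read_log)
  names(logs) <- sub("\\.csv$", "", basename(files))
  logs
}
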