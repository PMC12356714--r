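#' Score an event log into per-block cell summaries
#'
#' One summary row per (participant, session, block): the correct-only median
#' RT, the error rate, the too-slow rate, and the action-slip count. Median
#' RTs consider only correct responses, excluding wrong key presses and
#' too-slow trials; the error rate is the number of wrong-key responses
#' divided by the number of trials in the block (too-slow trials are tracked
#' as a separate rate by default; set \code{errors_include_too_slow} to fold
#' them in). A cell with no correct trial gets \code{median_rt_ms = NA} and
#' \code{degenerate = TRUE}.
#'
#' @param log an \code{mslt_log} data.frame (or several \code{rbind}-ed).
#' @param errors_include_too_slow count too-slow trials in the error rate.
#' @return data.frame with one row per cell: \code{participant_id,
#'   session_id, block_index, condition, n_trials, n_correct, n_wrong_key,
#'   n_too_slow, median_rt_ms, error_rate, too_slow_rate, n_skip_trials,
#'   n_action_slips, degenerate}.
#' @export
summarize_cells <- function(log,
                            errors_include_too_slow =
                              mslt_config()$analysis$errors_include_too_slow) {
  check_log(log)
  key <- interaction(log$participant_id, log$session_id, log$block_index,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(log)), key), function(idx) {
    g <- log[idx, ]
    ok <- g$outcome == "correct"
    wrong <- sum(g$outcome == "wrong_key")
    slow <- sum(g$outcome == "too_slow")
    data.frame(
      participant_id = g$participant_id[1],
      session_id     = g$session_id[1],
      block_index    = g$block_index[1],
      condition      = g$condition[1],
      n_trials       = nrow(g),
      n_correct      = sum(ok),
      n_wrong_key    = wrong,
      n_too_slow     = slow,
      median_rt_ms   = if (any(ok)) stats::median(g$rt_ms[ok]) else NA_real_,
      error_rate     = (wrong + if (errors_include_too_slow) slow else 0) / nrow(g),
      too_slow_rate  = slow / nrow(g),
      n_skip_trials  = sum(g$is_skip_successor),
      n_action_slips = sum(g$action_slip),
      degenerate     = !any(ok),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$session_id, out$block_index), ]
  rownames(out) <- NULL
  out
}

check_log <- function(log) {
  need <- c("participant_id", "session_id", "block_index", "condition",
            "outcome", "rt_ms", "is_skip_successor", "action_slip")
  miss <- setdiff(need, names(log))
  if (length(miss) > 0)
    abort_arg("log is missing column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Count action slips in one test block
#'
#' @param log an \code{mslt_log}.
#' @param block_index index of the block within the session; must be a test
#'   block.
#' @param session_id session to look in (defaults to the log's only session).
#' @return integer slip count, between 0 and the number of skip trials in the
#'   block.
#' @export
count_action_slips <- function(log, block_index, session_id = NULL) {
  check_log(log)
  if (is.null(session_id)) session_id <- unique(log$session_id)
  if (length(session_id) != 1)
    abort_arg("log spans several sessions; pass session_id")
  g <- log[log$session_id == session_id & log$block_index == block_index, ]
  if (nrow(g) == 0) abort_arg("no such block in the log")
  if (g$condition[1] != "test")
    abort_arg("block ", block_index, " is a ", g$condition[1],
              " block; action slips are defined for test blocks")
  sum(g$action_slip)
}

#' Map per-block summaries to the first/last analysis cells
#'
#' The RT and error-rate analyses compare the first and last block of the
#' random and learning conditions in each session. With the default block
#' order (random, learning, test, learning, learning, test, random) "first"
#' is block 1 (random) / block 2 (learning), and "last" is block 7 (random) /
#' block 5 (the third learning block). Test blocks are labeled first/last for
#' the slip analysis (blocks 3 and 6).
#'
#' @param cells output of \code{\link{summarize_cells}}.
#' @return the subset of \code{cells} with an added factor column
#'   \code{block_label} ("first"/"last").
#' @export
label_first_last <- function(cells) {
  pick <- function(cond, idx, label) {
    sub <- cells[cells$condition == cond & cells$block_index == idx, ]
    if (nrow(sub) > 0) sub$block_label <- label
    sub
  }
  blocks <- lapply(split(cells, cells$condition), function(sub) {
    idx <- sort(unique(sub$block_index))
    rbind(pick(sub$condition[1], idx[1], "first"),
          pick(sub$condition[1], idx[length(idx)], "last"))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Per-participant action-slip table across the four test blocks
#'
#' @param cells output of \code{\link{summarize_cells}} over a whole study.
#' @return data.frame with one row per participant and columns
#'   \code{s1_first, s1_last, s2_first, s2_last} (slip counts) plus matching
#'   \code{rt_*} columns (correct-only median RT in the same blocks).
#' @export
slip_table <- function(cells) {
  tests <- cells[cells$condition == "test", ]
  if (nrow(tests) == 0) abort_arg("no test blocks in the summaries")
  tests <- label_first_last(tests)
  tests <- tests[tests$condition == "test", ]
  ids <- sort(unique(tests$participant_id))
  cell <- function(s, lab, col) {
    sub <- tests[tests$session_id == s & tests$block_label == lab, ]
    sub[match(ids, sub$participant_id), col]
  }
  data.frame(
    participant_id = ids,
    s1_first = cell(1, "first", "n_action_slips"),
    s1_last  = cell(1, "last", "n_action_slips"),
    s2_first = cell(2, "first", "n_action_slips"),
    s2_last  = cell(2, "last", "n_action_slips"),
    rt_s1_first = cell(1, "first", "median_rt_ms"),
    rt_s1_last  = cell(1, "last", "median_rt_ms"),
    rt_s2_first = cell(2, "first", "median_rt_ms"),
    rt_s2_last  = cell(2, "last", "median_rt_ms")
  )
}

#' Reliable change index
#'
#' Quantifies whether an individual's change between two time points exceeds
#' measurement error: \deqn{RCI = (X_2 - X_1) / S_{diff}} with
#' \eqn{S_{diff} = \sqrt{2 SE^2}} and \eqn{SE = SD \sqrt{1 - r_{xx}}}, where
#' \eqn{SD} is the cohort SD of the first measurement and \eqn{r_{xx}} the
#' measure's reliability coefficient. An RCI at or above 1.96 marks a
#' reliable increase beyond chance or measurement error.
#'
#' @param x1 score at time 1 (here: action slips, first test block of
#'   session 1); vectorized.
#' @param x2 score at time 2 (last test block of session 2).
#' @param sd cohort standard deviation of \code{x1}.
#' @param r_xx reliability coefficient in [0, 1).
#' @param threshold reliable-change cutoff (config default 1.96).
#' @return list of class \code{mslt_rci}: \code{x1, x2, sd, r_xx, se, s_diff,
#'   rci, reliable}.
#' @examples
#' rci(5, 20, sd = 4, r_xx = 0.7)$rci  # ~4.84
#' @export
rci <- function(x1, x2, sd, r_xx,
                threshold = mslt_config()$analysis$rci_threshold) {
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd <= 0)
    abort_arg("sd must be a positive scalar (zero SD makes RCI undefined)")
  if (!is.numeric(r_xx) || length(r_xx) != 1 || !is.finite(r_xx) ||
      r_xx < 0 || r_xx >= 1)
    abort_arg("r_xx must lie in [0, 1); r_xx = 1 makes Sdiff zero")
  if (length(x1) != length(x2)) abort_arg("x1 and x2 must have equal length")
  se <- sd * sqrt(1 - r_xx)
  s_diff <- sqrt(2 * se^2)
  val <- (x2 - x1) / s_diff
  structure(list(x1 = x1, x2 = x2, sd = sd, r_xx = r_xx, se = se,
                 s_diff = s_diff, rci = val, reliable = val >= threshold,
                 threshold = threshold),
            class = "mslt_rci")
}

#' @export
print.mslt_rci <- function(x, ...) {
  cat(sprintf("<mslt_rci> SE %.4f, Sdiff %.4f, cutoff %.2f\n",
              x$se, x$s_diff, x$threshold))
  print(data.frame(x1 = x$x1, x2 = x$x2, rci = round(x$rci, 3),
                   reliable = x$reliable))
  invisible(x)
}

#' Estimate the reliability coefficient of a measure
#'
#' Default estimator: the Pearson correlation between two administrations of
#' the measure (internal test-retest; for slips, the two test blocks of
#' session 1).
#'
#' @param a,b paired cohort vectors (n >= 3).
#' @param method passed to \code{stats::cor}.
#' @return reliability in [-1, 1].
#' @export
estimate_rxx <- function(a, b, method = "pearson") {
  if (length(a) != length(b) || length(a) < 3)
    abort_arg("need >= 3 paired observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort_arg("zero variance: reliability undefined")
  stats::cor(a, b, method = method)
}

#' Cohort reliable-change analysis of action slips
#'
#' Applies \code{\link{rci}} to every participant's slip change from the
#' first test block of session 1 to the last test block of session 2, with
#' the cohort SD of the first measurement and (by default) the test-retest
#' reliability estimated as the Pearson correlation between the two session-1
#' test blocks.
#'
#' @param slips output of \code{\link{slip_table}}.
#' @param r_xx reliability coefficient; estimated from the data when NULL. A
#'   negative estimate (possible in small or untrained cohorts) is clamped to
#'   zero with a warning, which makes SE equal the full cohort SD — the most
#'   conservative reliable-change criterion.
#' @param threshold reliable-change cutoff.
#' @return list with the \code{mslt_rci} object, \code{r_xx},
#'   \code{reliable_rate} (proportion of the cohort with a reliable
#'   increase), and the per-participant table.
#' @export
rci_cohort <- function(slips, r_xx = NULL,
                       threshold = mslt_config()$analysis$rci_threshold) {
  if (is.null(r_xx)) {
    r_xx <- estimate_rxx(slips$s1_first, slips$s1_last)
    if (r_xx < 0) {
      warning("estimated reliability was negative (", round(r_xx, 3),
              "); clamped to 0")
      r_xx <- 0
    }
  }
  res <- rci(slips$s1_first, slips$s2_last, sd = stats::sd(slips$s1_first),
             r_xx = r_xx, threshold = threshold)
  tab <- data.frame(participant_id = slips$participant_id,
                    x1 = res$x1, x2 = res$x2, rci = res$rci,
                    reliable = res$reliable)
  list(rci = res, r_xx = r_xx, reliable_rate = mean(res$reliable), table = tab)
}

#' Speed-accuracy correlation in a test block
#'
#' Pearson correlation (with two-sided p) between per-participant correct-only
#' median RT and action-slip count in one test block. A negative correlation
#' is the speed-accuracy trade-off signature: faster responders slip more.
#'
#' @param cells output of \code{\link{summarize_cells}} over a study.
#' @param session_id,block_index the test block.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
speed_accuracy_correlation <- function(cells, session_id, block_index) {
  sub <- cells[cells$session_id == session_id &
                 cells$block_index == block_index, ]
  if (nrow(sub) < 3) abort_arg("need >= 3 participants")
  if (any(sub$condition != "test")) abort_arg("block is not a test block")
  if (stats::sd(sub$median_rt_ms) == 0 || stats::sd(sub$n_action_slips) == 0)
    abort_arg("zero variance: correlation undefined")
  ct <- stats::cor.test(sub$median_rt_ms, sub$n_action_slips,
                        method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(sub))
}
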