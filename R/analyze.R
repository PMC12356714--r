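#' Full statistical report for a simulated (or imported) study
#'
#' Bundles the analyses the task was designed for:
#' \itemize{
#'   \item a three-way repeated-measures ANOVA on correct-only median RTs
#'     with within-subject factors session (1 vs 2), block (first vs last)
#'     and condition (random vs learning), Greenhouse-Geisser corrected,
#'     with partial eta squared;
#'   \item the same three-way ANOVA on error rates;
#'   \item a two-way ANOVA (session x block) on action-slip counts in the
#'     test blocks;
#'   \item Bonferroni-corrected paired post-hoc t-tests on the first-to-last
#'     RT reduction per condition and session;
#'   \item the reliable-change analysis of slips (session 1 first test block
#'     to session 2 last test block);
#'   \item per-test-block speed-accuracy Pearson correlations.
#' }
#'
#' @param cells output of \code{\link{summarize_cells}} over all logs of a
#'   study (both sessions, all participants).
#' @return list of class \code{mslt_report} with components \code{rt_anova},
#'   \code{error_anova}, \code{slip_anova}, \code{posthoc}, \code{rci},
#'   \code{correlations}, \code{cell_means}.
#' @export
analyze_summaries <- function(cells) {
  fl <- label_first_last(cells)
  rl <- fl[fl$condition %in% c("random", "learning"), ]
  if (any(is.na(rl$median_rt_ms)))
    abort_arg("degenerate cells (no correct trials) cannot enter the RT ANOVA")
  rl$session <- factor(rl$session_id)
  rl$block <- factor(rl$block_label, levels = c("first", "last"))
  rl$condition <- factor(rl$condition, levels = c("random", "learning"))
  within3 <- c("session", "block", "condition")
  rt_anova <- rm_anova(rl, "median_rt_ms", within3, "participant_id")
  error_anova <- rm_anova(rl, "error_rate", within3, "participant_id")

  slips <- slip_table(cells)
  long <- data.frame(
    participant_id = rep(slips$participant_id, 4),
    session = factor(rep(c(1, 1, 2, 2), each = nrow(slips))),
    block = factor(rep(c("first", "last", "first", "last"), each = nrow(slips)),
                   levels = c("first", "last")),
    slips = c(slips$s1_first, slips$s1_last, slips$s2_first, slips$s2_last)
  )
  slip_anova <- rm_anova(long, "slips", c("session", "block"), "participant_id")

  ph <- list()
  for (cond in c("random", "learning")) for (s in 1:2) {
    first <- rl$median_rt_ms[rl$condition == cond & rl$session == s & rl$block == "first"]
    last <- rl$median_rt_ms[rl$condition == cond & rl$session == s & rl$block == "last"]
    first <- first[order(rl$participant_id[rl$condition == cond & rl$session == s & rl$block == "first"])]
    last <- last[order(rl$participant_id[rl$condition == cond & rl$session == s & rl$block == "last"])]
    tt <- paired_t(first, last)
    tt$comparison <- sprintf("%s RT first vs last, session %d", cond, s)
    ph[[length(ph) + 1]] <- tt
  }
  praw <- vapply(ph, `[[`, numeric(1), "p")
  padj <- bonferroni(praw, length(praw))
  for (i in seq_along(ph)) ph[[i]]$p_bonferroni <- padj[i]

  rci_res <- rci_cohort(slips)

  test_cells <- unique(cells[cells$condition == "test",
                             c("session_id", "block_index")])
  test_cells <- test_cells[order(test_cells$session_id, test_cells$block_index), ]
  cors <- lapply(seq_len(nrow(test_cells)), function(i) {
    r <- speed_accuracy_correlation(cells, test_cells$session_id[i],
                                    test_cells$block_index[i])
    c(list(session = test_cells$session_id[i],
           block_index = test_cells$block_index[i]), r)
  })

  agg <- stats::aggregate(cbind(median_rt_ms, error_rate, n_action_slips) ~
                            session_id + block_index + condition,
                          data = cells, FUN = mean)
  agg <- agg[order(agg$session_id, agg$block_index), ]
  structure(list(rt_anova = rt_anova, error_anova = error_anova,
                 slip_anova = slip_anova, posthoc = ph, rci = rci_res,
                 correlations = cors, cell_means = agg),
            class = "mslt_report")
}

#' @export
print.mslt_report <- function(x, ...) {
  cat("== Median RT (correct only), session x block x condition ==\n")
  print(x$rt_anova)
  cat("\n== Error rate, session x block x condition ==\n")
  print(x$error_anova)
  cat("\n== Action slips, session x block ==\n")
  print(x$slip_anova)
  cat(sprintf("\nReliable slip increase (RCI >= %.2f): %.1f%% of the cohort (r_xx = %.3f)\n",
              x$rci$rci$threshold, 100 * x$rci$reliable_rate, x$rci$r_xx))
  cat("Speed-accuracy correlations (median RT vs slips):\n")
  for (co in x$correlations)
    cat(sprintf("  session %d block %d: r = %.3f, p = %.2g (n = %d)\n",
                co$session, co$block_index, co$r, co$p, co$n))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report an \code{mslt_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  ser <- list(
    rt_anova = as.data.frame(unclass(report$rt_anova)),
    error_anova = as.data.frame(unclass(report$error_anova)),
    slip_anova = as.data.frame(unclass(report$slip_anova)),
    posthoc = report$posthoc,
    rci = list(r_xx = report$rci$r_xx, reliable_rate = report$rci$reliable_rate,
               se = report$rci$rci$se, s_diff = report$rci$rci$s_diff,
               table = report$rci$table),
    correlations = report$correlations,
    cell_means = report$cell_means
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
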