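# hand-built log rows for scoring tests
make_log <- function(outcome, rt, condition = "learning", block = 2L,
                     session = 1L, participant = 1L, is_skip = FALSE,
                     omitted = NA_integer_, response = 0L, stimulus = 0L) {
  n <- length(outcome)
  data.frame(
    participant_id = rep_len(participant, n), session_id = rep_len(session, n),
    block_index = rep_len(block, n), condition = rep_len(condition, n),
    trial_index = seq_len(n) - 1L, stimulus = rep_len(stimulus, n),
    seq_phase = NA_integer_, is_skip_successor = rep_len(is_skip, n),
    omitted_stimulus = rep_len(omitted, n),
    response = ifelse(outcome == "too_slow", NA_integer_, rep_len(response, n)),
    rt_ms = ifelse(outcome == "too_slow", NA_real_, rt),
    deadline_ms = 800, outcome = outcome,
    action_slip = rep_len(is_skip, n) & outcome == "wrong_key" &
      !is.na(rep_len(response, n)) & rep_len(response, n) == rep_len(omitted, n),
    stringsAsFactors = FALSE
  )
}

test_that("cell summaries apply the correct-only and error-rate rules", {
  log <- make_log(c(rep("correct", 8), "wrong_key", "wrong_key"),
                  c(295, 300, 305, 298, 302, 300, 299, 301, 250, 260))
  cells <- summarize_cells(log)
  expect_identical(nrow(cells), 1L)
  expect_equal(cells$error_rate, 0.2)
  expect_equal(cells$n_trials, 10)
  # wrong-trial RTs are excluded from the median
  log2 <- make_log(c("correct", "correct", "correct", "wrong_key"),
                   c(280, 300, 320, 250))
  expect_equal(summarize_cells(log2)$median_rt_ms, 300)
  # too-slow trials count in their own rate, not (by default) in error_rate
  log3 <- make_log(c("correct", "too_slow", "wrong_key", "correct"),
                   c(300, NA, 250, 310))
  c3 <- summarize_cells(log3)
  expect_equal(c3$error_rate, 0.25)
  expect_equal(c3$too_slow_rate, 0.25)
  expect_equal(summarize_cells(log3, errors_include_too_slow = TRUE)$error_rate, 0.5)
  # degenerate cell: no correct trial
  log4 <- make_log(rep("too_slow", 5), NA)
  c4 <- summarize_cells(log4)
  expect_true(is.na(c4$median_rt_ms))
  expect_true(c4$degenerate)
  # bookkeeping identity holds for every cell
  all3 <- rbind(log, log2, log3)
  cs <- summarize_cells(all3)
  expect_equal(cs$n_correct + cs$n_wrong_key + cs$n_too_slow, cs$n_trials)
  # purity: rescoring is idempotent
  expect_identical(summarize_cells(all3), summarize_cells(all3))
})

test_that("action-slip counting matches flags and rejects non-test blocks", {
  log <- default_session_log()
  for (b in c(3L, 6L)) {
    got <- count_action_slips(log, b)
    expect_identical(got, sum(log$action_slip[log$block_index == b]))
    expect_lte(got, 33L)
  }
  expect_error(count_action_slips(log, 2L), "learning")
  # a fully habitual responder: every skip trial answered with the omitted key
  forced <- make_log(rep("wrong_key", 33), rt = 300, condition = "test",
                     block = 3L, is_skip = TRUE, omitted = 1L, response = 1L,
                     stimulus = 2L)
  expect_identical(count_action_slips(forced, 3L), 33L)
})

test_that("the reliable change index reproduces its defining formulas", {
  r <- rci(x1 = 5, x2 = 20, sd = 4, r_xx = 0.7)
  # independent longhand arithmetic of the published formulas
  se <- 4 * sqrt(1 - 0.7)
  s_diff <- sqrt(2 * se^2)
  expect_equal(r$se, se, tolerance = 1e-9)
  expect_equal(r$s_diff, s_diff, tolerance = 1e-9)
  expect_equal(r$rci, (20 - 5) / s_diff, tolerance = 1e-9)
  expect_equal(r$rci, 4.841229, tolerance = 1e-6)
  expect_true(r$reliable)
  # no change: rci 0, not reliable; the cutoff itself is reliable (>=)
  expect_equal(rci(7, 7, 4, 0.7)$rci, 0)
  expect_false(rci(7, 7, 4, 0.7)$reliable)
  x2_at_cut <- 5 + 1.96 * s_diff
  expect_true(rci(5, x2_at_cut, 4, 0.7)$reliable)
  # degenerate reliability or dispersion is an error, not a silent NaN
  expect_error(rci(5, 20, sd = 4, r_xx = 1), "r_xx")
  expect_error(rci(5, 20, sd = 4, r_xx = 0.9999999999), NA)
  expect_error(rci(5, 20, sd = 0, r_xx = 0.7), "sd")
})

test_that("reliability estimation is a guarded Pearson correlation", {
  expect_equal(estimate_rxx(1:10, 1:10), 1.0)
  expect_equal(estimate_rxx(1:10, -(1:10) + 30), -1.0)
  set.seed(4)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(estimate_rxx(a, b)), 0.1)
  expect_error(estimate_rxx(rep(1, 5), 1:5), "zero variance")
  expect_error(estimate_rxx(1:2, 2:1), "paired")
})

test_that("speed-accuracy correlation is Pearson on per-participant cells", {
  cells <- data.frame(
    participant_id = 1:8, session_id = 2L, block_index = 6L,
    condition = "test",
    median_rt_ms = c(340, 330, 320, 310, 300, 290, 280, 270),
    n_action_slips = c(2, 4, 6, 8, 10, 12, 14, 16)
  )
  r <- speed_accuracy_correlation(cells, 2, 6)
  expect_equal(r$r, -1)
  # invariant to affine rescaling of RTs
  cells2 <- cells
  cells2$median_rt_ms <- 3.7 * cells$median_rt_ms + 120
  expect_equal(speed_accuracy_correlation(cells2, 2, 6)$r, r$r)
  cells$n_action_slips <- 5
  expect_error(speed_accuracy_correlation(cells, 2, 6), "zero variance")
})

test_that("cohort RCI pipeline classifies reliable slip increases", {
  set.seed(11)
  n <- 31L
  base <- rpois(n, 4)
  slips <- data.frame(
    participant_id = 1:n,
    s1_first = base,
    s1_last = base + rpois(n, 4),
    s2_first = base + rpois(n, 8),
    s2_last = base + rpois(n, 14)
  )
  rc <- rci_cohort(slips)
  expect_equal(rc$r_xx, cor(slips$s1_first, slips$s1_last))
  expect_identical(nrow(rc$table), n)
  manual_se <- sd(slips$s1_first) * sqrt(1 - rc$r_xx)
  manual <- (slips$s2_last - slips$s1_first) / sqrt(2 * manual_se^2)
  expect_equal(rc$table$rci, manual, tolerance = 1e-12)
  expect_equal(rc$reliable_rate, mean(manual >= 1.96))
})
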