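test_that("generated sequences satisfy the structural constraints", {
  s <- generate_sequence(7)
  expect_s3_class(s, "mslt_sequence")
  expect_identical(unclass(generate_sequence(7)), unclass(s))  # determinism
  expect_length(s, 12)
  expect_setequal(unique(unclass(s)), 0:3)
  # balanced: every position exactly 3 times
  expect_true(all(table(unclass(s)) == 3))
  # no adjacent repeats including the wrap, scanned over many seeds
  for (seed in 1:1000) {
    x <- unclass(generate_sequence(seed))
    expect_true(all(x != c(x[-1], x[1])),
                info = paste("wrap/adjacent repeat at seed", seed))
  }
})

test_that("unbalanced sequences still cover all positions without repeats", {
  x <- unclass(generate_sequence(3, length = 13, balanced = FALSE))
  expect_length(x, 13)
  expect_setequal(unique(x), 0:3)
  expect_true(all(x != c(x[-1], x[1])))
  expect_error(generate_sequence(1, length = 13, balanced = TRUE), "divide")
})

test_that("random blocks are balanced and repeat-free", {
  b <- build_random_block(99, seed = 5)
  expect_identical(nrow(b$trials), 99L)
  expect_identical(b$condition, "random")
  expect_true(all(is.na(b$trials$seq_phase)))
  expect_false(any(b$trials$is_skip_successor))
  # exact balance at n = 4
  b4 <- build_random_block(4, seed = 2)
  expect_true(all(table(b4$trials$stimulus) == 1))
  for (seed in 1:100) {
    stim <- build_random_block(99, seed = seed)$trials$stimulus
    expect_true(all(diff(stim) != 0), info = paste("repeat at seed", seed))
    expect_true(all(abs(table(factor(stim, levels = 0:3)) - 99 / 4) <= 1))
  }
  expect_error(build_random_block(0), "positive integer")
})

test_that("learning blocks are modular repetitions of the sequence", {
  s <- generate_sequence(7)
  b <- build_learning_block(s, n_reps = 66, start_offset = 3)
  expect_identical(nrow(b$trials), 792L)
  expect_identical(b$break_after, c(264L, 528L))
  expect_identical(build_learning_block(s, 1, 0)$trials$stimulus,
                   as.integer(unclass(s)))
  b2 <- build_learning_block(s, n_reps = 2, start_offset = 5)
  # 0-based trial 7 wraps to the first sequence item
  expect_identical(b2$trials$stimulus[b2$trials$trial_index == 7L],
                   unclass(s)[1])
  expect_identical(b2$trials$stimulus,
                   unclass(s)[(5L + 0:23) %% 12L + 1L])
  expect_error(build_learning_block(s, 66, 12), "start_offset")
  expect_error(build_learning_block(s, 0, 0), "n_reps")
})

test_that("test blocks carry the right number and placement of skips", {
  s <- generate_sequence(7)
  b <- build_test_block(s, n_reps = 66, start_offset = 4, seed = 9)
  expect_identical(nrow(b$trials), 759L)
  expect_identical(sum(b$trials$is_skip_successor), 33L)
  expect_identical(b$break_after, c(253L, 506L))
  # minimal case: two presentations, one skip
  b2 <- build_test_block(s, n_reps = 2, start_offset = 0, seed = 1)
  expect_identical(nrow(b2$trials), 23L)
  expect_identical(sum(b2$trials$is_skip_successor), 1L)
  # omitted stimulus present iff skip successor, and never the shown one
  sk <- b$trials[b$trials$is_skip_successor, ]
  expect_true(all(!is.na(sk$omitted_stimulus)))
  expect_true(all(sk$omitted_stimulus != sk$stimulus))
  expect_true(all(is.na(b$trials$omitted_stimulus[!b$trials$is_skip_successor])))
})

test_that("skip positions are balanced over the sequence phases", {
  s <- generate_sequence(7)
  for (seed in 1:100) {
    b <- build_test_block(s, 66, start_offset = seed %% 12, seed = seed)
    sk <- b$trials[b$trials$is_skip_successor, ]
    skipped_phase <- (sk$seq_phase - 1L) %% 12L  # phase before the successor
    counts <- table(factor(skipped_phase, levels = 0:11))
    expect_true(all(counts %in% 2:3), info = paste("seed", seed))
    expect_identical(sum(counts), 33L)
  }
})

test_that("re-inserting omitted items reconstructs the intact repetition", {
  for (seed in c(1, 7, 23, 99)) {
    s <- generate_sequence(seed)
    off <- seed %% 12
    b <- build_test_block(s, 66, start_offset = off, seed = seed + 1)
    stim <- b$trials$stimulus
    ins <- which(b$trials$is_skip_successor)
    # insert each omitted item immediately before its successor trial
    rebuilt <- stim
    for (i in rev(ins)) rebuilt <- append(rebuilt, b$trials$omitted_stimulus[i],
                                          after = i - 1L)
    expected <- unclass(s)[(off + seq_len(66 * 12) - 1L) %% 12L + 1L]
    expect_identical(rebuilt, as.integer(expected))
  }
})

test_that("sessions have the published block order and sizes", {
  s <- generate_sequence(7)
  plan <- build_session(1, s, mslt_config(), seed = 42)
  conds <- vapply(plan$blocks, function(b) b$condition, character(1))
  expect_identical(conds, c("random", "learning", "test", "learning",
                            "learning", "test", "random"))
  sizes <- vapply(plan$blocks, function(b) nrow(b$trials), integer(1))
  expect_identical(sizes, c(99L, 792L, 759L, 792L, 792L, 759L, 99L))
  expect_identical(sum(sizes[conds != "random"]), 3894L)  # 3x792 + 2x759
  # determinism: identical plans under the same seed
  plan2 <- build_session(1, s, mslt_config(), seed = 42)
  expect_identical(session_trials(plan), session_trials(plan2))
  expect_error(build_session(3, s, mslt_config(), 1), "session_id")
})
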