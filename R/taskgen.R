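#' Generate the fixed 12-item stimulus sequence
#'
#' Stimuli are screen positions coded 0-3 (left middle, left index, right
#' index, right middle finger). The default sequence is balanced: every
#' position occurs exactly \code{length / n_positions} times and no two
#' consecutive items are equal, including the wrap from the last item back to
#' the first (the sequence is presented cyclically). Balance keeps stimulus
#' frequency constant across positions so RT differences reflect order
#' knowledge; the no-repeat wrap guarantees that on a skip event the omitted
#' item always differs from the item displayed in its place.
#'
#' @param seed integer seed; the same seed always yields the same sequence.
#' @param length sequence length (config default 12).
#' @param n_positions number of stimulus positions (config default 4); must divide
#'   \code{length} when \code{balanced}.
#' @param balanced enforce the balance + no-adjacent-repeat constraints
#'   (default TRUE). When FALSE, only "no adjacent repeats including wrap"
#'   and "every position occurs" are enforced.
#' @return an integer vector of class \code{mslt_sequence} with attribute
#'   \code{seed}.
#' @examples
#' generate_sequence(7)
#' @export
generate_sequence <- function(seed, length = mslt_config()$task$sequence_length,
                              n_positions = mslt_config()$task$n_positions,
                              balanced = mslt_config()$task$balanced_sequence) {
  if (!is_count(length) || !is_count(n_positions, 2))
    abort_arg("length and n_positions must be positive integers")
  if (balanced && length %% n_positions != 0)
    abort_arg("balanced sequences need n_positions to divide length")
  if (!balanced && length < n_positions)
    abort_arg("length must be >= n_positions so every position occurs")
  items <- with_seed(seed, {
    for (attempt in 1:10000) {
      cand <- if (balanced) {
        sample(rep.int(0:(n_positions - 1L), length / n_positions))
      } else {
        c(sample(0:(n_positions - 1L)),
          sample(0:(n_positions - 1L), length - n_positions, replace = TRUE))
      }
      ok <- all(cand != c(cand[-1], cand[1])) &&
        base::length(unique(cand)) == n_positions
      if (ok) break
    }
    if (!ok) abort_arg("could not satisfy sequence constraints")
    as.integer(cand)
  })
  structure(items, class = "mslt_sequence", seed = as.integer(seed))
}

#' @export
print.mslt_sequence <- function(x, ...) {
  cat("<mslt_sequence> ", paste(unclass(x), collapse = "-"),
      "  (seed ", attr(x, "seed"), ")\n", sep = "")
  invisible(x)
}

# a block is a list(condition, trials = data.frame, break_after, start_offset)
new_block <- function(condition, trials, break_after, start_offset = NA_integer_) {
  structure(list(condition = condition, trials = trials,
                 break_after = as.integer(break_after),
                 start_offset = as.integer(start_offset)),
            class = "mslt_block")
}

#' @export
print.mslt_block <- function(x, ...) {
  cat(sprintf("<mslt_block> %s: %d trials, %d skip trials, breaks after {%s}\n",
              x$condition, nrow(x$trials), sum(x$trials$is_skip_successor),
              paste(x$break_after, collapse = ", ")))
  invisible(x)
}

trial_frame <- function(condition, stimulus, seq_phase = NA_integer_,
                        is_skip = FALSE, omitted = NA_integer_) {
  n <- length(stimulus)
  data.frame(
    trial_index       = seq_len(n) - 1L,
    condition         = rep_len(condition, n),
    stimulus          = as.integer(stimulus),
    seq_phase         = rep_len(as.integer(seq_phase), n),
    is_skip_successor = rep_len(is_skip, n),
    omitted_stimulus  = rep_len(as.integer(omitted), n),
    stringsAsFactors  = FALSE
  )
}

break_points <- function(n_trials, every) {
  if (is.na(every) || every <= 0 || every >= n_trials) return(integer(0))
  seq.int(every, n_trials - 1L, by = every)
}

#' Build a pseudo-randomized baseline block
#'
#' Trials are drawn as shuffled balanced tiles with adjacent-repeat repair:
#' per-position counts stay within one of \code{n_trials / 4} and no stimulus
#' repeats immediately, matching the per-position frequency of the sequenced
#' blocks so that the random condition is a clean RT baseline.
#'
#' @param n_trials number of trials (default 99).
#' @param seed integer seed.
#' @param n_positions number of stimulus positions.
#' @return an \code{mslt_block} with condition \code{"random"}.
#' @export
build_random_block <- function(n_trials = mslt_config()$task$random_trials,
                               seed = 1L,
                               n_positions = mslt_config()$task$n_positions) {
  if (!is_count(n_trials)) abort_arg("n_trials must be a positive integer")
  stim <- with_seed(seed, {
    base <- n_trials %/% n_positions
    counts <- rep.int(base, n_positions)
    extra <- n_trials - base * n_positions
    if (extra > 0) {
      idx <- sample.int(n_positions, extra)
      counts[idx] <- counts[idx] + 1L
    }
    x <- sample(rep.int(0:(n_positions - 1L), counts))
    repair_adjacent(x)
  })
  new_block("random", trial_frame("random", stim), integer(0))
}

# swap-based repair removing immediate repeats while preserving counts
repair_adjacent <- function(x) {
  n <- length(x)
  if (n < 2) return(as.integer(x))
  for (pass in 1:50) {
    bad <- which(x[-1] == x[-n]) + 1L
    if (length(bad) == 0) break
    for (i in bad) {
      if (x[i] != x[i - 1L]) next  # fixed by an earlier swap this pass
      for (j in sample.int(n)) {
        if (x[j] == x[i]) next
        # after swapping positions i and j neither site may repeat
        ok_i <- (i == 1L || x[i - 1L] != x[j]) && (i == n || x[i + 1L] != x[j] || i + 1L == j)
        xi <- x[i]
        ok_j <- (j == 1L || x[j - 1L] != xi || j - 1L == i) && (j == n || x[j + 1L] != xi || j + 1L == i)
        if (ok_i && ok_j) {
          tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
          break
        }
      }
    }
  }
  if (any(x[-1] == x[-n])) abort_arg("could not remove adjacent repeats")
  as.integer(x)
}

#' Build a learning block (intact repeating sequence)
#'
#' Trial \code{i} (0-based) displays \code{seq[(start_offset + i) mod 12]};
#' the random start offset hides the re-occurring nature of the sequence
#' between blocks. 10-s break markers are placed after every
#' \code{break_every} trials.
#'
#' @param seq an \code{mslt_sequence}.
#' @param n_reps number of full sequence repetitions (default 66).
#' @param start_offset index 0-11 the block starts at.
#' @param break_every spacing of within-block break markers (default 264).
#' @return an \code{mslt_block} with condition \code{"learning"}.
#' @export
build_learning_block <- function(seq, n_reps = mslt_config()$task$n_reps,
                                 start_offset = 0L,
                                 break_every = mslt_config()$task$learning_break_every) {
  check_seq_args(seq, n_reps, start_offset)
  L <- length(seq)
  phase <- (start_offset + seq_len(n_reps * L) - 1L) %% L
  trials <- trial_frame("learning", unclass(seq)[phase + 1L], phase)
  new_block("learning", trials, break_points(nrow(trials), break_every),
            start_offset)
}

check_seq_args <- function(seq, n_reps, start_offset) {
  if (!inherits(seq, "mslt_sequence")) abort_arg("seq must be an mslt_sequence")
  if (!is_count(n_reps)) abort_arg("n_reps must be a positive integer")
  if (!is_count(start_offset, 0) || start_offset >= length(seq))
    abort_arg("start_offset must be in 0..", length(seq) - 1L)
  invisible(TRUE)
}

#' Build a test block (sequence with intermittent skip events)
#'
#' The block presents \code{n_reps} repetitions of the sequence, but in every
#' second presentation (the 2nd, 4th, ...) one sequence item is omitted and
#' the following item is shown directly. The trial displayed in place of the
#' omitted item is flagged \code{is_skip_successor} and carries the omitted
#' stimulus; responding with the omitted item's key there is an action slip.
#' Skip positions cycle through the 12 sequence phases without replacement
#' (each phase is skipped \code{floor(33/12)} or \code{ceil(33/12)} times at
#' the defaults), shuffled per seed, never probing adjacent sequence phases
#' in consecutive skip events, and never skipping the final trial of the
#' block (which would leave the skip without a successor).
#'
#' @inheritParams build_learning_block
#' @param seed integer seed for the skip-position schedule.
#' @param skip_every skip in every \code{skip_every}-th presentation.
#' @param break_every spacing of break markers (default 253).
#' @return an \code{mslt_block} with condition \code{"test"}; total trials
#'   \code{n_reps * 12 - floor(n_reps / skip_every)}.
#' @export
build_test_block <- function(seq, n_reps = mslt_config()$task$n_reps,
                             start_offset = 0L, seed = 1L,
                             skip_every = mslt_config()$task$skip_every,
                             break_every = mslt_config()$task$test_break_every) {
  check_seq_args(seq, n_reps, start_offset)
  L <- length(seq)
  skip_reps <- which(seq_len(n_reps) %% skip_every == 0L)  # 1-based even reps
  n_skips <- length(skip_reps)
  last_phase <- (start_offset + n_reps * L - 1L) %% L
  sched <- with_seed(seed, skip_schedule(n_skips, L, forbid_last =
                       if (n_reps %% skip_every == 0L) last_phase else NA_integer_))

  # continuous phase stream, then drop the skipped trial of each skip rep
  phase <- (start_offset + seq_len(n_reps * L) - 1L) %% L
  rep_id <- rep(seq_len(n_reps), each = L)
  drop <- integer(n_skips)
  for (k in seq_len(n_skips)) {
    in_rep <- which(rep_id == skip_reps[k] & phase == sched[k])
    drop[k] <- in_rep[1L]
  }
  keep <- setdiff(seq_along(phase), drop)
  phase_kept <- phase[keep]
  stim <- unclass(seq)[phase_kept + 1L]
  # successor = the trial that followed each dropped one in the stream
  succ_stream <- drop + 1L
  succ_kept <- match(succ_stream, keep)
  is_skip <- rep(FALSE, length(keep))
  omitted <- rep(NA_integer_, length(keep))
  is_skip[succ_kept] <- TRUE
  omitted[succ_kept] <- unclass(seq)[sched + 1L]
  trials <- trial_frame("test", stim, phase_kept, is_skip, omitted)
  new_block("test", trials, break_points(nrow(trials), break_every), start_offset)
}

# balanced-without-replacement cycling over sequence phases, rejecting
# schedules with adjacent phases (mod L) in consecutive skips or a final skip
# that would remove the last trial of the block
skip_schedule <- function(n_skips, L, forbid_last = NA_integer_) {
  n_tiles <- ceiling(n_skips / L)
  for (attempt in 1:10000) {
    s <- unlist(lapply(seq_len(n_tiles), function(i) sample.int(L) - 1L))[seq_len(n_skips)]
    d <- abs(diff(s)) %% L
    adjacent <- any(d <= 1L | d == L - 1L)
    if (!adjacent && !(length(s) > 0 && !is.na(forbid_last) && s[n_skips] == forbid_last))
      return(s)
  }
  abort_arg("could not build a skip schedule under the adjacency constraints")
}

#' Assemble a full session plan
#'
#' A session runs seven blocks in the order random, learning, test, learning,
#' learning, test, random. All sequenced blocks use the same sequence, each
#' with a fresh random start offset.
#'
#' @param session_id 1 or 2.
#' @param seq an \code{mslt_sequence} shared by both sessions.
#' @param config an \code{\link{mslt_config}}.
#' @param seed integer seed controlling offsets, the random blocks, and skip
#'   schedules.
#' @return an object of class \code{mslt_session}: a list with
#'   \code{session_id}, \code{blocks} (list of \code{mslt_block}), and
#'   \code{sequence}.
#' @export
build_session <- function(session_id, seq, config = mslt_config(), seed = 1L) {
  if (!(is_count(session_id) && session_id %in% c(1L, 2L)))
    abort_arg("session_id must be 1 or 2")
  tk <- config$task
  order <- c("random", "learning", "test", "learning", "learning", "test", "random")
  n_seq_blocks <- sum(order != "random")
  seeds <- derive_seeds(seed, length(order))
  offsets <- with_seed(seeds[1] + 1L,
                       sample.int(length(seq), n_seq_blocks, replace = TRUE) - 1L)
  blocks <- vector("list", length(order))
  oi <- 0L
  for (b in seq_along(order)) {
    blocks[[b]] <- switch(order[b],
      random = build_random_block(tk$random_trials, seed = seeds[b],
                                  n_positions = tk$n_positions),
      learning = {
        oi <- oi + 1L
        build_learning_block(seq, tk$n_reps, offsets[oi], tk$learning_break_every)
      },
      test = {
        oi <- oi + 1L
        build_test_block(seq, tk$n_reps, offsets[oi], seed = seeds[b],
                         skip_every = tk$skip_every,
                         break_every = tk$test_break_every)
      })
  }
  structure(list(session_id = as.integer(session_id), blocks = blocks,
                 sequence = seq, seed = as.integer(seed)),
            class = "mslt_session")
}

#' @export
print.mslt_session <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) nrow(b$trials), integer(1))
  conds <- vapply(x$blocks, function(b) b$condition, character(1))
  cat(sprintf("<mslt_session> session %d: %s (%s trials)\n", x$session_id,
              paste(conds, collapse = "-"), paste(sizes, collapse = "/")))
  invisible(x)
}

#' Flatten a session plan to one row per trial
#'
#' @param plan an \code{mslt_session}.
#' @return a data.frame with columns \code{session_id, block_index, condition,
#'   trial_index, stimulus, seq_phase, is_skip_successor, omitted_stimulus}.
#' @export
session_trials <- function(plan) {
  stopifnot(inherits(plan, "mslt_session"))
  out <- do.call(rbind, lapply(seq_along(plan$blocks), function(b) {
    tr <- plan$blocks[[b]]$trials
    cbind(data.frame(session_id = plan$session_id, block_index = b), tr)
  }))
  rownames(out) <- NULL
  out
}
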