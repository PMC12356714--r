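#' Adaptive response-deadline staircase
#'
#' The task paces itself with a per-block response limit: each block starts
#' with a limit of twice the median correct RT of the practice block; after
#' every three consecutive correct responses the limit tightens by 30 ms, and
#' after an error (wrong key, and by default also a too-slow trial) it relaxes
#' to 1.5 times the median correct RT observed so far in the current block.
#' The limit is clamped at a floor (default 150 ms) so a fast agent can still
#' respond. All factors and steps come from the \code{pacing} section of
#' \code{\link{mslt_config}}.
#'
#' \code{deadline_init} creates the state from the practice-block RTs;
#' \code{deadline_update} advances it by one trial; \code{deadline_reset}
#' restores the block-start limit and clears the block RT record (called at
#' every block boundary; within-block 10-s breaks do not reset it).
#'
#' Block medians use the usual linear interpolation for even counts and are
#' computed over correct responses only (too-slow trials have no RT). Until
#' the current block has any correct response, the practice median stands in.
#'
#' @param practice_rts numeric vector of correct RTs (ms) from the practice
#'   block; must be non-empty.
#' @param params the \code{pacing} component of an \code{\link{mslt_config}}.
#' @return an object of class \code{mslt_deadline}: a list with
#'   \code{current_limit}, \code{consecutive_correct}, \code{block_rts},
#'   \code{practice_median}, \code{params}.
#' @examples
#' st <- deadline_init(c(250, 350, 450, 550))
#' st$current_limit  # 800
#' st <- deadline_update(st, "correct", 300)
#' @export
deadline_init <- function(practice_rts, params = mslt_config()$pacing) {
  if (length(practice_rts) == 0 || !is.numeric(practice_rts) ||
      any(!is.finite(practice_rts)) || any(practice_rts <= 0))
    abort_arg("practice_rts must be a non-empty vector of positive RTs")
  med <- stats::median(practice_rts)
  structure(list(
    current_limit       = clamp_limit(params$init_factor * med, params),
    consecutive_correct = 0L,
    block_rts           = numeric(0),
    practice_median     = med,
    params              = params
  ), class = "mslt_deadline")
}

clamp_limit <- function(x, params) round(max(params$floor_ms, x), 3)

#' @rdname deadline_init
#' @param state an \code{mslt_deadline}.
#' @param outcome one of \code{"correct"}, \code{"wrong_key"},
#'   \code{"too_slow"}.
#' @param rt the trial RT in ms; required for \code{correct} and
#'   \code{wrong_key} (a key was pressed), absent for \code{too_slow}.
#' @export
deadline_update <- function(state, outcome, rt = NULL) {
  stopifnot(inherits(state, "mslt_deadline"))
  outcome <- match.arg(outcome, c("correct", "wrong_key", "too_slow"))
  if (outcome != "too_slow" && (is.null(rt) || is.na(rt)))
    abort_arg("rt is required when a key was pressed")
  p <- state$params
  if (outcome == "correct") {
    state$block_rts <- c(state$block_rts, rt)
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= p$step_every) {
      state$current_limit <- clamp_limit(state$current_limit - p$step_down_ms, p)
      state$consecutive_correct <- 0L
    }
  } else {
    state$consecutive_correct <- 0L
    penalize <- outcome == "wrong_key" || isTRUE(p$penalize_too_slow)
    if (penalize) {
      med <- if (length(state$block_rts) > 0) stats::median(state$block_rts)
             else state$practice_median
      state$current_limit <- clamp_limit(p$penalty_factor * med, p)
    }
  }
  state
}

#' @rdname deadline_init
#' @export
deadline_reset <- function(state) {
  stopifnot(inherits(state, "mslt_deadline"))
  p <- state$params
  state$current_limit <- clamp_limit(p$init_factor * state$practice_median, p)
  state$consecutive_correct <- 0L
  state$block_rts <- numeric(0)
  state
}

#' @export
print.mslt_deadline <- function(x, ...) {
  cat(sprintf("<mslt_deadline> limit %.1f ms, streak %d, %d block RTs (practice median %.1f)\n",
              x$current_limit, x$consecutive_correct, length(x$block_rts),
              x$practice_median))
  invisible(x)
}
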