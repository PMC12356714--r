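#' Run one session of the task for one agent
#'
#' Drives a session plan through a synthetic agent and the adaptive deadline
#' controller, emitting one result row per planned trial. The session starts
#' with a short practice (warm-up) block of pseudo-random trials run under a
#' generous deadline; its correct-RT median seeds the staircase and its
#' trials are not part of the event log. The deadline is re-initialized at
#' every block boundary (twice the practice median) and updated after every
#' trial; within-block break markers do not touch it. The agent's association
#' strength is updated on sequenced trials only.
#'
#' Outcome classification is total and exclusive: \code{too_slow} iff no
#' response was emitted before the deadline, otherwise \code{correct} iff the
#' response matches the displayed stimulus, else \code{wrong_key}. An action
#' slip is a response on a skip-successor trial that matches the omitted
#' stimulus; slips are always \code{wrong_key} outcomes, and a too-slow
#' non-response on a skip trial is not a slip.
#'
#' @param plan an \code{\link{build_session}} plan.
#' @param agent an \code{\link{new_agent}} state; learning carries over, so
#'   pass the state returned by a previous session to model consolidation.
#' @param config an \code{\link{mslt_config}}.
#' @param seed integer seed for the agent's stochastic behavior.
#' @param participant_id identifier recorded in the log.
#' @return list with \code{log} (a data.frame of class \code{mslt_log}, one
#'   row per planned trial, columns \code{participant_id, session_id,
#'   block_index, condition, trial_index, stimulus, seq_phase,
#'   is_skip_successor, omitted_stimulus, response, rt_ms, deadline_ms,
#'   outcome, action_slip}, with attributes \code{fingerprint} and
#'   \code{seed}), the updated \code{agent}, and \code{practice_median}.
#' @export
run_session <- function(plan, agent, config = mslt_config(), seed = 1L,
                        participant_id = 1L) {
  stopifnot(inherits(plan, "mslt_session"), inherits(agent, "mslt_agent"))
  n_pos <- config$task$n_positions
  if (any(unlist(lapply(plan$blocks, function(b) b$trials$stimulus)) >= n_pos))
    abort_arg("plan uses more stimulus positions than the config allows")
  seeds <- derive_seeds(seed, 2L)
  warm <- build_random_block(config$task$warmup_trials, seed = seeds[1],
                             n_positions = n_pos)
  with_seed(seeds[2], {
    # practice: generous fixed deadline, collect correct RTs for the staircase
    wres <- run_block_trials(agent, NULL, warm, n_pos,
                             fixed_deadline = config$agents$warmup_deadline_ms)
    agent <- wres$agent
    practice_rts <- wres$rt[wres$outcome == 1L]
    if (length(practice_rts) == 0) practice_rts <- config$agents$warmup_deadline_ms / 2
    dstate <- deadline_init(practice_rts, config$pacing)

    per_block <- vector("list", length(plan$blocks))
    for (b in seq_along(plan$blocks)) {
      dstate <- deadline_reset(dstate)
      res <- run_block_trials(agent, dstate, plan$blocks[[b]], n_pos)
      agent <- res$agent
      dstate <- res$dstate
      tr <- plan$blocks[[b]]$trials
      per_block[[b]] <- data.frame(
        participant_id = participant_id,
        session_id = plan$session_id,
        block_index = b,
        tr,
        response = res$response,
        rt_ms = res$rt,
        deadline_ms = res$deadline,
        outcome = c("correct", "wrong_key", "too_slow")[res$outcome],
        action_slip = res$slip,
        stringsAsFactors = FALSE
      )
    }
    log <- do.call(rbind, per_block)
    log <- log[names(LOG_COLUMNS)]
    rownames(log) <- NULL
    attr(log, "fingerprint") <- config_fingerprint(config)
    attr(log, "seed") <- as.integer(seed)
    class(log) <- c("mslt_log", "data.frame")
    list(log = log, agent = agent, practice_median = stats::median(practice_rts))
  })
}

# tight per-trial loop shared by practice and scored blocks; when
# fixed_deadline is given the staircase is bypassed (practice block)
run_block_trials <- function(agent, dstate, block, n_pos, fixed_deadline = NULL) {
  tr <- block$trials
  n <- nrow(tr)
  cond <- tr$condition[1]
  stim <- tr$stimulus
  isk <- tr$is_skip_successor
  omit <- tr$omitted_stimulus
  response <- integer(n); rt <- numeric(n); dl <- numeric(n)
  outcome <- integer(n); slip <- logical(n)
  sequenced <- cond != "random"
  labels <- c("correct", "wrong_key", "too_slow")
  for (i in seq_len(n)) {
    dl[i] <- if (is.null(fixed_deadline)) dstate$current_limit else fixed_deadline
    act <- agent_act(agent,
                     list(condition = cond, stimulus = stim[i],
                          is_skip_successor = isk[i],
                          omitted_stimulus = omit[i]),
                     dl[i], n_pos)
    response[i] <- if (is.na(act$response)) NA_integer_ else act$response
    rt[i] <- act$rt_ms
    outcome[i] <- if (is.na(act$response)) 3L
                  else if (act$response == stim[i]) 1L else 2L
    slip[i] <- isk[i] && !is.na(act$response) && act$response == omit[i]
    if (is.null(fixed_deadline)) {
      dstate <- deadline_update(dstate, labels[outcome[i]],
                                rt = if (outcome[i] == 3L) NULL else rt[i])
    }
    agent <- agent_learn(agent, list(condition = cond))
  }
  list(agent = agent, dstate = dstate, response = response, rt = rt,
       deadline = dl, outcome = outcome, slip = slip)
}

#' @export
print.mslt_log <- function(x, ...) {
  cat(sprintf("<mslt_log> participant %s, session %s: %d trials, %d blocks, %d slips\n",
              x$participant_id[1], x$session_id[1], nrow(x),
              length(unique(x$block_index)), sum(x$action_slip)))
  invisible(as.data.frame(x))
}

#' Simulate a full two-session study
#'
#' Generates the shared 12-item sequence and the two session plans, draws a
#' heterogeneous cohort, and runs every participant through both sessions.
#' Agent state persists across sessions (association strength is carried
#' over, scaled by the \code{consolidation} factor, default 1), so session 2
#' starts from trained behavior. Deterministic under \code{seed}.
#'
#' @param n_participants cohort size (default from config: 31).
#' @param config an \code{\link{mslt_config}}.
#' @param seed master integer seed.
#' @return object of class \code{mslt_study}: list with \code{logs} (list of
#'   \code{2 * n} \code{mslt_log}s, named \code{p<id>_s<session>}),
#'   \code{cohort} (list of agent parameter sets), \code{sequence}, and
#'   \code{plans}.
#' @examples
#' \donttest{
#' study <- run_study(n_participants = 2, seed = 42,
#'                    config = mslt_config(task = list(n_reps = 4,
#'                                                     random_trials = 24)))
#' }
#' @export
run_study <- function(n_participants = NULL, config = mslt_config(), seed = 1L) {
  n <- if (is.null(n_participants)) config$agents$n_participants else n_participants
  if (!is_count(n)) abort_arg("n_participants must be a positive integer")
  seeds <- derive_seeds(seed, 4L + 2L * n)
  tk <- config$task
  sequence <- generate_sequence(seeds[1], tk$sequence_length, tk$n_positions,
                                tk$balanced_sequence)
  plans <- list(build_session(1L, sequence, config, seeds[2]),
                build_session(2L, sequence, config, seeds[3]))
  cohort <- sample_cohort(n, config$agents$hyper, seeds[4])
  logs <- vector("list", 2L * n)
  nm <- character(2L * n)
  for (i in seq_len(n)) {
    agent <- new_agent(cohort[[i]])
    for (s in 1:2) {
      res <- run_session(plans[[s]], agent, config,
                         seed = seeds[4L + 2L * (i - 1L) + s],
                         participant_id = i)
      agent <- res$agent
      if (s == 1L) agent$H <- agent$H * config$agents$consolidation
      k <- 2L * (i - 1L) + s
      logs[[k]] <- res$log
      nm[k] <- sprintf("p%02d_s%d", i, s)
    }
  }
  names(logs) <- nm
  structure(list(logs = logs, cohort = cohort, sequence = sequence,
                 plans = plans, seed = as.integer(seed)),
            class = "mslt_study")
}

#' @export
print.mslt_study <- function(x, ...) {
  cat(sprintf("<mslt_study> %d participants x 2 sessions (%d logs), seed %d\n",
              length(x$cohort), length(x$logs), x$seed))
  invisible(x)
}

#' Cohort parameters as a table
#'
#' @param cohort list of \code{mslt_agent_params} (e.g. \code{study$cohort}).
#' @return data.frame, one row per agent.
#' @export
cohort_table <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(p) as.data.frame(unclass(p))))
  cbind(participant_id = seq_along(cohort), out)
}
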