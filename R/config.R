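#' Default study configuration
#'
#' Builds the nested configuration list that every other module consumes.
#' The defaults reproduce the published task design: pseudo-random baseline
#' blocks of 99 trials, learning blocks of 792 trials (66 repetitions of the
#' 12-item sequence) with 10-s breaks every 264 trials, test blocks of 759
#' trials containing 33 skip events with breaks every 253 trials, block order
#' random-learning-test-learning-learning-test-random, and the adaptive
#' response-deadline staircase (initial limit twice the practice-block median
#' RT, lowered by 30 ms after every three consecutive correct responses,
#' relaxed to 1.5 times the current-block median RT after an error).
#'
#' All numeric design constants live here and only here; the task, pacing,
#' agent, engine, and analysis code read them from the configuration.
#'
#' @param ... named overrides, e.g. \code{task = list(n_reps = 2)}. Overrides
#'   are merged recursively into the defaults.
#' @return a nested list of class \code{mslt_config} with components
#'   \code{task}, \code{timing}, \code{pacing}, \code{agents},
#'   \code{analysis}.
#' @examples
#' cfg <- mslt_config()
#' cfg$task$n_reps
#' small <- mslt_config(task = list(n_reps = 4, random_trials = 12))
#' @export
mslt_config <- function(...) {
  defaults <- list(
    task = list(
      sequence_length      = 12L,
      n_positions          = 4L,
      balanced_sequence    = TRUE,  # each position 3x, no adjacent repeats
      random_trials        = 99L,
      n_reps               = 66L,   # sequence repetitions per sequenced block
      skip_every           = 2L,    # skip in every 2nd sequence presentation
      learning_break_every = 264L,  # 10-s pause spacing in learning blocks
      test_break_every     = 253L,  # 10-s pause spacing in test blocks
      warmup_trials        = 36L    # practice block seeding the staircase
    ),
    timing = list(       # carried as metadata; simulation is event-driven
      stimulus_ms          = 400,
      feedback_ms          = 700,
      iti_ms               = 100,
      within_block_break_s = 10,
      between_block_break_s = 30
    ),
    pacing = list(
      init_factor       = 2.0,   # initial limit = 2 x practice median
      step_down_ms      = 30,    # decrement after each run of correct trials
      step_every        = 3L,    # run length triggering the decrement
      penalty_factor    = 1.5,   # limit after an error = 1.5 x block median
      floor_ms          = 150,   # lower clamp keeping the task solvable
      penalize_too_slow = TRUE   # too-slow counts as "incorrect" for x1.5
    ),
    agents = list(
      n_participants = 31L,
      consolidation  = 1.0,      # carry-over factor on H between sessions
      warmup_deadline_ms = 10000, # effectively unlimited during practice
      hyper = list(              # cohort hyper-distribution (mean, sd, range)
        base_rt_ms         = list(mean = 430,    sd = 20,    min = 250,  max = 700),
        general_gain_ms    = list(mean = 90,     sd = 8,     min = 0,    max = 200),
        general_tau_trials = list(mean = 2000,   sd = 300,   min = 200,  max = 10000),
        seq_gain_ms        = list(mean = 160,    sd = 30,    min = 0,    max = 300),
        assoc_rate         = list(mean = 1.8e-4, sd = 1.5e-4, min = 3e-5, max = 0.05),
        slip_gain          = list(mean = 0.95,   sd = 0.04,  min = 0,    max = 1),
        pressure_scale_ms  = list(mean = 250,    sd = 40,    min = 10,   max = 600),
        lapse_rate         = list(mean = 0.03,   sd = 0.01,  min = 0.001, max = 0.2),
        rt_sigma_ms        = list(mean = 55,     sd = 8,     min = 10,   max = 150)
      )
    ),
    analysis = list(
      errors_include_too_slow = FALSE, # error rate counts wrong keys only
      rci_threshold = 1.96,
      rt_floor_ms   = 50               # physiological RT floor (truncation)
    )
  )
  utils::modifyList(structure(defaults, class = "mslt_config"), list(...))
}

#' Read / write a study configuration as YAML
#'
#' @param path file path.
#' @return \code{read_config} returns an \code{mslt_config} (unknown keys are
#'   rejected); \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- mslt_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown) > 0)
    abort_arg("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(base, raw)
}

#' @rdname read_config
#' @param config an \code{mslt_config} list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.mslt_config <- function(x, ...) {
  cat("<mslt_config>\n")
  cat(sprintf("  blocks: random %d | learning %d x 12 | test %d x 12 - %d skips\n",
              x$task$random_trials, x$task$n_reps, x$task$n_reps,
              x$task$n_reps %/% x$task$skip_every))
  cat(sprintf("  staircase: init %.1fx, -%g ms per %d correct, penalty %.1fx, floor %g ms\n",
              x$pacing$init_factor, x$pacing$step_down_ms, x$pacing$step_every,
              x$pacing$penalty_factor, x$pacing$floor_ms))
  cat(sprintf("  cohort: n = %d\n", x$agents$n_participants))
  invisible(x)
}

# Short stable fingerprint of a configuration, recorded in event logs.
config_fingerprint <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small polynomial hash; only needs to detect config drift, not be crypto
  bytes <- utf8ToInt(as.character(js))
  h <- Reduce(function(h, b) (h * 31 + b) %% 2147483647, bytes, accumulate = FALSE, 0)
  sprintf("cfg-%08x", as.integer(h))
}
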