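#' Synthetic participant model
#'
#' A generative agent producing the qualitative behavioral signatures the
#' task is designed to elicit: RTs that speed up with general practice and,
#' additionally, with sequence knowledge; occasional wrong-key lapses;
#' too-slow trials when the adaptive deadline outruns the agent; and, on
#' skip-successor trials, anticipatory responses to the omitted sequence item
#' (action slips) that grow with learned association strength and with
#' deadline pressure. The model is deliberately simple and monotone so its
#' predictions are analytically checkable; it is a synthetic stand-in for a
#' human participant, not a fitted cognitive model.
#'
#' Expected RT on trial \code{n} is
#' \deqn{\mu = base - g (1 - e^{-n/\tau}) - s H \cdot [sequenced]}
#' truncated below at the physiological floor, with additive Gaussian noise.
#' Sequence knowledge \code{H} in [0,1] follows the exponential learning rule
#' \code{H <- H + rate (1 - H)} on every sequenced (learning/test) trial and
#' is untouched by random trials. On a skip-successor trial the agent emits
#' the omitted item's response with probability
#' \deqn{p_{slip} = slip\_gain \cdot H \cdot \sigma((\mu - deadline)/scale)}
#' so slips require learned associations and become more likely the tighter
#' the deadline presses on the agent's attainable speed.
#'
#' @param base_rt_ms baseline mean RT (ms).
#' @param general_gain_ms,general_tau_trials saturating general practice
#'   speed-up: asymptotic gain (ms) and time constant (trials).
#' @param seq_gain_ms maximal sequence-specific speed-up (ms) at \code{H = 1}.
#' @param assoc_rate per-sequenced-trial association increment in (0, 1).
#' @param slip_gain maximal anticipatory-response probability in [0, 1].
#' @param pressure_scale_ms logistic width (ms) of the deadline-pressure term.
#' @param lapse_rate wrong-key probability in [0, 1].
#' @param rt_sigma_ms RT noise SD (ms).
#' @param rt_floor_ms truncation floor for drawn RTs (ms).
#'
#' Defaults are the means of the cohort hyper-distributions in
#' \code{mslt_config()}.
#' @return \code{agent_params}: a list of class \code{mslt_agent_params}.
#' @examples
#' p <- agent_params()
#' a <- new_agent(p)
#' @export
agent_params <- function(base_rt_ms = .hyper_mean("base_rt_ms"),
                         general_gain_ms = .hyper_mean("general_gain_ms"),
                         general_tau_trials = .hyper_mean("general_tau_trials"),
                         seq_gain_ms = .hyper_mean("seq_gain_ms"),
                         assoc_rate = .hyper_mean("assoc_rate"),
                         slip_gain = .hyper_mean("slip_gain"),
                         pressure_scale_ms = .hyper_mean("pressure_scale_ms"),
                         lapse_rate = .hyper_mean("lapse_rate"),
                         rt_sigma_ms = .hyper_mean("rt_sigma_ms"),
                         rt_floor_ms = mslt_config()$analysis$rt_floor_ms) {
  p <- list(base_rt_ms = base_rt_ms, general_gain_ms = general_gain_ms,
            general_tau_trials = general_tau_trials, seq_gain_ms = seq_gain_ms,
            assoc_rate = assoc_rate, slip_gain = slip_gain,
            pressure_scale_ms = pressure_scale_ms, lapse_rate = lapse_rate,
            rt_sigma_ms = rt_sigma_ms, rt_floor_ms = rt_floor_ms)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    abort_arg("all agent parameters must be finite scalars")
  if (assoc_rate < 0 || assoc_rate > 1) abort_arg("assoc_rate must be in [0, 1]")
  if (slip_gain < 0 || slip_gain > 1) abort_arg("slip_gain must be in [0, 1]")
  if (lapse_rate < 0 || lapse_rate > 1) abort_arg("lapse_rate must be in [0, 1]")
  if (base_rt_ms <= 0 || rt_sigma_ms < 0 || pressure_scale_ms <= 0 ||
      general_tau_trials <= 0 || general_gain_ms < 0 || seq_gain_ms < 0 ||
      rt_floor_ms <= 0)
    abort_arg("RT parameters out of range")
  structure(p, class = "mslt_agent_params")
}

#' Draw a heterogeneous cohort of agents
#'
#' Each parameter is drawn from a truncated normal hyper-distribution
#' (truncation at the parameter's valid range); a degenerate hyper (sd = 0)
#' yields identical agents. Deterministic under \code{seed}.
#'
#' @param n cohort size (the study default is 31 participants).
#' @param hyper hyper-distribution spec: named list of
#'   \code{list(mean, sd, min, max)}, as in \code{mslt_config()$agents$hyper}.
#' @param seed integer seed.
#' @return a list of \code{n} \code{mslt_agent_params}.
#' @export
sample_cohort <- function(n, hyper = mslt_config()$agents$hyper, seed = 1L) {
  if (!is_count(n)) abort_arg("n must be a positive integer")
  bad <- vapply(hyper, function(h) !is.numeric(h$sd) || h$sd < 0 || h$min > h$max,
                logical(1))
  if (any(bad)) abort_arg("invalid hyper ranges for: ",
                          paste(names(hyper)[bad], collapse = ", "))
  with_seed(seed, lapply(seq_len(n), function(i) {
    draw <- lapply(hyper, function(h) {
      if (h$sd == 0) return(h$mean)
      for (k in 1:1000) {
        x <- stats::rnorm(1, h$mean, h$sd)
        if (x >= h$min && x <= h$max) return(x)
      }
      min(max(h$mean, h$min), h$max)
    })
    do.call(agent_params, draw)
  }))
}

#' @rdname agent_params
#' @param params an \code{mslt_agent_params}.
#' @return \code{new_agent}: an \code{mslt_agent} state with counters
#'   \code{n_trials_total = 0} and association strength \code{H = 0}.
#' @export
new_agent <- function(params) {
  stopifnot(inherits(params, "mslt_agent_params"))
  structure(list(params = params, n_trials_total = 0L, H = 0),
            class = "mslt_agent")
}

#' @export
print.mslt_agent <- function(x, ...) {
  cat(sprintf("<mslt_agent> %d trials seen, H = %.3f (base RT %.0f ms)\n",
              x$n_trials_total, x$H, x$params$base_rt_ms))
  invisible(x)
}

# deterministic expected RT (no noise), exposed for the engine and for tests
agent_expected_rt <- function(state, sequenced) {
  p <- state$params
  mu <- p$base_rt_ms -
    p$general_gain_ms * (1 - exp(-state$n_trials_total / p$general_tau_trials)) -
    p$seq_gain_ms * state$H * as.numeric(sequenced)
  max(p$rt_floor_ms, mu)
}

#' One trial of agent behavior
#'
#' Draws a response and RT for a planned trial given the deadline currently
#' in force. Consumes the session RNG stream; callers seed it once per run.
#'
#' @param state an \code{mslt_agent}.
#' @param trial one row of a block's trial data.frame (fields
#'   \code{condition}, \code{stimulus}, \code{is_skip_successor},
#'   \code{omitted_stimulus}).
#' @param deadline response limit (ms) in force.
#' @param n_positions number of response keys.
#' @return list with \code{response} (position, or \code{NA} if the drawn RT
#'   exceeded the deadline) and \code{rt_ms} (the drawn RT, rounded to 0.1 ms;
#'   \code{NA} when no response was emitted).
#' @export
agent_act <- function(state, trial, deadline, n_positions = 4L) {
  sequenced <- trial$condition != "random"
  mu <- agent_expected_rt(state, sequenced)
  p <- state$params
  rt <- round(max(p$rt_floor_ms, mu + stats::rnorm(1, 0, p$rt_sigma_ms)), 1)
  if (rt > deadline) return(list(response = NA_integer_, rt_ms = NA_real_))
  response <- trial$stimulus
  if (isTRUE(trial$is_skip_successor)) {
    p_slip <- p$slip_gain * state$H *
      stats::plogis((mu - deadline) / p$pressure_scale_ms)
    if (stats::runif(1) < p_slip)
      return(list(response = as.integer(trial$omitted_stimulus), rt_ms = rt))
  }
  if (stats::runif(1) < p$lapse_rate) {
    others <- setdiff(0:(n_positions - 1L), response)
    response <- others[sample.int(length(others), 1)]
  }
  list(response = as.integer(response), rt_ms = rt)
}

#' @rdname agent_act
#' @details \code{agent_learn} applies the association update after a trial:
#'   \code{H} grows by \code{assoc_rate * (1 - H)} on sequenced trials and is
#'   unchanged on random trials; the total trial counter always advances.
#' @export
agent_learn <- function(state, trial) {
  stopifnot(inherits(state, "mslt_agent"))
  if (trial$condition != "random") {
    state$H <- state$H + state$params$assoc_rate * (1 - state$H)
  }
  state$n_trials_total <- state$n_trials_total + 1L
  state
}

# slip probability for a given expected RT and deadline (used in tests)
slip_probability <- function(state, deadline, sequenced = TRUE) {
  p <- state$params
  mu <- agent_expected_rt(state, sequenced)
  p$slip_gain * state$H * stats::plogis((mu - deadline) / p$pressure_scale_ms)
}

# cohort hyper-distribution mean, used as the single source of parameter
# defaults
.hyper_mean <- function(name) mslt_config()$agents$hyper[[name]]$mean
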