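# Independent oracles used to cross-check the implementation. These are
# written naively and share no code with the package internals.

# step-by-step replay of the deadline rules on an outcome/RT string
oracle_replay_deadline <- function(practice_rts, outcomes, rts,
                                   step_down = 30, step_every = 3,
                                   penalty = 1.5, init = 2, floor = 150) {
  med <- function(x) {  # interpolated median, written out longhand
    x <- sort(x)
    n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  pmed <- med(practice_rts)
  limit <- max(floor, init * pmed)
  streak <- 0
  seen <- c()
  limits <- numeric(length(outcomes))
  for (i in seq_along(outcomes)) {
    if (outcomes[i] == "correct") {
      seen <- c(seen, rts[i])
      streak <- streak + 1
      if (streak == step_every) {
        limit <- max(floor, limit - step_down)
        streak <- 0
      }
    } else {
      streak <- 0
      limit <- max(floor, penalty * if (length(seen)) med(seen) else pmed)
    }
    limits[i] <- limit
  }
  limits
}

# re-score action slips from the raw log columns only
oracle_rescore_slips <- function(log) {
  flag <- logical(nrow(log))
  for (i in seq_len(nrow(log))) {
    flag[i] <- isTRUE(log$is_skip_successor[i]) &&
      !is.na(log$response[i]) &&
      log$response[i] == log$omitted_stimulus[i]
  }
  flag
}

# brute-force within-subject ANOVA via aov() Error strata: F, p, SS per effect
oracle_rm_aov <- function(data, dv, within, subject) {
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  rhs <- paste(within, collapse = "*")
  form <- stats::as.formula(paste(dv, "~", rhs, "+ Error(", subject, "/(", rhs, "))"))
  fit <- stats::aov(form, data = data)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    for (r in rownames(tab)) {
      eff <- gsub(" ", "", r)
      if (eff == "Residuals") next
      res <- tab["Residuals", ]
      out[[eff]] <- list(F = tab[r, "F value"], p = tab[r, "Pr(>F)"],
                         ss_effect = tab[r, "Sum Sq"],
                         ss_error = res[["Sum Sq"]],
                         df_effect = tab[r, "Df"], df_error = res[["Df"]])
    }
  }
  out
}

# Greenhouse-Geisser epsilon / adjusted p via car's multivariate route
oracle_gg_car <- function(data, dv, within, subject) {
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  cells <- do.call(interaction, c(unname(data[within]), list(lex.order = TRUE, sep = ".")))
  wide <- tapply(data[[dv]], list(data[[subject]], cells), mean)
  idata <- unique(data[within])
  ord <- do.call(order, lapply(rev(within), function(w) idata[[w]]))
  idata <- idata[ord, , drop = FALSE]
  key <- do.call(interaction, c(unname(idata), list(lex.order = TRUE, sep = ".")))
  wide <- wide[, as.character(key), drop = FALSE]
  mod <- stats::lm(wide ~ 1)
  av <- car::Anova(mod, idata = idata,
                   idesign = stats::as.formula(paste("~", paste(within, collapse = "*"))),
                   type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  pva <- s$pval.adjustments
  eff <- gsub(" ", "", rownames(pva))
  list(effects = eff, eps = pva[, "GG eps"], p_gg = pva[, "Pr(>F[GG])"])
}

# random balanced within-subject dataset
random_rm_data <- function(n_subj, k, seed) {
  set.seed(seed)
  g <- expand.grid(c(list(id = factor(seq_len(n_subj))),
                     lapply(k, function(kk) factor(seq_len(kk)))))
  names(g)[-1] <- paste0("f", seq_along(k))
  g$y <- rnorm(nrow(g), sd = 2) + rep(rnorm(n_subj), length.out = nrow(g))
  g
}

# small fast study configuration for engine / io / cli tests
tiny_config <- function(...) {
  cfg <- mslt_config(
    task = list(random_trials = 24L, n_reps = 6L, warmup_trials = 12L,
                learning_break_every = 30L, test_break_every = 30L),
    agents = list(n_participants = 4L,
                  hyper = modifyList(mslt_config()$agents$hyper,
                    list(assoc_rate = list(mean = 0.02, sd = 0.005,
                                           min = 1e-3, max = 0.5))))
  )
  modifyList(cfg, list(...))
}

# one default-size simulated session, computed once per test run
default_session_cache <- new.env(parent = emptyenv())
default_session_log <- function() {
  if (is.null(default_session_cache$log)) {
    cfg <- mslt_config()
    seqn <- generate_sequence(11)
    plan <- build_session(1L, seqn, cfg, seed = 301L)
    agent <- new_agent(agent_params())
    default_session_cache$log <- run_session(plan, agent, cfg, seed = 302L,
                                             participant_id = 1L)$log
  }
  default_session_cache$log
}
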