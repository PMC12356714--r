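#' Within-subject repeated-measures ANOVA
#'
#' Fully within-subject factorial ANOVA for balanced complete designs with up
#' to three (or more) within factors, using the univariate sums-of-squares
#' decomposition in which each effect is tested against its interaction with
#' subjects. Implementation: for each effect, the subject-by-cell data are
#' projected onto an orthonormal contrast basis (polynomial contrasts per
#' factor, Kronecker products for interactions); the effect SS is \eqn{n
#' \lVert \bar z \rVert^2} over contrast columns and the error SS the
#' residual within-column variation, which for balanced designs equals the
#' classical subject-interaction error term. Greenhouse-Geisser epsilon is
#' estimated from the covariance of the contrast scores,
#' \eqn{\hat\varepsilon = tr(S)^2 / (df \, tr(S^2))}, clamped to
#' \eqn{[1/df, 1]}; with two-level factors every effect has one degree of
#' freedom and epsilon is exactly 1 (sphericity cannot be violated).
#' Effect sizes are partial eta squared,
#' \eqn{\eta_p^2 = SS_{effect} / (SS_{effect} + SS_{error})}.
#'
#' @param data long-format data.frame.
#' @param dv name of the numeric dependent-variable column.
#' @param within character vector of within-subject factor columns (order
#'   fixes the effect naming).
#' @param subject name of the subject identifier column.
#' @return data.frame of class \code{mslt_anova}, one row per main effect and
#'   interaction: \code{effect, df_effect, df_error, ss_effect, ss_error, F,
#'   p, epsilon, df_effect_gg, df_error_gg, p_gg, partial_eta_sq}. The
#'   uncorrected \code{p} is reported alongside the Greenhouse-Geisser
#'   corrected \code{p_gg}.
#' @examples
#' d <- expand.grid(id = factor(1:6), a = factor(c("x", "y")),
#'                  b = factor(c("u", "v")))
#' d$y <- rnorm(nrow(d))
#' rm_anova(d, "y", c("a", "b"), "id")
#' @export
rm_anova <- function(data, dv, within, subject) {
  miss <- setdiff(c(dv, within, subject), names(data))
  if (length(miss) > 0)
    abort_arg("column(s) not in data: ", paste(miss, collapse = ", "))
  if (!is.numeric(data[[dv]]) || any(!is.finite(data[[dv]])))
    abort_arg("dependent variable must be finite numeric")
  fac <- lapply(data[within], function(x) factor(x))
  levs <- lapply(fac, levels)
  k <- vapply(levs, length, integer(1))
  if (any(k < 2)) abort_arg("every within factor needs >= 2 levels")
  subj <- factor(data[[subject]])
  n <- nlevels(subj)
  if (n < 2) abort_arg("need >= 2 subjects")

  # wide matrix: rows = subjects, cols = cells ordered with the first factor
  # varying fastest (expand.grid order)
  cell <- interaction(rev(fac), drop = FALSE, lex.order = TRUE)
  p_cells <- prod(k)
  counts <- table(subj, cell)
  if (any(counts != 1))
    abort_arg("design must be complete and balanced: every subject exactly ",
              "once in every cell (no imputation is performed)")
  Y <- matrix(NA_real_, n, p_cells)
  col_of <- as.integer(cell)
  Y[cbind(as.integer(subj), col_of)] <- data[[dv]]
  rm_anova_core(Y, k, within)
}

# core on the wide subject x cell matrix; cells ordered first-factor-fastest
rm_anova_core <- function(Y, k, names_within) {
  n <- nrow(Y)
  m <- length(k)
  # orthonormal contrast columns per factor, plus the normalized unit vector
  contr <- lapply(k, function(kk) stats::contr.poly(kk))
  ones <- lapply(k, function(kk) matrix(1 / sqrt(kk), kk, 1))
  effects <- unlist(lapply(seq_len(m), function(sz)
    utils::combn(m, sz, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(idx) {
    mats <- lapply(seq_len(m), function(j)
      if (j %in% idx) contr[[j]] else ones[[j]])
    # kronecker with later factors outermost so that factor 1 varies fastest
    C <- Reduce(function(a, b) kronecker(b, a), mats)
    Z <- Y %*% C
    df1 <- ncol(C)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    ss_err <- sum(sweep(Z, 2, zbar)^2)
    df2 <- df1 * (n - 1)
    Fval <- (ss_eff / df1) / (ss_err / df2)
    eps <- if (df1 == 1) 1 else {
      S <- stats::cov(Z)
      e <- sum(diag(S))^2 / (df1 * sum(S * S))
      min(1, max(1 / df1, e))
    }
    data.frame(
      effect = paste(names_within[idx], collapse = ":"),
      df_effect = df1, df_error = df2,
      ss_effect = ss_eff, ss_error = ss_err, F = Fval,
      p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
      epsilon = eps,
      df_effect_gg = eps * df1, df_error_gg = eps * df2,
      p_gg = stats::pf(Fval, eps * df1, eps * df2, lower.tail = FALSE),
      partial_eta_sq = ss_eff / (ss_eff + ss_err),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mslt_anova", "data.frame")
  out
}

#' @export
print.mslt_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  show <- data.frame(effect = x$effect,
                     F = sprintf("%.3f", x$F),
                     df = sprintf("(%g, %g)", x$df_effect_gg, x$df_error_gg),
                     p_gg = format.pval(x$p_gg, digits = 3, eps = 1e-16),
                     epsilon = sprintf("%.3f", x$epsilon),
                     peta2 = sprintf("%.3f", x$partial_eta_sq))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t on the differences, df = n - 1. Degenerate inputs
#' (zero-variance differences) are flagged rather than erroring: identical
#' vectors give t = 0, p = 1; a constant nonzero difference gives an infinite
#' t with p = 0.
#'
#' @param x,y equal-length paired numeric vectors, n >= 2.
#' @return list: \code{t, df, p, mean_diff, degenerate}.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    abort_arg("x and y must be paired vectors of length >= 2")
  d <- x - y
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = length(d) - 1L, p = if (t == 0) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p vector of p values.
#' @param m number of comparisons corrected for; must be at least
#'   \code{length(p)} (defaults to it).
#' @return \code{pmin(1, m * p)}.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) abort_arg("m must be >= the number of p values")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_arg("p values must be in [0, 1]")
  pmin(1, m * p)
}
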