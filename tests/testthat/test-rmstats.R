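test_that("a hand-checked 2x2 design matches the manual SS decomposition", {
  # fixed small dataset; the oracle decomposes sums of squares via aov()
  d <- expand.grid(id = factor(1:3), a = factor(c("x", "y")),
                   b = factor(c("u", "v")))
  d$y <- c(10.1, 12.3, 14.2,   13.4, 15.1, 18.3,   11.2, 12.8, 15.1,   16.3, 19.2, 21.4)
  got <- rm_anova(d, "y", c("a", "b"), "id")
  want <- oracle_rm_aov(d, "y", c("a", "b"), "id")
  for (eff in c("a", "b", "a:b")) {
    row <- got[got$effect == eff, ]
    expect_equal(row$F, want[[eff]]$F, tolerance = 1e-9)
    expect_equal(row$p, want[[eff]]$p, tolerance = 1e-9)
    expect_equal(row$ss_effect, want[[eff]]$ss_effect, tolerance = 1e-9)
    expect_equal(row$ss_error, want[[eff]]$ss_error, tolerance = 1e-9)
    expect_equal(row$partial_eta_sq,
                 want[[eff]]$ss_effect / (want[[eff]]$ss_effect + want[[eff]]$ss_error),
                 tolerance = 1e-9)
  }
  # two-level factors force sphericity: epsilon exactly 1, p_gg == p
  expect_true(all(got$epsilon == 1))
  expect_equal(got$p_gg, got$p)
})

test_that("the ANOVA table is invariant to location shifts", {
  d <- random_rm_data(6, c(2, 2, 2), seed = 42)
  t1 <- rm_anova(d, "y", c("f1", "f2", "f3"), "id")
  d$y <- d$y + 1000
  t2 <- rm_anova(d, "y", c("f1", "f2", "f3"), "id")
  expect_equal(t1$F, t2$F, tolerance = 1e-8)
  expect_equal(t1$ss_effect, t2$ss_effect, tolerance = 1e-6)
  expect_identical(t1$effect, c("f1", "f2", "f3", "f1:f2", "f1:f3", "f2:f3",
                                "f1:f2:f3"))
})

test_that("F, p and effect sizes match the brute-force oracle on random designs", {
  designs <- list(c(2, 2), c(2, 2, 2), c(3, 2), c(2, 4))
  count <- 0
  for (des in designs) {
    for (rep in 1:15) {
      count <- count + 1
      n <- sample(3:8, 1)
      d <- random_rm_data(n, des, seed = 1000 + count)
      within <- paste0("f", seq_along(des))
      got <- rm_anova(d, "y", within, "id")
      want <- oracle_rm_aov(d, "y", within, "id")
      for (i in seq_len(nrow(got))) {
        eff <- got$effect[i]
        expect_equal(got$F[i], want[[eff]]$F, tolerance = 1e-8,
                     info = paste("F", eff, count))
        expect_equal(got$p[i], want[[eff]]$p, tolerance = 1e-8)
        expect_equal(got$df_effect[i], want[[eff]]$df_effect)
        expect_equal(got$df_error[i], want[[eff]]$df_error)
        expect_equal(got$partial_eta_sq[i],
                     want[[eff]]$ss_effect /
                       (want[[eff]]$ss_effect + want[[eff]]$ss_error),
                     tolerance = 1e-8)
      }
    }
  }
  expect_gte(count, 50)
})

test_that("Greenhouse-Geisser epsilon matches the multivariate-route oracle", {
  skip_if_not_installed("car")
  for (case in 1:6) {
    des <- if (case %% 2 == 0) c(3, 2) else c(4, 2)
    d <- random_rm_data(8, des, seed = 2000 + case)
    within <- paste0("f", seq_along(des))
    got <- rm_anova(d, "y", within, "id")
    want <- oracle_gg_car(d, "y", within, "id")
    for (i in seq_along(want$effects)) {
      j <- match(want$effects[i], got$effect)
      expect_equal(got$epsilon[j], unname(want$eps[i]), tolerance = 1e-6,
                   info = paste(case, want$effects[i]))
      expect_equal(got$p_gg[j], unname(want$p_gg[i]), tolerance = 1e-6)
    }
    # epsilon bounds: 1/(k-1) <= eps <= 1, and exactly 1 when df = 1
    expect_true(all(got$epsilon <= 1 + 1e-12))
    expect_true(all(got$epsilon >= 1 / got$df_effect - 1e-12))
    expect_true(all(got$epsilon[got$df_effect == 1] == 1))
  }
})

test_that("incomplete or unbalanced designs are rejected", {
  d <- random_rm_data(5, c(2, 2), seed = 3)
  expect_error(rm_anova(d[-1, ], "y", c("f1", "f2"), "id"), "balanced")
  d2 <- rbind(d, d[1, ])
  expect_error(rm_anova(d2, "y", c("f1", "f2"), "id"), "balanced")
  d$y[1] <- NA
  expect_error(rm_anova(d, "y", c("f1", "f2"), "id"), "finite")
})

test_that("paired t matches its longhand formula and handles degeneracy", {
  set.seed(9)
  x <- rnorm(31, 350, 40)
  y <- rnorm(31, 320, 40)
  got <- paired_t(x, y)
  d <- x - y
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(31)), tolerance = 1e-12)
  expect_identical(got$df, 30)   # n = 31 pairs
  expect_equal(got$p, 2 * pt(abs(got$t), 30, lower.tail = FALSE),
               tolerance = 1e-12)
  # symmetry: flipping the difference sign negates t, keeps p
  rev <- paired_t(y, x)
  expect_equal(rev$t, -got$t)
  expect_equal(rev$p, got$p)
  # degenerate inputs
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  shift <- paired_t(x + 5, x)
  expect_identical(shift$t, Inf)
  expect_equal(shift$p, 0)
})

test_that("Bonferroni adjustment clamps at one and matches p.adjust", {
  expect_equal(bonferroni(0.01, m = 4), 0.04)
  expect_equal(bonferroni(0.5, m = 4), 1.0)
  expect_equal(bonferroni(0.3), 0.3)  # m = 1: identity
  p <- c(0.001, 0.02, 0.4, 0.9)
  expect_equal(bonferroni(p), p.adjust(p, method = "bonferroni"))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m must be")
})
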