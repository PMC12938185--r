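# Group statistics: normality, split-plot ANOVA, post hocs, two-group tests.

test_that("Shapiro-Wilk behaves on normal quantiles and bimodal data", {
  z <- qnorm(ppoints(50))
  res <- shapiro_wilk(z)
  expect_gt(res$W, 0.99)
  expect_lte(res$W, 1)
  set.seed(71)
  bim <- c(rnorm(25, -10, 1), rnorm(25, 10, 1))
  expect_lt(shapiro_wilk(bim)$p, 0.01)
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
})

# Definitional split-plot sums of squares for a balanced design.
splitplot_oracle <- function(d) {
  a <- nlevels(factor(d$group)); b <- nlevels(factor(d$within))
  N <- length(unique(d$subject))
  n_g <- N / a
  grand <- mean(d$y)
  subj_mean <- tapply(d$y, d$subject, mean)
  group_of <- tapply(as.character(d$group), d$subject, `[`, 1)
  group_mean <- tapply(d$y, d$group, mean)
  class_mean <- tapply(d$y, d$within, mean)
  cell_mean <- tapply(d$y, list(d$group, d$within), mean)
  SS_T <- sum((d$y - grand)^2)
  SS_bs <- b * sum((subj_mean - grand)^2)
  SS_G <- b * n_g * sum((group_mean - grand)^2)
  SS_SwG <- SS_bs - SS_G
  SS_C <- N * sum((class_mean - grand)^2)
  SS_GC <- n_g * sum((sweep(sweep(cell_mean, 1, group_mean), 2, class_mean) + grand)^2)
  SS_E <- SS_T - SS_bs - SS_C - SS_GC
  list(F_G = (SS_G / (a - 1)) / (SS_SwG / (N - a)),
       F_C = (SS_C / (b - 1)) / (SS_E / ((N - a) * (b - 1))),
       F_GC = (SS_GC / ((a - 1) * (b - 1))) / (SS_E / ((N - a) * (b - 1))))
}

make_splitplot_data <- function(seed = 81, n_per_group = 2, effect = 0) {
  set.seed(seed)
  g <- rep(c("HC", "MD", "SV"), each = n_per_group * 4)
  subj <- rep(paste0("s", 1:(3 * n_per_group)), each = 4)
  w <- rep(LETTERS[1:4], 3 * n_per_group)
  y <- rnorm(length(g)) +
    effect * (g == "SV") * (w == "B")
  data.frame(subject = subj, group = g, within = w, y = y, value = y)
}

test_that("mixed ANOVA matches the definitional split-plot decomposition", {
  for (seed in c(81, 82)) {
    d <- make_splitplot_data(seed, n_per_group = 3, effect = 1.5)
    res <- mixed_anova(d, value = "y")
    o <- splitplot_oracle(d)
    expect_equal(res$F[res$effect == "group"], unname(o$F_G), tolerance = 1e-8)
    expect_equal(res$F[res$effect == "within"], unname(o$F_C), tolerance = 1e-8)
    expect_equal(res$F[res$effect == "group:within"], unname(o$F_GC),
                 tolerance = 1e-8)
    expect_true(all(res$p >= 0 & res$p <= 1))
  }
})

test_that("mixed ANOVA is invariant to a common relabeling of classes and flags degeneracy", {
  d <- make_splitplot_data(83, n_per_group = 3, effect = 1)
  res1 <- mixed_anova(d, value = "y")
  d2 <- d
  d2$within <- c(A = "D", B = "C", C = "A", D = "B")[d$within]
  res2 <- mixed_anova(d2, value = "y")
  expect_equal(res1$F, res2$F, tolerance = 1e-10)
  # all-identical values: zero error -> degenerate, not a crash
  d3 <- d; d3$y <- 1
  res3 <- mixed_anova(d3, value = "y")
  expect_true(all(res3$degenerate | res3$F == 0 | is.na(res3$F)))
  # missing cells rejected
  expect_error(mixed_anova(d[-1, ], value = "y"), "unbalanced")
})

test_that("Holm-Sidak matches the closed form and is monotone above raw p", {
  hs <- holm_sidak(c(0.01, 0.04, 0.03))
  expect_equal(hs$adjusted[1], 1 - 0.99^3, tolerance = 1e-12)  # 0.029701
  expect_equal(hs$adjusted[3], max(1 - 0.99^3, 1 - 0.97^2), tolerance = 1e-12)
  expect_equal(hs$adjusted[2], max(1 - 0.99^3, 1 - 0.97^2, 1 - 0.96),
               tolerance = 1e-12)
  expect_equal(holm_sidak(0.2)$adjusted, 0.2)
  expect_equal(holm_sidak(rep(0, 5))$adjusted, rep(0, 5))
  set.seed(72)
  for (case in 1:20) {
    p <- runif(sample(1:20, 1))
    adj <- holm_sidak(p)$adjusted
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    # definitional step-down oracle
    m <- length(p)
    oracle <- numeric(m); running <- 0
    for (i in seq_len(m)) {
      running <- max(running, 1 - (1 - p[o[i]])^(m - i + 1))
      oracle[o[i]] <- running
    }
    expect_equal(adj, oracle, tolerance = 1e-12)
  }
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-group t matches printed-table style summary computations", {
  md <- list(n = 31, mean = 0.383, sd = 0.104)
  sv <- list(n = 19, mean = 0.162, sd = 0.040)
  tt <- two_group_t(summary1 = md, summary2 = sv)
  expect_equal(tt$pooled$t, 8.84, tolerance = 0.01)
  expect_equal(tt$pooled$df, 48)
  expect_lt(tt$pooled$p, 1e-10)
  expect_equal(tt$welch$t, 10.62, tolerance = 0.01)
  expect_gt(tt$welch$df, 40)
  d <- cohens_d(summary1 = md, summary2 = sv)
  expect_equal(d, 2.576, tolerance = 0.001)
})

test_that("t variants agree with stats::t.test and collapse when groups are exchangeable", {
  set.seed(73)
  for (case in 1:10) {
    x <- rnorm(sample(5:20, 1)); y <- rnorm(sample(5:20, 1), 0.4)
    tt <- two_group_t(x, y)
    ref_w <- t.test(x, y)
    ref_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(tt$welch$t, unname(ref_w$statistic), tolerance = 1e-10)
    expect_equal(tt$welch$df, unname(ref_w$parameter), tolerance = 1e-10)
    expect_equal(tt$welch$p, ref_w$p.value, tolerance = 1e-10)
    expect_equal(tt$pooled$t, unname(ref_p$statistic), tolerance = 1e-10)
    expect_equal(tt$pooled$p, ref_p$p.value, tolerance = 1e-10)
  }
  x <- rnorm(12)
  same <- two_group_t(x, x)
  expect_equal(same$welch$t, 0)
  expect_equal(same$welch$p, 1)
  # equal n and equal sd: Welch reduces to pooled
  y <- x + 5
  tt <- two_group_t(x, y)
  expect_equal(tt$welch$t, tt$pooled$t, tolerance = 1e-12)
  expect_equal(tt$welch$df, tt$pooled$df, tolerance = 1e-12)
})

test_that("Cohen's d has the expected scale behavior", {
  expect_equal(cohens_d(summary1 = list(n = 10, mean = 2, sd = 1),
                        summary2 = list(n = 10, mean = 2, sd = 1)), 0)
  d1 <- cohens_d(summary1 = list(n = 12, mean = 1, sd = 1),
                 summary2 = list(n = 8, mean = 0, sd = 1.2))
  d2 <- cohens_d(summary1 = list(n = 12, mean = 1, sd = 2),
                 summary2 = list(n = 8, mean = 0, sd = 2.4))
  expect_equal(d1 / d2, 2, tolerance = 1e-12)
  expect_true(is.na(cohens_d(summary1 = list(n = 5, mean = 1, sd = 0),
                             summary2 = list(n = 5, mean = 0, sd = 0))))
})

test_that("Mann-Whitney U counts dominating pairs with half-credit ties", {
  expect_equal(mann_whitney_u(c(1, 2), 0)$U, 2)
  expect_equal(mann_whitney_u(5, 5)$U, 0.5)
  set.seed(74)
  for (case in 1:20) {
    x <- sample(1:10, 6, TRUE); y <- sample(1:10, 5, TRUE)
    res <- mann_whitney_u(x, y)
    brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(res$U, brute)
    # orientation identity
    expect_equal(res$U + mann_whitney_u(y, x)$U, length(x) * length(y))
  }
  # exact no-tie p agrees with wilcox.test
  set.seed(75)
  x <- rnorm(8); y <- rnorm(7, 1)
  res <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(res$U, unname(ref$statistic))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$method, "exact")
})
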