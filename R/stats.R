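# Group-level inference: normality screening, split-plot ANOVA with
# Holm-Sidak post hocs, two-group tests, effect sizes.

#' Shapiro-Wilk normality test
#'
#' Standard W statistic and p-value (Royston approximation, via
#' `stats::shapiro.test`).
#'
#' @param sample numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(sample) {
  if (stats::sd(sample) == 0) stop("constant sample")
  res <- stats::shapiro.test(sample)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Two-way mixed (split-plot) ANOVA
#'
#' Repeated-measures design with a between-subject group factor and a
#' within-subject microstate-class factor: between error is
#' subjects-within-groups, within error is class x subjects-within-groups.
#' Requires every subject to contribute all classes.
#'
#' @param data long-format data.frame.
#' @param value,subject,group,within column names (strings).
#' @return data.frame with one row per effect (`group`, `within`,
#'   `group:within`): `df1`, `df2`, `F`, `p`. Degenerate (zero-error)
#'   designs report `NA` F with a `degenerate` flag.
#' @export
mixed_anova <- function(data, value = "value", subject = "subject",
                        group = "group", within = "within") {
  d <- data.frame(y = data[[value]],
                  subject = factor(data[[subject]]),
                  group = factor(data[[group]]),
                  within = factor(data[[within]]))
  if (anyNA(d)) stop("missing cells are not supported")
  counts <- table(d$subject, d$within)
  if (any(counts != 1))
    stop("unbalanced within factor: every subject needs every class exactly once")
  if (any(table(unique(d[c("subject", "group")])$group) < 2))
    stop("need at least 2 subjects per group")
  fit <- stats::aov(y ~ group * within + Error(subject), data = d)
  sm <- summary(fit)
  tab_b <- sm[["Error: subject"]][[1]]
  tab_w <- sm[["Error: Within"]][[1]]
  scale2 <- (abs(mean(d$y)) + stats::sd(d$y) + 1)^2
  grab <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    err <- nrow(tab)  # Residuals row
    if (tab[err, "Mean Sq"] <= 1e-20 * scale2)   # zero error stratum
      return(c(df1 = tab[i, "Df"], df2 = tab[err, "Df"],
               F = NA_real_, p = NA_real_))
    c(df1 = tab[i, "Df"], df2 = tab[err, "Df"],
      F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  rows <- rbind(grab(tab_b, "group"),
                grab(tab_w, "within"),
                grab(tab_w, "group:within"))
  out <- data.frame(effect = c("group", "within", "group:within"), rows,
                    row.names = NULL)
  out$degenerate <- !is.finite(out$F)
  out
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorted ascending, adj_(i) = 1 - (1 - p_(i))^(m - i + 1), enforced
#' monotone non-decreasing, mapped back to input order.
#'
#' @param p_values raw p-values in \[0, 1\].
#' @param alpha rejection level for the reported rejection set.
#' @return list with `adjusted` (same order as input) and `reject`.
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  adj_sorted <- 1 - (1 - p_values[o])^(m - seq_len(m) + 1)
  adj_sorted <- cummax(adj_sorted)
  adj <- numeric(m); adj[o] <- adj_sorted
  list(adjusted = adj, reject = adj <= alpha)
}

summary_stats <- function(x) list(n = length(x), mean = mean(x), sd = stats::sd(x))

as_summary <- function(s) {
  stopifnot(all(c("n", "mean", "sd") %in% names(s)))
  lapply(s[c("n", "mean", "sd")], as.numeric)
}

t_from_summaries <- function(s1, s2, variant) {
  n1 <- s1$n; n2 <- s2$n
  if (variant == "welch") {
    se2 <- s1$sd^2 / n1 + s2$sd^2 / n2
    t <- (s1$mean - s2$mean) / sqrt(se2)
    df <- se2^2 / ((s1$sd^2 / n1)^2 / (n1 - 1) + (s2$sd^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1$sd^2 + (n2 - 1) * s2$sd^2) / (n1 + n2 - 2)
    t <- (s1$mean - s2$mean) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (!is.finite(t)) return(list(t = NA_real_, df = df, p = NA_real_))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Independent two-sample t test (Welch and pooled)
#'
#' Computes both the Welch (Satterthwaite df) and pooled-variance variants,
#' from raw samples or from summary statistics (n, mean, sd per group) so
#' printed tables can be checked. With `variant = "auto"` and raw data,
#' Levene's test at `alpha` decides: Welch when variance homogeneity is
#' violated, pooled otherwise.
#'
#' @param x,y numeric samples (n >= 2 each), or NULL when using summaries.
#' @param summary1,summary2 lists with `n`, `mean`, `sd`.
#' @param variant `"auto"`, `"welch"` or `"pooled"`.
#' @param alpha Levene decision level for `"auto"`.
#' @return list of class `two_group_t`: `welch` and `pooled` sublists
#'   (t, df, p), `chosen`, `levene_p` (NA for summary input), and per-group
#'   summaries.
#' @export
two_group_t <- function(x = NULL, y = NULL, variant = c("auto", "welch", "pooled"),
                        summary1 = NULL, summary2 = NULL, alpha = 0.05) {
  variant <- match.arg(variant)
  if (!is.null(x)) {
    if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
    s1 <- summary_stats(x); s2 <- summary_stats(y)
  } else {
    s1 <- as_summary(summary1); s2 <- as_summary(summary2)
  }
  welch <- t_from_summaries(s1, s2, "welch")
  pooled <- t_from_summaries(s1, s2, "pooled")
  levene_p <- NA_real_
  if (variant == "auto") {
    if (!is.null(x)) {
      lev <- car::leveneTest(c(x, y),
                             factor(rep(c("a", "b"), c(length(x), length(y)))))
      levene_p <- lev[1, "Pr(>F)"]
      variant <- if (is.finite(levene_p) && levene_p < alpha) "welch" else "pooled"
    } else {
      variant <- "welch"
    }
  }
  structure(list(welch = welch, pooled = pooled, chosen = variant,
                 statistic = (if (variant == "welch") welch else pooled)$t,
                 df = (if (variant == "welch") welch else pooled)$df,
                 p = (if (variant == "welch") welch else pooled)$p,
                 levene_p = levene_p, group1 = s1, group2 = s2),
            class = "two_group_t")
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' d = (m1 - m2) / s_pooled with
#' s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)).
#'
#' @inheritParams two_group_t
#' @return scalar d (NA when the pooled variance is zero).
#' @export
cohens_d <- function(x = NULL, y = NULL, summary1 = NULL, summary2 = NULL) {
  if (!is.null(x)) {
    s1 <- summary_stats(x); s2 <- summary_stats(y)
  } else {
    s1 <- as_summary(summary1); s2 <- as_summary(summary2)
  }
  sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / (s1$n + s2$n - 2)
  if (sp2 <= 0) return(NA_real_)
  (s1$mean - s2$mean) / sqrt(sp2)
}

#' Mann-Whitney U test
#'
#' U = #\{(x, y): x > y\} + 1/2 #\{ties\}. Two-sided p by exact null
#' enumeration when there are no ties and n1 * n2 <= 400, otherwise by the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 * n2 <= 400) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    p <- min(1, p)
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(c(x, y))
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "degenerate"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}
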