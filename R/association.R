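# Clinical correlation screen: Spearman + Benjamini-Hochberg FDR.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); two-tailed p
#' from the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors without missing values, n >= 4.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' q_(i) = min over j >= i of (m * p_(j) / j), mapped back to input order
#' (the step-up procedure; `stats::p.adjust(method = "BH")`).
#'
#' @param p_values raw p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Clinical correlation screen over all microstate features
#'
#' Restricts the cohort to patient rows (MD and SV), then Spearman-
#' correlates every microstate feature with each clinical scale. BH-FDR is
#' applied within scale across all tested features (q = 0.05 by default).
#' Subjects with a missing score are dropped pairwise per scale.
#'
#' @param feature_table a `feature_table` with group and score columns.
#' @param scales score column names (default VAS and ABC).
#' @param patients_only restrict to `groups` rows.
#' @param groups patient group labels.
#' @param q_threshold FDR significance level.
#' @return data.frame with `feature`, `scale`, `rho`, `p`, `q`, `n`,
#'   `significant`, ordered by `q` within scale.
#' @export
clinical_screen <- function(feature_table, scales = c("VAS", "ABC"),
                            patients_only = TRUE, groups = c("MD", "SV"),
                            q_threshold = 0.05) {
  ft <- feature_table
  if (patients_only) ft <- ft[ft$group %in% groups, , drop = FALSE]
  feats <- feature_columns(ft)
  if (!length(feats)) stop("no microstate feature columns found")
  res <- list()
  for (sc in scales) {
    if (!sc %in% names(ft)) stop("missing scale column: ", sc)
    rows <- lapply(feats, function(f) {
      keep <- stats::complete.cases(ft[[f]], ft[[sc]])
      if (sum(keep) < 4)
        return(data.frame(feature = f, scale = sc, rho = NA_real_,
                          p = NA_real_, n = sum(keep)))
      s <- spearman(ft[[f]][keep], ft[[sc]][keep])
      data.frame(feature = f, scale = sc, rho = s$rho, p = s$p, n = s$n)
    })
    tab <- do.call(rbind, rows)
    if (all(is.na(tab$p))) stop("fewer than 4 usable patients")
    tab$q <- NA_real_
    ok <- !is.na(tab$p)
    tab$q[ok] <- bh_fdr(tab$p[ok])
    tab$significant <- !is.na(tab$q) & tab$q < q_threshold
    res[[sc]] <- tab[order(tab$q), ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
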