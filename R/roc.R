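# Single-feature discrimination: AUC and stratified k-fold cross-validation.

#' Area under the ROC curve (rank statistic)
#'
#' AUC = (#\{x > y\} + 1/2 #\{x = y\}) / (n_pos * n_neg): the probability
#' that a random positive-group value exceeds a random negative-group value
#' (ties credited one half). Equals the Mann-Whitney U divided by
#' n_pos * n_neg.
#'
#' @param scores_positive,scores_negative nonempty numeric vectors.
#' @return scalar in \[0, 1\].
#' @export
auc <- function(scores_positive, scores_negative) {
  n1 <- length(scores_positive); n2 <- length(scores_negative)
  if (!n1 || !n2) stop("both groups must be nonempty")
  r <- rank(c(scores_positive, scores_negative))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U / (n1 * n2)
}

# Seeded stratified fold assignment preserving class ratios (fold sizes per
# class differ by at most 1).
stratified_folds <- function(labels, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop(sprintf("class '%s' has %d members (< k = %d): k too large",
                     cl, length(idx), k))
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validated AUC for one feature
#'
#' Splits subjects into `k` stratified folds; per fold, the orientation
#' (which direction of the feature marks the positive class) is fixed on
#' the training portion (training AUC >= 0.5), then the AUC is computed on
#' the held-out fold with that orientation. Reports the fold AUCs, their
#' mean, the 2.5th-97.5th percentile interval of the fold values, and a
#' two-sided pooled-data Mann-Whitney p.
#'
#' @param values numeric feature vector.
#' @param labels vector with exactly two classes.
#' @param positive label of the positive class (default first encountered).
#' @param k number of folds.
#' @param seed integer seed for the stratified partition.
#' @param folds optional precomputed fold assignment (overrides `seed`);
#'   lets several features share one partition.
#' @return object of class `roc_result`: `fold_aucs`, `mean_auc`, `ci_low`,
#'   `ci_high`, `p`, `orientation` (+1 higher values mark the positive
#'   class, -1 flipped), `positive`.
#' @export
stratified_kfold_auc <- function(values, labels, positive = NULL, k = 5,
                                 seed = NULL, folds = NULL) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) stop("need exactly two classes")
  positive <- positive %||% classes[1]
  negative <- setdiff(classes, positive)
  fold <- folds %||% stratified_folds(labels, k, seed)
  if (length(fold) != length(values)) stop("fold assignment length mismatch")
  fold_aucs <- numeric(k)
  orientations <- integer(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    a_tr <- auc(values[tr & labels == positive], values[tr & labels == negative])
    flip <- a_tr < 0.5
    a_te <- auc(values[te & labels == positive], values[te & labels == negative])
    fold_aucs[f] <- if (flip) 1 - a_te else a_te
    orientations[f] <- if (flip) -1L else 1L
  }
  ci <- unname(stats::quantile(fold_aucs, c(0.025, 0.975)))
  mw <- mann_whitney_u(values[labels == positive], values[labels == negative])
  structure(list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
                 ci_low = ci[1], ci_high = ci[2], p = mw$p,
                 orientation = sign(sum(orientations)),
                 positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> mean CV AUC = %.3f (95%% CI %.3f-%.3f), p = %.3g, positive = %s\n",
              x$mean_auc, x$ci_low, x$ci_high, x$p, x$positive))
  invisible(x)
}

#' Screen every feature with cross-validated ROC
#'
#' Evaluates [stratified_kfold_auc()] for every microstate feature column
#' of a feature table, restricted to two groups, and ranks the features by
#' mean cross-validated AUC.
#'
#' @param feature_table a `feature_table`.
#' @param groups the two group labels to contrast (positive class first).
#' @param k folds.
#' @param seed master seed; one stratified partition is drawn and shared by
#'   every feature (so identical columns earn identical fold AUCs).
#' @return data.frame ranked by `mean_auc`: `feature`, `mean_auc`,
#'   `ci_low`, `ci_high`, `p`, `orientation`.
#' @export
screen_all_features <- function(feature_table, groups = c("MD", "SV"),
                                k = 5, seed = NULL) {
  ft <- feature_table[feature_table$group %in% groups, , drop = FALSE]
  feats <- feature_columns(ft)
  seeds <- split_seed(seed, length(feats) + 1L)
  shared <- stratified_folds(as.character(ft$group), k,
                             seed = seeds[[length(feats) + 1L]])
  rows <- lapply(seq_along(feats), function(i) {
    v <- ft[[feats[i]]]
    keep <- !is.na(v)
    r <- if (all(keep))
      stratified_kfold_auc(v, ft$group, positive = groups[1], k = k,
                           folds = shared)
    else
      stratified_kfold_auc(v[keep], ft$group[keep], positive = groups[1],
                           k = k, seed = seeds[[i]])
    data.frame(feature = feats[i], mean_auc = r$mean_auc,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
               orientation = r$orientation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_auc), ]
  rownames(out) <- NULL
  out
}
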