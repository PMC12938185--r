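# Template back-fitting, minimum-duration smoothing, temporal metrics.

#' Back-fit microstate templates to continuous data
#'
#' Assigns each sample the template with the highest absolute spatial
#' correlation (polarity ignored). Exact ties break to the lowest class
#' index. Zero-variance samples inherit the previous sample's label (class
#' A for a leading zero) and are flagged.
#'
#' @param recording an `eeg_recording`.
#' @param template_set a `template_set` whose maps match the channels.
#' @return object of class `segmentation`: `labels` (per-sample class
#'   index), `fit` (winning absolute correlation), `corr` (samples x K
#'   matrix of absolute correlations), `sampling_rate`, `band`,
#'   `class_names`, `flagged` (zero-variance sample indices).
#' @export
backfit <- function(recording, template_set) {
  Tm <- template_set$maps
  if (ncol(Tm) != nrow(recording$data)) stop("channel counts do not match")
  X <- average_reference(recording$data)
  norms <- sqrt(colSums(X^2))
  K <- nrow(Tm)
  A <- t(Tm %*% X)                       # samples x K inner products
  zero <- norms < 1e-12
  safe <- ifelse(zero, 1, norms)
  corr <- abs(A / safe)
  labels <- max.col(corr, ties.method = "first")
  if (any(zero)) {
    for (i in which(zero)) labels[i] <- if (i == 1L) 1L else labels[i - 1L]
    corr[zero, ] <- 0
  }
  structure(list(labels = labels,
                 fit = corr[cbind(seq_along(labels), labels)],
                 corr = corr,
                 sampling_rate = recording$sampling_rate,
                 band = recording$band %||% NULL,
                 class_names = template_set$labels %||% LETTERS[seq_len(K)],
                 flagged = which(zero)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  r <- rle(x$labels)
  cat(sprintf("<segmentation> %d samples @ %g Hz, %d classes, %d runs\n",
              length(x$labels), x$sampling_rate,
              length(x$class_names), length(r$values)))
  invisible(x)
}

#' Enforce a minimum microstate duration
#'
#' Iteratively dissolves the shortest interior run below
#' `ceil(min_ms * rate / 1000)` samples: each of its samples is relabeled
#' to the better-correlated of the two flanking runs' labels. First and
#' last runs are exempt (their true extent is censored by the window).
#' A safety cap forces wholesale merging into the better flank if the
#' sample-wise rule ever stops shrinking the run count, guaranteeing
#' termination.
#'
#' @param segmentation a `segmentation` from [backfit()].
#' @param min_ms minimum duration in milliseconds (default 30).
#' @return the smoothed `segmentation` (labels and fit updated).
#' @export
smooth_min_duration <- function(segmentation, min_ms = 30) {
  lab <- segmentation$labels
  A <- segmentation$corr
  min_run <- ceiling(min_ms * segmentation$sampling_rate / 1000)
  r <- rle(lab)
  nr <- length(r$values)
  if (nr > 2L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    viol <- logical(nr)
    viol[2:(nr - 1L)] <- r$lengths[2:(nr - 1L)] < min_run
    # Islands: maximal blocks of consecutive violating runs. Dissolving a
    # run only redistributes its samples to its flanks, so compliant
    # separator runs can only grow and islands never interact; exact
    # shortest-first order therefore only matters within an island.
    vr <- rle(viol)
    vends <- cumsum(vr$lengths)
    vstarts <- vends - vr$lengths + 1L
    for (blk in which(vr$values)) {
      i0 <- vstarts[blk]; i1 <- vends[blk]          # violating run indices
      span <- starts[i0]:ends[i1]
      lab[span] <- dissolve_island(lab[span], A[span, , drop = FALSE],
                                   r$values[i0 - 1L], r$values[i1 + 1L],
                                   min_run)
    }
    rr <- rle(lab)
    lab <- rep.int(rr$values, rr$lengths)
  }
  out <- segmentation
  out$labels <- lab
  out$fit <- A[cbind(seq_along(lab), lab)]
  out$min_run <- min_run
  out
}

# Exact shortest-first dissolution of one island of violating runs.
# Lflank/Rflank are the labels of the (exempt) bounding runs, modelled as
# pseudo-runs of infinite length. Each dissolved sample is relabeled to the
# better-correlated of its two flanking runs' labels; a safety cap forces
# wholesale merging should the sample-wise rule ever stop making progress.
dissolve_island <- function(lab, A, Lflank, Rflank, min_run) {
  offset <- 2^40                           # pseudo-flank length (double)
  r <- rle(lab)
  vals <- c(Lflank, r$values, Rflank)
  lens <- c(offset, as.numeric(r$lengths), offset)
  m <- merge_runs(vals, lens)              # island edge may share flank label
  vals <- m$values; lens <- m$lengths
  iter <- 0L; cap <- 2L * length(lab)
  repeat {
    nr <- length(vals)
    if (nr <= 2L) break
    interior <- 2:(nr - 1L)
    viol <- interior[lens[interior] < min_run]
    if (!length(viol)) break
    iter <- iter + 1L
    i <- viol[which.min(lens[viol])]
    # sample positions of run i within the island
    start_i <- sum(lens[seq_len(i - 1L)]) - offset + 1L
    span <- start_i:(start_i + lens[i] - 1L)
    L <- vals[i - 1L]; R <- vals[i + 1L]
    if (L == R || iter > cap) {
      pick <- if (L == R) L
              else if (mean(A[span, L]) >= mean(A[span, R])) L else R
      newlab <- rep(pick, length(span))
    } else {
      newlab <- ifelse(A[span, L] >= A[span, R], L, R)
    }
    sub <- rle(newlab)
    m <- merge_runs(c(vals[seq_len(i - 1L)], sub$values, vals[(i + 1L):nr]),
                    c(lens[seq_len(i - 1L)], sub$lengths, lens[(i + 1L):nr]))
    vals <- m$values; lens <- m$lengths
  }
  # strip pseudo-flanks: rebuild the island's labels
  lens[1L] <- lens[1L] - offset
  lens[length(lens)] <- lens[length(lens)] - offset
  rep.int(vals, lens)
}

#' Per-class temporal metrics
#'
#' Run-length encodes the (smoothed) label sequence and reports, per class:
#' mean duration (ms) of its runs, coverage (fraction of samples), and
#' occurrence (runs per second). Censored first/last runs are included.
#' An absent class has `NA` duration, coverage 0, occurrence 0.
#'
#' @param segmentation a `segmentation`.
#' @return data.frame with columns `state`, `mean_duration`, `coverage`,
#'   `occurrence`, `n_runs`.
#' @export
temporal_metrics <- function(segmentation) {
  lab <- segmentation$labels
  rate <- segmentation$sampling_rate
  K <- length(segmentation$class_names)
  r <- rle(lab)
  total_s <- length(lab) / rate
  out <- data.frame(state = segmentation$class_names,
                    mean_duration = NA_real_, coverage = 0,
                    occurrence = 0, n_runs = 0L)
  for (k in seq_len(K)) {
    runs <- r$lengths[r$values == k]
    out$n_runs[k] <- length(runs)
    if (length(runs)) {
      out$mean_duration[k] <- mean(runs) * 1000 / rate
      out$coverage[k] <- sum(runs) / length(lab)
      out$occurrence[k] <- length(runs) / total_s
    }
  }
  out
}

#' Global explained variance per microstate class
#'
#' gev_k = sum over samples labeled k of (GFP(t) * corr(v_t, T_k))^2
#' divided by sum over all samples of GFP(t)^2.
#'
#' @param recording the `eeg_recording` the segmentation labels.
#' @param segmentation a `segmentation` aligned with the recording.
#' @param template_set the `template_set` used for back-fitting.
#' @return named numeric vector of per-class GEV fractions.
#' @export
gev_per_class <- function(recording, segmentation, template_set) {
  g <- gfp(recording)$values
  tot <- sum(g^2)
  if (tot < 1e-24) stop("zero total GFP")
  X <- average_reference(recording$data)
  norms <- sqrt(colSums(X^2))
  Tm <- template_set$maps
  lab <- segmentation$labels
  dots <- t(Tm %*% X)
  corr <- abs(dots[cbind(seq_along(lab), lab)]) / ifelse(norms < 1e-12, Inf, norms)
  # map GFP: spatial sd = norm / sqrt(C)
  contrib <- (g * corr)^2
  K <- length(segmentation$class_names)
  out <- vapply(seq_len(K), function(k) sum(contrib[lab == k]) / tot, numeric(1))
  names(out) <- segmentation$class_names
  out
}

#' Transition probabilities between microstate classes
#'
#' With `mode = "runs"` (the default convention, to which the package's
#' planted feature magnitudes are calibrated) counts ordered pairs of
#' consecutive distinct runs (i -> j, i != j) and normalizes each row by
#' its outgoing count; the diagonal is structurally zero. With
#' `mode = "samples"` counts all consecutive sample pairs including
#' self-transitions, which yields diagonal-dominant rows. Rows with no
#' outgoing transitions are `NA` and flagged.
#'
#' @param segmentation a smoothed `segmentation` with at least 2 runs
#'   (a single-run segmentation yields all-`NA` rows under `"runs"`).
#' @param mode counting convention, `"runs"` or `"samples"`.
#' @return K x K matrix (rows "from", columns "to") with attribute
#'   `undefined_rows`.
#' @export
transition_probabilities <- function(segmentation, mode = c("runs", "samples")) {
  mode <- match.arg(mode)
  K <- length(segmentation$class_names)
  v <- if (mode == "runs") rle(segmentation$labels)$values
       else segmentation$labels
  counts <- matrix(0, K, K,
                   dimnames = list(segmentation$class_names,
                                   segmentation$class_names))
  if (length(v) >= 2L) {
    from <- factor(v[-length(v)], levels = seq_len(K))
    to <- factor(v[-1L], levels = seq_len(K))
    counts[] <- table(from, to)
  }
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, NA, rs)
  undef <- which(rs == 0)
  P[undef, ] <- NA_real_
  attr(P, "undefined_rows") <- segmentation$class_names[undef]
  P
}
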