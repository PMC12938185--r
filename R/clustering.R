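# Polarity-invariant modified K-means microstate clustering.

#' Template set container
#'
#' @param maps K x n_channels matrix; each row is average-referenced and
#'   unit-norm (enforced).
#' @param labels optional canonical labels (e.g. `c("A","B","C","D")`).
#' @param band band name or NULL.
#' @param gev_total global explained variance of the fit that produced the
#'   maps (fraction in \[0, 1\]).
#' @param cv_criterion predictive-residual model-selection criterion.
#' @param k_profile optional data.frame of the K scan (columns K, gev, cv).
#' @return object of class `template_set`.
#' @export
template_set <- function(maps, labels = NULL, band = NULL,
                         gev_total = NA_real_, cv_criterion = NA_real_,
                         k_profile = NULL) {
  maps <- normalize_maps(as.matrix(maps))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(maps))
    rownames(maps) <- labels
  }
  structure(list(maps = maps, labels = labels, band = band,
                 gev_total = gev_total, cv_criterion = cv_criterion,
                 k_profile = k_profile),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> K = %d, %d channels%s%s\n",
              nrow(x$maps), ncol(x$maps),
              if (!is.null(x$band)) paste0(", band = ", x$band) else "",
              if (!is.na(x$gev_total)) sprintf(", GEV = %.3f", x$gev_total) else ""))
  if (!is.null(x$labels)) cat("  labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Spatial correlation between two scalp maps
#'
#' Pearson correlation across channels of the average-referenced maps;
#' with `ignore_polarity = TRUE` (the microstate convention for spontaneous
#' EEG) the absolute value is returned.
#'
#' @param map1,map2 numeric vectors of equal length (one value per channel).
#' @param ignore_polarity treat a map and its sign-flip as identical.
#' @return scalar in \[0, 1\] (or \[-1, 1\] if polarity is kept).
#' @export
spatial_correlation <- function(map1, map2, ignore_polarity = TRUE) {
  if (length(map1) != length(map2)) stop("maps must have equal channel counts")
  a <- map1 - mean(map1); b <- map2 - mean(map2)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-variance map")
  r <- sum(a * b) / (na * nb)
  if (ignore_polarity) abs(r) else r
}

# Internal core: one modified K-means fit from a given initialization.
# X: n x C maps (rows average-referenced); Xn: row-normalized copy;
# gfp2: per-map spatial variance. Returns list(T, assign, gev, corr_best).
modk_fit <- function(X, Xn, gfp2, K, max_iter, tol, init_rows) {
  Tm <- Xn[init_rows, , drop = FALSE]
  n <- nrow(X)
  gev_prev <- -Inf
  for (it in seq_len(max_iter)) {
    A <- Xn %*% t(Tm)                       # cosines = spatial correlations
    cl <- max.col(A^2, ties.method = "first")
    best <- A[cbind(seq_len(n), cl)]
    # empty clusters: re-seed from the currently worst-fit map
    for (k in seq_len(K)) {
      if (!any(cl == k)) {
        worst <- which.min(abs(best))
        Tm[k, ] <- Xn[worst, ]
        cl[worst] <- k
        A <- Xn %*% t(Tm)
        cl <- max.col(A^2, ties.method = "first")
        best <- A[cbind(seq_len(n), cl)]
      }
    }
    gev <- sum(gfp2 * best^2) / sum(gfp2)
    # template update: dominant eigenvector of assigned maps' outer products
    for (k in seq_len(K)) {
      idx <- which(cl == k)
      S <- crossprod(X[idx, , drop = FALSE])
      e <- eigen(S, symmetric = TRUE)
      v <- e$vectors[, 1L]
      Tm[k, ] <- v / sqrt(sum(v^2))
    }
    if (is.finite(gev_prev) && abs(gev - gev_prev) < tol * max(gev, 1e-12)) break
    gev_prev <- gev
  }
  A <- Xn %*% t(Tm)
  cl <- max.col(A^2, ties.method = "first")
  best <- abs(A[cbind(seq_len(n), cl)])
  gev <- sum(gfp2 * best^2) / sum(gfp2)
  list(Tm = Tm, assign = cl, gev = gev, corr_best = best)
}

#' Modified K-means clustering of GFP-peak maps
#'
#' Polarity-invariant microstate clustering: maps are assigned to the
#' template with the highest squared spatial correlation, and each template
#' is updated as the dominant eigenvector of its assigned maps' outer
#' product sum. The best of `n_restarts` seeded restarts (by total global
#' explained variance) is returned.
#'
#' @param peak_maps a `peak_maps` object or an n x channels numeric matrix
#'   of average-referenced maps.
#' @param K number of clusters (1 <= K <= n maps).
#' @param n_restarts number of random restarts.
#' @param max_iter,tol convergence controls (relative GEV change).
#' @param seed integer seed.
#' @param band band name carried into the result.
#' @return a `template_set` with `gev_total` and `cv_criterion` filled in.
#' @export
modkmeans <- function(peak_maps, K, n_restarts = 20, max_iter = 300,
                      tol = 1e-6, seed = NULL, band = NULL) {
  X <- if (inherits(peak_maps, "peak_maps")) peak_maps$maps else as.matrix(peak_maps)
  band <- band %||% (if (inherits(peak_maps, "peak_maps")) peak_maps$band else NULL)
  X <- X - rowMeans(X)
  n <- nrow(X); C <- ncol(X)
  if (n < K) stop("fewer maps than clusters")
  gfp2 <- rowSums(X^2) / C
  keep <- gfp2 > 1e-20
  X <- X[keep, , drop = FALSE]; gfp2 <- gfp2[keep]; n <- nrow(X)
  Xn <- X / sqrt(rowSums(X^2))
  fits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      init <- sample.int(n, K)
      modk_fit(X, Xn, gfp2, K, max_iter, tol, init)
    })
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "gev"))]]
  sigma2 <- mean((1 - best$corr_best^2) * gfp2)
  cv <- if (C - 1 - K > 0) sigma2 * ((C - 1) / (C - 1 - K))^2 else Inf
  ts <- template_set(best$Tm, band = band,
                     gev_total = best$gev, cv_criterion = cv)
  ts$assignment <- best$assign
  ts
}

#' Cluster-number selection over a range of K
#'
#' Fits `modkmeans` for each K in `k_range`, recording total GEV and the
#' predictive-residual criterion CV(K) = sigma2_K * ((C-1)/(C-1-K))^2 with
#' sigma2_K the mean unexplained map variance. Returns the CV-minimizing
#' solution, or the `forced_k` solution when requested (K = 4 is the
#' conventional microstate choice); the full K profile is attached either way.
#'
#' @inheritParams modkmeans
#' @param k_range candidate cluster numbers.
#' @param forced_k if non-NULL, return this K's solution regardless of CV.
#' @return a `template_set` with a `k_profile` data.frame.
#' @export
select_k <- function(peak_maps, k_range = 2:10, n_restarts = 20,
                     max_iter = 300, tol = 1e-6, seed = NULL,
                     forced_k = NULL, band = NULL) {
  seeds <- split_seed(seed, length(k_range))
  fits <- lapply(seq_along(k_range), function(i)
    modkmeans(peak_maps, k_range[i], n_restarts, max_iter, tol,
              seed = seeds[[i]], band = band))
  prof <- data.frame(K = k_range,
                     gev = vapply(fits, `[[`, numeric(1), "gev_total"),
                     cv = vapply(fits, `[[`, numeric(1), "cv_criterion"))
  pick <- if (!is.null(forced_k)) {
    if (!forced_k %in% k_range) stop("forced_k outside k_range")
    match(forced_k, k_range)
  } else which.min(prof$cv)
  out <- fits[[pick]]
  out$k_profile <- prof
  out
}

# All permutations of 1..n (n small).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Canonical A-D labeling of a four-template set
#'
#' Finds the one-to-one assignment between fitted templates and the
#' canonical templates that maximizes the summed absolute spatial
#' correlation over all 24 permutations, and reorders the set to A, B, C, D.
#'
#' @param ts a `template_set` with K = 4.
#' @param canonical a `template_set` of canonical maps (defaults to
#'   [canonical_templates()] on `montage`).
#' @param montage used only when `canonical` is NULL.
#' @return the relabeled, reordered `template_set`; the matching
#'   correlations are stored in `$label_correlations`.
#' @export
canonical_label <- function(ts, canonical = NULL, montage = NULL) {
  if (nrow(ts$maps) != 4) stop("canonical labeling requires K = 4")
  if (is.null(canonical)) {
    if (is.null(montage)) stop("supply canonical templates or a montage")
    canonical <- canonical_templates(montage)
  }
  cmaps <- if (inherits(canonical, "template_set")) canonical$maps else as.matrix(canonical)
  S <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    S[i, j] <- spatial_correlation(ts$maps[i, ], cmaps[j, ], ignore_polarity = TRUE)
  perms <- all_permutations(4L)
  scores <- apply(perms, 1L, function(p) sum(S[cbind(1:4, p)]))
  p <- perms[which.max(scores), ]          # template i -> canonical class p[i]
  ord <- order(p)                          # reorder rows to A, B, C, D
  out <- ts
  out$maps <- ts$maps[ord, , drop = FALSE]
  out$labels <- LETTERS[1:4]
  rownames(out$maps) <- out$labels
  out$label_correlations <- S[cbind(ord, 1:4)]
  names(out$label_correlations) <- out$labels
  out
}
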