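# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate expr with a private RNG state; NULL seed leaves the global RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministically derive child seeds (< 2^31) from a master seed.
split_seed <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

# Subtract the spatial mean from every sample (columns of a channel x sample matrix).
average_reference <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# Row-wise average reference + unit norm (for template / map matrices, rows = maps).
normalize_maps <- function(m) {
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12)) stop("cannot normalize a zero map")
  m / nrm
}

# Merge adjacent equal-valued runs; vals/lens parallel vectors.
merge_runs <- function(vals, lens) {
  if (length(vals) <= 1L) return(list(values = vals, lengths = lens))
  grp <- cumsum(c(TRUE, vals[-1L] != vals[-length(vals)]))
  list(values = vals[!duplicated(grp)],
       lengths = as.vector(rowsum(lens, grp)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
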