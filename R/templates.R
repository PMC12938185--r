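# Canonical microstate topographies and synthetic template generation.
#
# Maps are modelled as scalp potentials of current dipoles inside a
# single-sphere head: V(p) ~ q . (p - r0) / |p - r0|^3 for a dipole with
# moment q at r0. This gives smooth, dipolar fields that are nonlinear in
# the electrode positions, so the four classes are not linearly dependent.

dipole_field <- function(pos, r0, q) {
  d <- sweep(pos, 2L, r0, "-")
  dist3 <- (rowSums(d^2))^(3 / 2)
  as.vector(d %*% q) / dist3
}

# Fixed dipole parameterization of the four canonical classes:
# A: left-posterior -> right-anterior diagonal field
# B: right-posterior -> left-anterior diagonal field
# C: anterior-posterior (occipital-to-frontal) field
# D: fronto-central, mostly radial field
canonical_dipoles <- function() {
  list(
    A = list(r0 = c(-0.15, -0.10, 0.35), q = c(0.80, 0.55, 0.0)),
    B = list(r0 = c(0.15, -0.10, 0.35), q = c(-0.80, 0.55, 0.0)),
    C = list(r0 = c(0.00, 0.05, 0.30), q = c(0.0, 0.95, -0.30)),
    D = list(r0 = c(0.00, 0.25, 0.45), q = c(0.0, 0.30, 0.95))
  )
}

#' Stylized canonical microstate templates (classes A-D)
#'
#' Analytic, montage-independent definitions of the four canonical
#' resting-state topographies: two mirrored diagonal dipolar fields (A, B),
#' an anterior-posterior field (C) and a fronto-central field (D). Each map
#' is average-referenced and unit-norm.
#'
#' @param montage a `montage`.
#' @return a `template_set` with K = 4 rows labeled `A`-`D`.
#' @export
canonical_templates <- function(montage) {
  validate_montage(montage)
  pos <- montage_positions(montage)
  dip <- canonical_dipoles()
  maps <- t(vapply(dip, function(d) dipole_field(pos, d$r0, d$q),
                   numeric(nrow(pos))))
  maps <- normalize_maps(maps)
  template_set(maps, labels = names(dip), band = NULL)
}

# Rotate vector v by angle (radians) about unit axis (Rodrigues).
rotate_about <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Generate synthetic microstate template maps
#'
#' The first four states are jittered versions of the canonical A-D dipole
#' fields (a small seeded rotation of each dipole moment); additional states
#' use randomly placed and oriented dipoles. Maps are average-referenced,
#' unit-norm, and mutually distinct (pairwise absolute spatial correlation
#' below 0.95, enforced by rejection).
#'
#' @param montage a `montage`.
#' @param n_states number of templates (<= number of channels).
#' @param seed integer seed (same seed, same maps).
#' @param jitter_sd standard deviation (radians) of the rotation jitter
#'   applied to the canonical dipole moments.
#' @return an `n_states x n_channels` matrix with rownames `A`, `B`, ...
#' @export
make_templates <- function(montage, n_states = 4, seed = NULL,
                           jitter_sd = 0.08) {
  validate_montage(montage)
  if (n_states > nrow(montage))
    stop("montage too small: fewer channels than requested states")
  pos <- montage_positions(montage)
  dip <- canonical_dipoles()
  with_seed(seed, {
    for (attempt in 1:100) {
      maps <- matrix(0, n_states, nrow(pos))
      for (k in seq_len(n_states)) {
        if (k <= 4) {
          d <- dip[[k]]
          axis <- stats::rnorm(3)
          q <- rotate_about(d$q, axis, stats::rnorm(1, 0, jitter_sd))
          maps[k, ] <- dipole_field(pos, d$r0, q)
        } else {
          r0 <- stats::rnorm(3); r0 <- r0 / sqrt(sum(r0^2)) * stats::runif(1, 0.2, 0.5)
          q <- stats::rnorm(3); q <- q / sqrt(sum(q^2))
          maps[k, ] <- dipole_field(pos, r0, q)
        }
      }
      maps <- normalize_maps(maps)
      cc <- abs(stats::cor(t(maps)))
      if (n_states == 1 || max(cc[upper.tri(cc)]) < 0.95) break
      if (attempt == 100) stop("could not generate mutually distinct templates")
    }
    rownames(maps) <- LETTERS[seq_len(n_states)]
    maps
  })
}
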