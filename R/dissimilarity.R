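#' Jensen-Shannon divergence between two probability vectors
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2` and the
#' convention `0 * log 0 = 0`. In base 2 the divergence is bounded in
#' `[0, 1]`; its square root is a metric.
#'
#' @param p,q non-negative vectors of equal length, each summing to 1
#'   (within 1e-9).
#' @param base logarithm base, `2` (default, bounded in `[0,1]`) or `exp(1)`.
#' @return the divergence, a single non-negative number.
#' @export
jsd_pair <- function(p, q, base = 2) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probability vectors must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("probability vectors must sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i], base) - log(b[i], base)))
  }
  max(0, (kl(p, m) + kl(q, m)) / 2)
}

#' All-against-all Jensen-Shannon dissimilarity matrix
#'
#' Computes pairwise Jensen-Shannon divergence between the samples of a
#' relative-abundance table. With `as_distance = TRUE` (default) the square
#' root of each divergence is returned, which is a metric and is the standard
#' choice for downstream medoid clustering and principal-coordinates
#' ordination.
#'
#' @param t a [rel_abund()] table (samples x ASVs).
#' @param base logarithm base (default 2).
#' @param as_distance return `sqrt(JSD)` (a metric) instead of the raw
#'   divergence.
#' @return symmetric matrix with zero diagonal and sample ids as dimnames.
#' @export
jsd_matrix <- function(t, base = 2, as_distance = TRUE) {
  m <- unclass(t)
  d <- .jsd_matrix_cpp(m, base)
  if (as_distance) d <- sqrt(d)
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: double-centre `-d^2/2`, eigendecompose, and keep
#' the axes with positive eigenvalues, scaled by the square root of their
#' eigenvalue. Negative-eigenvalue axes are dropped (no Cailliez correction);
#' the fraction of negative inertia is recorded.
#'
#' @param d symmetric dissimilarity matrix with sample ids as dimnames.
#' @param n_axes number of axes to return; truncated with a warning if it
#'   exceeds the number of positive eigenvalues. `NULL` keeps all positive axes.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (positive,
#'   non-increasing), `sample_ids`, and `negative_inertia` (fraction of total
#'   absolute eigenvalue mass on negative axes).
#' @export
pcoa <- function(d, n_axes = NULL) {
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; positivity is
  # handled explicitly below
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  ev <- fit$eig
  pos <- which(ev > sqrt(.Machine$double.eps) * max(abs(ev)))
  neg_inertia <- sum(abs(ev[ev < 0])) / sum(abs(ev))
  if (is.null(n_axes)) n_axes <- length(pos)
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive-eigenvalue axes available; truncating")
    n_axes <- length(pos)
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  rownames(coords) <- rownames(d)
  list(coordinates = coords,
       eigenvalues = ev[pos][seq_len(n_axes)],
       sample_ids = rownames(d),
       negative_inertia = neg_inertia)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between- versus within-group dissimilarities:
#' all `M = n(n-1)/2` off-diagonal dissimilarities are ranked (ties get
#' average ranks) and
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`.
#' R is near 0 for random groupings and 1 when every between-group pair is
#' more dissimilar than every within-group pair. Significance comes from
#' permuting group labels (group sizes preserved) with the add-one estimator
#' `p = (#{R_perm >= R_obs} + 1) / (n_perm + 1)`.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups vector of group labels, one per sample; at least two groups,
#'   and at least one group with more than one member.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return list with `R`, `p_value`, `n_groups`, `n_permutations`, and
#'   `perm_R` (the permutation null values).
#' @export
anosim_test <- function(d, groups, n_perm = 1000, seed = 1) {
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  if (length(unique(groups)) < 2) stop("at least two groups required")
  if (length(unique(groups)) == n)
    stop("every sample in its own group: within-group ranks undefined")
  rk <- matrix(0, n, n)
  lower <- lower.tri(rk)
  rk[lower] <- rank(d[lower])     # average ranks for ties
  rk <- rk + t(rk)
  M <- n * (n - 1) / 2
  S <- sum(rk) / 2                # total rank sum over all pairs
  denom <- n * (n - 1) / 4
  # Within-group rank sums via per-group submatrix sums: O(sum |g|^2) per
  # permutation instead of O(M), which matters with many small groups.
  stat <- function(g) {
    sw <- 0; cw <- 0
    for (idx in split(seq_len(n), g)) {
      if (length(idx) > 1) {
        sw <- sw + sum(rk[idx, idx]) / 2
        cw <- cw + length(idx) * (length(idx) - 1) / 2
      }
    }
    if (cw == 0 || cw == M) stop("grouping leaves no between- or within-group pairs")
    ((S - sw) / (M - cw) - sw / cw) / denom
  }
  R_obs <- stat(groups)
  perm_R <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(groups)), numeric(1))
  })
  list(R = R_obs,
       p_value = (sum(perm_R >= R_obs) + 1) / (n_perm + 1),
       n_groups = length(unique(groups)),
       n_permutations = n_perm,
       perm_R = perm_R)
}

#' Serialise a dissimilarity matrix as square TSV
#' @param d symmetric matrix with sample ids as dimnames.
#' @param path file path.
#' @export
write_dissimilarity <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), as.data.frame(d, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
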