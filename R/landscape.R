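#' Resampled-median centroid of a community class
#'
#' Each member of the class is resampled once as a multinomial draw of
#' `depth` reads from its relative abundances; the centroid is the per-ASV
#' median of the resampled counts across members, renormalised to a
#' composition. The resampling step makes members commensurate regardless of
#' their original sequencing depth. With `n_resamples > 1` the median counts
#' are averaged over resampling rounds.
#'
#' @param t a [rel_abund()] table.
#' @param members sample ids forming the class (non-empty, all present in `t`).
#' @param depth reads drawn per member (default 10000).
#' @param seed integer seed.
#' @param n_resamples resampling rounds to average (default 1).
#' @return list with `abund` (named composition over the table's ASVs,
#'   summing to 1), `members`, `depth`, `seed`.
#' @export
class_centroid <- function(t, members, depth = 10000, seed = 1, n_resamples = 1) {
  t <- unclass(t)
  if (length(members) == 0) stop("empty class")
  if (!all(members %in% rownames(t)))
    stop("unknown members: ", paste(setdiff(members, rownames(t)), collapse = ", "))
  m <- t[members, , drop = FALSE]
  med <- with_seed(seed, {
    rounds <- vapply(seq_len(n_resamples), function(r) {
      res <- apply(m, 1, function(p) stats::rmultinom(1, depth, p))  # ASVs x members
      apply(res, 1, stats::median)
    }, numeric(ncol(m)))
    rowMeans(rounds)
  })
  if (sum(med) == 0)
    stop("degenerate centroid: no ASV has a positive median resampled count")
  list(abund = stats::setNames(med / sum(med), colnames(t)),
       members = members, depth = depth, seed = seed)
}

#' Distances from starting communities to final classes and their borders
#'
#' For each starting community and each final class this computes the
#' Jensen-Shannon distance to the class centroid and the border distance,
#' defined as the distance to the closest member community of that class.
#' When a query sample also belongs to the reference class it is excluded
#' from its own border search, otherwise every member would trivially sit at
#' distance zero from itself.
#'
#' @param start a [rel_abund()] table of query communities.
#' @param final a [rel_abund()] table of reference (final) communities.
#' @param final_labels class label per row of `final` (named by sample id or
#'   in row order).
#' @param centroids named list of [class_centroid()] results, one per class.
#' @param base,as_distance passed to the Jensen-Shannon computation
#'   (defaults: base 2, square-root distance).
#' @return data.frame with one row per (query, class): `sample_id`, `class`,
#'   `dist_to_centroid`, `dist_to_border`.
#' @export
distances_to_classes <- function(start, final, final_labels, centroids,
                                 base = 2, as_distance = TRUE) {
  start <- unclass(start); final <- unclass(final)
  if (!identical(colnames(start), colnames(final)))
    stop("start and final tables must share ASV columns")
  if (is.null(names(final_labels))) names(final_labels) <- rownames(final)
  cls <- sort(unique(as.character(final_labels)))
  if (!all(cls %in% names(centroids)))
    stop("missing centroid for class(es): ",
         paste(setdiff(cls, names(centroids)), collapse = ", "))
  cent <- do.call(rbind, lapply(centroids[cls], function(x) x$abund))
  refs <- rbind(final, cent)                 # ids may collide with queries, so
  comb <- rbind(start, refs)                 # everything is indexed by position
  d <- .jsd_matrix_cpp(comb / rowSums(comb), base)
  if (as_distance) d <- sqrt(d)
  ns <- nrow(start)
  cross <- d[seq_len(ns), ns + seq_len(nrow(refs)), drop = FALSE]
  out <- lapply(seq_len(ns), function(si) {
    sid <- rownames(start)[si]
    do.call(rbind, lapply(seq_along(cls), function(ci) {
      cl <- cls[ci]
      members <- which(final_labels == cl & names(final_labels) != sid)  # self-exclusion
      if (length(members) == 0) stop("class ", cl, " has no non-self members")
      data.frame(sample_id = sid, class = cl,
                 dist_to_centroid = cross[si, nrow(final) + ci],
                 dist_to_border = min(cross[si, members]))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean Jensen-Shannon distance between classes of two labelled tables
#'
#' Entry (i, j) is the mean pairwise distance between members of class i in
#' `a` and class j in `b`. When both tables contain the same sample under the
#' same id, the self-pair is excluded from the mean.
#'
#' @param a,b [rel_abund()] tables sharing ASV columns.
#' @param labels_a,labels_b class labels per row of `a` and `b`.
#' @param base,as_distance Jensen-Shannon options.
#' @return matrix, classes of `a` x classes of `b`.
#' @export
class_mean_distance <- function(a, labels_a, b, labels_b,
                                base = 2, as_distance = TRUE) {
  a <- unclass(a); b <- unclass(b)
  if (!identical(colnames(a), colnames(b))) stop("tables must share ASV columns")
  la <- as.character(labels_a); lb <- as.character(labels_b)
  if (any(table(la) == 0) || any(table(lb) == 0)) stop("empty class")
  comb <- rbind(a, b)
  rn <- make.unique(c(paste0("a.", rownames(a)), paste0("b.", rownames(b))))
  rownames(comb) <- rn
  d <- jsd_matrix(rel_abund(comb), base = base, as_distance = as_distance)
  cross <- d[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b)), drop = FALSE]
  self_pair <- outer(rownames(a), rownames(b), `==`)
  ca <- sort(unique(la)); cb <- sort(unique(lb))
  out <- matrix(NA_real_, length(ca), length(cb), dimnames = list(ca, cb))
  for (i in ca) for (j in cb) {
    block <- cross[la == i, lb == j, drop = FALSE]
    keep <- !self_pair[la == i, lb == j, drop = FALSE]
    if (!any(keep)) stop("classes ", i, " and ", j, " share all samples")
    out[i, j] <- mean(block[keep])
  }
  out
}
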