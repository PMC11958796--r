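#' Partition around medoids on a dissimilarity matrix
#'
#' k-medoids: a greedy BUILD phase seeds the medoids by repeatedly adding the
#' point that most reduces the total dissimilarity to the nearest medoid,
#' then a SWAP phase exchanges (medoid, non-medoid) pairs while any exchange
#' lowers the total cost. The default is fully deterministic (ties broken
#' towards the lowest index). SWAP is a local search; `restarts` additional
#' descents from random medoid seeds (controlled by `seed`) can escape local
#' optima on hard instances — the best solution found is returned.
#'
#' @param d symmetric dissimilarity matrix with sample ids as dimnames.
#' @param k number of classes, `2 <= k < n`.
#' @param restarts extra SWAP descents from random seeds (default 0).
#' @param seed integer seed, used only when `restarts > 0`.
#' @return list with `medoid_ids`, `medoid_idx`, `labels` (integer class per
#'   sample, classes numbered by medoid order), `cost` (total dissimilarity of
#'   samples to their medoid) and `build_cost`.
#' @export
pam_cluster <- function(d, k, restarts = 0, seed = 1) {
  n <- nrow(d)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n (n = ", n, ")")

  nearest_two <- function(med) {
    sub <- d[, med, drop = FALSE]
    ord1 <- max.col(-sub, ties.method = "first")
    dn <- sub[cbind(seq_len(n), ord1)]
    sub[cbind(seq_len(n), ord1)] <- Inf
    ds <- sub[cbind(seq_len(n), max.col(-sub, ties.method = "first"))]
    list(nearest = ord1, dnear = dn, dsecond = ds)
  }

  # SWAP: FASTPAM-style delta evaluation; for candidate h the cost change of
  # swapping out medoid m is a shared term plus a correction for the points
  # currently served by m. Steepest descent to a local optimum.
  swap_descent <- function(med) {
    repeat {
      nt <- nearest_two(med)
      best <- list(delta = -1e-12, m = 0L, h = 0L)
      cand <- setdiff(seq_len(n), med)
      for (h in cand) {
        dh <- d[, h]
        a <- pmin(nt$dnear, dh) - nt$dnear      # if removed medoid is not the nearest
        b <- pmin(nt$dsecond, dh) - nt$dnear    # if it is
        # every medoid serves itself, so groups 1..k all appear in `nearest`
        dm <- sum(a) + as.vector(rowsum(b - a, nt$nearest))
        m_best <- which.min(dm)
        if (dm[m_best] < best$delta) best <- list(delta = dm[m_best], m = m_best, h = h)
      }
      if (best$m == 0L) break
      med[best$m] <- best$h
    }
    med
  }
  cost_of <- function(med) sum(nearest_two(med)$dnear)

  # BUILD: first medoid minimises total dissimilarity; then greedy additions.
  med <- which.min(colSums(d))
  dnear <- d[, med]
  while (length(med) < k) {
    gain <- colSums(pmax(dnear - d, 0))
    gain[med] <- -Inf
    h <- which.max(gain)            # which.max takes the first (lowest index) tie
    med <- c(med, h)
    dnear <- pmin(dnear, d[, h])
  }
  build_cost <- sum(dnear)

  med <- swap_descent(med)
  if (restarts > 0) {
    starts <- with_seed(seed, lapply(seq_len(restarts), function(i)
      sample.int(n, k)))
    for (s in starts) {
      m2 <- swap_descent(s)
      if (cost_of(m2) < cost_of(med) - 1e-12) med <- m2
    }
  }
  med <- med[order(med)]
  nt <- nearest_two(med)
  list(medoid_ids = rownames(d)[med],
       medoid_idx = med,
       labels = nt$nearest,
       cost = sum(nt$dnear),
       build_cost = build_cost)
}

#' Calinski-Harabasz index of a labelled embedding
#'
#' `CH = [B / (k-1)] / [W / (n-k)]` where B and W are the between- and
#' within-class sums of squared Euclidean deviations from the class and
#' global centroids. For dissimilarity-based classes the embedding is the
#' principal-coordinates space of the dissimilarity matrix.
#'
#' @param coords numeric matrix, samples x axes (e.g. `pcoa(d)$coordinates`).
#' @param labels class label per sample; at least two non-empty classes and
#'   `n > k` required.
#' @return the CH value (a single positive number).
#' @export
ch_index <- function(coords, labels) {
  labels <- as.character(labels)
  n <- nrow(coords)
  cls <- unique(labels)
  k <- length(cls)
  if (k < 2) stop("CH needs at least two classes")
  if (any(table(labels) == 0) || n <= k) stop("classes must be non-empty with n > k")
  centre <- colMeans(coords)
  B <- 0; W <- 0
  for (c in cls) {
    rows <- coords[labels == c, , drop = FALSE]
    mu <- colMeans(rows)
    B <- B + nrow(rows) * sum((mu - centre)^2)
    W <- W + sum(sweep(rows, 2, mu)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Scan cluster numbers and pick the Calinski-Harabasz optimum
#'
#' Runs [pam_cluster()] for each `k` in `k_min:k_max`, scores each partition
#' with [ch_index()] in the principal-coordinates embedding of `d`, and
#' returns the assignment at the global CH maximum. All scanned partitions
#' and all local CH maxima are retained, because compositional data sets can
#' present several defensible class numbers; `pin_k` overrides the automatic
#' choice.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k_min,k_max scan bounds; `k_max` defaults to `min(25, n - 1)`.
#' @param pin_k optional fixed class number; must lie within the scanned range.
#' @param restarts,seed passed to [pam_cluster()].
#' @return object of class `"class_assignment"`: list with `sample_ids`,
#'   `labels`, `k`, `medoid_ids`, `ch_by_k` (named numeric), `local_maxima`,
#'   `k_opt` (global CH argmax) and `assignments` (per-k pam results).
#' @export
scan_k <- function(d, k_min = 2, k_max = NULL, pin_k = NULL,
                   restarts = 0, seed = 1) {
  n <- nrow(d)
  if (is.null(k_max)) k_max <- min(25, n - 1)
  if (k_max >= n) stop("k_max must be < n")
  ks <- k_min:k_max
  emb <- pcoa(d)$coordinates
  fits <- lapply(ks, function(k) pam_cluster(d, k, restarts = restarts,
                                             seed = seed))
  ch <- vapply(fits, function(f) ch_index(emb, f$labels), numeric(1))
  names(ch) <- ks
  local_max <- ks[which(diff(sign(diff(c(-Inf, ch, -Inf)))) == -2)]
  k_opt <- ks[which.max(ch)]
  k_use <- if (is.null(pin_k)) k_opt else {
    if (!pin_k %in% ks) stop("pin_k outside scanned range")
    pin_k
  }
  f <- fits[[match(k_use, ks)]]
  structure(list(sample_ids = rownames(d),
                 labels = f$labels,
                 k = k_use,
                 medoid_ids = f$medoid_ids,
                 ch_by_k = ch,
                 local_maxima = local_max,
                 k_opt = k_opt,
                 assignments = stats::setNames(fits, ks)),
            class = "class_assignment")
}

#' Serialise a class assignment to TSV (plus a companion k-vs-CH table)
#' @param a a `"class_assignment"` object from [scan_k()].
#' @param path output TSV of sample_id, class; the CH curve is written next to
#'   it with suffix `.ch.tsv`.
#' @export
write_class_assignment <- function(a, path) {
  utils::write.table(data.frame(sample_id = a$sample_ids, class = a$labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(k = as.integer(names(a$ch_by_k)), ch = a$ch_by_k),
                     paste0(path, ".ch.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
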