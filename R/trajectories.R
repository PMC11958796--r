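#' Classify community trajectories as convergent or divergent
#'
#' A trajectory is one starting (parent) community plus its final replicates.
#' It is convergent to class c ("C1", "C2", ...) when every replicate's final
#' class equals c, and divergent ("D") otherwise. Parents with fewer labelled
#' replicates than `n_replicates` are excluded with a warning.
#'
#' @param meta a [sample_metadata()] data.frame.
#' @param final_labels named vector (sample id -> final class) covering the
#'   final samples, e.g. harmonised [scan_k()] labels.
#' @param n_replicates replicates required per trajectory (default 4).
#' @return data.frame of class `"trajectory_set"`: one row per parent with
#'   columns `parent_id`, `type`, and `class_rep1..class_repK`.
#' @export
classify_trajectories <- function(meta, final_labels, n_replicates = 4) {
  fin <- meta[meta$time_point == "final", ]
  fin$class <- unname(final_labels[fin$sample_id])
  parents <- unique(fin$parent_id)
  rows <- lapply(parents, function(p) {
    rep_cls <- fin$class[fin$parent_id == p][order(fin$replicate[fin$parent_id == p])]
    if (length(rep_cls) < n_replicates || anyNA(rep_cls)) return(NULL)
    type <- if (length(unique(rep_cls)) == 1) paste0("C", rep_cls[1]) else "D"
    out <- data.frame(parent_id = p, type = type)
    out[paste0("class_rep", seq_len(n_replicates))] <- as.list(rep_cls[seq_len(n_replicates)])
    out
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " parent(s) excluded: missing or unlabelled replicates")
  out <- do.call(rbind, rows)
  class(out) <- c("trajectory_set", class(data.frame()))
  out
}

# Map each sample of a count table to its trajectory type.
# Start samples inherit the type of their own trajectory; final samples
# inherit their parent's, so all five communities of a trajectory share one
# type.
sample_trajectory_types <- function(sample_ids, meta, traj) {
  parent_of <- stats::setNames(meta$parent_id, meta$sample_id)
  type_of <- stats::setNames(traj$type, traj$parent_id)
  unname(type_of[parent_of[sample_ids]])
}

#' Per-ASV propensity towards trajectory types
#'
#' For each ASV i and trajectory type T, the propensity is
#' `log( P(ASV i present | community in T) / P(ASV i present) )`,
#' with presence meaning a count of at least `min_count` reads and
#' probabilities estimated as occurrence fractions over the communities of
#' one time point. A positive propensity means the ASV is observed more often
#' in communities of that trajectory type than overall. Types in which an ASV
#' is never observed give `-Inf`. ASVs absent from every community are
#' dropped.
#'
#' @param t a [count_table()] for a single time point.
#' @param types trajectory type per sample of `t` (no NAs; every community
#'   belongs to exactly one type).
#' @param min_count presence threshold in reads (default 1).
#' @param log_base base of the logarithm (default natural).
#' @param marginal_extra optional count matrix (same ASV columns) of further
#'   sequenced communities that carry no trajectory; they widen the marginal
#'   occurrence probability `P(present)` but never enter a type stratum.
#'   With the default `NULL` the marginal comes from `t` alone and the
#'   total-probability identity `sum_T P(T) exp(prop_T) = 1` holds exactly.
#' @return matrix ASVs x types of propensities, with attribute `"marginal"`
#'   (the per-ASV marginal presence probability).
#' @export
propensity <- function(t, types, min_count = 1, log_base = exp(1),
                       marginal_extra = NULL) {
  m <- unclass(t)
  types <- as.character(types)
  if (length(types) != nrow(m)) stop("one trajectory type per sample required")
  if (anyNA(types)) stop("NA trajectory types")
  tl <- sort(unique(types))
  counts_by_type <- table(factor(types, levels = tl))
  if (any(counts_by_type == 0)) stop("empty type stratum: ",
                                     paste(tl[counts_by_type == 0], collapse = ", "))
  pres <- m >= min_count
  marg_pool <- if (is.null(marginal_extra)) pres else
    rbind(pres, unclass(marginal_extra)[, colnames(m), drop = FALSE] >= min_count)
  marg <- colMeans(marg_pool)
  keep <- marg > 0
  pres <- pres[, keep, drop = FALSE]
  marg <- marg[keep]
  out <- vapply(tl, function(T) {
    log(colMeans(pres[types == T, , drop = FALSE]) / marg, base = log_base)
  }, numeric(sum(keep)))
  if (!is.matrix(out))    # single retained ASV: vapply collapses to a vector
    out <- matrix(out, nrow = 1, dimnames = list(names(marg), tl))
  attr(out, "marginal") <- marg
  out
}

#' Bootstrap confidence intervals for ASV propensities
#'
#' Communities (rows) are resampled with replacement, their trajectory labels
#' travelling with them; propensities are recomputed on each bootstrap table
#' and 95% percentile intervals are formed. Bootstrap draws in which a type
#' stratum vanishes are redrawn (and counted). An ASV is significantly
#' positively associated with a type when the lower CI bound is positive.
#'
#' @param t a [count_table()] for a single time point.
#' @param types trajectory type per sample.
#' @param n_boot bootstrap tables (default 1000).
#' @param seed integer seed.
#' @param min_count,log_base,marginal_extra as in [propensity()]; when
#'   `marginal_extra` is given, its communities are bootstrapped
#'   independently of the typed communities on every draw.
#' @return data.frame of class `"propensity_table"`: `asv_id`, `type`,
#'   `propensity`, `ci_low`, `ci_high`, `significant_positive`; attribute
#'   `"n_redrawn"` counts redrawn bootstrap tables.
#' @export
bootstrap_propensities <- function(t, types, n_boot = 1000, seed = 1,
                                   min_count = 1, log_base = exp(1),
                                   marginal_extra = NULL) {
  m <- unclass(t)
  types <- as.character(types)
  point <- propensity(t, types, min_count = min_count, log_base = log_base,
                      marginal_extra = marginal_extra)
  tl <- colnames(point)
  pres <- (m >= min_count)[, rownames(point), drop = FALSE]
  pres_extra <- if (!is.null(marginal_extra))
    unclass(marginal_extra)[, rownames(point), drop = FALSE] >= min_count
  n <- nrow(m)
  ne <- if (is.null(pres_extra)) 0L else nrow(pres_extra)
  n_redrawn <- 0L
  boots <- with_seed(seed, {
    res <- array(NA_real_, c(nrow(point), length(tl), n_boot))
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        ty <- types[idx]
        if (all(tl %in% ty)) break
        n_redrawn <- n_redrawn + 1L
      }
      pb <- pres[idx, , drop = FALSE]
      marg <- if (ne > 0) {
        eb <- pres_extra[sample.int(ne, ne, replace = TRUE), , drop = FALSE]
        (colSums(pb) + colSums(eb)) / (n + ne)
      } else colMeans(pb)
      for (ti in seq_along(tl)) {
        res[, ti, b] <- log(colMeans(pb[ty == tl[ti], , drop = FALSE]) / marg,
                            base = log_base)
      }
    }
    res
  })
  rows <- lapply(seq_along(tl), function(ti) {
    ci <- apply(boots[, ti, , drop = FALSE], 1, function(v) {
      v <- v[!is.na(v)]                      # NaN when marginal hits 0 in a draw
      stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    })
    data.frame(asv_id = rownames(point), type = tl[ti],
               propensity = point[, ti],
               ci_low = ci[1, ], ci_high = ci[2, ],
               significant_positive = is.finite(ci[1, ]) & ci[1, ] > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_redrawn") <- n_redrawn
  class(out) <- c("propensity_table", class(data.frame()))
  out
}

#' Assign ASVs to propensity groups from start and final propensity tables
#'
#' The signature of an ASV records in which (type, time point) cells its
#' propensity is significantly positive. Named groups: `cosmopolitan` (all
#' three types at both time points), and `SF1`/`SF2` (the class-1 or class-2
#' convergent type at both time points, and not cosmopolitan — cosmopolitan
#' takes priority so the groups are disjoint). Everything else keeps its raw
#' signature (e.g. `start:C1` for a start-only association, `none` for no
#' significant cell).
#'
#' @param start_pt,final_pt `"propensity_table"`s from
#'   [bootstrap_propensities()] over the same ASVs.
#' @return data.frame `asv_id`, `group`, `signature`.
#' @export
assign_groups <- function(start_pt, final_pt) {
  asvs <- sort(unique(c(start_pt$asv_id, final_pt$asv_id)))
  cell <- function(pt, tag) {
    stats::setNames(pt$significant_positive, paste0(pt$asv_id, "|", tag, ":", pt$type))
  }
  hits <- c(cell(start_pt, "start"), cell(final_pt, "final"))
  types <- sort(unique(c(start_pt$type, final_pt$type)))
  rows <- lapply(asvs, function(a) {
    cells <- paste0(a, "|", c(paste0("start:", types), paste0("final:", types)))
    on <- hits[cells]; on[is.na(on)] <- FALSE
    names(on) <- sub("^[^|]*\\|", "", cells)
    sig <- paste(names(on)[on], collapse = "+")
    if (sig == "") sig <- "none"
    both <- function(T) on[paste0("start:", T)] && on[paste0("final:", T)]
    cosmo <- all(vapply(c("C1", "C2", "D"), both, logical(1)))
    # SF groups must point at one attractor: an ASV associated with both
    # convergent types at both time points is near-cosmopolitan, not a core
    group <- if (cosmo) "cosmopolitan"
    else if (both("C1") && !both("C2")) "SF1"
    else if (both("C2") && !both("C1")) "SF2"
    else sig
    data.frame(asv_id = a, group = group, signature = sig)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summed relative abundance of an ASV group per sample
#'
#' @param t a [rel_abund()] table.
#' @param group ASV ids; members missing from the table contribute 0.
#' @return named numeric vector, one value per sample, in `[0, 1]`.
#' @export
group_abundance <- function(t, group) {
  m <- unclass(t)
  present <- intersect(group, colnames(m))
  if (length(present) == 0) return(stats::setNames(rep(0, nrow(m)), rownames(m)))
  rowSums(m[, present, drop = FALSE])
}

#' Tipping-point classification of trajectories from group abundances
#'
#' Predicts the convergence type of a community from the summed relative
#' abundances of the two antagonistic core groups: convergent-to-class-1
#' (`"C1"`) when the SF1 sum exceeds its threshold while the cosmopolitan sum
#' does not exceed its own; convergent-to-class-2 (`"C2"`) in the mirrored
#' case; `"D"` (unpredictable) when both sums exceed or both fall below their
#' thresholds — unbalanced starting conditions between the two groups are
#' what makes a trajectory predictable.
#'
#' @param sf1_sum,cosmo_sum numeric vectors in `[0, 1]` (recycled pairwise).
#' @param sf1_threshold tipping point on the SF1 sum (default 0.125).
#' @param cosmo_threshold tipping point on the cosmopolitan sum (default 0.2).
#' @return character vector of predicted types (`"C1"`, `"C2"`, `"D"`).
#' @export
threshold_classify <- function(sf1_sum, cosmo_sum,
                               sf1_threshold = 0.125, cosmo_threshold = 0.2) {
  if (any(sf1_sum < 0 | sf1_sum > 1, na.rm = TRUE) ||
      any(cosmo_sum < 0 | cosmo_sum > 1, na.rm = TRUE))
    stop("group sums must lie in [0, 1]")
  hi1 <- sf1_sum > sf1_threshold
  hi2 <- cosmo_sum > cosmo_threshold
  ifelse(hi1 & !hi2, "C1", ifelse(!hi1 & hi2, "C2", "D"))
}
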