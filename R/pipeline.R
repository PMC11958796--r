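#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end analysis. Randomised
#' defaults follow the study design the pipeline reproduces: 1000 ANOSIM
#' permutations, 50 RMSD randomisations, 1000 bootstrap tables.
#'
#' @param min_asv_reads ASV filter threshold (default 100 reads summed
#'   across samples).
#' @param min_sample_reads sample filter threshold (default 10000 reads).
#' @param jsd_base,sqrt_distance Jensen-Shannon options (base 2, square-root
#'   distance).
#' @param k_max_start,k_max_final upper bounds of the class-number scans.
#' @param pin_k_start,pin_k_final optional pinned class numbers.
#' @param fit_replicate final replicate used to fit the superposition
#'   (default 1); the remaining replicates are held out.
#' @param n_perm ANOSIM permutations. @param n_rand RMSD randomisations.
#' @param n_boot bootstrap tables per time point.
#' @param sf1_threshold,cosmo_threshold tipping thresholds (0.125, 0.2).
#' @param centroid_depth resampling depth for class centroids (10000).
#' @param seed global seed; per-stage child seeds are derived from it.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(min_asv_reads = 100,
                            min_sample_reads = 10000,
                            jsd_base = 2,
                            sqrt_distance = TRUE,
                            k_max_start = 10,
                            k_max_final = 8,
                            pin_k_start = NULL,
                            pin_k_final = NULL,
                            fit_replicate = 1,
                            n_perm = 1000,
                            n_rand = 50,
                            n_boot = 1000,
                            sf1_threshold = 0.125,
                            cosmo_threshold = 0.2,
                            centroid_depth = 10000,
                            seed = 1) {
  stopifnot(n_perm >= 1, n_rand >= 1, n_boot >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# Harmonise class labels of `other` (a scan_k assignment) to those of `ref`
# by greedily pairing classes with minimal Jensen-Shannon distance between
# their medoid profiles. Returns the relabelled integer labels of `other`.
match_class_labels <- function(ref, other, ref_rel, other_rel, base = 2) {
  med_profile <- function(a, rel) unclass(rel)[a$medoid_ids, , drop = FALSE]
  A <- med_profile(ref, ref_rel); B <- med_profile(other, other_rel)
  k <- nrow(A)
  d <- outer(seq_len(k), seq_len(nrow(B)),
             Vectorize(function(i, j) jsd_pair(A[i, ], B[j, ], base = base)))
  map <- integer(nrow(B))
  free_r <- seq_len(k); free_o <- seq_len(nrow(B))
  while (length(free_o) > 0 && length(free_r) > 0) {
    sub <- d[free_r, free_o, drop = FALSE]
    ij <- arrayInd(which.min(sub), dim(sub))
    map[free_o[ij[2]]] <- free_r[ij[1]]
    free_r <- free_r[-ij[1]]; free_o <- free_o[-ij[2]]
  }
  if (length(free_o) > 0) map[free_o] <- k + seq_along(free_o)
  map[other$labels]
}

#' Run the full compositional-landscape analysis
#'
#' Executes, in order: quality filters, relative-abundance conversion,
#' community typing of the starting communities and of each final replicate
#' (labels harmonised across replicates by medoid matching), ANOSIM tests,
#' rigid-body superposition of starts onto one final replicate with a
#' shuffled null and held-out SVD-component comparison, attractor geometry
#' (class centroids, border and centroid distances, class-to-class mean
#' distances), trajectory typing, bootstrap propensities at both time
#' points, propensity-group assignment, group abundance sums and
#' tipping-point classification.
#'
#' @param start [count_table()] of starting (parent) communities; rownames
#'   are the parent ids referenced by `meta`.
#' @param final [count_table()] of final communities (all replicates).
#' @param meta [sample_metadata()] covering all samples.
#' @param extra_start optional [count_table()] of additional starting
#'   communities without trajectories; they join the occurrence marginal of
#'   the propensity stage (and nothing else).
#' @param config a [pipeline_config()].
#' @return list of class `"landscape_run"` with elements `typing`, `anosim`,
#'   `superposition`, `landscape`, `trajectories`, `summary` (plain named
#'   values suitable for serialisation) and `config`.
#' @export
run_all <- function(start, final, meta, extra_start = NULL,
                    config = pipeline_config()) {
  cf <- config
  seeds <- with_seed(cf$seed, sample.int(.Machine$integer.max - 1, 12))

  ## --- filters: ASV filter jointly across all samples, then sample filter
  all_counts <- rbind(unclass(start), unclass(final),
                      if (!is.null(extra_start)) unclass(extra_start))
  keep_asv <- colSums(all_counts) >= cf$min_asv_reads
  apply_filters <- function(t) {
    t <- unclass(t)[, keep_asv, drop = FALSE]
    count_table(t[rowSums(t) >= cf$min_sample_reads, , drop = FALSE])
  }
  start <- apply_filters(start); final <- apply_filters(final)
  if (!is.null(extra_start)) extra_start <- apply_filters(extra_start)

  start_rel <- to_relative(start)
  final_rel <- to_relative(final)

  fin_meta <- meta[meta$time_point == "final" &
                     meta$sample_id %in% rownames(final), ]
  reps <- sort(unique(fin_meta$replicate))
  rep_ids <- lapply(reps, function(r) fin_meta$sample_id[fin_meta$replicate == r])
  names(rep_ids) <- paste0("R", reps)

  ## --- community typing
  d_start <- jsd_matrix(start_rel, base = cf$jsd_base,
                        as_distance = cf$sqrt_distance)
  typing_start <- scan_k(d_start, k_max = min(cf$k_max_start, nrow(d_start) - 1),
                         pin_k = cf$pin_k_start)
  rep_rel <- lapply(rep_ids, function(ids)
    rel_abund(unclass(final_rel)[ids, , drop = FALSE]))
  typing_final <- lapply(rep_rel, function(rel) {
    d <- jsd_matrix(rel, base = cf$jsd_base, as_distance = cf$sqrt_distance)
    scan_k(d, k_max = min(cf$k_max_final, nrow(d) - 1), pin_k = cf$pin_k_final)
  })
  # harmonise labels of replicates 2..n to replicate 1
  for (j in seq_along(typing_final)[-1]) {
    typing_final[[j]]$labels <- match_class_labels(
      typing_final[[1]], typing_final[[j]], rep_rel[[1]], rep_rel[[j]],
      base = cf$jsd_base)
  }
  # canonical numbering: class 1 is the most populated final class (the
  # dominant attractor), so the tipping thresholds refer to a fixed side
  all_lab <- unlist(lapply(typing_final, `[[`, "labels"))
  sz <- table(factor(all_lab, levels = sort(unique(all_lab))))
  rank_of <- stats::setNames(rank(-as.vector(sz), ties.method = "first"),
                             names(sz))
  for (j in seq_along(typing_final)) {
    typing_final[[j]]$labels <-
      as.integer(rank_of[as.character(typing_final[[j]]$labels)])
  }
  perm1 <- order(as.integer(rank_of[as.character(seq_along(typing_final[[1]]$medoid_ids))]))
  typing_final[[1]]$medoid_ids <- typing_final[[1]]$medoid_ids[perm1]
  final_labels <- unlist(lapply(typing_final, function(a)
    stats::setNames(a$labels, a$sample_ids)), use.names = TRUE)
  names(final_labels) <- unlist(lapply(typing_final, `[[`, "sample_ids"))

  ## --- ANOSIM
  d_final_all <- jsd_matrix(final_rel, base = cf$jsd_base,
                            as_distance = cf$sqrt_distance)
  parent_of <- stats::setNames(fin_meta$parent_id, fin_meta$sample_id)
  an_parent <- anosim_test(d_final_all, parent_of[rownames(final_rel)],
                           n_perm = cf$n_perm, seed = seeds[1])
  an_start <- anosim_test(d_start, typing_start$labels,
                          n_perm = cf$n_perm, seed = seeds[2])
  d_rep1 <- jsd_matrix(rep_rel[[1]], base = cf$jsd_base,
                       as_distance = cf$sqrt_distance)
  an_final <- anosim_test(d_rep1, typing_final[[1]]$labels,
                          n_perm = cf$n_perm, seed = seeds[3])

  ## --- superposition: starts vs the chosen replicate, holdouts = the rest
  fit_name <- paste0("R", cf$fit_replicate)
  pair_parents <- intersect(rownames(start_rel),
                            sub("\\.R[0-9]+$", "", rep_ids[[fit_name]]))
  x <- unclass(start_rel)[pair_parents, , drop = FALSE]
  rep_of_parent <- function(nm) {
    ids <- rep_ids[[nm]]
    ids[match(pair_parents, sub("\\.R[0-9]+$", "", ids))]
  }
  y <- unclass(final_rel)[rep_of_parent(fit_name), , drop = FALSE]
  rownames(y) <- pair_parents
  fit <- kabsch_fit(x, y)
  null_ci <- randomised_rmsd_ci(x, y, n_rand = cf$n_rand, seed = seeds[4])
  holdouts <- lapply(setdiff(names(rep_ids), fit_name), function(nm) {
    h <- unclass(final_rel)[rep_of_parent(nm), , drop = FALSE]
    rownames(h) <- pair_parents
    h
  })
  names(holdouts) <- setdiff(names(rep_ids), fit_name)
  comparison <- predict_and_compare(x, fit, holdouts)

  ## --- landscape on the fitted replicate
  lab_rep1 <- stats::setNames(typing_final[[fit_name]]$labels,
                              typing_final[[fit_name]]$sample_ids)
  cls <- sort(unique(lab_rep1))
  centroids <- lapply(seq_along(cls), function(ci)
    class_centroid(rep_rel[[fit_name]],
                   names(lab_rep1)[lab_rep1 == cls[ci]],
                   depth = cf$centroid_depth,
                   seed = seeds[5] %% 100000000L + ci))
  names(centroids) <- cls
  positions <- distances_to_classes(start_rel, rep_rel[[fit_name]], lab_rep1,
                                    centroids, base = cf$jsd_base,
                                    as_distance = cf$sqrt_distance)
  cls_dist <- class_mean_distance(start_rel, typing_start$labels,
                                  rep_rel[[fit_name]], lab_rep1,
                                  base = cf$jsd_base,
                                  as_distance = cf$sqrt_distance)

  ## --- trajectories and propensities
  traj <- classify_trajectories(meta, final_labels,
                                n_replicates = length(reps))
  start_types <- sample_trajectory_types(rownames(start), meta, traj)
  names(start_types) <- rownames(start)
  final_types <- sample_trajectory_types(rownames(final), meta, traj)
  names(final_types) <- rownames(final)
  # occurrence marginals draw on every sequenced community
  marg_extra_start <- rbind(if (!is.null(extra_start)) unclass(extra_start),
                            unclass(final))
  marg_extra_final <- rbind(unclass(start),
                            if (!is.null(extra_start)) unclass(extra_start))
  start_typed <- !is.na(start_types)
  final_typed <- !is.na(final_types)
  pt_start <- bootstrap_propensities(
    count_table(unclass(start)[start_typed, , drop = FALSE]),
    start_types[start_typed], n_boot = cf$n_boot, seed = seeds[6],
    marginal_extra = rbind(marg_extra_start,
                           unclass(start)[!start_typed, , drop = FALSE]))
  pt_final <- bootstrap_propensities(
    count_table(unclass(final)[final_typed, , drop = FALSE]),
    final_types[final_typed], n_boot = cf$n_boot, seed = seeds[7],
    marginal_extra = rbind(marg_extra_final,
                           unclass(final)[!final_typed, , drop = FALSE]))
  groups <- assign_groups(pt_start, pt_final)
  sf1_set <- groups$asv_id[groups$group == "SF1"]
  cosmo_set <- groups$asv_id[groups$group == "cosmopolitan"]

  sf1_start <- group_abundance(start_rel, sf1_set)
  cosmo_start <- group_abundance(start_rel, cosmo_set)
  sf1_final <- group_abundance(final_rel, sf1_set)
  cosmo_final <- group_abundance(final_rel, cosmo_set)
  avg_by_parent <- function(v) {
    tapply(v[names(final_types)], parent_of[names(final_types)], mean)
  }
  sf1_final_avg <- avg_by_parent(sf1_final)
  cosmo_final_avg <- avg_by_parent(cosmo_final)

  predicted <- threshold_classify(sf1_start[traj$parent_id],
                                  cosmo_start[traj$parent_id],
                                  cf$sf1_threshold, cf$cosmo_threshold)
  names(predicted) <- traj$parent_id
  confusion <- table(predicted = predicted, observed = traj$type)

  summary <- list(
    n_start = nrow(start), n_final = nrow(final), n_asvs = ncol(start),
    seed = cf$seed,
    anosim_r_parent = an_parent$R, anosim_p_parent = an_parent$p_value,
    anosim_r_start_classes = an_start$R, anosim_p_start_classes = an_start$p_value,
    anosim_r_final_classes = an_final$R, anosim_p_final_classes = an_final$p_value,
    k_opt_start = typing_start$k_opt,
    ch_by_k_start = as.list(typing_start$ch_by_k),
    k_final = lapply(typing_final, `[[`, "k"),
    rmsd = fit$rmsd,
    null_rmsd_ci = c(null_ci$lower, null_ci$upper),
    component_r2 = stats::setNames(comparison$r_squared,
                                   paste0(comparison$replicate_id, ".c",
                                          comparison$component)),
    n_convergent_1 = sum(traj$type == "C1"),
    n_convergent_2 = sum(traj$type == "C2"),
    n_divergent = sum(traj$type == "D"),
    fraction_convergent = mean(traj$type != "D"),
    sf1_members = sf1_set,
    cosmopolitan_members = cosmo_set,
    confusion = as.list(stats::setNames(as.vector(confusion),
                                        outer(rownames(confusion),
                                              colnames(confusion),
                                              paste, sep = "->"))))

  structure(list(
    typing = list(start = typing_start, final = typing_final),
    anosim = list(parent = an_parent, start_classes = an_start,
                  final_classes = an_final),
    superposition = list(fit = fit, null_ci = null_ci,
                         comparison = comparison),
    landscape = list(centroids = centroids, positions = positions,
                     class_mean_distance = cls_dist),
    trajectories = list(set = traj, start_propensities = pt_start,
                        final_propensities = pt_final, groups = groups,
                        sf1_start = sf1_start, cosmo_start = cosmo_start,
                        sf1_final_avg = sf1_final_avg,
                        cosmo_final_avg = cosmo_final_avg,
                        predicted_type = predicted, confusion = confusion),
    summary = summary,
    config = cf), class = "landscape_run")
}

#' Serialise a pipeline summary deterministically
#'
#' @param run a [run_all()] result.
#' @param path optional file; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
write_run_summary <- function(run, path = NULL) {
  js <- jsonlite::toJSON(run$summary, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
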