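#' Configuration for the community-trajectory simulator
#'
#' Defaults mirror the experimental design the pipeline targets: 275 parent
#' communities in 5 compositional classes, four revived replicates each
#' (1100 final microcosms), ~15,000 reads per sample, two final classes, and
#' planted "SF1" and "cosmopolitan" ASV groups whose summed abundances carry
#' tipping-point information. Everything else is a modelling choice of this
#' package (see the methods vignette).
#'
#' @param n_parents starting communities assayed in microcosms (default 275).
#' @param n_extra_start additional starting communities that are sequenced
#'   but never revived (default 383, so the starting pool totals 658); they
#'   share the class structure but lack the planted groups, and enter only
#'   the marginal occurrence probabilities of the propensity stage.
#' @param n_replicates final replicates per parent (default 4).
#' @param n_asvs total ASVs (default 300).
#' @param reads_per_sample sequencing depth per sample (default 15000).
#' @param n_start_classes,n_final_classes compositional classes (5 and 2).
#' @param sf1_size,cosmo_size planted group sizes (default 25 each).
#' @param sf1_targets,cosmo_targets per-start-class summed relative abundance
#'   of each planted group; the defaults put classes 1, 2 and 4 on the
#'   class-1 side of the tipping point, class 3 on the class-2 side, and
#'   class 5 on the knife edge.
#' @param final_group_share baseline share of a planted group in a final
#'   class base (default 0.04).
#' @param sf1_boost,cosmo_boost multiplicative enrichment of SF1 in final
#'   class 1 and of the cosmopolitan block in final class 2 (default 12).
#' @param class_tilt_sd log-normal sd of the per-class tilt applied to the
#'   shared background composition (default 1.2); larger values separate the
#'   classes more.
#' @param background_floor fraction of background mass spread uniformly so
#'   background ASVs stay present in every class (default 0.3).
#' @param within_theta Dirichlet concentration of communities around their
#'   class base (default 2000; larger = tighter classes). May be a vector,
#'   one value per start class.
#' @param final_theta Dirichlet concentration of final samples around their
#'   target composition (default 2000).
#' @param parent_carryover weight of the parent profile mixed into each
#'   final sample's target composition (default 0.15).
#' @param transition_probs matrix (start classes x final classes) of baseline
#'   fate probabilities; rows must sum to 1. Default: uniform, so fates are
#'   driven entirely by the tipping term.
#' @param tipping_noise strength of the tipping perturbation: the parent's
#'   planted contrast (SF1 sum minus cosmopolitan sum, relative to
#'   `tipping_center`) is added to the logit of the class-1 fate probability
#'   with this gain. 0 disables tipping and fates follow `transition_probs`
#'   exactly.
#' @param tipping_center centre of the tipping contrast (default 0).
#' @param seed integer seed.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_parents = 275,
                       n_extra_start = 383,
                       n_replicates = 4,
                       n_asvs = 300,
                       reads_per_sample = 15000,
                       n_start_classes = 5,
                       n_final_classes = 2,
                       sf1_size = 25,
                       cosmo_size = 25,
                       sf1_targets = c(0.45, 0.30, 0.0008, 0.25, 0.11),
                       cosmo_targets = c(0.05, 0.08, 0.35, 0.10, 0.11),
                       final_group_share = 0.04,
                       sf1_boost = 12,
                       cosmo_boost = 12,
                       class_tilt_sd = 1.2,
                       background_floor = 0.3,
                       within_theta = 2000,
                       final_theta = 2000,
                       parent_carryover = 0.15,
                       transition_probs = NULL,
                       tipping_noise = 25,
                       tipping_center = 0,
                       seed = 1) {
  if (sf1_size + cosmo_size >= n_asvs)
    stop("planted group sizes must leave room for background ASVs")
  if (length(sf1_targets) != n_start_classes || length(cosmo_targets) != n_start_classes)
    stop("group targets need one value per start class")
  if (any(sf1_targets + cosmo_targets >= 1)) stop("group targets must sum below 1")
  if (is.null(transition_probs))
    transition_probs <- matrix(1 / n_final_classes, n_start_classes, n_final_classes)
  if (!all(dim(transition_probs) == c(n_start_classes, n_final_classes)))
    stop("transition_probs must be start classes x final classes")
  if (any(abs(rowSums(transition_probs) - 1) > 1e-9))
    stop("transition_probs rows must sum to 1")
  if (sf1_boost < 1 || cosmo_boost < 1) stop("boosts must be >= 1")
  structure(as.list(environment()), class = "sim_config")
}

rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate replicated community trajectories with planted ground truth
#'
#' The generative model is Dirichlet-multinomial throughout: class-level base
#' compositions, community-level Dirichlet draws around the base, and a
#' multinomial read count per sample. Start classes differ in a log-normal
#' tilt of a shared background composition and in the summed share of the
#' two planted groups; the probability that a replicate lands in final class
#' 1 is a logistic function of the parent's SF1-minus-cosmopolitan contrast
#' added to the baseline transition probability on the logit scale, so
#' tipping-point behaviour is planted and recoverable. Final compositions mix
#' the final-class base (group blocks boosted in their respective class)
#' with a carryover of the parent profile.
#'
#' @param config a [sim_config()].
#' @return list with `start` (parents, a [count_table()]), `final`
#'   ([count_table()], `n_parents * n_replicates` rows), `extra_start`
#'   ([count_table()] or NULL), `meta` ([sample_metadata()] covering all
#'   samples), and `truth` (list: `start_class` per parent, `extra_class`,
#'   `final_class` matrix parents x replicates, `type` per parent,
#'   `asv_groups` data.frame, `config`).
#' @export
simulate_communities <- function(config = sim_config()) {
  cf <- config
  with_seed(cf$seed, {
    p <- cf$n_asvs
    sf1_idx <- seq_len(cf$sf1_size)
    cosmo_idx <- cf$sf1_size + seq_len(cf$cosmo_size)
    bg_idx <- setdiff(seq_len(p), c(sf1_idx, cosmo_idx))
    asv_ids <- sprintf("ASV%03d", seq_len(p))

    # shared background with a uniform floor, tilted per class
    q_bg <- rdirichlet(rep(1, length(bg_idx)))
    q_bg <- (1 - cf$background_floor) * q_bg +
      cf$background_floor / length(bg_idx)
    tilt <- function() {
      w <- q_bg * exp(stats::rnorm(length(bg_idx), 0, cf$class_tilt_sd))
      (1 - cf$background_floor) * (w / sum(w)) +
        cf$background_floor / length(bg_idx)
    }
    block <- function(k) rdirichlet(rep(2, k))   # within-group composition

    start_base <- lapply(seq_len(cf$n_start_classes), function(k) {
      base <- numeric(p)
      base[sf1_idx] <- cf$sf1_targets[k] * block(cf$sf1_size)
      base[cosmo_idx] <- cf$cosmo_targets[k] * block(cf$cosmo_size)
      base[bg_idx] <- (1 - cf$sf1_targets[k] - cf$cosmo_targets[k]) * tilt()
      base
    })
    # final classes share one background tilt: they differ only in the
    # planted group blocks, so background ASVs carry no fate association
    final_bg <- tilt()
    final_base <- lapply(seq_len(cf$n_final_classes), function(f) {
      base <- numeric(p)
      s0 <- cf$final_group_share
      base[sf1_idx] <- (if (f == 1) s0 * cf$sf1_boost else 0) * block(cf$sf1_size)
      base[cosmo_idx] <- (if (f == 2) s0 * cf$cosmo_boost else s0) * block(cf$cosmo_size)
      base[bg_idx] <- (1 - sum(base)) * final_bg
      base
    })

    theta <- rep(cf$within_theta, length.out = cf$n_start_classes)
    draw_sample <- function(base, th) {
      prof <- rdirichlet(th * base)
      counts <- stats::rmultinom(1, cf$reads_per_sample, prof)[, 1]
      list(profile = prof, counts = counts)
    }

    start_class <- sample(rep_len(seq_len(cf$n_start_classes), cf$n_parents))
    parent_ids <- sprintf("P%03d", seq_len(cf$n_parents))
    start_counts <- matrix(0, cf$n_parents, p, dimnames = list(parent_ids, asv_ids))
    parent_profile <- matrix(0, cf$n_parents, p)
    for (i in seq_len(cf$n_parents)) {
      s <- draw_sample(start_base[[start_class[i]]], theta[start_class[i]])
      start_counts[i, ] <- s$counts
      parent_profile[i, ] <- s$profile
    }

    extra_counts <- NULL; extra_class <- NULL
    if (cf$n_extra_start > 0) {
      extra_ids <- sprintf("E%03d", seq_len(cf$n_extra_start))
      extra_class <- sample(rep_len(seq_len(cf$n_start_classes), cf$n_extra_start))
      extra_counts <- matrix(0, cf$n_extra_start, p,
                             dimnames = list(extra_ids, asv_ids))
      for (i in seq_len(cf$n_extra_start)) {
        base <- start_base[[extra_class[i]]]
        base[c(sf1_idx, cosmo_idx)] <- 0        # unassayed pool lacks the groups
        base <- base / sum(base)
        extra_counts[i, ] <- draw_sample(base, theta[extra_class[i]])$counts
      }
    }

    # fates: baseline transition row perturbed on the logit scale by the
    # parent's planted contrast (only meaningful with two final classes)
    z <- rowSums(parent_profile[, sf1_idx, drop = FALSE]) -
      rowSums(parent_profile[, cosmo_idx, drop = FALSE])
    final_class <- matrix(0L, cf$n_parents, cf$n_replicates)
    for (i in seq_len(cf$n_parents)) {
      probs <- cf$transition_probs[start_class[i], ]
      if (cf$tipping_noise > 0 && cf$n_final_classes == 2) {
        eps <- 1e-9
        p1 <- stats::plogis(stats::qlogis(min(max(probs[1], eps), 1 - eps)) +
                              cf$tipping_noise * (z[i] - cf$tipping_center))
        probs <- c(p1, 1 - p1)
      }
      final_class[i, ] <- sample.int(cf$n_final_classes, cf$n_replicates,
                                     replace = TRUE, prob = probs)
    }

    final_ids <- as.vector(t(outer(parent_ids, seq_len(cf$n_replicates),
                                   function(a, b) paste0(a, ".R", b))))
    final_counts <- matrix(0, cf$n_parents * cf$n_replicates, p,
                           dimnames = list(final_ids, asv_ids))
    row <- 0
    for (i in seq_len(cf$n_parents)) {
      for (r in seq_len(cf$n_replicates)) {
        row <- row + 1
        target <- (1 - cf$parent_carryover) * final_base[[final_class[i, r]]] +
          cf$parent_carryover * parent_profile[i, ]
        final_counts[row, ] <- draw_sample(target, cf$final_theta)$counts
      }
    }

    meta <- data.frame(
      sample_id = c(parent_ids,
                    if (!is.null(extra_counts)) rownames(extra_counts),
                    final_ids),
      time_point = c(rep("start", cf$n_parents + cf$n_extra_start),
                     rep("final", length(final_ids))),
      parent_id = c(parent_ids,
                    if (!is.null(extra_counts)) rownames(extra_counts),
                    rep(parent_ids, each = cf$n_replicates)),
      replicate = c(rep(NA_integer_, cf$n_parents + cf$n_extra_start),
                    rep(seq_len(cf$n_replicates), times = cf$n_parents)),
      stringsAsFactors = FALSE)

    type <- apply(final_class, 1, function(v)
      if (length(unique(v)) == 1) paste0("C", v[1]) else "D")
    asv_groups <- data.frame(
      asv_id = asv_ids,
      group = c(rep("SF1", cf$sf1_size), rep("cosmopolitan", cf$cosmo_size),
                rep("background", length(bg_idx))))

    list(start = count_table(start_counts),
         final = count_table(final_counts),
         extra_start = if (!is.null(extra_counts)) count_table(extra_counts),
         meta = sample_metadata(meta),
         truth = list(start_class = stats::setNames(start_class, parent_ids),
                      extra_class = if (!is.null(extra_class))
                        stats::setNames(extra_class, rownames(extra_counts)),
                      final_class = `dimnames<-`(final_class,
                                                 list(parent_ids, NULL)),
                      type = stats::setNames(type, parent_ids),
                      contrast = stats::setNames(z, parent_ids),
                      asv_groups = asv_groups,
                      config = cf))
  })
}

#' Adjusted Rand agreement between two labelings
#'
#' Label-permutation-invariant agreement; 1 for identical partitions, about 0
#' for random labels. Vectors are matched by names when both are named.
#'
#' @param a,b label vectors.
#' @return adjusted Rand index.
#' @export
ari_score <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0) stop("no shared ids between labelings")
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("labelings differ in length")
  mclust::adjustedRandIndex(a, b)
}

#' Precision and recall of an inferred ASV set against a planted set
#' @param inferred,planted character vectors of ASV ids.
#' @return list with `precision`, `recall`.
#' @export
set_precision_recall <- function(inferred, planted) {
  tp <- length(intersect(inferred, planted))
  list(precision = if (length(inferred)) tp / length(inferred) else NA_real_,
       recall = if (length(planted)) tp / length(planted) else NA_real_)
}

#' Score pipeline inferences against simulation ground truth
#'
#' @param inferred a [run_all()] result.
#' @param truth the `truth` element of [simulate_communities()].
#' @return list with `start_class_ari`, `final_class_ari` (replicate 1),
#'   `type_accuracy` (trajectory typing vs truth), `sf1_precision`,
#'   `sf1_recall`, `cosmo_precision`, `cosmo_recall`,
#'   `tipping_accuracy_convergent` (threshold prediction on truly convergent
#'   trajectories).
#' @export
truth_metrics <- function(inferred, truth) {
  st <- inferred$typing$start
  start_ari <- ari_score(stats::setNames(st$labels, st$sample_ids),
                         truth$start_class)
  f1 <- inferred$typing$final[[1]]
  parent_of_final <- sub("\\.R[0-9]+$", "", f1$sample_ids)
  true_f1 <- truth$final_class[parent_of_final, 1]
  final_ari <- ari_score(stats::setNames(f1$labels, f1$sample_ids),
                         stats::setNames(true_f1, f1$sample_ids))
  # inferred class numbers are arbitrary; map each to the planted class it
  # mostly overlaps, then translate trajectory types accordingly
  conf <- table(inferred = f1$labels, planted = true_f1)
  lab_map <- stats::setNames(colnames(conf)[apply(conf, 1, which.max)],
                             rownames(conf))
  remap_type <- function(v) {
    conv <- grepl("^C", v)
    v[conv] <- paste0("C", lab_map[sub("^C", "", v[conv])])
    v
  }
  tr <- inferred$trajectories$set
  tr$type <- remap_type(tr$type)
  obs <- truth$type[tr$parent_id]
  gr <- inferred$trajectories$groups
  sf1_inf <- gr$asv_id[gr$group == "SF1"]
  cos_inf <- gr$asv_id[gr$group == "cosmopolitan"]
  sf1_tru <- truth$asv_groups$asv_id[truth$asv_groups$group == "SF1"]
  cos_tru <- truth$asv_groups$asv_id[truth$asv_groups$group == "cosmopolitan"]
  pr1 <- set_precision_recall(sf1_inf, sf1_tru)
  pr2 <- set_precision_recall(cos_inf, cos_tru)
  pred <- remap_type(inferred$trajectories$predicted_type)
  names(pred) <- names(inferred$trajectories$predicted_type)
  conv <- names(truth$type)[truth$type != "D"]
  conv <- intersect(conv, names(pred))
  list(start_class_ari = start_ari,
       final_class_ari = final_ari,
       type_accuracy = mean(tr$type == obs),
       sf1_precision = pr1$precision, sf1_recall = pr1$recall,
       cosmo_precision = pr2$precision, cosmo_recall = pr2$recall,
       tipping_accuracy_convergent = mean(pred[conv] == truth$type[conv]))
}
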