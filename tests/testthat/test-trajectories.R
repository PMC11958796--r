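toy_meta <- function(types_by_parent) {
  parents <- names(types_by_parent)
  fin <- do.call(rbind, lapply(parents, function(p)
    data.frame(sample_id = paste0(p, ".R", 1:4), time_point = "final",
               parent_id = p, replicate = 1:4)))
  sample_metadata(rbind(
    data.frame(sample_id = parents, time_point = "start",
               parent_id = parents, replicate = NA_integer_),
    fin))
}

test_that("trajectories are typed by the unanimity rule", {
  meta <- toy_meta(list(p1 = NULL, p2 = NULL, p3 = NULL))
  labels <- c(stats::setNames(c(1, 1, 1, 1), paste0("p1.R", 1:4)),
              stats::setNames(c(1, 1, 1, 2), paste0("p2.R", 1:4)),
              stats::setNames(c(2, 2, 2, 2), paste0("p3.R", 1:4)))
  tr <- classify_trajectories(meta, labels)
  expect_equal(stats::setNames(tr$type, tr$parent_id),
               c(p1 = "C1", p2 = "D", p3 = "C2"))
  # a parent with an unlabelled replicate is excluded with a warning
  expect_warning(tr2 <- classify_trajectories(meta, labels[-2]), "excluded")
  expect_false("p1" %in% tr2$parent_id)
})

test_that("propensities match the hand-evaluated worked example", {
  # 10 communities, 4 of type C1; the ASV occurs in those 4 plus 1 other
  m <- matrix(0, 10, 2, dimnames = list(sprintf("c%02d", 1:10), c("hit", "flat")))
  m[1:5, "hit"] <- 5
  m[, "flat"] <- 3
  types <- c(rep("C1", 4), rep("C2", 3), rep("D", 3))
  pr <- propensity(count_table(m), types)
  expect_equal(pr["hit", "C1"], log(1 / 0.5), tolerance = 1e-12)   # ln 2
  expect_equal(unname(pr["flat", ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(pr["hit", "C2"], log((1 / 3) / 0.5), tolerance = 1e-12)
  expect_identical(pr["hit", "D"], -Inf)    # never present in the D stratum
  expect_error(propensity(count_table(m), rep(c("C1", NA), 5)), "NA")
})

test_that("the total-probability identity holds for finite propensities", {
  set.seed(61)
  for (i in 1:5) {
    t0 <- random_counts(30, 15, depth = 40, seed = 200 + i)
    types <- sample(c("C1", "C2", "D"), 30, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    pr <- propensity(t0, types)
    pt <- table(factor(types, levels = colnames(pr))) / 30
    mix <- exp(pr) %*% as.vector(pt)
    fin <- apply(is.finite(pr), 1, all)
    expect_equal(unname(mix[fin, 1]), rep(1, sum(fin)), tolerance = 1e-9)
  }
})

test_that("a widened marginal shifts propensities as the mixture predicts", {
  m <- matrix(0, 6, 1, dimnames = list(paste0("c", 1:6), "asv"))
  m[1:6, 1] <- 2                       # present in every typed community
  extra <- matrix(0, 6, 1, dimnames = list(paste0("e", 1:6), "asv"))
  extra[1:3, 1] <- 2                   # present in half the untyped pool
  types <- rep(c("C1", "C2", "D"), 2)
  pr <- propensity(count_table(m), types, marginal_extra = extra)
  expect_equal(unname(pr[1, ]), rep(log(1 / 0.75), 3), tolerance = 1e-12)
})

test_that("bootstrap propensities recover planted enrichment and are seeded", {
  set.seed(67)
  n <- 200
  types <- sample(c(rep("C1", 80), rep("C2", 60), rep("D", 60)))
  pres_prob <- ifelse(types == "C1", 0.9, 0.3)
  m <- matrix(0, n, 3, dimnames = list(sprintf("c%03d", 1:n),
                                       c("enriched", "flat", "rare")))
  m[, "enriched"] <- rbinom(n, 1, pres_prob) * 5
  m[, "flat"] <- rbinom(n, 1, 0.6) * 5
  m[, "rare"] <- rbinom(n, 1, 0.1) * 5
  bp <- bootstrap_propensities(count_table(m), types, n_boot = 400, seed = 3)
  en <- bp[bp$asv_id == "enriched" & bp$type == "C1", ]
  planted <- log(0.9 / (0.9 * 0.4 + 0.3 * 0.6))
  expect_lt(abs(en$propensity - planted), 0.1)
  expect_true(en$significant_positive)
  bp2 <- bootstrap_propensities(count_table(m), types, n_boot = 400, seed = 3)
  expect_identical(bp$ci_low, bp2$ci_low)
  expect_true(all(bp$ci_low <= bp$propensity + 1e-12 | !is.finite(bp$propensity)))
})

test_that("group assignment follows the signature and priority rules", {
  mk_pt <- function(sig) {
    # sig: named logical over C1, C2, D
    data.frame(asv_id = "a", type = c("C1", "C2", "D"),
               propensity = 0.5, ci_low = ifelse(sig, 0.1, -0.1), ci_high = 1,
               significant_positive = sig)
  }
  all_on <- c(C1 = TRUE, C2 = TRUE, D = TRUE)
  only_c1 <- c(C1 = TRUE, C2 = FALSE, D = FALSE)
  off <- c(C1 = FALSE, C2 = FALSE, D = FALSE)
  expect_equal(assign_groups(mk_pt(only_c1), mk_pt(only_c1))$group, "SF1")
  expect_equal(assign_groups(mk_pt(all_on), mk_pt(all_on))$group, "cosmopolitan")
  expect_equal(assign_groups(mk_pt(only_c1), mk_pt(off))$group, "start:C1")
  c2 <- c(C1 = FALSE, C2 = TRUE, D = FALSE)
  expect_equal(assign_groups(mk_pt(c2), mk_pt(c2))$group, "SF2")
  # associated with both convergent types at both time points: no core group
  both_c <- c(C1 = TRUE, C2 = TRUE, D = FALSE)
  expect_equal(assign_groups(mk_pt(both_c), mk_pt(both_c))$group,
               "start:C1+start:C2+final:C1+final:C2")
  expect_equal(assign_groups(mk_pt(off), mk_pt(off))$group, "none")
})

test_that("group abundance sums and tipping classification behave as stated", {
  m <- matrix(c(0.2, 0.1, 0.7), 1, 3,
              dimnames = list("s1", c("a1", "a2", "a3")))
  rel <- rel_abund(m)
  expect_equal(unname(group_abundance(rel, c("a1", "a2"))), 0.3)
  expect_equal(unname(group_abundance(rel, colnames(m))), 1)
  expect_equal(unname(group_abundance(rel, character(0))), 0)
  expect_equal(unname(group_abundance(rel, c("a1", "ghost"))), 0.2)

  expect_equal(threshold_classify(0.5, 0.05), "C1")
  expect_equal(threshold_classify(0.01, 0.6), "C2")
  expect_equal(threshold_classify(0.3, 0.3), "D")
  expect_equal(threshold_classify(0.01, 0.01), "D")
  expect_error(threshold_classify(1.2, 0.1), "\\[0, 1\\]")
})
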