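small_cfg <- function(...) sim_config(n_parents = 40, n_extra_start = 20, ...)

test_that("simulation is byte-reproducible and satisfies table invariants", {
  a <- simulate_communities(small_cfg(seed = 5))
  b <- simulate_communities(small_cfg(seed = 5))
  expect_identical(a, b)
  c2 <- simulate_communities(small_cfg(seed = 6))
  expect_false(identical(unclass(a$start), unclass(c2$start)))

  expect_s3_class(a$start, "count_table")
  expect_s3_class(a$final, "count_table")
  expect_true(all(unclass(a$final) == round(unclass(a$final))))
  expect_equal(nrow(a$final), 40 * 4)
  expect_equal(unname(rowSums(a$start)), rep(15000, 40))
  # generated tables survive the default quality filters intact
  expect_equal(nrow(filter_samples_min_reads(a$start)), 40)
  expect_gt(ncol(filter_asvs_min_reads(a$final)), 0.9 * ncol(a$final))
})

test_that("trajectory types follow the unanimity rule on the planted classes", {
  sim <- simulate_communities(small_cfg(seed = 9))
  fc <- sim$truth$final_class
  expected <- apply(fc, 1, function(v)
    if (length(unique(v)) == 1) paste0("C", v[1]) else "D")
  expect_identical(unname(sim$truth$type), unname(expected))
})

test_that("fates follow the transition matrix when tipping is disabled", {
  # deterministic identity-like transitions: every trajectory convergent
  tp <- matrix(c(1, 0,
                 0, 1), 2, 2, byrow = TRUE)
  sim <- simulate_communities(sim_config(
    n_parents = 30, n_extra_start = 0, n_start_classes = 2,
    sf1_targets = c(0.3, 0.01), cosmo_targets = c(0.05, 0.3),
    transition_probs = tp, tipping_noise = 0, seed = 13))
  expect_true(all(sim$truth$type != "D"))
  cls1 <- names(sim$truth$start_class)[sim$truth$start_class == 1]
  expect_true(all(sim$truth$type[cls1] == "C1"))

  # a fair-coin row with independent replicates: P(convergent) = 2 * 0.5^4
  sim2 <- simulate_communities(sim_config(
    n_parents = 500, n_extra_start = 0, n_replicates = 4, n_asvs = 60,
    reads_per_sample = 2000, n_start_classes = 1, n_final_classes = 2,
    sf1_targets = 0.2, cosmo_targets = 0.2,
    transition_probs = matrix(0.5, 1, 2), tipping_noise = 0, seed = 17))
  frac <- mean(sim2$truth$type != "D")
  se <- sqrt(0.125 * 0.875 / 500)
  expect_lt(abs(frac - 0.125), 4 * se)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_asvs = 40, sf1_size = 25, cosmo_size = 25),
               "group sizes")
  expect_error(sim_config(sf1_targets = c(0.9, 0.3, 0.1, 0.2, 0.1),
                          cosmo_targets = c(0.2, 0.1, 0.1, 0.1, 0.1)),
               "sum below 1")
  expect_error(sim_config(transition_probs = matrix(0.4, 5, 2)), "sum to 1")
  expect_error(sim_config(sf1_boost = 0.5), ">= 1")
})

test_that("stronger class separation raises ANOSIM R and recovery", {
  r_at <- function(theta) {
    sim <- simulate_communities(sim_config(n_parents = 60, n_extra_start = 0,
                                           within_theta = theta, seed = 19))
    d <- jsd_matrix(to_relative(sim$start))
    anosim_test(d, sim$truth$start_class[rownames(d)], n_perm = 10, seed = 1)$R
  }
  expect_gt(r_at(2000), r_at(30))
})

test_that("agreement scores behave as expected", {
  lab <- stats::setNames(rep(1:3, each = 10), sprintf("s%02d", 1:30))
  expect_equal(ari_score(lab, lab), 1)
  relabelled <- stats::setNames(c(3, 1, 2)[lab], names(lab))
  expect_equal(ari_score(lab, relabelled), 1)     # label-permutation invariance
  set.seed(23)
  rand <- vapply(1:50, function(i)
    ari_score(lab, stats::setNames(sample(lab), names(lab))), numeric(1))
  expect_lt(abs(mean(rand)), 0.05)
  pr <- set_precision_recall(c("a", "b", "c", "x"), c("a", "b", "c", "d"))
  expect_equal(pr$precision, 0.75)
  expect_equal(pr$recall, 0.75)
})

test_that("planted groups show the intended presence contrasts", {
  sim <- simulate_communities(sim_config(seed = 3))
  pres_start <- unclass(sim$start) > 0
  sf1 <- sim$truth$asv_groups$asv_id[sim$truth$asv_groups$group == "SF1"]
  cosmo <- sim$truth$asv_groups$asv_id[sim$truth$asv_groups$group == "cosmopolitan"]
  c1_parents <- names(sim$truth$type)[sim$truth$type == "C1"]
  c2_parents <- names(sim$truth$type)[sim$truth$type == "C2"]
  expect_gt(mean(pres_start[c1_parents, sf1]), 0.95)
  expect_lt(mean(pres_start[c2_parents, sf1]), 0.5)
  expect_gt(mean(pres_start[c(c1_parents, c2_parents), cosmo]), 0.95)
  # the unassayed pool lacks both planted groups
  pres_extra <- unclass(sim$extra_start) > 0
  expect_lt(mean(pres_extra[, c(sf1, cosmo)]), 0.05)
})
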