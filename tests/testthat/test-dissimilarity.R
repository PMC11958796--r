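test_that("pairwise Jensen-Shannon divergence matches hand-derived values", {
  expect_equal(jsd_pair(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd_pair(c(1, 0), c(0, 1)), 1)                 # disjoint supports
  expect_equal(jsd_pair(c(0.5, 0.5), c(1, 0)), 0.311278, tolerance = 1e-6)
  expect_equal(jsd_pair(c(0.5, 0.5), c(1, 0), base = exp(1)),
               0.311278 * log(2), tolerance = 1e-6)
  expect_error(jsd_pair(c(0.5, 0.6), c(1, 0)), "sum to 1")
  expect_error(jsd_pair(c(1, 0, 0), c(1, 0)), "equal length")
})

test_that("the divergence matrix agrees with a naive double-loop oracle", {
  rel <- random_rel(10, 12, seed = 6)
  for (dist_flag in c(TRUE, FALSE)) {
    got <- jsd_matrix(rel, as_distance = dist_flag)
    want <- naive_jsd_matrix(unclass(rel), as_distance = dist_flag)
    expect_equal(got, want, tolerance = 1e-12)
  }
  one <- random_rel(1, 5, seed = 1)
  expect_equal(unname(jsd_matrix(one)), matrix(0, 1, 1))
})

test_that("square-root JSD behaves as a metric on random triples", {
  set.seed(8)
  rel <- random_rel(60, 15, seed = 8)
  d <- jsd_matrix(rel, as_distance = TRUE)
  expect_true(all(abs(d - t(d)) < 1e-14))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1 + 1e-12))
  for (rep in 1:1000) {
    ijk <- sample(60, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("principal coordinates recover planar configurations", {
  set.seed(3)
  pts <- matrix(rnorm(30), 15, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:15), paste0("s", 1:15))
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))

  # duplicated samples land on identical coordinates
  d2 <- as.matrix(dist(pts[c(1, 1, 2:6), ]))
  dimnames(d2) <- list(paste0("q", 1:7), paste0("q", 1:7))
  ord2 <- pcoa(d2)
  expect_equal(ord2$coordinates[1, ], ord2$coordinates[2, ], tolerance = 1e-9)
  expect_warning(pcoa(d, n_axes = 14), "truncating")
})

test_that("ANOSIM reproduces the hand-ranked four-sample oracle", {
  d <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d[1, 2] <- 0.1; d[3, 4] <- 0.2                   # within ranks 1, 2
  d[1, 3] <- 0.3; d[1, 4] <- 0.4; d[2, 3] <- 0.5; d[2, 4] <- 0.6
  d <- d + t(d)
  res <- anosim_test(d, c("A", "A", "B", "B"), n_perm = 10, seed = 1)
  # mean between rank 4.5, mean within rank 1.5, denominator 4*3/4 = 3
  expect_equal(res$R, (4.5 - 1.5) / 3)
  expect_gte(res$p_value, 1 / 11)
})

test_that("ANOSIM is 1 for separated groups and centred at 0 under shuffling", {
  set.seed(5)
  d <- matrix(10 + runif(64), 8, 8)
  d[1:4, 1:4] <- as.matrix(dist(matrix(rnorm(8), 4)))
  d[5:8, 5:8] <- as.matrix(dist(matrix(rnorm(8), 4)))
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(letters[1:8], letters[1:8])
  res <- anosim_test(d, rep(c("x", "y"), each = 4), n_perm = 99, seed = 2)
  expect_equal(res$R, 1)
  expect_lte(res$p_value, 0.05)

  du <- as.matrix(dist(matrix(rnorm(40), 20)))
  dimnames(du) <- list(paste0("s", 1:20), paste0("s", 1:20))
  res2 <- anosim_test(du, rep(c("x", "y"), 10), n_perm = 1000, seed = 3)
  expect_lt(abs(mean(res2$perm_R)), 0.05)
})

test_that("ANOSIM matches the brute-force oracle and rank invariance holds", {
  set.seed(7)
  for (i in 1:5) {
    d <- as.matrix(dist(matrix(runif(30), 10)))
    dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
    g <- sample(rep(c("a", "b"), 5))
    got <- anosim_test(d, g, n_perm = 5, seed = 1)$R
    expect_equal(got, brute_anosim_R(d, g), tolerance = 1e-12)
    # rank-based: any strictly monotone transform leaves R unchanged
    expect_equal(anosim_test(d^2, g, n_perm = 5, seed = 1)$R, got,
                 tolerance = 1e-12)
    # agreement with the reference implementation in vegan
    expect_equal(got, unname(vegan::anosim(stats::as.dist(d), g,
                                           permutations = 5)$statistic),
                 tolerance = 1e-12)
  }
  d <- as.matrix(dist(matrix(runif(12), 4)))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_error(anosim_test(d, rep("a", 4)), "two groups")
  expect_error(anosim_test(d, letters[1:4]), "own group")
})

test_that("planted two-cluster structure is detected above the permutation null", {
  sim <- simulate_communities(sim_config(
    n_parents = 40, n_extra_start = 0, n_start_classes = 2,
    sf1_targets = c(0.35, 0.001), cosmo_targets = c(0.02, 0.35), seed = 21))
  d <- jsd_matrix(to_relative(sim$start))
  res <- anosim_test(d, sim$truth$start_class[rownames(d)],
                     n_perm = 200, seed = 4)
  expect_gt(res$R, quantile(res$perm_R, 0.95))
})
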