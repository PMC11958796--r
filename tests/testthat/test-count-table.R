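test_that("count table reading round-trips and both orientations agree", {
  t0 <- random_counts(3, 2, depth = 500, seed = 4)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_count_table(t0, f1)
  back <- read_count_table(f1)
  expect_identical(unclass(back), unclass(t0))

  # transpose on disk, read with asvs_as_rows
  df <- data.frame(asv_id = colnames(t0), t(unclass(t0)), check.names = FALSE)
  utils::write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_count_table(f2, orientation = "asvs_as_rows")
  expect_identical(unclass(back2), unclass(t0))
})

test_that("malformed count tables are rejected with informative errors", {
  f <- tempfile(fileext = ".tsv")
  write_tsv_raw(c("sample_id\ta1\ta2", "s1\t1\t2", "s1\t3\t4"), f)
  expect_error(read_count_table(f), "duplicate sample ids")
  write_tsv_raw(c("sample_id\ta1\ta2", "s1\t1\tx"), f)
  expect_error(read_count_table(f), "non-numeric")
  m <- matrix(c(1.5, 2, 3, 4), 2, 2,
              dimnames = list(c("s1", "s2"), c("a1", "a2")))
  expect_error(count_table(m), "non-integer")
  m[] <- c(-1, 2, 3, 4)
  expect_error(count_table(m), "negative")
})

test_that("ASV filter keeps totals at or above the threshold", {
  m <- matrix(c(50, 100,   # a1: 150
                49, 50,    # a2: 99
                40, 60),   # a3: 100
              nrow = 2,
              dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  t0 <- count_table(m)
  kept <- filter_asvs_min_reads(t0, 100)
  expect_identical(colnames(kept), c("a1", "a3"))   # 100 survives "fewer than"
  expect_identical(rownames(kept), rownames(t0))
  expect_identical(unclass(filter_asvs_min_reads(t0, 0)), unclass(t0))
  none <- filter_asvs_min_reads(t0, 1e6)
  expect_identical(ncol(none), 0L)
})

test_that("sample filter boundary is inclusive and filters are idempotent", {
  m <- matrix(c(5000, 5000, 4999, 5000), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a1", "a2")))
  t0 <- count_table(m)
  kept <- filter_samples_min_reads(t0, 10000)
  expect_identical(rownames(kept), "s1")
  expect_identical(unclass(filter_samples_min_reads(t0, 0)), unclass(t0))
  expect_warning(filter_samples_min_reads(t0, 1e7), "no sample")

  t1 <- random_counts(6, 8, depth = 300, seed = 2)
  once <- filter_asvs_min_reads(t1, 150)
  expect_identical(unclass(filter_asvs_min_reads(once, 150)), unclass(once))
  once2 <- filter_samples_min_reads(t1, 300)
  expect_identical(unclass(filter_samples_min_reads(once2, 300)), unclass(once2))
})

test_that("rarefaction hits the target depth, keeps support, is seeded", {
  t0 <- random_counts(5, 20, depth = 3000, seed = 9)
  r1 <- rarefy(t0, depth = 1000, seed = 3)
  expect_true(all(rowSums(r1) == 1000))
  expect_true(all(unclass(r1)[unclass(t0) == 0] == 0))      # support preserved
  r2 <- rarefy(t0, depth = 1000, seed = 3)
  expect_identical(unclass(r1), unclass(r2))

  one <- count_table(matrix(20000, 1, 1, dimnames = list("s1", "a1")))
  expect_equal(as.vector(rarefy(one, 10000, seed = 1)), 10000)

  shallow <- count_table(matrix(c(50L, 5000L), 2, 1,
                                dimnames = list(c("low", "hi"), "a1")))
  expect_error(rarefy(shallow, 1000), "low")
})

test_that("relative abundance conversion normalises rows and rejects zeros", {
  m <- matrix(c(2, 2, 1, 0, 3, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  r <- to_relative(count_table(m))
  expect_equal(unname(r["s1", ]), c(2, 2, 1) / 5)
  expect_equal(unname(r["s2", ]), c(0, 3, 0) / 3)
  for (s in 1:5) {
    t1 <- random_counts(4, 6, depth = 100, seed = s)
    expect_equal(unname(rowSums(to_relative(t1))), rep(1, 4))
  }
  z <- matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a1", "a2")))
  expect_error(to_relative(count_table(z)), "zero-sum")
})

test_that("metadata validation catches duplicates and orphans", {
  df <- data.frame(sample_id = c("p1", "p1.R1", "p1.R2"),
                   time_point = c("start", "final", "final"),
                   parent_id = c("p1", "p1", "p1"),
                   replicate = c(NA, 1L, 2L))
  expect_s3_class(sample_metadata(df), "sample_metadata")
  dup <- df; dup$replicate[3] <- 1L
  expect_error(sample_metadata(dup), "duplicate \\(parent_id, replicate\\)")
  orph <- df; orph$parent_id[2] <- "ghost"
  expect_warning(sample_metadata(orph), "unknown parents")
  f <- tempfile(fileext = ".tsv")
  write_sample_metadata(sample_metadata(df), f)
  expect_identical(read_sample_metadata(f)$sample_id, df$sample_id)
})
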