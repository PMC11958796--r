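#' Construct and validate an ASV count table
#'
#' A count table is the raw currency of the pipeline: an integer matrix of
#' sequencing read counts with samples as rows and amplicon sequence variants
#' (ASVs) as columns. Row and column names are the sample and ASV identifiers
#' and must be unique.
#'
#' @param counts numeric matrix of non-negative integer read counts,
#'   samples x ASVs, with unique rownames (sample ids) and colnames (ASV ids).
#' @return the validated matrix with class `"count_table"` prepended.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0))
    stop("count table needs sample ids as rownames and ASV ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts))) stop("count table contains NA")
  if (any(counts < 0)) stop("count table contains negative values")
  if (any(counts != round(counts))) stop("count table contains non-integer values")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in sums
  class(counts) <- c("count_table", class(matrix()))
  counts
}

#' Construct and validate a relative-abundance table
#'
#' @param abund numeric matrix of proportions, samples x ASVs; every row must
#'   sum to 1 (within 1e-9) and all entries must lie in `[0, 1]`.
#' @return the matrix with class `"rel_abund"` prepended.
#' @export
rel_abund <- function(abund) {
  if (!is.matrix(abund)) stop("`abund` must be a matrix")
  if (is.null(rownames(abund)) || is.null(colnames(abund)))
    stop("relative-abundance table needs sample ids as rownames and ASV ids as colnames")
  if (anyDuplicated(rownames(abund)) || anyDuplicated(colnames(abund)))
    stop("duplicate sample or ASV ids")
  if (any(is.na(abund)) || any(abund < 0) || any(abund > 1))
    stop("relative abundances must lie in [0, 1]")
  rs <- rowSums(abund)
  if (any(abs(rs - 1) > 1e-9))
    stop("rows must sum to 1; offending samples: ",
         paste(rownames(abund)[abs(rs - 1) > 1e-9], collapse = ", "))
  class(abund) <- c("rel_abund", class(matrix()))
  abund
}

#' Read an ASV count table from tab-separated text
#'
#' The expected layout is one header row of ASV ids and one leading column of
#' sample ids; `orientation = "asvs_as_rows"` reads the transpose. Lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"asvs_as_rows"`.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, orientation = c("samples_as_rows", "asvs_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed count table: ", path, " has fewer than 2 columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric count column(s) in ", path, ": ",
         paste(names(df)[-1][bad], collapse = ", "))
  }
  rownames(m) <- ids
  if (orientation == "asvs_as_rows") m <- t(m)
  count_table(m)
}

#' Write an ASV count table as tab-separated text
#'
#' @param t a [count_table()] (or any named matrix).
#' @param path file path; the leading column is named `sample_id`.
#' @export
write_count_table <- function(t, path) {
  df <- data.frame(sample_id = rownames(t), as.data.frame(unclass(t)[, , drop = FALSE],
                                                          check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop rare ASVs
#'
#' Removes ASVs with fewer than `min_total` reads summed across all samples;
#' ASVs whose total equals the threshold survive. The sample set is unchanged.
#'
#' @param t a [count_table()].
#' @param min_total minimum summed read count for an ASV to be kept (default 100).
#' @return the filtered [count_table()].
#' @export
filter_asvs_min_reads <- function(t, min_total = 100) {
  stopifnot(min_total >= 0)
  keep <- colSums(t) >= min_total
  count_table(unclass(t)[, keep, drop = FALSE])
}

#' Drop shallow samples
#'
#' Removes samples with fewer than `min_total` sequences; samples whose total
#' equals the threshold survive. Warns if nothing survives.
#'
#' @param t a [count_table()].
#' @param min_total minimum sequencing depth for a sample to be kept (default 10000).
#' @return the filtered [count_table()].
#' @export
filter_samples_min_reads <- function(t, min_total = 10000) {
  stopifnot(min_total >= 0)
  keep <- rowSums(t) >= min_total
  if (!any(keep)) warning("no sample reaches a depth of ", min_total)
  count_table(unclass(t)[keep, , drop = FALSE])
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement down to `depth`
#' (intended for visualisation and centroid paths, not for the statistical
#' stages). Reproducible given `seed`.
#'
#' @param t a [count_table()]; every row sum must be at least `depth`.
#' @param depth target depth (default 10000).
#' @param seed integer seed.
#' @return a [count_table()] whose every row sums to exactly `depth`.
#' @export
rarefy <- function(t, depth = 10000, seed = 1) {
  shallow <- rowSums(t) < depth
  if (any(shallow))
    stop("samples shallower than depth ", depth, ": ",
         paste(rownames(t)[shallow], collapse = ", "))
  # rrarefy warns when counts lack singletons; integrality is validated here
  r <- with_seed(seed, suppressWarnings(vegan::rrarefy(unclass(t), depth)))
  count_table(r)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Convert counts to relative abundances
#'
#' @param t a [count_table()] with strictly positive row sums.
#' @return a [rel_abund()] table.
#' @export
to_relative <- function(t) {
  rs <- rowSums(t)
  if (any(rs == 0))
    stop("zero-sum sample(s): ", paste(rownames(t)[rs == 0], collapse = ", "))
  rel_abund(unclass(t) / rs)
}
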