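#!/usr/bin/env Rscript
# Stage 3: rigid-body prediction of final from starting compositions.
#
# Fits the optimal translation + rotation (Kabsch) taking the starting
# relative abundances onto replicate 1 of the final communities, judges the
# RMSD against a null built from 50 cell-shuffled starting matrices, and
# compares the first two SVD components of the transformed starts against
# the three held-out replicates.

suppressPackageStartupMessages(library(mclandscape))
seed <- 1
dir.create("results", showWarnings = FALSE)

start <- read_count_table("results/data/start_counts.tsv")
final <- read_count_table("results/data/final_counts.tsv")
extra <- read_count_table("results/data/extra_start_counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")

keep <- colSums(rbind(unclass(start), unclass(final), unclass(extra))) >= 100
flt <- function(t) filter_samples_min_reads(
  count_table(unclass(t)[, keep, drop = FALSE]), 10000)
start_rel <- to_relative(flt(start))
final_rel <- to_relative(flt(final))

fin_meta <- meta[meta$time_point == "final" &
                   meta$sample_id %in% rownames(final_rel), ]
rep_table <- function(r) {
  ids <- fin_meta$sample_id[fin_meta$replicate == r]
  parents <- fin_meta$parent_id[fin_meta$replicate == r]
  keep_p <- parents %in% rownames(start_rel)
  m <- unclass(final_rel)[ids[keep_p], , drop = FALSE]
  rownames(m) <- parents[keep_p]
  m[rownames(start_rel)[rownames(start_rel) %in% rownames(m)], , drop = FALSE]
}

y <- rep_table(1)
x <- unclass(start_rel)[rownames(y), , drop = FALSE]
fit <- kabsch_fit(x, y)
ci <- randomised_rmsd_ci(x, y, n_rand = 50, seed = seed)
cat(sprintf("superposition RMSD = %.4f, shuffled null 95%% CI [%.4f, %.4f]\n",
            fit$rmsd, ci$lower, ci$upper))
cat(if (fit$rmsd < ci$lower)
  "observed RMSD falls below the null interval: final compositions are a\nnear-rigid image of the starting ones\n"
  else "observed RMSD is not separated from the null\n")

holdouts <- lapply(c(R2 = 2, R3 = 3, R4 = 4), rep_table)
holdouts <- lapply(holdouts, function(h) h[rownames(y), , drop = FALSE])
cmp <- predict_and_compare(x, fit, holdouts)
utils::write.table(cbind(cmp, rmsd = fit$rmsd, null_lower = ci$lower,
                         null_upper = ci$upper),
                   "results/superposition.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
for (i in seq_len(nrow(cmp)))
  cat(sprintf("holdout %s component %d: R^2 = %.3f (p = %.3g)\n",
              cmp$replicate_id[i], cmp$component[i], cmp$r_squared[i],
              cmp$p_value[i]))
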