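#!/usr/bin/env Rscript
# Stage 2: quality filters, community classes, ANOSIM.
#
# ASVs with fewer than 100 reads across all samples are dropped, then
# samples with fewer than 10,000 sequences. Classes are found by PAM over
# the square-root Jensen-Shannon distance matrix, scanning k and scoring
# with the Calinski-Harabasz index; each final replicate is typed
# independently and the ANOSIM R statistic quantifies (i) how strongly the
# four replicates of a parent cluster together and (ii) how sharply the
# classes are delimited.

suppressPackageStartupMessages(library(mclandscape))
seed <- 1
dir.create("results", showWarnings = FALSE)

start <- read_count_table("results/data/start_counts.tsv")
final <- read_count_table("results/data/final_counts.tsv")
extra <- read_count_table("results/data/extra_start_counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")

# joint ASV filter, then per-table sample filter
keep <- colSums(rbind(unclass(start), unclass(final), unclass(extra))) >= 100
flt <- function(t) filter_samples_min_reads(
  count_table(unclass(t)[, keep, drop = FALSE]), 10000)
start <- flt(start); final <- flt(final)
cat(sprintf("after filtering: %d ASVs retained\n", sum(keep)))

start_rel <- to_relative(start)
d_start <- jsd_matrix(start_rel)
typing <- scan_k(d_start, k_max = 10)
cat(sprintf("start classes: CH optimum at k = %d (local maxima: %s)\n",
            typing$k_opt, paste(typing$local_maxima, collapse = ", ")))
write_class_assignment(typing, "results/start_classes.tsv")

an_start <- anosim_test(d_start, typing$labels, n_perm = 1000, seed = seed)
cat(sprintf("start-class ANOSIM R = %.3f (p = %.4g)\n",
            an_start$R, an_start$p_value))

final_rel <- to_relative(final)
fin_meta <- meta[meta$time_point == "final" & meta$sample_id %in% rownames(final), ]
d_final <- jsd_matrix(final_rel)
an_parent <- anosim_test(d_final, fin_meta$parent_id[match(rownames(final), fin_meta$sample_id)],
                         n_perm = 1000, seed = seed)
cat(sprintf("replicates-track-parents ANOSIM R = %.3f (p = %.4g), %d groups\n",
            an_parent$R, an_parent$p_value, an_parent$n_groups))

for (r in sort(unique(fin_meta$replicate))) {
  ids <- fin_meta$sample_id[fin_meta$replicate == r]
  rel_r <- rel_abund(unclass(final_rel)[ids, , drop = FALSE])
  ty <- scan_k(jsd_matrix(rel_r), k_max = 8)
  write_class_assignment(ty, sprintf("results/final_classes_rep%d.tsv", r))
  cat(sprintf("final replicate %d: k_opt = %d\n", r, ty$k_opt))
}

# ordination coordinates for external plotting
ord <- pcoa(d_start, n_axes = 2)
utils::write.table(
  data.frame(sample_id = ord$sample_ids, ord$coordinates,
             class = typing$labels),
  "results/start_pcoa.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
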