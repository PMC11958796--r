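#!/usr/bin/env Rscript
# Stage 4: attractor geometry.
#
# Builds resampled-median centroids of the two final classes (replicate 1),
# then positions every starting community relative to each final class: the
# Jensen-Shannon distance to the class centroid and to the class border (the
# closest member community). Class-to-class mean distances summarise how the
# five starting classes sit relative to the two attractors.

suppressPackageStartupMessages(library(mclandscape))
seed <- 1
dir.create("results", showWarnings = FALSE)

start <- read_count_table("results/data/start_counts.tsv")
final <- read_count_table("results/data/final_counts.tsv")
extra <- read_count_table("results/data/extra_start_counts.tsv")

keep <- colSums(rbind(unclass(start), unclass(final), unclass(extra))) >= 100
flt <- function(t) filter_samples_min_reads(
  count_table(unclass(t)[, keep, drop = FALSE]), 10000)
start_rel <- to_relative(flt(start))
final_rel <- to_relative(flt(final))

start_classes <- utils::read.delim("results/start_classes.tsv")
rep1 <- utils::read.delim("results/final_classes_rep1.tsv")
rep1_rel <- rel_abund(unclass(final_rel)[rep1$sample_id, , drop = FALSE])
labels <- stats::setNames(rep1$class, rep1$sample_id)

centroids <- lapply(sort(unique(labels)), function(cl)
  class_centroid(rep1_rel, names(labels)[labels == cl],
                 depth = 10000, seed = seed + cl))
names(centroids) <- sort(unique(labels))

pos <- distances_to_classes(start_rel, rep1_rel, labels, centroids)
utils::write.table(pos, "results/landscape_positions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cmd <- class_mean_distance(start_rel,
                           start_classes$class[match(rownames(start_rel),
                                                     start_classes$sample_id)],
                           rep1_rel, labels)
utils::write.table(data.frame(start_class = rownames(cmd), cmd,
                              check.names = FALSE),
                   "results/class_mean_distance.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("mean start-class to final-class distances:\n")
print(round(cmd, 3))
cat(sprintf("wrote per-community centroid and border distances for %d starts\n",
            nrow(start_rel)))
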