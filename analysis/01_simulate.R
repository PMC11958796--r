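#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study fixture.
#
# Emulates the experimental design the analysis targets: 275 parent
# communities in five compositional classes, each revived in four replicate
# microcosms (1100 final communities), ~15,000 reads per sample, plus an
# unassayed pool of 383 further starting communities. Two ASV groups ("SF1"
# and "cosmopolitan") are planted with tipping-point behaviour. Tables are
# written as TSV so the later stages run from files, exactly as they would
# on downloaded data.

suppressPackageStartupMessages(library(mclandscape))
seed <- 1
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

sim <- simulate_communities(sim_config(seed = seed))

write_count_table(sim$start, "results/data/start_counts.tsv")
write_count_table(sim$final, "results/data/final_counts.tsv")
write_count_table(sim$extra_start, "results/data/extra_start_counts.tsv")
write_sample_metadata(sim$meta, "results/data/metadata.tsv")

truth <- sim$truth
utils::write.table(
  data.frame(parent_id = names(truth$type),
             start_class = truth$start_class,
             type = truth$type,
             truth$final_class |> `colnames<-`(paste0("final_class_rep", 1:4))),
  "results/data/truth_trajectories.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(truth$asv_groups, "results/data/truth_asv_groups.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "wrote fixture: %d parents (+%d unassayed), %d final samples, %d ASVs\n",
  nrow(sim$start), nrow(sim$extra_start), nrow(sim$final), ncol(sim$start)))
cat(sprintf("planted trajectory types: %s\n",
            paste(names(table(truth$type)), table(truth$type),
                  sep = "=", collapse = ", ")))
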