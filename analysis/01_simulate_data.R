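#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Emits, under sim/: a four-condition per-gene peak table with planted
# dependence classes at the study-scale proportions (peaks.tsv +
# truth.tsv), and a small genome with motif copies planted in the
# promoters of positively regulated genes (genome.fa + genes.bed +
# motif_truth.tsv).  Everything downstream (02-05) reads these files.

suppressPackageStartupMessages(library(polpool))

dir.create("sim", showWarnings = FALSE)
seed <- 20260922L

# peak table: desk-scale n keeps later stages quick while preserving the
# study's class proportions
cfg <- simulation_config(n_genes = 5000L, seed = seed)
sim <- simulate_peak_table(cfg)
write_gene_peak_table(sim$table, "sim/peaks.tsv")
write.table(sim$truth, "sim/truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("peak table: %d genes, %d planted active, %d planted dependent\n",
            nrow(sim$table), sum(sim$truth$in_pool1),
            sum(sim$truth$in_pool2)))

# genome for motif work: a target-rich design (1/3 positively regulated,
# 2/3 unregulated) with the 10-mer planted in 40% of target and 5% of
# background promoters
gcfg <- simulation_config(
  n_genes = 600L, seed = seed,
  class_proportions = c(inactive = 0, no_change = 2/3, pool4_pos = 0,
                        pool4_neg = 0, pool5_pos = 1/3, pool5_neg = 0,
                        pool6_pos = 0, pool6_neg = 0),
  motif_plant_rate_target = 0.4, motif_plant_rate_background = 0.05)
gen <- simulate_genome_with_motifs(gcfg)
write_fasta(gen$genome, "sim/genome.fa")
write_gene_models(gen$models, "sim/genes.bed")
write.table(gen$truth, "sim/motif_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("genome: %d contigs; motif %s planted in %d promoters (%d targets)\n",
            length(gen$genome), gcfg$planted_motif$sequence,
            sum(gen$truth$planted),
            sum(gen$truth$planted & gen$truth$is_target)))
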