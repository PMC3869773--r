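#!/usr/bin/env Rscript
# Stage 5: three-way overlap between the PARP-14-regulated gene list and
# an external regulator's regulation/binding lists -- the comparison the
# study runs against published STAT6 microarray and binding data.  The
# external lists here are synthetic: drawn to overlap the positively
# regulated genes at fixed rates, since the real lists belong to a
# different study.
#
# Reads results/ (from 02); writes results/venn.json.

suppressPackageStartupMessages(library(polpool))

if (!file.exists("results/pool2_positive.txt"))
  stop("run analysis/02_classify_pools.R first")

parp14_pos <- readLines("results/pool2_positive.txt")
unregulated <- readLines("results/no_change.txt")

set.seed(20260922)
# external "factor X": positively regulates 60% of the PARP-14 list plus
# many genes of its own; binds a subset of what it regulates
factor_pos <- c(sample(parp14_pos, round(0.6 * length(parp14_pos))),
                sample(unregulated, 400))
factor_bound <- c(sample(intersect(factor_pos, parp14_pos),
                         round(0.4 * length(intersect(factor_pos,
                                                      parp14_pos)))),
                  sample(setdiff(factor_pos, parp14_pos), 100))

# simulate the platform mismatch the real comparison faces, then match
# case-insensitively
h <- harmonize_ids(parp14_pos, toupper(factor_pos))

v <- venn3(parp14_pos, factor_pos, factor_bound,
           set_names = c("PARP14_pos", "factorX_pos", "factorX_bound"))
jsonlite::write_json(list(region_counts = as.list(v$region_counts),
                          region_members = v$region_members),
                     "results/venn.json", auto_unbox = TRUE,
                     pretty = TRUE)

cat("three-way overlap region counts:\n")
print(v$region_counts)
triple <- v$region_counts[[7]]
cat(sprintf("%d genes are positively regulated by both factors and bound by factor X\n",
            triple))
stopifnot(sum(v$region_counts) ==
            length(union(union(parp14_pos, factor_pos), factor_bound)))
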