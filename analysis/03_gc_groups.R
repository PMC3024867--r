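#!/usr/bin/env Rscript
# Stage 3: GC profiles and grouping.
#
# Computes whole-genome GC and the per-gene GC baseline per genome, the
# length-weighted GC of every set (inserted genes included, matching how a
# set's GC drops when a low-GC insertion is counted), z-scores against the
# per-gene baseline, and the exact optimal k=3 contiguous grouping of
# non-orphan set GC values per genome. Writes gc.tsv and genomes_gc.tsv.

suppressMessages(library(ptsHGT))

bundles <- load_genomes("results/data")
sets <- utils::read.delim("results/sets.tsv", stringsAsFactors = FALSE)
res <- run_gc(bundles, sets, outdir = "results", k = 3)

message("genome baselines:")
print(res$genomes)
message("set GC and z-scores:")
print(res$sets_gc[, c("set_id", "gc_percent", "z", "direction", "group")])
for (g in names(res$groupings)) {
  message("GC grouping for ", g, ":")
  print(res$groupings[[g]])
}
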