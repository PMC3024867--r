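#!/usr/bin/env Rscript
# Stage 1: generate the reference synthetic dataset.
#
# Three genomes — a high-GC donor (50%) and two low-GC recipients (30%,
# 32%) — each with ~200 background genes, plus seven planted
# fructose/mannose/sorbose entities: a native donor set, a recipient set
# with an inserted hypothetical gene, a 95%-identity duplicated pair, two
# IS-flanked HGT plants at +6 GC points, and one orphan IIB gene. All
# downstream stages read the files written here.

suppressMessages(library(ptsHGT))

seed <- if (length(commandArgs(TRUE)) >= 1) as.integer(commandArgs(TRUE)[1]) else 1L
datadir <- "results/data"

sim <- run_simulate(default_sim_spec(seed), datadir)

message("wrote ", length(sim$bundles), " genomes to ", datadir)
message("planted entities:")
print(sim$manifest[, c("label", "genome_id", "architecture", "class",
                       "orphan", "hgt", "is_flanked")])
message("species tree: ", ape::write.tree(sim$species_tree))
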