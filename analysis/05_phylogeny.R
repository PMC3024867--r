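#!/usr/bin/env Rscript
# Stage 5: IIB gene tree and duplicate detection.
#
# The substrate-specificity (IIB) subunit proteins of every
# fructose/mannose/sorbose set are progressively aligned, Poisson-corrected
# distances computed, and a neighbour-joining tree built with 500 bootstrap
# replicates. Same-genome set pairs at >= 90% IIB identity with matching
# architecture are reported as duplicates. Writes gene_tree.nwk,
# distances.tsv and duplicates.tsv.

suppressMessages(library(ptsHGT))

seed <- if (length(commandArgs(TRUE)) >= 1) as.integer(commandArgs(TRUE)[1]) else 1L
bundles <- load_genomes("results/data")
sets <- utils::read.delim("results/sets.tsv", stringsAsFactors = FALSE)

tree_res <- run_tree(bundles, sets, outdir = "results", B = 500L, seed = seed)
message("IIB gene tree (supports = bootstrap %):")
message(ape::write.tree(tree_res$tree))

dup <- detect_duplicates(sets, do.call(rbind, lapply(bundles, `[[`, "genes")))
utils::write.table(dup, "results/duplicates.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("set pairs compared on IIB identity:")
print(dup[, c("set_a", "set_b", "identity", "architecture_match", "verdict")])
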