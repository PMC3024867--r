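#!/usr/bin/env Rscript
# Stage 4: synteny scan.
#
# Examines the 4 flanking genes on each side of every set for sigma-54
# factors, sugar isomerase (SIS) genes and transposases (domain evidence
# first, product-text regex as fallback), assigns the synteny class
# (BOTH / SIGMA54_ONLY / OTHER / NEITHER) and flags sets flanked by
# insertion sequences on both sides. Writes synteny.tsv.

suppressMessages(library(ptsHGT))

bundles <- load_genomes("results/data")
sets <- utils::read.delim("results/sets.tsv", stringsAsFactors = FALSE)
syn <- run_synteny(bundles, sets, outdir = "results")

message("synteny classes:")
print(syn[, c("set_id", "synteny_class", "flanked_by_IS", "architecture")])
message("class counts: ")
print(table(syn$synteny_class))
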