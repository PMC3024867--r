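---
title: "Cataloguing PTS enzyme II gene sets and screening them for horizontal transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing PTS enzyme II gene sets and screening them for horizontal transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptsHGT)
```

## The problem

The phosphotransferase system (PTS) couples sugar import to
phosphorylation: enzyme I and HPr relay a phosphate to the sugar-specific
enzyme II complex. Enzyme II splits into at least seven substrate families;
the fructose/mannose/sorbose family is the only one with a IID subunit, and
the IIB subunit determines substrate specificity. Genomes of low-GC
Gram-positive bacteria can carry dozens of enzyme II gene sets whose GC
content sits consistently *above* the host genome's — the signature
expected if the sets were acquired from higher-GC donors by horizontal gene
transfer (HGT) and have not yet ameliorated to the host composition.

`ptsHGT` operationalizes that analysis: catalogue the enzyme II gene sets
of annotated genomes, group their GC values, read their neighbourhood
context, build the IIB gene tree, and combine the evidence into per-set
HGT verdicts. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Catalogue model

Domain hits (InterProScan-style TSV, e-value ≤ 1e-5) are mapped through an
editable vocabulary (`inst/extdata/pts_domain_vocab.tsv`) to
(subunit, family) tokens. Per gene, subunit tokens are ordered by domain
start coordinate, so a gene with IIA at residues 1–140 and IIB at 150–300
is the fusion `IIAB`; the gene's family is the majority family among its
PTS domains, with ties logged as UNKNOWN. Sets are maximal same-contig,
same-family runs of PTS-called genes. Two parameters shape the runs:

* `max_gap_bp = 300` — the largest intergenic gap between consecutive
  genes along a run. Typical operon spacing in bacteria is well under
  300 bp, and the synthetic generator's intra-operon gaps (40–150 bp) and
  background intergenic spacing (120–280 bp) bracket realistic values; the
  parameter exists because no distance rule is canonical.
* `max_inserted = 1` — at most one tolerated non-PTS gene inside a run,
  reflecting that a single inserted hypothetical protein inside an
  otherwise contiguous set is the observed pattern; longer interruptions
  break the run.

Completeness is family-specific: fructose/mannose/sorbose requires
{IIA, IIB, IIC, IID}; every other family {IIA, IIB, IIC}. A IID subunit in
a set labelled with any other family is contradictory annotation and
reclassifies the set to fructose/mannose/sorbose with a warning. A
singleton incomplete set is an orphan. Assembly is invariant under input
order (genes are re-sorted by coordinate) and partitions the PTS-called
genes: every called gene lands in exactly one set.

## GC model

GC of a set is computed on the concatenated coding sequences of its
members — i.e. the length-weighted mean of member GC. Strand does not
matter (GC is strand-symmetric), and ambiguity codes count in the
denominator only. Inserted genes are included by default at the pipeline
level because a low-GC insertion legitimately dilutes a set's GC; the flag
`include_inserted` exposes the choice.

The anomaly baseline is the **per-gene** GC distribution of all CDS in the
host genome (mean and SD), not sliding windows, because the compared units
are genes and gene sets; the whole-genome GC is reported separately and
fixes the *direction* ("above"/"below"). The z-score of a set is
`(GC_set − mean_gene)/sd_gene`.

Grouping of a genome's set GC values uses exact 1-D clustering: dynamic
programming over contiguous partitions of the sorted values minimizing the
within-group sum of squares, `k = 3` by default. Ties between equal-cost
partitions prefer boundaries at the largest value gaps, then the leftmost
boundary. Orphans are excluded from grouping by default since lone
subunit genes need not conform to set-level structure. An exhaustive
enumeration oracle in the tests confirms optimality for all n ≤ 12, k ≤ 4.

## Synteny model

The context of a set is up to 4 genes on each flank on the same contig
(truncated at contig ends); 4 is the conventional inspection window and is
exposed as `window`. Markers fire on domain labels first (sigma-54, SIS,
transposase signatures) and fall back to case-insensitive product-text
regexes (`inst/extdata/marker_vocab.tsv`). The class is a pure function of
the sigma-54 and SIS flags (BOTH / SIGMA54_ONLY / OTHER / NEITHER).
Insertion-sequence evidence distinguishes transposases on both flanks
(`flanked_by_IS`, the HGT-relevant state) from a single-side match
(`is_adjacent`). Architecture comparison treats a reversed gene order as a
match (sets read on opposite strands traverse genes in opposite genomic
order; within-gene domain order is a property of the protein and does not
flip), so `IID/IIC/IIB/IIA` matches `IIA/IIB/IIC/IID` but never the fused
`IIAB/IIC/IID`. Whether a marker must fall inside the 4-gene window is our
rule (it must); neighbourhood membership has no canonical definition.

## Phylogeny

Pairwise alignment is global Gotoh with affine gaps; protein scoring is
BLOSUM62 with X scoring 0, gap open 11 / extend 1 (a length-L gap costs
11 + L), mirroring blastp defaults so reported identities are comparable to
published blastp identities within a couple of points (global vs local
alignment differs slightly). Traceback ties prefer match/mismatch over
gap-in-a over gap-in-b, fixed at fill time, so alignments are
deterministic. The progressive MSA uses an NJ guide tree on pairwise
p-distances and merges profiles by expected sum-of-pairs scoring; with no
indels in the inputs the result is the ungapped homology.

Distances are Poisson-corrected protein distances `d = −ln(1 − p)` with
pairwise deletion; p-distance is available by flag. The Poisson correction
is the package's choice of a standard protein correction — the upstream
tooling this mirrors (ClustalW + MEGA-era NJ) does not pin a model — so
cross-study tree comparisons should stay at the topology level (cluster
membership), not branch lengths. Saturated pairs (p ≥ 1) are flagged and
set to a ceiling of 5 substitutions/site.

NJ follows the classic Q-criterion with ties broken by the smallest index
pair in the current matrix order; negative branch-length estimates are
clamped to zero with a message. On additive matrices the reconstruction is
exact: tests verify RF = 0 and path-metric agreement to 1e-9 on 200 random
trees up to n = 16. Bootstrap resamples alignment columns, rebuilds
distance + NJ per replicate, and reports per-edge bipartition frequencies
(B = 500 by default); identical seeds give identical supports.

## HGT verdict

Three binary evidence lines per set:

1. **GC anomaly** — z ≥ `z_min` (default 2.0, i.e. two per-gene SDs) *and*
   the set GC above the whole-genome GC;
2. **tree incongruence** — the set's leaf in the IIB gene tree sits in a
   mixed clade: its smallest surrounding non-trivial bipartition side
   contains leaves from both taxon groups. Taxa are split by the deepest
   bipartition of the supplied species tree, with the higher-mean-GC side
   the donor clade; explicit labels override.
3. **mobility** — the set is flanked by insertion sequences on both sides.

Two or more lines give STRONG, one gives CANDIDATE, none NONE; the rule is
monotone (more evidence never downgrades). A donor group is inferred only
when the set GC is elevated — depressed GC is an anomaly but carries no
directional information under the high-GC-donor model. `z_min = 2` flags
roughly the top 2% of a genome's own gene-GC distribution; with planted
offsets of +6 points against per-gene SDs near 1.5–2 points the realized z
is 3–4, so detection is insensitive to the exact threshold. All three
thresholds are config keys.

Two known limitations of the clade test: when *several* transferred sets
cluster together, each one's smallest surrounding clade may consist only of
the other transfers (all recipient-group), so the mixed flag can miss
grouped transfers — GC and IS evidence still carry those to STRONG; and the
donor's own gene legitimately shares a clade with the transferred copies,
so donors surface as CANDIDATE. Both behaviours are visible in the worked
example.

## Synthetic data: what it emulates, what it does not

`sim_pts_genomes` generates, deterministically per seed: a Yule species
tree (taxa placed so genome GC is clade-structured at the root split, as in
real 16S trees separating high-GC Gram-negatives from low-GC
Gram-positives); per-subunit family proteins evolved along that tree under
a Poisson substitution model; genomes of ~100–450-codon background genes
drawn codon-wise at the target GC (the codon sampler is calibrated by
root-finding so the sense-codon distribution realizes the target exactly —
naive per-base weighting is biased by stop-codon exclusion); and planted
sets whose nucleotide sequences reverse-translate their proteins with codon
third-position bias chosen to hit a target GC offset over the measured
background baseline. Native sets sit at +1.0 ± 0.4 GC points (the mild
elevation typical of PTS sets in their hosts), HGT plants at +6 with donor
protein sequence and IS flanks, duplicates substitute exactly 5% of
residues (95% identity). The default spec is three genomes (donor at 50%
GC, recipients at 30% and 32%) with ~200 background genes each, seven
planted entities, and ~210 kb per genome; the benchmark spec plants 200
sets (half HGT) across 50 recipient genomes. These sizes keep the full test
suite and the acceptance script within a few minutes on one CPU while
leaving per-gene GC noise (binomial, SD ≈ 1.5–2 points at these lengths)
realistic.

Not emulated: indels (the true alignment is the ungapped homology, so the
MSA is validated on gap-free ground truth plus hand-made gapped cases),
codon-usage structure beyond third-position GC bias, rearrangements,
amelioration over time, and annotation noise (domain hits are clean).
Passing the recovery tests therefore demonstrates correctness of the
pipeline's logic under its stated assumptions — not robustness to noisy
real-world annotation, which varies with annotation version and pipeline.

## Numerical and design notes

* Coordinates are 1-based inclusive throughout; locus tags join gene
  table, protein FASTA and domain TSV; unmatched proteins/hits are
  dropped with a warning.
* GC values are kept at full precision internally and rounded only in
  reports.
* Newick branch lengths are written with 15 significant digits so
  round-trips preserve lengths to 1e-9.
* The clustal reader handles the plain CLUSTAL block format directly
  (names + chunks, conservation lines skipped); aligned FASTA goes through
  Biostrings.
* Mixed-strand runs take the majority strand and are logged; genomes in
  practice encode operons on one strand.
* `run_all` validates thresholds before any compute and each stage is a
  pure function of its inputs, so re-running a stage is idempotent and a
  fixed config + seed reproduces every report byte-identically.
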