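# ptsHGT

Bacterial sugar uptake commonly runs through the phosphotransferase system
(PTS): enzyme I and the phosphocarrier protein HPr relay a phosphate to the
sugar-specific enzyme II complex, whose IIA/IIB/IIC (and, in the
fructose/mannose/sorbose family only, IID) subunits transport and
phosphorylate the substrate. Solventogenic clostridia and other
low-GC Gram-positives carry unusually many enzyme II gene sets, and those
sets tend to sit *above* their host genome's GC content — the footprint
expected if low-GC species acquired the system from higher-GC donors by
horizontal gene transfer (HGT).

`ptsHGT` turns that comparative analysis into a reproducible pipeline for
annotated genomes (nucleotide FASTA + gene table + protein FASTA +
InterProScan-style domain TSV):

1. **Catalogue** — map domain signatures to subunit/family tokens, call
   per-gene subunits in N-to-C order (fusions like IIAB or IIABC
   preserved), and assemble coordinate-contiguous same-family runs into
   gene sets, tolerating one inserted non-PTS gene and intergenic gaps
   ≤ 300 bp; singletons become orphans.
2. **GC profile** — per-set GC is the length-weighted GC of the
   concatenated coding sequences; each set gets a z-score
   `z = (GC_set − mean_gene) / sd_gene` against the host per-gene GC
   distribution, and the set GC values of a genome are partitioned into
   `k = 3` groups by *exact* dynamic-programming 1-D clustering (minimum
   within-group sum of squares over contiguous partitions of the sorted
   values).
3. **Synteny** — the 4 flanking genes on each side are scanned for
   sigma-54 factors, sugar isomerase (SIS) genes and transposases, giving
   the class BOTH / SIGMA54_ONLY / OTHER / NEITHER and an
   insertion-sequence flanking flag.
4. **Phylogeny** — global pairwise alignment (Gotoh affine gaps, BLOSUM62,
   gap open 11 / extend 1), progressive MSA, Poisson-corrected distances
   `d = −ln(1 − p)`, neighbour-joining (Q-criterion, deterministic
   tie-breaks) with 500 column-bootstrap replicates, Robinson–Foulds
   comparison, and duplicate-set detection at ≥ 90% IIB identity with
   matching architecture.
5. **HGT screen** — per set, three evidence lines: GC z ≥ 2 above
   baseline, placement in a mixed donor/recipient clade of the IIB gene
   tree (taxa split by the species tree's deepest bipartition, higher-GC
   side = donor clade), and IS flanking. Two or more lines ⇒ STRONG, one
   ⇒ CANDIDATE, none ⇒ NONE; the donor group is inferred only for
   GC-elevated sets.

A deterministic synthetic-genome generator (`sim_pts_genomes`) plants gene
sets with controlled GC offsets (realized at codon third positions),
fusions, insertions, orphans, markers, 95%-identity duplicates and
donor-sequence HGT copies, together with a ground-truth manifest, so the
whole pipeline is testable offline.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
reference synthetic dataset and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1     # genomes + ground truth
Rscript analysis/02_catalog.R       # gene sets
Rscript analysis/03_gc_groups.R     # GC baselines, z, grouping
Rscript analysis/04_synteny.R       # neighbourhood classes
Rscript analysis/05_phylogeny.R 1   # IIB tree + duplicates
Rscript analysis/06_hgt_screen.R 1  # verdicts + benchmark
```

With seed 1 the screen prints:

```
   set_id gc_percent      gc_z mixed_clade flanked_by_IS   verdict
1 G1_set1   50.52209 0.2720123        TRUE         FALSE CANDIDATE
2 G2_set1   31.11803 0.5186542       FALSE         FALSE      NONE
3 G2_set2   32.08835 1.0370107       FALSE         FALSE      NONE
4 G2_set3   37.30924 3.8260704        TRUE          TRUE    STRONG
5 G2_set4   31.92771 0.9511935       FALSE         FALSE      NONE
6 G3_set1   39.15663 3.5715659        TRUE          TRUE    STRONG
7 G3_set2   34.16667 0.9897090        TRUE         FALSE CANDIDATE
```

The two planted HGT sets (`G2_set3`, `G3_set1`) are the only STRONG calls:
each sits ~+6 GC points over its host baseline (z ≈ 3.6–3.8), groups with
the high-GC donor's genes in the IIB tree, and is flanked by insertion
sequences. The donor's own set (`G1_set1`) is CANDIDATE on tree evidence
alone — its gene genuinely shares a clade with the transferred copies —
and the native recipient sets stay NONE. Stage 5 recovers the planted
duplicated pair at exactly 95.0% IIB identity with matching
`IID/IIC/IIB/IIA` architecture, and the benchmark re-run over 200
independently planted sets reports sensitivity 1.00 at false-positive
rate 0.00.

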