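test_that("FASTA reading normalizes case and rejects duplicate headers", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 some description", "acGT"), f)
  x <- read_fasta(f)
  expect_identical(x, c(g1 = "ACGT"))

  writeLines(c(">g1", "ACGT", ">g1", "TTTT"), f)
  expect_error(read_fasta(f), "g1")

  f2 <- withr::local_tempfile(fileext = ".fa")
  file.create(f2)
  expect_warning(x2 <- read_fasta(f2), "empty")
  expect_length(x2, 0)

  writeLines(c("not a header", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("FASTA write/read round-trips arbitrary records modulo wrapping", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(1:6, 1)
    seqs <- stats::setNames(
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), sample(1:250, 1), TRUE),
              collapse = ""), ""),
      paste0("s", seq_len(n)))
    f <- withr::local_tempfile(fileext = ".fa")
    write_fasta(seqs, f)
    expect_identical(read_fasta(f), seqs)
  }
})

test_that("gene tables parse from GFF3 with reverse-complement extraction", {
  contig <- c(ctg1 = "AAAAAAAAAACATAAA")
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("ctg1", "src", "CDS", "11", "13", ".", "-", "0",
                     "ID=c1;locus_tag=g1;product=test protein", sep = "\t")),
             g)
  genes <- read_gene_table(g, "gff3", contigs = contig)
  expect_equal(genes$nt, "ATG")  # reverse complement of CAT
  expect_equal(genes$strand, "-")

  # gene features only -> empty with warning
  writeLines(c("##gff-version 3",
               paste("ctg1", "src", "gene", "1", "5", ".", "+", ".",
                     "ID=gene1", sep = "\t")), g)
  expect_warning(empty <- read_gene_table(g, "gff3", contigs = contig),
                 "no CDS")
  expect_equal(nrow(empty), 0)

  # CDS without locus_tag skipped with warning
  writeLines(c("##gff-version 3",
               paste("ctg1", "src", "CDS", "1", "3", ".", "+", "0",
                     "ID=c2", sep = "\t"),
               paste("ctg1", "src", "CDS", "11", "13", ".", "+", "0",
                     "ID=c3;locus_tag=g3", sep = "\t")), g)
  expect_warning(one <- read_gene_table(g, "gff3", contigs = contig),
                 "locus_tag")
  expect_equal(one$gene_id, "g3")
})

test_that("TSV gene tables are sorted and validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcontig\tstart\tend\tstrand\tproduct",
               "b\tc2\t5\t10\t+\tp2",
               "a\tc1\t50\t60\t-\tp1",
               "c\tc1\t5\t10\t+\tp3"), f)
  genes <- read_gene_table(f, "tsv")
  expect_equal(genes$gene_id, c("c", "a", "b"))  # (contig, start) order
  expect_equal(nrow(genes), 3)

  writeLines(c("gene_id\tcontig\tstart\tend\tstrand\tproduct",
               "bad\tc1\t10\t5\t+\tp"), f)
  expect_error(read_gene_table(f, "tsv"), "start > end")
})

test_that("minus-strand extraction equals reverse complement of the slice", {
  set.seed(23)
  for (rep in 1:10) {
    L <- 200L
    contig <- c(chr = paste(sample(c("A", "C", "G", "T"), L, TRUE),
                            collapse = ""))
    s <- sample(1:(L - 30L), 1)
    e <- s + sample(5:25, 1)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tcontig\tstart\tend\tstrand\tproduct",
                 paste("g", "chr", s, e, "-", "p", sep = "\t")), f)
    genes <- read_gene_table(f, "tsv", contigs = contig)
    expect_identical(genes$nt, revcomp(substr(contig[["chr"]], s, e)))
  }
})

test_that("domain tables apply the e-value threshold and the vocabulary", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsignature_id\tdescription\taa_start\taa_end\tevalue",
               "g1\tPF03830\tPTS IIB\t1\t150\t1e-30",
               "g2\tPF03830\tPTS IIB\t1\t150\t1e-4",
               "g3\tPFXXXXX\tmystery\t1\t50\t1e-30"), f)
  hits <- read_domain_tsv(f)
  expect_equal(nrow(hits), 2)  # 1e-4 hit dropped at the 1e-5 threshold
  expect_false("g2" %in% hits$gene_id)
  expect_equal(hits$signature_label[hits$gene_id == "g1"], "PTS_IIB")
  expect_equal(hits$subunit[hits$gene_id == "g1"], "IIB")
  expect_equal(hits$signature_label[hits$gene_id == "g3"], "OTHER")

  # property: never emits a hit above the threshold
  set.seed(5)
  ev <- 10^stats::runif(40, -40, 0)
  writeLines(c("gene_id\tsignature_id\tdescription\taa_start\taa_end\tevalue",
               sprintf("g%d\tPF03830\tx\t1\t10\t%g", seq_along(ev), ev)), f)
  hits <- read_domain_tsv(f, evalue_max = 1e-5)
  expect_true(all(hits$evalue <= 1e-5))
  expect_equal(nrow(hits), sum(ev <= 1e-5))

  writeLines(c("gene_id\tsignature_id\tdescription\taa_start\taa_end\tevalue",
               "g1\tPF03830\tx\t1\t10\tnot_a_number"), f)
  expect_error(read_domain_tsv(f), "non-numeric")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  file.create(f2)
  expect_equal(nrow(read_domain_tsv(f2)), 0)
})

test_that("headerless InterProScan column order is accepted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("g1", "md5", "300", "Pfam", "PF03613", "PTS IID",
                   "3", "250", "2.1e-40", "T", "2020-01-01", sep = "\t"), f)
  hits <- read_domain_tsv(f)
  expect_equal(hits$signature_label, "PTS_IID")
  expect_equal(hits$aa_start, 3L)
})

test_that("Newick I/O round-trips topology, lengths and supports", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)95:0.5,C:2);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_true("95" %in% tr$node.label)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_equal(rf_distance(tr, tr2), 0)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_true("95" %in% tr2$node.label)

  writeLines("((A:1,B:1):0.5,C:2;", f)
  expect_error(read_newick(f), "[Uu]nbalanced|parse")
})

test_that("random trees round-trip through Newick", {
  set.seed(7)
  for (rep in 1:5) {
    tr <- ape::rtree(sample(4:12, 1))
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, f)
    tr2 <- read_newick(f)
    expect_equal(rf_distance(tr, tr2), 0)
    D1 <- stats::cophenetic(tr); D2 <- stats::cophenetic(tr2)
    expect_equal(D2[rownames(D1), colnames(D1)], D1, tolerance = 1e-9)
  }
})

test_that("alignment reading checks lengths and normalizes gaps", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "AC-DE", ">s2", "ACQD."), f)
  aln <- read_alignment(f, "fasta")
  expect_identical(unname(aln["s2"]), "ACQD-")

  writeLines(c(">s1", "ACDE", ">s2", "AC"), f)
  expect_error(read_alignment(f, "fasta"), "s2")

  fc <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "s1    ACDE-", "s2    AC-EF", ""), fc)
  alnc <- read_alignment(fc, "clustal")
  expect_equal(sort(names(alnc)), c("s1", "s2"))
  expect_identical(unname(alnc["s1"]), "ACDE-")
})
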