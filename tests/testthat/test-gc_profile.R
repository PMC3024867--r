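test_that("gc_percent counts G+C over the full length", {
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("GCGC"), 100)
  expect_equal(gc_percent("GCAN"), 50)  # N in the denominator only
  expect_equal(gc_percent("gcat"), 50)
  expect_error(gc_percent(""), "non-empty")
})

test_that("gc_percent is invariant under reverse complement", {
  set.seed(31)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(10:200, 1), TRUE,
                      prob = c(.3, .2, .2, .3, .02)), collapse = "")
    expect_equal(gc_percent(s), gc_percent(revcomp(s)))
  }
})

test_that("set GC is the length-weighted member mean", {
  genes <- make_genes(c("g1", "g2", "ins"), c(100, 600, 1100),
                      lens = c(4L, 12L, 4L),
                      nt = c("GGGG", "ATATATATATAT", "GGCC"))
  set_row <- data.frame(set_id = "s", members = "g1,g2", inserted = "ins",
                        architecture = "IIA/IIB", stringsAsFactors = FALSE)
  expect_equal(set_gc(set_row, genes), 25)  # (4*100 + 12*0)/16, not 50
  # including the inserted high-GC gene shifts the value up
  expect_equal(set_gc(set_row, genes, include_inserted = TRUE), 40)
  single <- data.frame(set_id = "s2", members = "g1", inserted = "",
                       stringsAsFactors = FALSE)
  expect_equal(set_gc(single, genes), gc_percent("GGGG"))
  bad <- data.frame(set_id = "s3", members = "nope", inserted = "",
                    stringsAsFactors = FALSE)
  expect_error(set_gc(bad, genes), "nope")
})

test_that("set GC equals the length-weighted mean of member GC", {
  set.seed(13)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    nts <- vapply(seq_len(k), function(i)
      paste(sample(c("A", "C", "G", "T"), sample(30:300, 1), TRUE),
            collapse = ""), "")
    genes <- make_genes(paste0("g", seq_len(k)),
                        cumsum(rep(1000, k)), lens = nchar(nts), nt = nts)
    row <- data.frame(set_id = "s", members = paste(genes$gene_id, collapse = ","),
                      inserted = "", stringsAsFactors = FALSE)
    w <- nchar(nts)
    expect_equal(set_gc(row, genes),
                 sum(vapply(nts, gc_percent, 0) * w) / sum(w))
  }
})

test_that("genome baseline measures whole-genome and per-gene GC", {
  contig <- c(chr = strrep("GCAT", 100))
  genes <- make_genes(c("a", "b"), c(1, 201), lens = 100L,
                      nt = c(substr(strrep("GCAT", 25), 1, 100),
                             substr(strrep("GAAT", 25), 1, 100)))
  bl <- genome_baseline(contig, genes)
  expect_equal(bl$genome_gc, 50)
  expect_equal(bl$gene_mean, mean(c(50, 25)))
  expect_equal(bl$gene_sd, stats::sd(c(50, 25)))

  # degenerate: all genes identical GC -> sd 0 flagged
  genes2 <- make_genes(c("a", "b"), c(1, 201), lens = 4L, nt = c("GCAT", "GCTA"))
  expect_warning(bl2 <- genome_baseline(contig, genes2), "degenerate")
  an <- gc_anomaly(55, bl2)
  expect_true(is.na(an$z))
})

test_that("simulated genomes hit their target GC within binomial error", {
  spec <- default_sim_spec(901)
  spec$taxa <- spec$taxa[2, , drop = FALSE]  # one recipient, GC 0.30
  spec$templates <- spec$templates[0, , drop = FALSE]
  sim <- sim_pts_genomes(spec)
  contig <- sim$bundles$G2$contigs[[1]]
  L <- nchar(contig)
  expect_gt(L, 100000)
  se <- 100 * sqrt(0.3 * 0.7 / L)
  expect_lt(abs(gc_percent(contig) - 30), 3 * se + 0.2)
})

test_that("group_gc matches exhaustive search on random inputs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    k <- sample(1:min(4, n), 1)
    v <- round(stats::runif(n, 25, 45), 1)
    g <- group_gc(v, k)
    oracle <- brute_partition(v, k)
    expect_equal(g$within_ss, oracle$within_ss, tolerance = 1e-9)
    # the reported assignment realizes the reported (optimal) cost
    ss <- sum(vapply(seq_len(k), function(gr) {
      x <- v[g$assignment == gr]
      sum((x - mean(x))^2)
    }, 0))
    expect_equal(ss, g$within_ss, tolerance = 1e-9)
    # groups are contiguous in sorted order
    expect_true(all(diff(g$assignment[order(v)]) >= 0))
  }
})

test_that("group_gc handles the degenerate k values", {
  v <- c(3, 1, 2, 10)
  g1 <- group_gc(v, 1)
  expect_equal(g1$within_ss, sum((v - mean(v))^2))
  gn <- group_gc(v, 4)
  expect_equal(gn$within_ss, 0)
  expect_equal(sort(unique(gn$assignment)), 1:4)
  expect_error(group_gc(v, 5), "exceeds")
})

test_that("the nine complete-set GC values split into the reported groups", {
  # complete fructose/mannose/sorbose sets, inserted-gene set counted with
  # its insertion (33.1)
  vals <- c(37.5, 31.8, 31.9, 33.1, 32.4, 32.0, 35.1, 30.3, 35.1)
  ids <- c("s0711", "s0955", "s0963", "s2195", "s2901", "s2905", "s3871",
           "s4557", "s4911")
  g <- group_gc(vals, 3, ids = ids)
  grp_of <- stats::setNames(g$assignment, ids)
  # low group: 30.3..33.1; middle: the two 35.1 duplicates; high: 37.5
  expect_length(unique(grp_of[c("s4557", "s0955", "s0963", "s2905", "s2901",
                                "s2195")]), 1)
  expect_length(unique(grp_of[c("s3871", "s4911")]), 1)
  expect_length(unique(grp_of), 3)
  expect_false(grp_of["s0711"] %in% grp_of[c("s3871", "s4557")])
  expect_false(grp_of["s3871"] %in% grp_of[c("s0711", "s4557")])
  sizes <- tabulate(g$assignment, 3)
  expect_equal(sort(sizes), c(1, 2, 6))
})

test_that("gc_anomaly computes the z-score and direction", {
  bl <- list(genome_gc = 29.9, gene_mean = 30, gene_sd = 2)
  expect_equal(gc_anomaly(30, bl)$z, 0)
  an <- gc_anomaly(36, bl)
  expect_equal(an$z, 3)
  expect_equal(an$direction, "above")
  expect_equal(gc_anomaly(25, bl)$direction, "below")
})
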