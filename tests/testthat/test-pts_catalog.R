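test_that("subunit calls follow domain order and majority family", {
  # fused IIA+IIB gene: two domains ordered by aa_start
  d <- data.frame(gene_id = "g1",
                  signature_id = c("PF03830", "PF03610"),
                  signature_label = c("PTS_IIB", "PTS_IIA"),
                  subunit = c("IIB", "IIA"), family = "FRU_MAN_SOR",
                  aa_start = c(150L, 1L), aa_end = c(300L, 140L),
                  evalue = 1e-30, stringsAsFactors = FALSE)
  calls <- assign_subunits(d)
  expect_equal(calls$subunits, "IIA+IIB")  # N-to-C order, not row order
  expect_equal(calls$arch, "IIAB")
  expect_true(calls$fused)

  # triple-fused IIABC gene of the fructose/mannitol family
  d3 <- make_domains("g2", c("IIA", "IIB", "IIC"), family = "FRU_MANNITOL")
  calls3 <- assign_subunits(d3)
  expect_equal(calls3$arch, "IIABC")
  expect_equal(calls3$family, "FRU_MANNITOL")

  # gene with only unmapped domains gets no call
  d0 <- data.frame(gene_id = "g3", signature_id = "PFX", signature_label = "OTHER",
                   subunit = NA_character_, family = NA_character_,
                   aa_start = 1L, aa_end = 10L, evalue = 1e-30,
                   stringsAsFactors = FALSE)
  expect_equal(nrow(assign_subunits(d0)), 0)

  # family tie -> UNKNOWN with a warning
  dt <- rbind(make_domains("g4", "IIA", family = "FRU_MAN_SOR"),
              make_domains("g4", "IIB", family = "GLUCOSE"))
  dt$aa_start <- c(1L, 200L); dt$aa_end <- c(150L, 350L)
  expect_warning(ct <- assign_subunits(dt), "UNKNOWN")
  expect_equal(ct$family, "UNKNOWN")
})

test_that("family completeness rules follow the IID criterion", {
  r <- classify_family(c("IIA", "IIB", "IIC", "IID"), "FRU_MAN_SOR")
  expect_true(r$complete)
  r2 <- classify_family(c("IIA", "IIB", "IIC"), "FRU_MANNITOL")
  expect_true(r2$complete)
  r3 <- classify_family(c("IIA", "IIB", "IIC"), "FRU_MAN_SOR")
  expect_false(r3$complete)  # fru/man/sor also needs IID
  r4 <- classify_family("IIB", "FRU_MAN_SOR")
  expect_false(r4$complete)
  # IID forces the fru/man/sor family
  expect_warning(r5 <- classify_family(c("IIA", "IIB", "IIC", "IID"), "GLUCOSE"),
                 "FRU_MAN_SOR")
  expect_equal(r5$family, "FRU_MAN_SOR")
  expect_true(r5$complete)
})

make_run <- function() {
  # [IIC, IID, IIB, <hypothetical>, IIA] with small gaps, then a distant
  # orphan IIB and a second complete set far away
  ids <- c("p1", "p2", "p3", "ins", "p4", sprintf("bg%d", 1:6), "orph",
           sprintf("bg%d", 7:12), "q1", "q2", "q3", "q4")
  starts <- cumsum(c(1000, rep(400, length(ids) - 1)))  # gaps 100 < 300
  genes <- make_genes(ids, starts)
  calls <- rbind(
    data.frame(gene_id = c("p1", "p2", "p3", "p4"),
               subunits = c("IIC", "IID", "IIB", "IIA"),
               arch = c("IIC", "IID", "IIB", "IIA"), family = "FRU_MAN_SOR",
               fused = FALSE, stringsAsFactors = FALSE),
    data.frame(gene_id = "orph", subunits = "IIB", arch = "IIB",
               family = "FRU_MAN_SOR", fused = FALSE, stringsAsFactors = FALSE),
    data.frame(gene_id = c("q1", "q2", "q3", "q4"),
               subunits = c("IID", "IIC", "IIB", "IIA"),
               arch = c("IID", "IIC", "IIB", "IIA"), family = "FRU_MAN_SOR",
               fused = FALSE, stringsAsFactors = FALSE))
  list(genes = genes, calls = calls)
}

test_that("set assembly tolerates one inserted gene and isolates orphans", {
  x <- make_run()
  sets <- assemble_sets(x$genes, x$calls)
  expect_equal(nrow(sets), 3)
  s1 <- sets[1, ]
  expect_equal(set_members(s1), c("p1", "p2", "p3", "p4"))
  expect_equal(set_inserted(s1), "ins")
  expect_equal(s1$architecture, "IIC/IID/IIB/IIA")
  expect_true(s1$complete)
  expect_false(s1$orphan)
  s2 <- sets[2, ]
  expect_equal(set_members(s2), "orph")
  expect_true(s2$orphan)
  expect_false(s2$complete)
  s3 <- sets[3, ]
  expect_equal(set_members(s3), c("q1", "q2", "q3", "q4"))
  expect_equal(s3$inserted, "")
})

test_that("sets separated by many non-PTS genes are never merged", {
  ids <- c("a1", "a2", "a3", "a4", sprintf("bg%02d", 1:50), "b1", "b2", "b3", "b4")
  starts <- cumsum(c(1000, rep(350, length(ids) - 1)))
  genes <- make_genes(ids, starts)
  calls <- data.frame(gene_id = c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
                      subunits = rep(c("IIA", "IIB", "IIC", "IID"), 2),
                      arch = rep(c("IIA", "IIB", "IIC", "IID"), 2),
                      family = "FRU_MAN_SOR", fused = FALSE,
                      stringsAsFactors = FALSE)
  sets <- assemble_sets(genes, calls)
  expect_equal(nrow(sets), 2)
  expect_equal(sort(unlist(lapply(seq_len(2), function(i) set_members(sets[i, ])))),
               sort(calls$gene_id))
})

test_that("gaps above max_gap_bp break a run", {
  genes <- make_genes(c("a", "b"), c(1000, 1000 + 300 + 400))  # gap 400 bp
  calls <- data.frame(gene_id = c("a", "b"), subunits = c("IIA", "IIB"),
                      arch = c("IIA", "IIB"), family = "FRU_MAN_SOR",
                      fused = FALSE, stringsAsFactors = FALSE)
  sets <- assemble_sets(genes, calls, max_gap_bp = 300)
  expect_equal(nrow(sets), 2)
  sets2 <- assemble_sets(genes, calls, max_gap_bp = 500)
  expect_equal(nrow(sets2), 1)
})

test_that("assembly partitions PTS genes and ignores input order", {
  x <- make_run()
  sets <- assemble_sets(x$genes, x$calls)
  members <- unlist(lapply(seq_len(nrow(sets)), function(i) set_members(sets[i, ])))
  expect_equal(sort(members), sort(x$calls$gene_id))  # exactly one set each
  expect_false(anyDuplicated(members) > 0)
  set.seed(42)
  shuffled <- x$genes[sample(nrow(x$genes)), ]
  sets2 <- assemble_sets(shuffled, x$calls)
  expect_equal(sets2, sets)
  # idempotence: same inputs, same output
  expect_equal(assemble_sets(x$genes, x$calls), sets)
})

test_that("catalogue summary reports totals, positions and strand flags", {
  x <- make_run()
  sets <- assemble_sets(x$genes, x$calls)
  L <- c(G = 2 * max(x$genes$end))  # all sets in the first genome half
  summ <- catalog_summary(sets, L, x$genes)
  expect_equal(summ$genomes$n_sets, 3)
  expect_equal(summ$genomes$n_complete, 2)
  expect_equal(summ$genomes$n_orphans, 1)
  expect_equal(summ$genomes$complete_FRU_MAN_SOR, 2)
  expect_true(all(summ$sets$position > 0 & summ$sets$position < 1))
  expect_true(all(summ$sets$pos_strand_in_first_half[summ$sets$strand == "+"]))
})

test_that("empty input yields an empty set table", {
  x <- make_run()
  empty <- assemble_sets(x$genes[0, ], x$calls[0, ])
  expect_equal(nrow(empty), 0)
})
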