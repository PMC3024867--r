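test_that("two- and three-taxon NJ trees have the closed-form lengths", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- nj_tree(D)
  expect_equal(sum(tr$edge.length), 0.4)  # single edge of total length d

  D3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  D3["A", "B"] <- D3["B", "A"] <- 0.6
  D3["A", "C"] <- D3["C", "A"] <- 0.8
  D3["B", "C"] <- D3["C", "B"] <- 1.0
  tr3 <- nj_tree(D3)
  bl <- stats::setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[["A"]], (0.6 + 0.8 - 1.0) / 2)
  expect_equal(bl[["B"]], (0.6 + 1.0 - 0.8) / 2)
  expect_equal(bl[["C"]], (0.8 + 1.0 - 0.6) / 2)

  expect_error(nj_tree(matrix(0, 1, 1)), "at least 2")
  Dn <- D3; Dn["A", "B"] <- 0.7
  expect_error(nj_tree(Dn), "symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(29)
  for (rep in 1:25) {
    x <- random_additive(sample(4:16, 1))
    tr <- nj_tree(x$D)
    expect_equal(rf_distance(tr, x$tree), 0)
    P <- stats::cophenetic(tr)[rownames(x$D), colnames(x$D)]
    expect_lt(max(abs(P - x$D)), 1e-9)
  }
})

test_that("NJ topology agrees with the reference implementation", {
  set.seed(37)
  for (rep in 1:5) {
    x <- random_additive(sample(5:12, 1))
    noisy <- x$D + stats::runif(length(x$D), 0, 0.01)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    mine <- nj_tree(noisy)
    ref <- ape::nj(noisy)
    expect_equal(rf_distance(mine, ref), 0)
  }
})

test_that("NJ is deterministic", {
  set.seed(41)
  x <- random_additive(8)
  expect_identical(ape::write.tree(nj_tree(x$D)), ape::write.tree(nj_tree(x$D)))
})

test_that("RF distance matches brute-force bipartition comparison", {
  set.seed(43)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    labs <- paste0("t", seq_len(n))
    t1 <- ape::rtree(n, tip.label = labs)
    t2 <- ape::rtree(n, tip.label = labs)
    b1 <- brute_bipartitions(t1); b2 <- brute_bipartitions(t2)
    oracle <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
    expect_equal(rf_distance(t1, t2), oracle)
    if (requireNamespace("phangorn", quietly = TRUE)) {
      expect_equal(rf_distance(t1, t2),
                   as.integer(phangorn::RF.dist(t1, t2)))
    }
  }
})

test_that("RF distance behaves as a metric", {
  set.seed(47)
  labs <- paste0("t", 1:7)
  trees <- lapply(1:3, function(i) ape::rtree(7, tip.label = labs))
  expect_equal(rf_distance(trees[[1]], trees[[1]]), 0)
  expect_equal(rf_distance(trees[[1]], trees[[2]]),
               rf_distance(trees[[2]], trees[[1]]))
  d12 <- rf_distance(trees[[1]], trees[[2]])
  d23 <- rf_distance(trees[[2]], trees[[3]])
  d13 <- rf_distance(trees[[1]], trees[[3]])
  expect_lte(d13, d12 + d23)
  expect_lte(d12, 2 * (7 - 3))  # upper bound on binary trees
})

test_that("trees with different leaf sets are rejected", {
  t1 <- ape::rtree(4, tip.label = paste0("a", 1:4))
  t2 <- ape::rtree(4, tip.label = paste0("b", 1:4))
  expect_error(rf_distance(t1, t2), "leaf sets")
})

test_that("bootstrap supports are reproducible and bounded", {
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.5,(C:0.05,D:0.05):0.5);")
  set.seed(3)
  root <- paste(sample(ptsHGT:::AA_ALPHABET[1:20], 400, TRUE), collapse = "")
  seqs <- sim_sequences(tr, root, model = "poisson", rate = 1)
  aln <- progressive_msa(seqs)
  b1 <- bootstrap_support(aln, B = 50, seed = 7)
  b2 <- bootstrap_support(aln, B = 50, seed = 7)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports$support >= 0 & b1$supports$support <= 100))
  # the single internal edge separates the two simulated cherries cleanly
  expect_equal(nrow(b1$supports), 1)
  expect_gte(b1$supports$support, 90)
  expect_true(any(nzchar(b1$tree$node.label)))
})

test_that("B = 0 returns a tree without support labels", {
  aln <- c(a = "MKVLA", b = "MKVLT", c = "MKILA", d = "MRILA")
  b0 <- bootstrap_support(aln, B = 0)
  expect_true(is.null(b0$tree$node.label))
  expect_true(all(is.na(b0$supports$support)))
})

test_that("duplicate sets are detected by IIB identity and architecture", {
  prot <- paste(rep("MKVLATPLLR", 16), collapse = "")  # 160 aa
  mut <- function(aa, k) {
    r <- strsplit(aa, "")[[1]]
    pos <- round(seq(2, 158, length.out = k))
    for (p in pos) r[p] <- if (r[p] == "W") "Y" else "W"
    paste(r, collapse = "")
  }
  genes <- make_genes(c("a1", "a2", "b1", "b2", "c1", "c2"),
                      cumsum(rep(2000, 6)), lens = 480L)
  genes$aa <- c("M", prot, "M", mut(prot, 8), "M", mut(prot, 40))
  sets <- data.frame(
    set_id = c("s1", "s2", "s3"), genome_id = "G",
    architecture = c("IIA/IIB", "IIA/IIB", "IIA/IIB"),
    members = c("a1,a2", "b1,b2", "c1,c2"),
    inserted = "", stringsAsFactors = FALSE)
  dup <- detect_duplicates(sets, genes, identity_min = 90)
  d12 <- dup[dup$set_a == "s1" & dup$set_b == "s2", ]
  expect_equal(d12$verdict, "duplicate")
  expect_equal(d12$identity, 100 * (160 - 8) / 160)
  d13 <- dup[dup$set_a == "s1" & dup$set_b == "s3", ]
  expect_equal(d13$verdict, "paralog")  # 75% identity below the threshold
  # identical sets give identity 100
  sets2 <- sets[c(1, 1), ]; sets2$set_id <- c("x1", "x2")
  dup2 <- detect_duplicates(sets2, genes)
  expect_equal(dup2$identity, 100)
  expect_equal(dup2$verdict, "duplicate")
})
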