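# Independent oracles used across tests. These deliberately avoid the code
# paths they check: exhaustive enumeration for alignment and grouping,
# tree path metrics from ape for NJ additivity.

# exhaustive global alignment score with affine gaps (gap of length L
# costs open + L*ext), by direct recursion over all alignments
brute_align_score <- function(a, b, S, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, S[av[i], bv[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= n) {
      best <- max(best, -(ext + if (prev != 2L) open else 0) + rec(i + 1L, j, 2L))
    }
    if (j <= m) {
      best <- max(best, -(ext + if (prev != 1L) open else 0) + rec(i, j + 1L, 1L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# exhaustive optimal contiguous k-partition of sorted values: minimum
# within-group sum of squares over all boundary placements
brute_partition <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ss <- function(x) sum((x - mean(x))^2)
  if (k == 1) return(list(within_ss = ss(v), sizes = n))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; best_sizes <- NULL
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    tot <- 0
    for (g in seq_len(k)) tot <- tot + ss(v[(b[g] + 1):b[g + 1]])
    if (tot < best) { best <- tot; best_sizes <- diff(b) }
  }
  list(within_ss = best, sizes = best_sizes)
}

# random binary tree with strictly positive branch lengths and its exact
# additive path-metric matrix
random_additive <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
  list(tree = tr, D = stats::cophenetic(tr))
}

# exhaustive bipartition set of a tree (oracle for rf_distance)
brute_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- sort(tree$tip.label)
  n <- length(labs)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (p in pp) {
    tips <- sort(attr(pp, "labels")[p])
    if (length(tips) >= 2 && length(tips) <= n - 2) {
      side <- if (labs[1] %in% tips) sort(setdiff(labs, tips)) else tips
      out <- c(out, paste(side, collapse = "|"))
    }
  }
  unique(out)
}

# small gene table builder for catalogue/synteny tests
make_genes <- function(ids, starts, lens = 300L, strand = "+",
                       contig = "chr", genome = "G", product = "hypothetical protein",
                       nt = NULL) {
  n <- length(ids)
  lens <- rep_len(lens, n)
  strand <- rep_len(strand, n)
  product <- rep_len(product, n)
  data.frame(gene_id = ids, genome_id = genome, contig = rep_len(contig, n),
             start = starts, end = starts + lens - 1L, strand = strand,
             product = product,
             nt = if (is.null(nt)) strrep("ACGT", ceiling(lens / 4)) |>
               substr(1, lens) else nt,
             aa = NA_character_, stringsAsFactors = FALSE)
}

# domain-hit rows for a gene: one row per subunit token
make_domains <- function(gene_id, subunits, family = "FRU_MAN_SOR",
                         evalue = 1e-30) {
  v <- pts_vocab()
  starts <- seq(1, by = 200, length.out = length(subunits))
  data.frame(gene_id = gene_id,
             signature_id = vapply(subunits, function(su)
               v$signature_id[v$family == family & v$subunit == su][1], ""),
             signature_label = paste0("PTS_", subunits),
             subunit = subunits, family = family,
             aa_start = starts, aa_end = starts + 150L, evalue = evalue,
             stringsAsFactors = FALSE)
}
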