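# Neighbour-joining tree construction, bipartition machinery, bootstrap
# support and Robinson-Foulds distance. Trees are ape "phylo" objects
# throughout; NJ output is unrooted (trifurcating root node for n >= 3).

check_dist <- function(D) {
  if (!is.matrix(D)) D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(!is.finite(D))) stop("non-finite distances")
  if (any(D < 0)) stop("negative distances")
  D
}

fmt_bl <- function(x) sprintf("%.15g", x)

#' Neighbour-joining tree from a distance matrix
#'
#' Classic NJ: repeatedly join the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths `l_i = d(i,j)/2 + (R_i - R_j)/(2(n-2))` and reduced distances
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j))/2`. Ties in Q are broken by the
#' smallest (i, j) index pair in the current matrix order; negative branch
#' length estimates are clamped to zero with a message. On an additive
#' matrix the output tree's path metric reproduces the input exactly.
#'
#' @param D symmetric distance matrix with labelled rows/columns.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- check_dist(D)
  labels <- rownames(D)
  n <- nrow(D)
  clamp <- function(x) {
    if (x < 0) {
      message("negative NJ branch length ", format(x, digits = 4),
              " clamped to 0")
      0
    } else x
  }
  if (n == 2L) {
    h <- D[1, 2] / 2
    txt <- paste0("(", labels[1], ":", fmt_bl(h), ",",
                  labels[2], ":", fmt_bl(h), ");")
    return(ape::read.tree(text = txt))
  }
  node <- labels  # newick fragment per active cluster
  while (length(node) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # smallest Q; ties -> smallest (i, j) with i < j in current order
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
      }
    }
    li <- clamp(D[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (m - 2)))
    lj <- clamp(D[bi, bj] - (D[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (m - 2))))
    newd <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
    merged <- paste0("(", node[bi], ":", fmt_bl(li), ",",
                     node[bj], ":", fmt_bl(lj), ")")
    keep <- setdiff(seq_len(m), c(bi, bj))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    node <- c(node[keep], merged)
    rownames(D2) <- colnames(D2) <- paste0("c", seq_len(m - 1))
    D <- D2
  }
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- paste0("(", node[1], ":", fmt_bl(l1), ",", node[2], ":", fmt_bl(l2),
                ",", node[3], ":", fmt_bl(l3), ");")
  ape::read.tree(text = txt)
}

#' NJ binary join order (guide-tree order for progressive alignment)
#'
#' Runs the NJ agglomeration on `D` and returns the sequence of n-1 binary
#' joins. Leaves are ids 1..n; the cluster created by the k-th join has id
#' n+k. The final three clusters are joined closest-pair-first.
#'
#' @param D symmetric distance matrix.
#' @return list of length-2 integer vectors.
#' @keywords internal
nj_join_order <- function(D) {
  D <- check_dist(D)
  n <- nrow(D)
  ids <- seq_len(n)
  joins <- list()
  nextid <- n
  while (length(ids) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
      }
    }
    nextid <- nextid + 1L
    joins[[length(joins) + 1L]] <- c(ids[bi], ids[bj])
    newd <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
    keep <- setdiff(seq_len(m), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    rownames(D) <- colnames(D) <- NULL
    ids <- c(ids[keep], nextid)
  }
  while (length(ids) > 1L) {
    if (length(ids) >= 3L) {
      m <- nrow(D)
      best <- Inf; bi <- 1L; bj <- 2L
      for (i in seq_len(m - 1)) {
        for (j in (i + 1):m) {
          if (D[i, j] < best - 1e-12) { best <- D[i, j]; bi <- i; bj <- j }
        }
      }
    } else { bi <- 1L; bj <- 2L }
    nextid <- nextid + 1L
    joins[[length(joins) + 1L]] <- c(ids[bi], ids[bj])
    if (length(ids) > 2L) {
      newd <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
      keep <- setdiff(seq_len(nrow(D)), c(bi, bj))
      D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
      ids <- c(ids[keep], nextid)
    } else {
      ids <- nextid
    }
  }
  joins
}

# Tip-label sets below each internal edge (child side), trivial sides
# excluded. The workhorse for bootstrap supports, RF distance and the
# clade-composition tests.
bip_sides <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  if (is.null(tree$edge) || tree$Nnode < 2L) return(list())
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::postorder(tree)
  for (e in po) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- n + 1L
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch > n) {
      tips <- sort(tree$tip.label[desc[[ch]]])
      if (length(tips) >= 2L && length(tips) <= n - 2L) {
        out[[length(out) + 1L]] <- list(node = ch, tips = tips)
      }
    }
  }
  out
}

canon_bip <- function(tips, all_labels) {
  # canonical side: the one NOT containing the alphabetically first label
  first <- sort(all_labels)[1]
  side <- if (first %in% tips) sort(setdiff(all_labels, tips)) else tips
  paste(side, collapse = "|")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' @param tree an [ape::phylo] tree.
#' @return character vector of canonical bipartition strings.
#' @export
bipartitions <- function(tree) {
  sides <- bip_sides(tree)
  labs <- tree$tip.label
  unique(vapply(sides, function(s) canon_bip(s$tips, labs), ""))
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets.
#' Both trees must share the same leaf set.
#'
#' @param t1,t2 [ape::phylo] trees on the same labels.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the
#' distance matrix and NJ tree for each replicate, and reports for each
#' internal edge of the reference tree the percentage of replicates
#' containing the same leaf bipartition. Reproducible given `seed`.
#'
#' @param alignment named character vector of equal-length gapped rows.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @param model `"poisson"` for Poisson-corrected distances, `"p"` for raw
#'   p-distances.
#' @return list(tree = reference tree with supports as internal node
#'   labels, supports = data.frame(bipartition, support)).
#' @export
bootstrap_support <- function(alignment, B = 500L, seed = NULL,
                              model = c("poisson", "p")) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  M <- aln_matrix(alignment)
  labs <- names(alignment)
  n <- nrow(M)
  dist_of <- function(Mat) {
    D <- matrix(0, n, n, dimnames = list(labs, labs))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        keep <- Mat[i, ] != "-" & Mat[j, ] != "-"
        if (!any(keep)) stop("no comparable columns in replicate")
        p <- mean(Mat[i, keep] != Mat[j, keep])
        D[i, j] <- D[j, i] <- if (model == "poisson")
          as.numeric(poisson_distance(p)) else p
      }
    }
    D
  }
  ref <- nj_tree(dist_of(M))
  refbips <- bipartitions(ref)
  counts <- stats::setNames(numeric(length(refbips)), refbips)
  if (B > 0L) {
    for (b in seq_len(B)) {
      cols <- sample.int(ncol(M), replace = TRUE)
      bips <- bipartitions(nj_tree(dist_of(M[, cols, drop = FALSE])))
      hit <- refbips %in% bips
      counts[hit] <- counts[hit] + 1
    }
    supports <- 100 * counts / B
  } else {
    supports <- stats::setNames(rep(NA_real_, length(refbips)), refbips)
  }
  # attach supports as internal-node labels of the reference tree
  sides <- bip_sides(ref)
  node_lab <- rep("", ref$Nnode)
  for (s in sides) {
    key <- canon_bip(s$tips, ref$tip.label)
    if (key %in% names(supports) && !is.na(supports[key])) {
      node_lab[s$node - length(ref$tip.label)] <- format(supports[key],
                                                         digits = 4)
    }
  }
  if (B > 0L) ref$node.label <- node_lab
  list(tree = ref,
       supports = data.frame(bipartition = refbips,
                             support = unname(supports),
                             stringsAsFactors = FALSE))
}

#' Detect duplicated PTS gene sets within genomes
#'
#' Same-genome set pairs are compared on their substrate-specificity (IIB)
#' subunit: pairs whose globally aligned IIB protein identity reaches
#' `identity_min` and (optionally) whose architectures match up to a
#' strand-flip reversal are called duplicates; high-identity pairs failing
#' the threshold are reported as paralogs.
#'
#' @param sets set table from [assemble_sets()].
#' @param genes gene table with `aa` sequences.
#' @param identity_min percent identity threshold for a duplicate call.
#' @param require_architecture_match require [shared_architecture()] too.
#' @return data.frame of compared pairs with identity, architecture_match
#'   and verdict ("duplicate" or "paralog").
#' @export
detect_duplicates <- function(sets, genes, identity_min = 90,
                              require_architecture_match = TRUE) {
  iib_gene <- function(set_row) {
    mem <- set_members(set_row)
    toks <- strsplit(set_row$architecture, "/", fixed = TRUE)[[1]]
    hit <- grepl("B", substring(toks, 3L))
    if (!any(hit)) return(NA_character_)
    mem[which(hit)[1]]
  }
  out <- list()
  for (g in unique(sets$genome_id)) {
    s <- sets[sets$genome_id == g, , drop = FALSE]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1)) {
      for (j in (i + 1):nrow(s)) {
        ga <- iib_gene(s[i, ]); gb <- iib_gene(s[j, ])
        if (is.na(ga) || is.na(gb)) next
        aa_a <- genes$aa[match(ga, genes$gene_id)]
        aa_b <- genes$aa[match(gb, genes$gene_id)]
        if (is.na(aa_a) || is.na(aa_b)) next
        al <- nw_align(aa_a, aa_b)
        arch <- shared_architecture(s[i, ], s[j, ])
        dup <- al$identity >= identity_min &&
          (!require_architecture_match || arch$architecture_match)
        out[[length(out) + 1L]] <- data.frame(
          genome_id = g, set_a = s$set_id[i], set_b = s$set_id[j],
          gene_a = ga, gene_b = gb, identity = al$identity,
          architecture_match = arch$architecture_match,
          verdict = if (dup) "duplicate" else "paralog",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(genome_id = character(0), set_a = character(0),
                      set_b = character(0), gene_a = character(0),
                      gene_b = character(0), identity = numeric(0),
                      architecture_match = logical(0), verdict = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
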