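# Pairwise and progressive multiple alignment, and alignment-based
# distances. Pairwise alignment is global with affine gaps (Gotoh); the
# default protein scoring mirrors blastp defaults (BLOSUM62, gap open 11,
# gap extend 1, a length-L gap costing 11 + L).

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.matrix_cache <- new.env(parent = emptyenv())

#' Protein scoring matrix (BLOSUM62 with X scoring 0)
#' @keywords internal
blosum62x <- function() {
  if (!is.null(.matrix_cache$blosum)) return(.matrix_cache$blosum)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  S["X", ] <- 0
  S[, "X"] <- 0
  .matrix_cache$blosum <- S
  S
}

dna_matrix <- function(match = 5, mismatch = -4) {
  S <- matrix(mismatch, 5, 5, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(S) <- match
  S["N", ] <- 0
  S[, "N"] <- 0
  S
}

seq_to_idx <- function(s, alphabet) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet)
  idx[is.na(idx)] <- length(alphabet)  # unknown residue -> X / N
  idx - 1L  # 0-based for C++
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment. For proteins the default
#' scoring is BLOSUM62 (X scores 0 against everything) with gap open 11 and
#' gap extend 1. Identity is 100 * matches / aligned columns; positives is
#' 100 * (columns with positive substitution score) / aligned columns (gap
#' columns count in the denominator only). The traceback is deterministic:
#' ties prefer match/mismatch over gap-in-a over gap-in-b.
#'
#' @param a,b sequences (character scalars).
#' @param type `"protein"` or `"dna"`.
#' @param gap_open,gap_extend affine gap parameters; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param matrix optional custom scoring matrix with dimnames covering the
#'   alphabet.
#' @return list(score, aligned_a, aligned_b, identity, positives, length).
#' @export
nw_align <- function(a, b, type = c("protein", "dna"), gap_open = 11,
                     gap_extend = 1, matrix = NULL) {
  type <- match.arg(type)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  alphabet <- if (type == "protein") AA_ALPHABET else DNA_ALPHABET
  S <- if (!is.null(matrix)) matrix[alphabet, alphabet]
       else if (type == "protein") blosum62x() else dna_matrix()
  ai <- seq_to_idx(a, alphabet)
  bi <- seq_to_idx(b, alphabet)
  r <- gotoh_align_cpp(ai, bi, S, gap_open, gap_extend)
  ach <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bch <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  col_a <- ifelse(r$path_a == 0L, "-", ach[pmax(r$path_a, 1L)])
  col_b <- ifelse(r$path_b == 0L, "-", bch[pmax(r$path_b, 1L)])
  ncol <- length(col_a)
  res_cols <- r$path_a > 0L & r$path_b > 0L
  matches <- sum(res_cols & col_a == col_b)
  pos <- sum(S[cbind(ai[r$path_a[res_cols]] + 1L,
                     bi[r$path_b[res_cols]] + 1L)] > 0)
  list(score = r$score,
       aligned_a = paste(col_a, collapse = ""),
       aligned_b = paste(col_b, collapse = ""),
       identity = 100 * matches / ncol,
       positives = 100 * pos / ncol,
       length = ncol)
}

aln_matrix <- function(alignment) {
  stopifnot(length(unique(nchar(alignment))) == 1L)
  do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
}

#' Observed proportion of differing sites (p-distance)
#'
#' Pairwise deletion: columns with a gap in either row are skipped.
#'
#' @param row_i,row_j equal-length gapped sequences.
#' @return p in `[0, 1]`.
#' @export
pdistance <- function(row_i, row_j) {
  x <- strsplit(toupper(row_i), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(row_j), "", fixed = TRUE)[[1]]
  stopifnot(length(x) == length(y))
  keep <- x != "-" & y != "-"
  if (!any(keep)) stop("no comparable columns (all-gap overlap)")
  mean(x[keep] != y[keep])
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param alignment named character vector of equal-length gapped rows.
#' @return symmetric matrix of p-distances with zero diagonal.
#' @export
pdist_matrix <- function(alignment) {
  M <- aln_matrix(alignment)
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- M[i, ] != "-" & M[j, ] != "-"
      if (!any(keep)) stop("no comparable columns between ",
                           names(alignment)[i], " and ", names(alignment)[j])
      D[i, j] <- D[j, i] <- mean(M[i, keep] != M[j, keep])
    }
  }
  D
}

#' Poisson-corrected protein distance
#'
#' `d = -ln(1 - p)`, correcting the observed proportion of differences for
#' multiple substitutions. Saturated inputs (p >= 1) are set to `ceiling`
#' and flagged via the "saturated" attribute.
#'
#' @param p observed proportion(s) of differences.
#' @param ceiling distance assigned to saturated pairs.
#' @return corrected distance(s), attribute "saturated" marking p >= 1.
#' @export
poisson_distance <- function(p, ceiling = 5) {
  sat <- p >= 1
  d <- ifelse(sat, ceiling, -log(1 - pmin(p, 1 - 1e-12)))
  d[!sat] <- -log(1 - p[!sat])
  attr(d, "saturated") <- sat
  d
}

profile_of <- function(alignment, alphabet) {
  M <- aln_matrix(alignment)
  K <- length(alphabet)
  P <- matrix(0, ncol(M), K)
  nr <- nrow(M)
  for (k in seq_len(K)) P[, k] <- colSums(M == alphabet[k]) / nr
  P  # gap mass excluded: rows need not sum to 1
}

merge_profiles <- function(alnA, alnB, S, alphabet, gap_open, gap_extend) {
  PA <- profile_of(alnA, alphabet)
  PB <- profile_of(alnB, alphabet)
  r <- profile_align_cpp(PA, PB, S, gap_open, gap_extend)
  expand <- function(aln, path) {
    M <- aln_matrix(aln)
    out <- matrix("-", nrow(M), length(path))
    out[, path > 0L] <- M[, path[path > 0L], drop = FALSE]
    stats::setNames(apply(out, 1, paste, collapse = ""), names(aln))
  }
  c(expand(alnA, r$path_a), expand(alnB, r$path_b))
}

#' Progressive multiple sequence alignment
#'
#' Guide tree: neighbour-joining on pairwise p-distances taken from global
#' pairwise alignments; profiles are then merged in the NJ join order using
#' profile-profile Gotoh alignment with expected sum-of-pairs scoring.
#' Deterministic given input order.
#'
#' @param seqs named character vector of unaligned sequences.
#' @inheritParams nw_align
#' @return named character vector of equal-length aligned rows (input
#'   order preserved).
#' @export
progressive_msa <- function(seqs, type = c("protein", "dna"), gap_open = 11,
                            gap_extend = 1) {
  type <- match.arg(type)
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  n <- length(seqs)
  if (n == 1L) return(seqs)
  alphabet <- if (type == "protein") AA_ALPHABET else DNA_ALPHABET
  S <- if (type == "protein") blosum62x() else dna_matrix()
  if (n == 2L) {
    r <- nw_align(seqs[1], seqs[2], type, gap_open, gap_extend)
    return(stats::setNames(c(r$aligned_a, r$aligned_b), names(seqs)))
  }
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- nw_align(seqs[i], seqs[j], type, gap_open, gap_extend)
      D[i, j] <- D[j, i] <- pdistance(r$aligned_a, r$aligned_b)
    }
  }
  joins <- nj_join_order(D)  # n-1 binary joins; merged cluster k gets id n+k
  clusters <- lapply(seq_len(n), function(i) seqs[i])
  for (k in seq_along(joins)) {
    jn <- joins[[k]]
    clusters[[n + k]] <- merge_profiles(clusters[[jn[1]]], clusters[[jn[2]]],
                                        S, alphabet, gap_open, gap_extend)
  }
  final <- clusters[[n + length(joins)]]
  final[names(seqs)]
}
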