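# GC statistics of genes, gene sets and genomes, exact 1-D grouping of set
# GC values, and GC-anomaly scoring. GC is computed on coding-strand CDS
# concatenations; ambiguity codes (N etc.) count in the denominator only.

#' GC content of a nucleotide sequence, in percent
#'
#' `100 * (#G + #C) / length`. Ambiguity codes contribute to the length but
#' never to the GC count, so gc_percent("GCAN") is 50.
#'
#' @param seq nucleotide string (case-insensitive).
#' @return GC percentage on the 0-100 scale.
#' @export
gc_percent <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("gc_percent needs one non-empty sequence")
  }
  100 * nchar(gsub("[^GCgc]", "", seq)) / nchar(seq)
}

#' Length-weighted GC content of a PTS gene set
#'
#' GC of the concatenated coding sequences of the set members, optionally
#' including tolerated inserted (non-PTS) genes. Concatenation makes the
#' value the length-weighted mean of the member GC percentages.
#'
#' @param set_row one row of a set table (see [assemble_sets()]).
#' @param genes gene table with `gene_id` and `nt` columns.
#' @param include_inserted include inserted non-PTS members in the
#'   concatenation.
#' @return GC percentage (full precision; round only at report time).
#' @export
set_gc <- function(set_row, genes, include_inserted = FALSE) {
  ids <- set_members(set_row)
  if (include_inserted) ids <- c(ids, set_inserted(set_row))
  nt <- genes$nt[match(ids, genes$gene_id)]
  if (anyNA(nt)) {
    stop("missing nucleotide sequence for gene(s): ",
         paste(ids[is.na(nt)], collapse = ", "))
  }
  gc_percent(paste(nt, collapse = ""))
}

#' Genome GC baseline
#'
#' Whole-genome GC over the concatenated contigs plus the mean and standard
#' deviation of the per-gene GC distribution over all CDS; that per-gene
#' distribution is the baseline against which set GC anomalies are scored.
#'
#' @param contigs named character vector of contig sequences.
#' @param genes gene table with an `nt` column.
#' @return list(genome_gc, gene_mean, gene_sd, n_genes).
#' @export
genome_baseline <- function(contigs, genes) {
  genome_gc <- gc_percent(paste(contigs, collapse = ""))
  gvals <- vapply(genes$nt[!is.na(genes$nt)], gc_percent, 0)
  sd <- stats::sd(gvals)
  if (length(gvals) > 1L && (is.na(sd) || sd == 0)) {
    warning("degenerate per-gene GC distribution (sd = 0); z-scores undefined")
  }
  list(genome_gc = genome_gc, gene_mean = mean(gvals), gene_sd = sd,
       n_genes = length(gvals))
}

sum_sq_segment <- function(pref, pref2, i, j) {
  # within-segment sum of squares of sorted values i..j via prefix sums
  n <- j - i + 1
  s <- pref[j + 1] - pref[i]
  s2 <- pref2[j + 1] - pref2[i]
  s2 - s * s / n
}

#' Optimal contiguous grouping of 1-D values
#'
#' Exact optimal partition of the sorted values into `k` contiguous groups
#' minimizing the total within-group sum of squared deviations, found by
#' dynamic programming. Ties are broken by preferring boundaries at the
#' largest gaps between consecutive sorted values, then the leftmost
#' boundary.
#'
#' @param values numeric vector (e.g. per-set GC percentages).
#' @param k number of groups, `1 <= k <= length(values)`.
#' @param ids optional entity identifiers parallel to `values`.
#' @return object of class `gc_grouping`: list with `k`, `ids`, `values`
#'   (sorted), `assignment` (group index per *input* element), `boundaries`
#'   (last sorted index of each group) and `within_ss`.
#' @export
group_gc <- function(values, k, ids = NULL) {
  n <- length(values)
  if (k > n) stop("k (", k, ") exceeds number of values (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(values)
  v <- values[ord]
  pref <- c(0, cumsum(v))
  pref2 <- c(0, cumsum(v^2))
  gap_before <- c(NA_real_, diff(v))  # gap_before[i] = v[i] - v[i-1]
  # C[i, m]: min cost of first i sorted values in m groups; B: chosen split
  C <- matrix(Inf, n + 1, k)
  B <- matrix(NA_integer_, n + 1, k)
  C[1, ] <- 0  # zero values cost 0 (unused except as DP base)
  for (i in seq_len(n)) C[i + 1, 1] <- sum_sq_segment(pref, pref2, 1, i)
  if (k > 1) {
    for (m in 2:k) {
      for (i in m:n) {
        best <- Inf; bestj <- NA_integer_; bestgap <- -Inf
        for (j in m:i) {
          # last group = sorted j..i
          cost <- C[j, m - 1] + sum_sq_segment(pref, pref2, j, i)
          g <- gap_before[j]
          better <- cost < best - 1e-12 ||
            (abs(cost - best) <= 1e-12 &&
               (g > bestgap + 1e-12 ||
                  (abs(g - bestgap) <= 1e-12 && j < bestj)))
          if (better) { best <- cost; bestj <- j; bestgap <- g }
        }
        C[i + 1, m] <- best
        B[i + 1, m] <- bestj
      }
    }
  }
  # recover boundaries
  bounds <- integer(k)
  i <- n
  for (m in k:1) {
    bounds[m] <- i
    if (m > 1) i <- B[i + 1, m] - 1L
  }
  grp_sorted <- rep(seq_len(k), times = diff(c(0L, bounds)))
  assignment <- integer(n)
  assignment[ord] <- grp_sorted
  structure(list(k = k, ids = ids, order = ord, values = v,
                 assignment = assignment, boundaries = bounds,
                 within_ss = C[n + 1, k]),
            class = "gc_grouping")
}

#' @export
print.gc_grouping <- function(x, ...) {
  cat("Optimal contiguous grouping: k =", x$k,
      " within-SS =", format(x$within_ss, digits = 6), "\n")
  for (g in seq_len(x$k)) {
    idx <- which(x$assignment[x$order] == g)
    cat(sprintf("  group %d: %s\n", g,
                paste(format(x$values[idx], digits = 4), collapse = ", ")))
  }
  invisible(x)
}

#' GC anomaly of a gene set against its host-genome baseline
#'
#' z-score of the set GC against the per-gene GC distribution of the host
#' genome; the direction compares against whole-genome GC.
#'
#' @param set_gc_percent set GC (0-100).
#' @param baseline output of [genome_baseline()].
#' @return list(z, direction) with direction "above"/"below"/"equal".
#' @export
gc_anomaly <- function(set_gc_percent, baseline) {
  z <- if (is.na(baseline$gene_sd) || baseline$gene_sd == 0) NA_real_ else
    (set_gc_percent - baseline$gene_mean) / baseline$gene_sd
  direction <- if (set_gc_percent > baseline$genome_gc) "above"
  else if (set_gc_percent < baseline$genome_gc) "below" else "equal"
  list(z = z, direction = direction)
}
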