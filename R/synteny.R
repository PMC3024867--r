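# Neighbourhood analysis of PTS gene sets: the 4 flanking genes on each
# side are scanned for regulatory (sigma-54), metabolic (sugar isomerase)
# and mobility (transposase / insertion sequence) markers, and set
# architectures are compared across sets.

#' Extract the flanking-gene context of a gene set
#'
#' Up to `window` genes on each flank, on the same contig, excluding the
#' set's own members and inserted genes; truncated silently at contig ends.
#'
#' @param set_row one row of the set table.
#' @param genes gene table.
#' @param window flank size in genes.
#' @return list(set_id, upstream, downstream) with gene-table subsets;
#'   upstream genes lie before the set start in genome coordinates.
#' @export
extract_context <- function(set_row, genes, window = 4L) {
  g <- genes[genes$contig == set_row$contig, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  own <- c(set_members(set_row), set_inserted(set_row))
  idx <- which(g$gene_id %in% own)
  before <- g[seq_len(min(idx) - 1L), , drop = FALSE]
  before <- before[!before$gene_id %in% own, , drop = FALSE]
  after <- if (max(idx) < nrow(g)) g[(max(idx) + 1L):nrow(g), , drop = FALSE]
           else g[0, , drop = FALSE]
  after <- after[!after$gene_id %in% own, , drop = FALSE]
  up <- utils::tail(before, window)
  down <- utils::head(after, window)
  list(set_id = set_row$set_id, upstream = up, downstream = down)
}

#' Detect synteny markers in a set's neighbourhood
#'
#' A marker fires if any neighbourhood gene matches by domain label
#' (preferred) or, as a fallback, by case-insensitive product regex.
#' Insertion-sequence evidence distinguishes `flanked_by_IS` (matches on
#' both flanks) from `is_adjacent` (one flank only). The synteny class is a
#' pure function of the sigma-54 and SIS flags: BOTH, SIGMA54_ONLY, OTHER
#' (SIS without sigma-54) or NEITHER.
#'
#' @param context output of [extract_context()].
#' @param domains domain-hit table (for the domain-label evidence).
#' @param vocab marker vocabulary (see [marker_vocab()]).
#' @return list with flags sigma54, sis, is_adjacent, flanked_by_IS, the
#'   supporting gene ids per marker, and synteny_class.
#' @export
detect_markers <- function(context, domains = NULL, vocab = marker_vocab()) {
  match_genes <- function(flank, marker) {
    row <- vocab[vocab$marker == marker, , drop = FALSE]
    if (nrow(row) == 0L || nrow(flank) == 0L) return(character(0))
    hit <- rep(FALSE, nrow(flank))
    if (!is.null(domains) && nrow(domains) > 0L) {
      lab_genes <- domains$gene_id[domains$signature_label %in% row$domain_label]
      hit <- hit | flank$gene_id %in% lab_genes
    }
    prod <- ifelse(is.na(flank$product), "", flank$product)
    hit <- hit | grepl(row$product_regex[1], prod, ignore.case = TRUE,
                       perl = TRUE)
    flank$gene_id[hit]
  }
  up <- context$upstream; down <- context$downstream
  res <- list(set_id = context$set_id)
  for (mk in c("sigma54", "sis", "is_element")) {
    u <- match_genes(up, mk); d <- match_genes(down, mk)
    res[[paste0(mk, "_genes")]] <- c(u, d)
    if (mk == "is_element") {
      res$flanked_by_IS <- length(u) > 0L && length(d) > 0L
      res$is_adjacent <- xor(length(u) > 0L, length(d) > 0L)
    } else {
      res[[mk]] <- length(c(u, d)) > 0L
    }
  }
  res$synteny_class <- synteny_class(res$sigma54, res$sis)
  res
}

#' Synteny class from the sigma-54 and SIS flags
#' @param sigma54,sis logical flags.
#' @return one of "BOTH", "SIGMA54_ONLY", "OTHER", "NEITHER".
#' @export
synteny_class <- function(sigma54, sis) {
  if (sigma54 && sis) "BOTH"
  else if (sigma54) "SIGMA54_ONLY"
  else if (sis) "OTHER"
  else "NEITHER"
}

flip_architecture <- function(arch) {
  paste(rev(strsplit(arch, "/", fixed = TRUE)[[1]]), collapse = "/")
}

#' Compare the genetic organization of two gene sets
#'
#' Architectures match when the architecture strings are equal, or equal
#' after reversing the gene order (sets read on opposite strands traverse
#' their genes in opposite genomic order; the within-gene domain order is
#' unchanged because it is a property of the protein).
#'
#' @param setA,setB rows of the set table (optionally carrying
#'   `synteny_class` and marker columns for the class/marker comparisons).
#' @return list(architecture_match, class_match, markers_match); the last
#'   two are NA when the class/marker columns are absent.
#' @export
shared_architecture <- function(setA, setB) {
  a <- setA$architecture; b <- setB$architecture
  arch_match <- identical(a, b) || identical(a, flip_architecture(b))
  cls <- function(s) if (!is.null(s$synteny_class)) s$synteny_class else NA
  class_match <- if (is.na(cls(setA)) || is.na(cls(setB))) NA
                 else cls(setA) == cls(setB)
  mk <- function(s) {
    if (is.null(s$flanked_by_IS)) return(NA)
    paste(s$sigma54, s$sis, s$flanked_by_IS)
  }
  markers_match <- if (is.na(mk(setA)) || is.na(mk(setB))) NA
                   else mk(setA) == mk(setB)
  list(architecture_match = arch_match, class_match = class_match,
       markers_match = markers_match)
}
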