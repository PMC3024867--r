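# File readers/writers for every external format the pipeline touches.
# Coordinates are 1-based inclusive throughout (GFF3 convention); locus tags
# are the join key between gene table, protein FASTA and domain TSV.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; duplicate headers are an error. Only the first
#' whitespace-delimited token of each header is kept as the identifier.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA header at line ", nonblank[1], " of ", path)
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  stats::setNames(toupper(as.character(x)), ids)
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width in characters.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' Handles A/C/G/T/N and lowercase; other IUPAC codes pass through via
#' complementation of the standard table.
#'
#' @param seq nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTacgtRYKMrykm", "TGCAtgcaYRMKyrmk",
         vapply(seq, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                       collapse = ""), "", USE.NAMES = FALSE))
}

#' Read an annotated gene table (GFF3 CDS features or plain TSV)
#'
#' GFF3 input keeps CDS features carrying a `locus_tag` attribute; features
#' without one are skipped with a warning. The TSV dialect expects columns
#' `gene_id`, `contig`, `start`, `end`, `strand`, `product`. When `contigs`
#' is supplied, the coding-strand nucleotide sequence is extracted (reverse
#' complement for strand `-`); when `proteins` is supplied, amino-acid
#' sequences are joined by locus tag (proteins without a matching gene are
#' dropped with a warning).
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param contigs optional named character vector of contig sequences.
#' @param proteins optional named character vector of protein sequences.
#' @param genome_id genome identifier attached to every record.
#' @return data.frame sorted by (contig, start) with columns gene_id,
#'   genome_id, contig, start, end, strand, product, nt, aa.
#' @export
read_gene_table <- function(path, dialect = c("gff3", "tsv"), contigs = NULL,
                            proteins = NULL, genome_id = "genome") {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    df <- df[df$type == "CDS", , drop = FALSE]
    if (nrow(df) > 0L && is.null(df$locus_tag)) df$locus_tag <- NA_character_
    miss <- is.na(df$locus_tag)
    if (any(miss)) {
      warning(sum(miss), " CDS feature(s) without locus_tag skipped")
      df <- df[!miss, , drop = FALSE]
    }
    if (nrow(df) == 0L) {
      warning("no CDS features with locus_tag in ", path)
      return(data.frame(gene_id = character(0), genome_id = character(0),
                        contig = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        product = character(0), nt = character(0),
                        aa = character(0), stringsAsFactors = FALSE))
    }
    genes <- data.frame(
      gene_id = as.character(df$locus_tag),
      genome_id = genome_id,
      contig = as.character(df$seqnames),
      start = as.integer(df$start),
      end = as.integer(df$end),
      strand = as.character(df$strand),
      product = if (is.null(df$product)) NA_character_ else as.character(df$product),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "contig", "start", "end", "strand")
    if (!all(need %in% names(tab))) {
      stop("TSV gene table must have columns: ", paste(need, collapse = ", "))
    }
    genes <- data.frame(
      gene_id = as.character(tab$gene_id),
      genome_id = genome_id,
      contig = as.character(tab$contig),
      start = as.integer(tab$start),
      end = as.integer(tab$end),
      strand = as.character(tab$strand),
      product = if (is.null(tab$product)) NA_character_ else as.character(tab$product),
      stringsAsFactors = FALSE
    )
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$gene_id[genes$start > genes$end]
    stop("start > end for gene(s): ", paste(bad, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes$nt <- NA_character_
  if (!is.null(contigs)) {
    unknown <- setdiff(unique(genes$contig), names(contigs))
    if (length(unknown) > 0L) {
      stop("gene contig(s) not in contig FASTA: ", paste(unknown, collapse = ", "))
    }
    genes$nt <- vapply(seq_len(nrow(genes)), function(i) {
      s <- substr(contigs[[genes$contig[i]]], genes$start[i], genes$end[i])
      if (genes$strand[i] == "-") revcomp(s) else s
    }, "")
  }
  genes$aa <- NA_character_
  if (!is.null(proteins)) {
    orphan_prot <- setdiff(names(proteins), genes$gene_id)
    if (length(orphan_prot) > 0L) {
      warning("protein(s) without a matching gene dropped: ",
              paste(utils::head(orphan_prot, 5), collapse = ", "),
              if (length(orphan_prot) > 5) " ...")
    }
    hit <- genes$gene_id %in% names(proteins)
    genes$aa[hit] <- unname(proteins[genes$gene_id[hit]])
  }
  genes
}

#' Read a domain-annotation table (InterProScan-style TSV)
#'
#' Two dialects are accepted: a headered TSV with columns `gene_id`,
#' `signature_id`, `description`, `aa_start`, `aa_end`, `evalue`, or the
#' headerless InterProScan column order (protein, md5, length, analysis,
#' signature accession, description, start, end, e-value, ...). Signatures
#' are mapped to normalized labels through the controlled vocabulary; hits
#' above the e-value threshold are dropped.
#'
#' @param path input TSV.
#' @param vocab domain vocabulary data.frame (see [pts_vocab()]).
#' @param evalue_max e-value threshold; hits with larger e-values are dropped.
#' @return data.frame with gene_id, signature_id, signature_label, subunit,
#'   family, aa_start, aa_end, evalue.
#' @export
read_domain_tsv <- function(path, vocab = pts_vocab(), evalue_max = 1e-5) {
  empty <- data.frame(gene_id = character(0), signature_id = character(0),
                      signature_label = character(0), subunit = character(0),
                      family = character(0), aa_start = integer(0),
                      aa_end = integer(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(empty)
  first <- readLines(path, n = 1L, warn = FALSE)
  headered <- grepl("\\bgene_id\\b", first)
  if (headered) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    hits <- data.frame(gene_id = as.character(tab$gene_id),
                       signature_id = as.character(tab$signature_id),
                       aa_start = as.integer(tab$aa_start),
                       aa_end = as.integer(tab$aa_end),
                       evalue_raw = as.character(tab$evalue),
                       stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 9L) stop("domain TSV needs >= 9 columns (InterProScan order)")
    hits <- data.frame(gene_id = as.character(tab[[1]]),
                       signature_id = as.character(tab[[5]]),
                       aa_start = as.integer(tab[[7]]),
                       aa_end = as.integer(tab[[8]]),
                       evalue_raw = as.character(tab[[9]]),
                       stringsAsFactors = FALSE)
  }
  if (nrow(hits) == 0L) return(empty)
  ev <- suppressWarnings(as.numeric(hits$evalue_raw))
  if (anyNA(ev)) {
    stop("non-numeric e-value(s) in ", path, ": ",
         paste(unique(hits$evalue_raw[is.na(ev)]), collapse = ", "))
  }
  hits$evalue <- ev
  hits$evalue_raw <- NULL
  if (any(hits$evalue < 0)) stop("negative e-value in ", path)
  if (any(hits$aa_start > hits$aa_end)) stop("aa_start > aa_end in ", path)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  label_domains(hits, vocab)
}

#' Map domain hits to normalized labels via the controlled vocabulary
#'
#' Adds `signature_label` (OTHER for unmapped signatures), `subunit` and
#' `family` columns; idempotent on already-labelled tables.
#'
#' @param hits data.frame with at least gene_id, signature_id, aa_start,
#'   aa_end, evalue.
#' @param vocab vocabulary from [pts_vocab()].
#' @return labelled data.frame.
#' @export
label_domains <- function(hits, vocab = pts_vocab()) {
  m <- match(hits$signature_id, vocab$signature_id)
  hits$signature_label <- ifelse(is.na(m), "OTHER", vocab$label[m])
  hits$subunit <- ifelse(is.na(m), NA_character_, vocab$subunit[m])
  hits$subunit[!is.na(hits$subunit) & hits$subunit == ""] <- NA_character_
  hits$family <- ifelse(is.na(m), NA_character_, vocab$family[m])
  hits$family[!is.na(hits$family) & hits$family == ""] <- NA_character_
  rownames(hits) <- NULL
  hits[, c("gene_id", "signature_id", "signature_label", "subunit", "family",
           "aa_start", "aa_end", "evalue")]
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that keep
#' branch lengths and internal-node support labels and fail loudly on
#' malformed input.
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  no_paren <- gsub("[^()]", "", txt)
  open <- sum(strsplit(no_paren, "")[[1]] == "(")
  close <- nchar(no_paren) - open
  if (open != close) {
    stop("unbalanced parentheses in ", path, " (", open, " '(' vs ",
         close, " ')')")
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a multiple alignment (aligned FASTA or Clustal)
#'
#' All rows must have equal gapped length; gap characters (`.`) are
#' normalized to `-` and sequences are uppercased.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    rows <- read_fasta(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0L || !startsWith(lines[1], "CLUSTAL")) {
      stop("not a CLUSTAL file: ", path)
    }
    lines <- lines[-1]
    keep <- nzchar(lines) & !startsWith(lines, " ")  # drop conservation rows
    lines <- lines[keep]
    nm <- sub("\\s.*$", "", lines)
    chunk <- toupper(gsub("\\s|\\d", "", sub("^\\S+\\s+", "", lines)))
    rows <- vapply(unique(nm), function(x)
      paste(chunk[nm == x], collapse = ""), "")
  }
  rows <- gsub(".", "-", rows, fixed = TRUE)
  len <- nchar(rows)
  if (length(unique(len)) > 1L) {
    bad <- names(rows)[len != stats::median(len)]
    stop("ragged alignment rows: ", paste(bad, collapse = ", "))
  }
  rows
}
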