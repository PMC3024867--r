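# Classify genes into PTS enzyme II subunits/families from their domain
# architecture and assemble them into operon-like gene sets.

REQUIRED_SUBUNITS <- list(default = c("IIA", "IIB", "IIC"),
                          FRU_MAN_SOR = c("IIA", "IIB", "IIC", "IID"))

#' Architecture token of one gene ("IIA", "IIAB", "IIABC", ...)
#' @keywords internal
arch_token <- function(subunits) {
  paste0("II", paste(substr(subunits, 3L, 3L), collapse = ""))
}

set_members <- function(set_row) strsplit(set_row$members, ",", fixed = TRUE)[[1]]
set_inserted <- function(set_row) {
  if (is.na(set_row$inserted) || !nzchar(set_row$inserted)) character(0)
  else strsplit(set_row$inserted, ",", fixed = TRUE)[[1]]
}

#' Call PTS enzyme II subunits per gene from domain hits
#'
#' Subunit tokens are ordered by domain start coordinate (N- to C-terminal);
#' genes with two or more subunit domains are fusions (IIAB, IIABC, ...).
#' The gene's family is the majority family token over its PTS domains;
#' ties give UNKNOWN with a warning. Genes with no PTS domain get no call.
#'
#' @param domains domain-hit table from [read_domain_tsv()] (needs columns
#'   gene_id, subunit, family, aa_start).
#' @return data.frame: gene_id, subunits ("IIA+IIB" style), arch token,
#'   family, fused.
#' @export
assign_subunits <- function(domains) {
  pts <- domains[!is.na(domains$subunit), , drop = FALSE]
  out <- data.frame(gene_id = character(0), subunits = character(0),
                    arch = character(0), family = character(0),
                    fused = logical(0), stringsAsFactors = FALSE)
  if (nrow(pts) == 0L) return(out)
  for (gid in unique(pts$gene_id)) {
    g <- pts[pts$gene_id == gid, , drop = FALSE]
    g <- g[order(g$aa_start), , drop = FALSE]
    subs <- g$subunit
    fams <- table(g$family)
    top <- names(fams)[fams == max(fams)]
    if (length(top) > 1L) {
      warning("gene ", gid, ": no majority family among domains (",
              paste(top, collapse = " vs "), "); family set to UNKNOWN")
      fam <- "UNKNOWN"
    } else {
      fam <- top
    }
    out <- rbind(out, data.frame(gene_id = gid,
                                 subunits = paste(subs, collapse = "+"),
                                 arch = arch_token(subs),
                                 family = fam,
                                 fused = length(subs) >= 2L,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Family and completeness of a subunit union
#'
#' The fructose/mannose/sorbose family is complete with {IIA,IIB,IIC,IID};
#' every other family with {IIA,IIB,IIC}. A IID subunit in a set labelled
#' with any other family reclassifies it to FRU_MAN_SOR with a warning,
#' since IID occurs in that family only.
#'
#' @param subunit_union character vector of distinct subunits present.
#' @param family family label carried by the member genes.
#' @return list(family, complete).
#' @export
classify_family <- function(subunit_union, family) {
  if ("IID" %in% subunit_union && family != "FRU_MAN_SOR") {
    warning("set with IID subunit labelled ", family,
            "; reclassified to FRU_MAN_SOR")
    family <- "FRU_MAN_SOR"
  }
  req <- if (family == "FRU_MAN_SOR") REQUIRED_SUBUNITS$FRU_MAN_SOR
         else REQUIRED_SUBUNITS$default
  list(family = family, complete = all(req %in% subunit_union))
}

#' Assemble PTS genes into operon-like gene sets
#'
#' Maximal same-contig, same-family runs of PTS-called genes, tolerating up
#' to `max_inserted` consecutive non-PTS genes inside a run and intergenic
#' gaps of at most `max_gap_bp` between consecutive genes along the run.
#' The set strand is the majority strand of its members; singleton
#' incomplete sets are flagged orphan. Input order does not matter (genes
#' are re-sorted by coordinate).
#'
#' @param genes gene table (see [read_gene_table()]).
#' @param calls subunit calls from [assign_subunits()].
#' @param max_gap_bp maximum intergenic gap between run members, in bp.
#' @param max_inserted maximum number of consecutive tolerated non-PTS
#'   genes inside a run.
#' @return data.frame, one row per set: set_id, genome_id, contig, start,
#'   end, strand, family, architecture, members, inserted, n_members,
#'   complete, orphan.
#' @export
assemble_sets <- function(genes, calls, max_gap_bp = 300L, max_inserted = 1L) {
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  ci <- match(genes$gene_id, calls$gene_id)
  out <- list()
  flush <- function(run) {
    if (length(run$members) == 0L) return(NULL)
    midx <- run$members
    rows <- genes[midx, , drop = FALSE]
    mcalls <- calls[ci[midx], , drop = FALSE]
    subs <- unique(unlist(strsplit(mcalls$subunits, "+", fixed = TRUE)))
    fam <- classify_family(subs, run$family)
    orphan <- length(midx) == 1L && !fam$complete
    strand <- names(sort(table(rows$strand), decreasing = TRUE))[1]
    if (length(unique(rows$strand)) > 1L) {
      message("mixed-strand set at ", rows$contig[1], ":", min(rows$start),
              "; majority strand ", strand)
    }
    span_rows <- genes[sort(c(midx, run$inserted)), , drop = FALSE]
    data.frame(
      genome_id = rows$genome_id[1],
      contig = rows$contig[1],
      start = min(span_rows$start),
      end = max(span_rows$end),
      strand = strand,
      family = fam$family,
      architecture = paste(mcalls$arch, collapse = "/"),
      members = paste(rows$gene_id, collapse = ","),
      inserted = paste(genes$gene_id[run$inserted], collapse = ","),
      n_members = length(midx),
      complete = fam$complete,
      orphan = orphan,
      stringsAsFactors = FALSE
    )
  }
  for (ctg in unique(genes$contig)) {
    idx <- which(genes$contig == ctg)
    run <- NULL
    pending <- integer(0)
    for (i in idx) {
      is_pts <- !is.na(ci[i])
      if (is_pts) {
        fam_i <- calls$family[ci[i]]
        ok <- !is.null(run) &&
          fam_i == run$family &&
          length(pending) <= max_inserted
        if (ok) {
          # gap check along the path: previous gene in genomic order
          path <- c(run$members, run$inserted, pending, i)
          path <- sort(path)
          pos <- match(i, path)
          prev <- path[pos - 1L]
          ok <- (genes$start[i] - genes$end[prev] - 1L) <= max_gap_bp
          # pending non-PTS genes must themselves respect the gap chain
          if (ok && length(pending) > 0L) {
            chain <- sort(c(run$members, run$inserted, pending, i))
            gaps <- genes$start[chain[-1]] - genes$end[chain[-length(chain)]] - 1L
            ok <- all(gaps <= max_gap_bp)
          }
        }
        if (ok) {
          run$inserted <- c(run$inserted, pending)
          run$members <- c(run$members, i)
          pending <- integer(0)
        } else {
          out[[length(out) + 1L]] <- flush(run)
          run <- list(family = fam_i, members = i, inserted = integer(0))
          pending <- integer(0)
        }
      } else if (!is.null(run)) {
        pending <- c(pending, i)
        if (length(pending) > max_inserted) {
          out[[length(out) + 1L]] <- flush(run)
          run <- NULL
          pending <- integer(0)
        }
      }
    }
    out[[length(out) + 1L]] <- flush(run)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(set_id = character(0), genome_id = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      family = character(0), architecture = character(0),
                      members = character(0), inserted = character(0),
                      n_members = integer(0), complete = logical(0),
                      orphan = logical(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$genome_id, out$contig, out$start), , drop = FALSE]
  out <- cbind(set_id = paste0(out$genome_id, "_set",
                               stats::ave(seq_len(nrow(out)), out$genome_id,
                                          FUN = seq_along)),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Catalogue summary per genome
#'
#' Per genome: total sets, complete sets per family, orphans; per set the
#' strand and fractional genomic position (span midpoint / genome length)
#' plus the flag `pos_strand_in_first_half`. Enzyme I and Hpr genes, which
#' typically occur once per genome, are counted by product-text keyword as
#' a convenience.
#'
#' @param sets set table from [assemble_sets()].
#' @param genome_lengths named numeric vector of genome lengths in bp.
#' @param genes optional gene table used for the enzyme I / Hpr counts.
#' @return list(genomes = per-genome data.frame, sets = per-set data.frame).
#' @export
catalog_summary <- function(sets, genome_lengths, genes = NULL) {
  per_set <- sets[, c("set_id", "genome_id", "strand", "family", "complete",
                      "orphan")]
  L <- genome_lengths[sets$genome_id]
  per_set$position <- ((sets$start + sets$end) / 2) / L
  per_set$pos_strand_in_first_half <- sets$strand == "+" & per_set$position <= 0.5
  rows <- lapply(unique(sets$genome_id), function(g) {
    s <- sets[sets$genome_id == g, , drop = FALSE]
    fam_counts <- table(factor(s$family[s$complete], levels = PTS_FAMILIES))
    cnt <- data.frame(genome_id = g, n_sets = nrow(s),
                      n_complete = sum(s$complete), n_orphans = sum(s$orphan),
                      stringsAsFactors = FALSE)
    for (f in PTS_FAMILIES) cnt[[paste0("complete_", f)]] <- unname(fam_counts[f])
    if (!is.null(genes)) {
      gg <- genes[genes$genome_id == g, , drop = FALSE]
      prod <- tolower(ifelse(is.na(gg$product), "", gg$product))
      cnt$n_enzyme_I <- sum(grepl("phosphoenolpyruvate.protein phosphotransferase|enzyme i\\b",
                                  prod))
      cnt$n_hpr <- sum(grepl("phosphocarrier|\\bhpr\\b", prod))
    }
    cnt
  })
  list(genomes = do.call(rbind, rows), sets = per_set)
}
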