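# Pipeline stages. Each stage is a pure function of in-memory objects that
# optionally writes its report (TSV/JSON) when `outdir` is given; `run_all`
# chains the stages. Re-running a stage on unchanged inputs is idempotent.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

all_genes <- function(bundles) {
  do.call(rbind, lapply(bundles, `[[`, "genes"))
}

all_domains <- function(bundles) {
  do.call(rbind, lapply(bundles, `[[`, "domains"))
}

#' Simulate genomes and write them in the pipeline's input formats
#'
#' Writes, per genome: `<id>.fna` (contigs), `<id>_genes.tsv` (gene table),
#' `<id>_proteins.faa`, `<id>_domains.tsv` (headered domain table), plus
#' `species_tree.nwk` and the ground-truth `manifest.tsv`.
#'
#' @param spec SimSpec (see [default_sim_spec()]).
#' @param outdir output directory (created if missing).
#' @return the simulation object from [sim_pts_genomes()], invisibly.
#' @export
run_simulate <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- sim_pts_genomes(spec)
  for (gid in names(sim$bundles)) {
    b <- sim$bundles[[gid]]
    write_fasta(b$contigs, file.path(outdir, paste0(gid, ".fna")))
    write_tsv(b$genes[, c("gene_id", "contig", "start", "end", "strand",
                          "product")],
              file.path(outdir, paste0(gid, "_genes.tsv")))
    write_fasta(stats::setNames(b$genes$aa, b$genes$gene_id),
                file.path(outdir, paste0(gid, "_proteins.faa")))
    d <- b$domains
    write_tsv(d, file.path(outdir, paste0(gid, "_domains.tsv")))
  }
  if (!is.null(sim$species_tree)) {
    write_newick(sim$species_tree, file.path(outdir, "species_tree.nwk"))
  }
  write_tsv(sim$manifest, file.path(outdir, "manifest.tsv"))
  invisible(sim)
}

#' Load a directory of per-genome inputs into genome bundles
#'
#' Expects the file layout written by [run_simulate()] (or equivalent
#' exports): `<id>.fna`, `<id>_genes.tsv`, `<id>_proteins.faa`,
#' `<id>_domains.tsv`.
#'
#' @param indir input directory.
#' @param evalue_max domain e-value threshold.
#' @return named list of genome bundles.
#' @export
load_genomes <- function(indir, evalue_max = 1e-5) {
  gene_files <- list.files(indir, pattern = "_genes\\.tsv$", full.names = TRUE)
  if (length(gene_files) == 0L) stop("no *_genes.tsv files in ", indir)
  bundles <- list()
  for (gf in gene_files) {
    gid <- sub("_genes\\.tsv$", "", basename(gf))
    contigs <- read_fasta(file.path(indir, paste0(gid, ".fna")))
    prots <- read_fasta(file.path(indir, paste0(gid, "_proteins.faa")))
    genes <- read_gene_table(gf, dialect = "tsv", contigs = contigs,
                             proteins = prots, genome_id = gid)
    domains <- read_domain_tsv(file.path(indir, paste0(gid, "_domains.tsv")),
                               evalue_max = evalue_max)
    bundles[[gid]] <- list(genome_id = gid, contigs = contigs, genes = genes,
                           domains = domains,
                           genome_gc = gc_percent(paste(contigs, collapse = "")))
  }
  bundles
}

#' Catalogue stage: subunit calls and gene-set assembly
#'
#' @param bundles named list of genome bundles.
#' @param outdir optional report directory (`sets.tsv`, `catalog.json`).
#' @param max_gap_bp,max_inserted see [assemble_sets()].
#' @return list(sets, calls, summary).
#' @export
run_catalog <- function(bundles, outdir = NULL, max_gap_bp = 300L,
                        max_inserted = 1L) {
  sets <- list(); calls <- list()
  for (gid in names(bundles)) {
    b <- bundles[[gid]]
    dom <- b$domains
    if (is.null(dom$subunit)) dom <- label_domains(dom)
    cl <- assign_subunits(dom)
    calls[[gid]] <- cl
    sets[[gid]] <- assemble_sets(b$genes, cl, max_gap_bp, max_inserted)
  }
  sets <- do.call(rbind, sets)
  rownames(sets) <- NULL
  glen <- vapply(bundles, function(b) sum(nchar(b$contigs)), 0)
  summary <- catalog_summary(sets, glen, all_genes(bundles))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(sets, file.path(outdir, "sets.tsv"))
    jsonlite::write_json(list(genomes = summary$genomes, sets = summary$sets),
                         file.path(outdir, "catalog.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(sets = sets, calls = calls, summary = summary)
}

#' GC stage: baselines, per-set GC, z-scores and per-genome grouping
#'
#' @param bundles genome bundles.
#' @param sets set table from [run_catalog()].
#' @param outdir optional report directory (`gc.tsv`, `genomes_gc.tsv`).
#' @param k number of GC groups per genome.
#' @param include_inserted include inserted genes in set GC.
#' @param exclude_orphans exclude orphan sets from the grouping (they need
#'   not conform to the set-level grouping).
#' @return list(sets_gc, genomes, groupings).
#' @export
run_gc <- function(bundles, sets, outdir = NULL, k = 3L,
                   include_inserted = TRUE, exclude_orphans = TRUE) {
  genomes <- data.frame(genome_id = names(bundles),
                        genome_gc = NA_real_, gene_mean = NA_real_,
                        gene_sd = NA_real_, stringsAsFactors = FALSE)
  sets_gc <- sets[, c("set_id", "genome_id", "family", "complete", "orphan")]
  sets_gc$length_bp <- rep(NA_integer_, nrow(sets_gc))
  sets_gc$gc_percent <- rep(NA_real_, nrow(sets_gc))
  sets_gc$z <- rep(NA_real_, nrow(sets_gc))
  sets_gc$direction <- rep(NA_character_, nrow(sets_gc))
  sets_gc$group <- rep(NA_integer_, nrow(sets_gc))
  groupings <- list()
  for (gi in seq_along(bundles)) {
    b <- bundles[[gi]]
    bl <- genome_baseline(b$contigs, b$genes)
    genomes$genome_gc[gi] <- bl$genome_gc
    genomes$gene_mean[gi] <- bl$gene_mean
    genomes$gene_sd[gi] <- bl$gene_sd
    idx <- which(sets_gc$genome_id == b$genome_id)
    for (i in idx) {
      row <- sets[i, ]
      ids <- c(set_members(row),
               if (include_inserted) set_inserted(row))
      nt <- b$genes$nt[match(ids, b$genes$gene_id)]
      sets_gc$length_bp[i] <- sum(nchar(nt))
      sets_gc$gc_percent[i] <- set_gc(row, b$genes, include_inserted)
      an <- gc_anomaly(sets_gc$gc_percent[i], bl)
      sets_gc$z[i] <- an$z
      sets_gc$direction[i] <- an$direction
    }
    el <- idx[!exclude_orphans | !sets_gc$orphan[idx]]
    if (length(el) >= k) {
      gr <- group_gc(sets_gc$gc_percent[el], k, ids = sets_gc$set_id[el])
      sets_gc$group[el] <- gr$assignment
      groupings[[b$genome_id]] <- gr
    }
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(sets_gc, file.path(outdir, "gc.tsv"))
    write_tsv(genomes, file.path(outdir, "genomes_gc.tsv"))
  }
  list(sets_gc = sets_gc, genomes = genomes, groupings = groupings)
}

#' Synteny stage: neighbourhood markers and class per set
#'
#' @param bundles genome bundles.
#' @param sets set table.
#' @param outdir optional report directory (`synteny.tsv`).
#' @param window flank size in genes.
#' @param vocab marker vocabulary.
#' @return data.frame, one row per set.
#' @export
run_synteny <- function(bundles, sets, outdir = NULL, window = 4L,
                        vocab = marker_vocab()) {
  doms <- lapply(bundles, function(b) {
    if (is.null(b$domains$signature_label)) label_domains(b$domains)
    else b$domains
  })
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    b <- bundles[[sets$genome_id[i]]]
    ctx <- extract_context(sets[i, ], b$genes, window)
    mk <- detect_markers(ctx, doms[[sets$genome_id[i]]], vocab)
    data.frame(set_id = sets$set_id[i], genome_id = sets$genome_id[i],
               synteny_class = mk$synteny_class,
               sigma54 = mk$sigma54, sis = mk$sis,
               flanked_by_IS = mk$flanked_by_IS, is_adjacent = mk$is_adjacent,
               sigma54_genes = paste(mk$sigma54_genes, collapse = ","),
               sis_genes = paste(mk$sis_genes, collapse = ","),
               is_genes = paste(mk$is_element_genes, collapse = ","),
               architecture = sets$architecture[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(out, file.path(outdir, "synteny.tsv"))
  }
  out
}

set_iib_gene <- function(set_row) {
  mem <- set_members(set_row)
  toks <- strsplit(set_row$architecture, "/", fixed = TRUE)[[1]]
  hit <- grepl("B", substring(toks, 3L))
  if (!any(hit)) return(NA_character_)
  mem[which(hit)[1]]
}

#' Tree stage: IIB gene tree of a family with bootstrap supports
#'
#' One leaf per set carrying a IIB subunit (fused IIAB counts): the IIB
#' protein sequences are progressively aligned, Poisson-corrected distances
#' computed, and an NJ tree with bootstrap supports built.
#'
#' @param bundles genome bundles.
#' @param sets set table.
#' @param outdir optional report directory (`gene_tree.nwk`,
#'   `distances.tsv`).
#' @param family PTS family to analyse.
#' @param B bootstrap replicates (0 = no supports).
#' @param seed RNG seed for the bootstrap.
#' @return list(tree, supports, alignment, D, leaf_genomes) or NULL when
#'   fewer than two sets carry the subunit.
#' @export
run_tree <- function(bundles, sets, outdir = NULL, family = "FRU_MAN_SOR",
                     B = 500L, seed = 1L) {
  fs <- sets[sets$family == family, , drop = FALSE]
  if (nrow(fs) < 2L) return(NULL)
  genes <- all_genes(bundles)
  seqs <- character(0); leaf_genomes <- character(0)
  for (i in seq_len(nrow(fs))) {
    gid <- set_iib_gene(fs[i, ])
    if (is.na(gid)) next
    aa <- genes$aa[match(gid, genes$gene_id)]
    if (is.na(aa)) next
    seqs[fs$set_id[i]] <- aa
    leaf_genomes[fs$set_id[i]] <- fs$genome_id[i]
  }
  if (length(seqs) < 2L) return(NULL)
  aln <- progressive_msa(seqs)
  bs <- bootstrap_support(aln, B = B, seed = seed)
  D <- poisson_distance(pdist_matrix(aln))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_newick(bs$tree, file.path(outdir, "gene_tree.nwk"))
    dm <- as.data.frame(unclass(D))
    dm <- cbind(label = rownames(D), dm)
    write_tsv(dm, file.path(outdir, "distances.tsv"))
  }
  list(tree = bs$tree, supports = bs$supports, alignment = aln, D = D,
       leaf_genomes = leaf_genomes)
}

#' HGT stage: combine GC anomaly, tree incongruence and IS flanking
#'
#' @param gc_res output of [run_gc()].
#' @param synteny_tab output of [run_synteny()].
#' @param tree_res output of [run_tree()] (NULL = no tree evidence).
#' @param species_tree species tree whose tips are genome ids (NULL = no
#'   taxon classification; donor groups are then unlabelled).
#' @param outdir optional report directory (`hgt_calls.tsv`,
#'   `gradient.tsv`).
#' @param z_min GC evidence threshold.
#' @param family family for the gradient report.
#' @return list(calls, gradient, taxon_groups).
#' @export
run_hgt <- function(gc_res, synteny_tab, tree_res = NULL, species_tree = NULL,
                    outdir = NULL, z_min = 2, family = "FRU_MAN_SOR") {
  sets_gc <- gc_res$sets_gc
  groups <- NULL
  mixed <- stats::setNames(rep(NA, nrow(sets_gc)), sets_gc$set_id)
  if (!is.null(species_tree) && !is.null(tree_res)) {
    ggc <- stats::setNames(gc_res$genomes$genome_gc, gc_res$genomes$genome_id)
    groups <- classify_taxa(species_tree, ggc)
    leaf_groups <- groups[tree_res$leaf_genomes]
    names(leaf_groups) <- names(tree_res$leaf_genomes)
    mx <- mixed_clade_test(tree_res$tree, leaf_groups)
    mixed[names(mx$mixed)] <- mx$mixed
  }
  is_fl <- stats::setNames(synteny_tab$flanked_by_IS, synteny_tab$set_id)
  calls <- lapply(seq_len(nrow(sets_gc)), function(i) {
    sid <- sets_gc$set_id[i]
    v <- hgt_verdict(sets_gc$z[i], sets_gc$direction[i],
                     mixed_flag = mixed[[sid]],
                     is_flag = isTRUE(is_fl[[sid]]), z_min = z_min)
    data.frame(set_id = sid, genome_id = sets_gc$genome_id[i],
               family = sets_gc$family[i],
               gc_percent = sets_gc$gc_percent[i], gc_z = sets_gc$z[i],
               gc_direction = sets_gc$direction[i],
               mixed_clade = mixed[[sid]],
               flanked_by_IS = isTRUE(is_fl[[sid]]),
               n_evidence = v$n_evidence, verdict = v$verdict,
               inferred_donor_group = v$inferred_donor_group,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  genome_tab <- gc_res$genomes[, c("genome_id", "genome_gc")]
  gradient <- gc_gradient_report(genome_tab, sets_gc, family = family)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(calls, file.path(outdir, "hgt_calls.tsv"))
    write_tsv(gradient, file.path(outdir, "gradient.tsv"))
  }
  list(calls = calls, gradient = gradient, taxon_groups = groups)
}

#' Run the whole pipeline
#'
#' Chains catalogue, GC, synteny, duplicate detection, gene tree and HGT
#' stages over a directory of genome inputs (or an in-memory simulation)
#' and writes every stage report into `outdir`.
#'
#' @param indir input directory (see [load_genomes()]); ignored when `sim`
#'   is given.
#' @param outdir report directory.
#' @param sim optional simulation object from [sim_pts_genomes()].
#' @param config named list overriding defaults: evalue, max_gap_bp,
#'   max_inserted, k_groups, window, identity_min, z_min, bootstrap_B,
#'   family, seed.
#' @return list with every stage's outputs.
#' @export
run_all <- function(indir = NULL, outdir = NULL, sim = NULL, config = list()) {
  cfg <- utils::modifyList(list(evalue = 1e-5, max_gap_bp = 300L,
                                max_inserted = 1L, k_groups = 3L,
                                window = 4L, identity_min = 90,
                                z_min = 2, bootstrap_B = 500L,
                                family = "FRU_MAN_SOR", seed = 1L,
                                include_inserted = TRUE), config)
  stopifnot(cfg$evalue > 0, cfg$max_gap_bp > 0, cfg$k_groups >= 1,
            cfg$window >= 1, cfg$z_min > 0)
  if (!is.null(sim)) {
    bundles <- sim$bundles
    species_tree <- sim$species_tree
  } else {
    bundles <- load_genomes(indir, evalue_max = cfg$evalue)
    stf <- file.path(indir, "species_tree.nwk")
    species_tree <- if (file.exists(stf)) read_newick(stf) else NULL
  }
  cat_res <- run_catalog(bundles, outdir, cfg$max_gap_bp, cfg$max_inserted)
  gc_res <- run_gc(bundles, cat_res$sets, outdir, k = cfg$k_groups,
                   include_inserted = cfg$include_inserted)
  syn <- run_synteny(bundles, cat_res$sets, outdir, window = cfg$window)
  dup <- detect_duplicates(cat_res$sets, all_genes(bundles),
                           identity_min = cfg$identity_min)
  tree_res <- run_tree(bundles, cat_res$sets, outdir, family = cfg$family,
                       B = cfg$bootstrap_B, seed = cfg$seed)
  hgt <- run_hgt(gc_res, syn, tree_res, species_tree, outdir,
                 z_min = cfg$z_min, family = cfg$family)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(dup, file.path(outdir, "duplicates.tsv"))
  }
  list(config = cfg, bundles = bundles, sets = cat_res$sets,
       summary = cat_res$summary, gc = gc_res, synteny = syn,
       duplicates = dup, tree = tree_res, hgt = hgt,
       species_tree = species_tree)
}
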