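# Synthetic-genome generator. Emits genomes with a controlled background
# GC, planted multi-gene PTS sets with GC offsets realized at codon third
# positions, fused-subunit variants, inserted hypothetical genes, orphan
# subunits, sigma-54 / SIS / transposase marker genes, near-identical
# duplicated sets and HGT plants copying donor-composition sequence into a
# recipient, together with a ground-truth manifest. Fully deterministic
# given the spec seed.

AA20 <- AA_ALPHABET[1:20]

genetic_code_tab <- function() {
  if (!is.null(.matrix_cache$gcode)) return(.matrix_cache$gcode)
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  codons <- names(sense)
  bases <- do.call(rbind, strsplit(codons, ""))
  .matrix_cache$gcode <- list(codon = codons, aa = unname(sense),
                              is_gc = bases == "G" | bases == "C")
  .matrix_cache$gcode
}

codon_weights <- function(q) {
  tab <- genetic_code_tab()
  apply(ifelse(tab$is_gc, q / 2, (1 - q) / 2), 1, prod)
}

# per-base GC parameter whose sense-codon distribution realizes the target
# gene GC exactly (stop-codon exclusion biases the naive weighting)
gc_calibrated <- function(target) {
  key <- sprintf("cal%.6f", target)
  if (!is.null(.matrix_cache[[key]])) return(.matrix_cache[[key]])
  tab <- genetic_code_tab()
  frac <- rowMeans(tab$is_gc)
  f <- function(q) {
    w <- codon_weights(q)
    sum(w * frac) / sum(w) - target
  }
  q <- stats::uniroot(f, c(0.005, 0.995), tol = 1e-9)$root
  .matrix_cache[[key]] <- q
  q
}

# sample n sense codons realizing an expected gene GC of `gc`
random_cds <- function(n_codons, gc) {
  tab <- genetic_code_tab()
  w <- codon_weights(gc_calibrated(gc))
  idx <- sample.int(length(tab$codon), n_codons, replace = TRUE, prob = w)
  list(nt = paste(tab$codon[idx], collapse = ""),
       aa = paste(tab$aa[idx], collapse = ""))
}

random_dna <- function(len, gc) {
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# reverse-translate a protein, biasing codon third positions to GC
# probability q3 (positions 1-2 uniform over the residue's codons)
reverse_translate <- function(aa, q3) {
  tab <- genetic_code_tab()
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  vapply(res, function(r) {
    cand <- which(tab$aa == r)
    if (length(cand) == 0L) cand <- which(tab$aa == "L")  # X fallback
    w <- ifelse(tab$is_gc[cand, 3], q3, 1 - q3)
    tab$codon[cand[sample.int(length(cand), 1L, prob = w)]]
  }, "") |> paste(collapse = "")
}

# expected GC fraction at codon positions 1-2 for a given protein
expected_gc12 <- function(aa) {
  tab <- genetic_code_tab()
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  per_res <- vapply(unique(res), function(r) {
    cand <- which(tab$aa == r)
    if (length(cand) == 0L) cand <- which(tab$aa == "L")
    mean(tab$is_gc[cand, 1:2])
  }, 0)
  mean(per_res[res])
}

# reverse-translate to a target overall gene GC fraction
encode_protein <- function(aa, target_gc) {
  g12 <- expected_gc12(aa)
  q3 <- min(0.98, max(0.02, 3 * target_gc - 2 * g12))
  reverse_translate(aa, q3)
}

# substitute exactly n_sub residues (uniform different target)
mutate_protein <- function(aa, n_sub) {
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  if (n_sub == 0L) return(aa)
  pos <- sample.int(length(res), min(n_sub, length(res)))
  for (p in pos) {
    res[p] <- sample(setdiff(AA20, res[p]), 1L)
  }
  paste(res, collapse = "")
}

#' Simulate a species tree (Yule process)
#'
#' Ultrametric pure-birth tree, deterministic given the seed.
#'
#' @param n number of taxa.
#' @param birth_rate speciation rate.
#' @param seed RNG seed (set only when non-NULL).
#' @param labels optional tip labels (replaces t1..tn in order).
#' @return rooted ultrametric [ape::phylo] tree.
#' @export
sim_species_tree <- function(n, birth_rate = 1, seed = NULL, labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = birth_rate, death = 0)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    tr$tip.label <- labels
  }
  tr
}

#' Simulate sequences along a tree
#'
#' DNA evolves under JC69 (per site, the probability of remaining the same
#' base over a branch of expected `rate * length` substitutions/site is
#' `1/4 + 3/4 exp(-4/3 d)`); proteins under a Poisson uniform-substitution
#' model (change probability `1 - exp(-d)`, uniform target among the other
#' 19 residues). No indels, so the true alignment is the ungapped site
#' homology.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param root_seq sequence at the root.
#' @param model `"jc69"` (DNA) or `"poisson"` (protein).
#' @param rate expected substitutions per site per unit branch length.
#' @param seed RNG seed (set only when non-NULL).
#' @return named character vector of tip sequences.
#' @export
sim_sequences <- function(tree, root_seq, model = c("jc69", "poisson"),
                          rate = 1, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  alphabet <- if (model == "jc69") c("A", "C", "G", "T") else AA20
  n <- length(tree$tip.label)
  root <- n + 1L
  seqs <- vector("list", n + tree$Nnode)
  seqs[[root]] <- strsplit(toupper(root_seq), "", fixed = TRUE)[[1]]
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    d <- rate * tree$edge.length[e]
    s <- seqs[[p]]
    p_change <- if (model == "jc69") 0.75 * (1 - exp(-4 / 3 * d))
                else 1 - exp(-d)
    hit <- stats::runif(length(s)) < p_change
    if (any(hit)) {
      k <- length(alphabet)
      cur <- match(s[hit], alphabet)
      shift <- sample.int(k - 1L, sum(hit), replace = TRUE)
      s[hit] <- alphabet[((cur - 1L + shift) %% k) + 1L]
    }
    seqs[[ch]] <- s
  }
  stats::setNames(vapply(seqs[seq_len(n)], paste, "", collapse = ""),
                  tree$tip.label)
}

#' Default simulation spec: the reference study conditions
#'
#' Three genomes — one high-GC donor (50% GC) and two low-GC recipients
#' (30% and 32%) — with ~200 background genes each and seven planted
#' fructose/mannose/sorbose entities: a native donor set, a recipient set
#' with an inserted hypothetical gene, a 95%-identity duplicated set pair,
#' two HGT plants at +6 GC points flanked by insertion sequences, and one
#' orphan IIB gene.
#'
#' @param seed mandatory RNG seed.
#' @return SimSpec list understood by [sim_pts_genomes()].
#' @export
default_sim_spec <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  templates <- data.frame(
    label = c("t_donor", "t_ins", "t_dupA", "t_dupB", "t_hgt1", "t_hgt2",
              "t_orph"),
    genome_id = c("G1", "G2", "G2", "G2", "G2", "G3", "G3"),
    architecture = c("IID/IIC/IIB/IIA", "IIC/IID/IIB/IIA", "IID/IIC/IIB/IIA",
                     "IID/IIC/IIB/IIA", "IIAB/IIC/IID", "IIA/IIB/IIC/IID",
                     "IIB"),
    family = "FRU_MAN_SOR",
    class = c("NEITHER", "BOTH", "SIGMA54_ONLY", "SIGMA54_ONLY", "NEITHER",
              "NEITHER", "NEITHER"),
    inserted = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    orphan = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    duplicate_of = c(NA, NA, NA, "t_dupA", NA, NA, NA),
    donor = c(NA, NA, NA, NA, "G1", "G1", NA),
    hgt = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    is_flanked = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    offset = c(NA, NA, NA, NA, 6, 6, NA),
    stringsAsFactors = FALSE
  )
  list(
    seed = as.integer(seed),
    taxa = data.frame(genome_id = c("G1", "G2", "G3"),
                      gc = c(0.50, 0.30, 0.32),
                      n_background = c(200L, 200L, 200L),
                      stringsAsFactors = FALSE),
    birth_rate = 1,
    prot_rate = 0.25,
    set_extra_sub = 0.04,
    hgt_extra_sub = 0.01,
    dup_identity = 95,
    native_offset_mean = 1.0,
    native_offset_sd = 0.4,
    gene_len_codons = c(100L, 450L),
    intergenic = c(120L, 280L),
    intrablock_gap = c(40L, 150L),
    subunit_len = c(IIA = 140L, IIB = 160L, IIC = 260L, IID = 270L),
    templates = templates
  )
}

#' Benchmark spec: many replicate sets for sensitivity/FPR estimation
#'
#' `n_genomes` low-GC genomes, each with 2 native sets (GC offset drawn
#' around +1 point) and 2 HGT plants (+6 points, IS-flanked), yielding
#' `4 * n_genomes` scored sets with known ground truth.
#'
#' @param seed RNG seed.
#' @param n_genomes number of replicate genomes.
#' @param n_background background genes per genome.
#' @return SimSpec list.
#' @export
hgt_benchmark_spec <- function(seed, n_genomes = 50L, n_background = 120L) {
  gids <- sprintf("R%02d", seq_len(n_genomes))
  archs_nat <- c("IID/IIC/IIB/IIA", "IIA/IIB/IIC/IID")
  archs_hgt <- c("IIC/IID/IIB/IIA", "IIAB/IIC/IID")
  templates <- do.call(rbind, lapply(seq_len(n_genomes), function(i) {
    data.frame(
      label = sprintf("%s_%s", gids[i], c("nat1", "nat2", "hgt1", "hgt2")),
      genome_id = gids[i],
      architecture = c(archs_nat, archs_hgt),
      family = "FRU_MAN_SOR",
      class = c("BOTH", "SIGMA54_ONLY", "NEITHER", "NEITHER"),
      inserted = FALSE, orphan = FALSE,
      duplicate_of = NA_character_, donor = NA_character_,
      hgt = c(FALSE, FALSE, TRUE, TRUE),
      is_flanked = c(FALSE, FALSE, TRUE, TRUE),
      offset = c(NA, NA, 6, 6),
      stringsAsFactors = FALSE)
  }))
  spec <- default_sim_spec(seed)
  spec$taxa <- data.frame(genome_id = gids, gc = 0.30,
                          n_background = n_background,
                          stringsAsFactors = FALSE)
  spec$templates <- templates
  spec
}

subunits_of_token <- function(token) {
  paste0("II", strsplit(substring(token, 3L), "", fixed = TRUE)[[1]])
}

#' Simulate genomes, planted PTS sets and ground truth from a SimSpec
#'
#' Background genes are drawn codon-wise at the genome's target GC; planted
#' PTS proteins evolve along a Yule species tree and are reverse-translated
#' with third-position codon bias to realize the configured GC offset over
#' the measured background baseline; HGT plants carry the donor taxon's
#' protein sequence; duplicates substitute exactly enough residues to hit
#' the target identity. Marker genes (sigma-54, SIS, transposases) are
#' placed immediately adjacent to their set, well inside the 4-gene window.
#'
#' @param spec SimSpec, e.g. [default_sim_spec()].
#' @return list(spec, species_tree, bundles, manifest) where bundles is a
#'   named list of genome bundles (contigs, genes, domains, genome_gc) and
#'   manifest is the ground-truth table.
#' @export
sim_pts_genomes <- function(spec) {
  set.seed(spec$seed)
  taxa <- spec$taxa
  ntax <- nrow(taxa)
  tree <- if (ntax >= 2L) {
    sim_species_tree(ntax, spec$birth_rate, labels = taxa$genome_id)
  } else {
    NULL
  }
  if (!is.null(tree) && ntax >= 3L) {
    # place taxa so that genome GC is clade-structured at the root split
    # (high-GC donors on one side), as in real 16S trees separating
    # high-GC Gram-negatives from low-GC Gram-positives
    root <- ntax + 1L
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    tipset <- function(nd) {
      if (nd <= ntax) nd else
        match(ape::extract.clade(tree, nd)$tip.label, tree$tip.label)
    }
    sides <- lapply(kids, tipset)
    sides <- sides[order(lengths(sides))]
    by_gc <- order(-taxa$gc)
    labs <- character(ntax)
    labs[unlist(sides)] <- taxa$genome_id[by_gc]
    tree$tip.label <- labs
  }
  vocab <- pts_vocab()
  # family subunit proteins at the species-tree leaves
  subunits <- names(spec$subunit_len)
  leaf_prots <- list()
  for (su in subunits) {
    root_aa <- random_cds(spec$subunit_len[[su]], 0.35)$aa
    leaf_prots[[su]] <- if (is.null(tree)) {
      stats::setNames(rep(root_aa, ntax), taxa$genome_id)
    } else {
      sim_sequences(tree, root_aa, model = "poisson", rate = spec$prot_rate)
    }
  }
  bundles <- list()
  manifest <- list()
  realized_prots <- list()  # template label -> list(subunit token -> aa)
  # ensure duplicate sources are built before their copies
  tpl_all <- spec$templates
  ord <- order(!is.na(tpl_all$duplicate_of))
  tpl_all <- tpl_all[ord, , drop = FALSE]

  for (gi in seq_len(ntax)) {
    gid <- taxa$genome_id[gi]
    gc_bg <- taxa$gc[gi]
    nbg <- taxa$n_background[gi]
    # background genes (two of them get enzyme I / HPr product labels)
    lens <- sample(spec$gene_len_codons[1]:spec$gene_len_codons[2], nbg,
                   replace = TRUE)
    bg <- lapply(lens, random_cds, gc = gc_bg)
    bg_gc <- vapply(bg, function(x) gc_percent(x$nt), 0)
    baseline_mean <- mean(bg_gc) / 100
    units <- data.frame(kind = "bg", label = NA_character_,
                        token = NA_character_,
                        nt = vapply(bg, `[[`, "", "nt"),
                        aa = vapply(bg, `[[`, "", "aa"),
                        product = "hypothetical protein",
                        stringsAsFactors = FALSE)
    ei <- sample.int(nbg, 2L)
    units$product[ei[1]] <- "phosphoenolpyruvate-protein phosphotransferase (enzyme I)"
    units$product[ei[2]] <- "phosphocarrier protein HPr"

    tpls <- tpl_all[tpl_all$genome_id == gid, , drop = FALSE]
    blocks <- list()
    for (ti in seq_len(nrow(tpls))) {
      tp <- tpls[ti, ]
      tokens <- strsplit(tp$architecture, "/", fixed = TRUE)[[1]]
      offset <- if (!is.na(tp$offset)) tp$offset
                else stats::rnorm(1, spec$native_offset_mean,
                                  spec$native_offset_sd)
      target_gc <- baseline_mean + offset / 100
      # member proteins
      prots <- list()
      for (tok in tokens) {
        sus <- subunits_of_token(tok)
        parts <- vapply(sus, function(su) {
          src_tax <- if (!is.na(tp$donor)) tp$donor else gid
          aa <- leaf_prots[[su]][[src_tax]]
          extra <- if (!is.na(tp$donor)) spec$hgt_extra_sub
                   else spec$set_extra_sub
          mutate_protein(aa, round(extra * nchar(aa)))
        }, "")
        prots[[tok]] <- paste(parts, collapse = "")
      }
      if (!is.na(tp$duplicate_of)) {
        src <- realized_prots[[tp$duplicate_of]]
        stopifnot(!is.null(src))
        prots <- lapply(src, function(aa) {
          mutate_protein(aa, round((100 - spec$dup_identity) / 100 * nchar(aa)))
        })
      }
      realized_prots[[tp$label]] <- prots
      block <- data.frame(kind = character(0), label = character(0),
                          token = character(0), nt = character(0),
                          aa = character(0), product = character(0),
                          stringsAsFactors = FALSE)
      add <- function(block, kind, token, nt, aa, product) {
        rbind(block, data.frame(kind = kind, label = tp$label, token = token,
                                nt = nt, aa = aa, product = product,
                                stringsAsFactors = FALSE))
      }
      marker_gene <- function(block, mk) {
        g <- random_cds(sample(120:200, 1L), gc_bg)
        prod <- switch(mk,
                       sigma54 = "RNA polymerase sigma-54 factor RpoN",
                       sis = "sugar isomerase (SIS) domain protein",
                       is_element = "IS66-family transposase")
        add(block, paste0("marker_", mk), NA_character_, g$nt, g$aa, prod)
      }
      if (tp$is_flanked) block <- marker_gene(block, "is_element")
      if (tp$class %in% c("BOTH", "SIGMA54_ONLY")) {
        block <- marker_gene(block, "sigma54")
      }
      if (tp$class == "BOTH") block <- marker_gene(block, "sis")
      ins_at <- if (tp$inserted) max(1L, length(tokens) - 1L) else 0L
      for (k in seq_along(tokens)) {
        tok <- tokens[k]
        nt <- encode_protein(prots[[tok]], target_gc)
        block <- add(block, "pts", tok, nt, prots[[tok]],
                     sprintf("PTS system %s family %s component",
                             tolower(gsub("_", "/", tp$family)), tok))
        if (k == ins_at) {
          g <- random_cds(sample(120:180, 1L), gc_bg)
          block <- add(block, "inserted", NA_character_, g$nt, g$aa,
                       "hypothetical protein")
        }
      }
      if (tp$is_flanked) block <- marker_gene(block, "is_element")
      block$strand_block <- sample(c("+", "-"), 1L)
      blocks[[tp$label]] <- block
    }

    # interleave: pick spaced insertion points among background genes
    npts <- length(blocks)
    pos <- integer(0)
    if (npts > 0L) {
      cand <- 8:(nbg - 8L)
      for (k in seq_len(npts)) {
        ok <- cand[vapply(cand, function(p) all(abs(p - pos) >= 12L), TRUE)]
        if (length(ok) == 0L) stop("genome too small to place all templates")
        pos <- c(pos, sample(ok, 1L))
      }
      pos <- sort(pos)
    }
    rows <- list()
    prev <- 0L
    for (k in seq_len(npts)) {
      rows[[length(rows) + 1L]] <- transform(
        units[(prev + 1L):pos[k], , drop = FALSE],
        strand_block = NA_character_)
      rows[[length(rows) + 1L]] <- blocks[[k]]
      prev <- pos[k]
    }
    rows[[length(rows) + 1L]] <- transform(
      units[(prev + 1L):nbg, , drop = FALSE], strand_block = NA_character_)
    allu <- do.call(rbind, rows)
    ng <- nrow(allu)
    allu$gene_id <- sprintf("%s_%04d", gid, seq_len(ng) * 10L)
    allu$strand <- ifelse(is.na(allu$strand_block),
                          sample(c("+", "-"), ng, replace = TRUE),
                          allu$strand_block)
    # coordinates: intra-block gaps are small, inter-unit gaps larger
    in_block <- !is.na(allu$label)
    same_block_as_prev <- c(FALSE, in_block[-1] & in_block[-ng] &
                              allu$label[-1] == allu$label[-ng])
    gaps <- ifelse(same_block_as_prev,
                   sample(spec$intrablock_gap[1]:spec$intrablock_gap[2], ng,
                          replace = TRUE),
                   sample(spec$intergenic[1]:spec$intergenic[2], ng,
                          replace = TRUE))
    lens_nt <- nchar(allu$nt)
    starts <- integer(ng)
    cur <- 500L
    for (i in seq_len(ng)) {
      cur <- cur + gaps[i]
      starts[i] <- cur + 1L
      cur <- cur + lens_nt[i]
    }
    allu$start <- starts
    allu$end <- starts + lens_nt - 1L
    # contig assembly
    contig_id <- paste0("chr_", gid)
    total_len <- allu$end[ng] + 500L
    seg <- character(2L * ng + 1L)
    prev_end <- 0L
    for (i in seq_len(ng)) {
      seg[2L * i - 1L] <- random_dna(allu$start[i] - prev_end - 1L, gc_bg)
      seg[2L * i] <- if (allu$strand[i] == "+") allu$nt[i] else revcomp(allu$nt[i])
      prev_end <- allu$end[i]
    }
    seg[2L * ng + 1L] <- random_dna(total_len - prev_end, gc_bg)
    contig <- paste(seg, collapse = "")

    genes <- data.frame(gene_id = allu$gene_id, genome_id = gid,
                        contig = contig_id, start = allu$start,
                        end = allu$end, strand = allu$strand,
                        product = allu$product, nt = allu$nt, aa = allu$aa,
                        stringsAsFactors = FALSE)
    # domain hits
    dh <- list()
    for (i in seq_len(ng)) {
      kind <- allu$kind[i]
      if (kind == "pts") {
        tp <- tpl_all[tpl_all$label == allu$label[i], ]
        sus <- subunits_of_token(allu$token[i])
        off <- 1L
        for (su in sus) {
          L <- spec$subunit_len[[su]]
          dh[[length(dh) + 1L]] <- data.frame(
            gene_id = allu$gene_id[i],
            signature_id = vocab_signature(tp$family, su, vocab),
            aa_start = off, aa_end = off + L - 1L, evalue = 1e-30,
            stringsAsFactors = FALSE)
          off <- off + L
        }
      } else if (startsWith(kind, "marker_")) {
        lab <- switch(sub("marker_", "", kind), sigma54 = "SIGMA54",
                      sis = "SIS", is_element = "TRANSPOSASE")
        sig <- vocab$signature_id[vocab$label == lab][1]
        dh[[length(dh) + 1L]] <- data.frame(
          gene_id = allu$gene_id[i], signature_id = sig, aa_start = 5L,
          aa_end = min(120L, nchar(allu$aa[i])), evalue = 1e-20,
          stringsAsFactors = FALSE)
      }
    }
    domains <- if (length(dh)) do.call(rbind, dh) else
      data.frame(gene_id = character(0), signature_id = character(0),
                 aa_start = integer(0), aa_end = integer(0),
                 evalue = numeric(0), stringsAsFactors = FALSE)
    bundles[[gid]] <- list(genome_id = gid,
                           contigs = stats::setNames(contig, contig_id),
                           genes = genes, domains = domains,
                           genome_gc = gc_percent(contig))
    # manifest rows
    for (lb in names(blocks)) {
      bu <- allu[!is.na(allu$label) & allu$label == lb, , drop = FALSE]
      tp <- tpl_all[tpl_all$label == lb, ]
      mem <- bu$gene_id[bu$kind == "pts"]
      ins <- bu$gene_id[bu$kind == "inserted"]
      manifest[[length(manifest) + 1L]] <- data.frame(
        label = lb, genome_id = gid, contig = contig_id,
        members = paste(mem, collapse = ","),
        inserted = paste(ins, collapse = ","),
        architecture = tp$architecture, family = tp$family,
        class = tp$class, orphan = tp$orphan,
        duplicate_of = tp$duplicate_of, hgt = tp$hgt, donor = tp$donor,
        is_flanked = tp$is_flanked,
        strand = bu$strand[1],
        start = min(bu$start[bu$kind %in% c("pts", "inserted")]),
        end = max(bu$end[bu$kind %in% c("pts", "inserted")]),
        stringsAsFactors = FALSE)
    }
  }
  list(spec = spec, species_tree = tree, bundles = bundles,
       manifest = do.call(rbind, manifest))
}
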