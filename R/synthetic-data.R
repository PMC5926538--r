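#' Simulation configuration
#'
#' Study conditions for the synthetic genomes, expression matrices and
#' capture tables. Defaults emulate a scaled-down two-species ruminant
#' setting: a pair of genomes with conserved gene order, planted orthologous
#' intergenic lncRNAs at controlled divergence and stochastic per-species
#' capture, and a 13-tissue expression atlas (11 core tissues plus one cell
#' type under two conditions) with six replicates per tissue.
#'
#' @param seed integer RNG seed; every generator derives its own stream from
#'   it plus a fixed per-generator offset, so outputs are byte-identical
#'   under a fixed seed and adding one generator never reshuffles another.
#' @param n_chroms,genes_per_chrom genome shape.
#' @param gene_len,intergenic_len,lncrna_len sampling ranges (bp).
#' @param n_planted_lncrnas planted orthologous lncRNAs (must fit in the
#'   available intergenic gaps).
#' @param divergence_mu per-base substitution probability between the two
#'   species' copies of a planted lncRNA.
#' @param indel_rate optional per-base indel probability (default 0;
#'   substitution-only divergence is the clean recovery regime for a
#'   gapless-run acceptance criterion).
#' @param p_capture probability a planted lncRNA is "assembled" (appears in
#'   the annotation) in a given species, independently per species.
#' @param rearrangement_rate controls gene-order breakage in species B;
#'   implemented as segmental translocation with per-boundary cut probability
#'   rate/2, so the fraction of conserved gene triples declines
#'   approximately linearly with the rate (rate 1 applies a perfect shuffle
#'   leaving no conserved triple).
#' @param tissues named character vector tissue -> group (organ system).
#' @param replicates_per_tissue replicates (individuals) per tissue.
#' @param n_housekeeping,n_tissue_specific planted expression categories.
#' @param n_coexpressed_pairs planted enhancer-like lncRNA/mRNA pairs; each
#'   pair shares a per-sample latent profile and the lncRNA is placed close
#'   (within ~200 bp) to its partner gene.
#' @param n_programs distinct co-expression programmes the pairs cycle over
#'   (default one per pair; must not exceed the number of tissues).
#' @param noise_sd lognormal (natural-log scale) noise on expression.
#' @param dropout_p per-library probability a transcript is not fully
#'   captured (then absent or truncated with equal probability).
#' @param n_individuals individuals for the per-library capture tables.
#' @param n_coding_contaminants planted protein-coding contaminants in the
#'   coding-potential score tables.
#' @return A validated list of class \code{sim_config}.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L,
                              genes_per_chrom = 50L,
                              gene_len = c(1000L, 3000L),
                              intergenic_len = c(1500L, 4000L),
                              n_planted_lncrnas = 40L,
                              lncrna_len = c(500L, 1500L),
                              divergence_mu = 0.02,
                              indel_rate = 0,
                              p_capture = 0.7,
                              rearrangement_rate = 0.1,
                              tissues = c(
                                bicep_muscle = "musculoskeletal",
                                hippocampus = "CNS",
                                ileum = "gastrointestinal",
                                kidney_medulla = "urinary",
                                left_ventricle = "cardiovascular",
                                liver = "hepatic",
                                ovary = "reproductive",
                                reticulum = "gastrointestinal",
                                spleen = "immune",
                                testes = "reproductive",
                                thymus = "immune",
                                BMDM_unstim = "myeloid",
                                BMDM_LPS = "myeloid"),
                              replicates_per_tissue = 6L,
                              n_housekeeping = 15L,
                              n_tissue_specific = 15L,
                              n_coexpressed_pairs = 10L,
                              n_programs = NULL,
                              noise_sd = 0.15,
                              dropout_p = 0.3,
                              n_individuals = 6L,
                              n_coding_contaminants = 10L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              genes_per_chrom = as.integer(genes_per_chrom),
              gene_len = as.integer(gene_len),
              intergenic_len = as.integer(intergenic_len),
              n_planted_lncrnas = as.integer(n_planted_lncrnas),
              lncrna_len = as.integer(lncrna_len),
              divergence_mu = divergence_mu, indel_rate = indel_rate,
              p_capture = p_capture, rearrangement_rate = rearrangement_rate,
              tissues = tissues,
              replicates_per_tissue = as.integer(replicates_per_tissue),
              n_housekeeping = as.integer(n_housekeeping),
              n_tissue_specific = as.integer(n_tissue_specific),
              n_coexpressed_pairs = as.integer(n_coexpressed_pairs),
              n_programs = as.integer(n_programs %||% n_coexpressed_pairs),
              noise_sd = noise_sd, dropout_p = dropout_p,
              n_individuals = as.integer(n_individuals),
              n_coding_contaminants = as.integer(n_coding_contaminants))
  probs <- c(cfg$divergence_mu, cfg$indel_rate, cfg$p_capture,
             cfg$rearrangement_rate, cfg$dropout_p)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_chroms, cfg$genes_per_chrom, cfg$n_planted_lncrnas,
              cfg$n_housekeeping, cfg$n_tissue_specific,
              cfg$n_coexpressed_pairs, cfg$n_individuals)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(cfg$tissues) < 2L) stop("need at least 2 tissues")
  if (cfg$replicates_per_tissue < 2L) stop("need at least 2 replicates per tissue")
  if (cfg$n_programs > length(cfg$tissues)) {
    stop("n_programs cannot exceed the number of tissues")
  }
  structure(cfg, class = "sim_config")
}

.mutate_seq <- function(seq, mu, indel_rate = 0) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  hit <- stats::runif(n) < mu
  if (any(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    bases[hit] <- vapply(bases[hit], function(b) {
      substring(alt[[b]], s <- sample.int(3L, 1L), s)
    }, character(1L))
  }
  if (indel_rate > 0) {
    keep <- stats::runif(length(bases)) >= indel_rate / 2  # deletions
    bases <- bases[keep]
    ins <- which(stats::runif(length(bases)) < indel_rate / 2)
    if (length(ins)) {
      out <- character(0)
      prev <- 1L
      for (i in ins) {
        out <- c(out, bases[prev:i], sample(c("A", "C", "G", "T"), 1L))
        prev <- i + 1L
      }
      if (prev <= length(bases)) out <- c(out, bases[prev:length(bases)])
      bases <- out
    }
  }
  paste(bases, collapse = "")
}

# species-B gene order after segmental translocation (indices into 1..n)
.rearranged_order <- function(n, rate) {
  if (rate <= 0 || n < 4L) return(seq_len(n))
  if (rate >= 1) {
    # perfect shuffle: no originally adjacent pair stays adjacent
    return(c(seq(1L, n, by = 2L), seq(2L, n, by = 2L)))
  }
  cuts <- which(stats::runif(n - 1L) < rate / 2)
  if (!length(cuts)) return(seq_len(n))
  bounds <- c(0L, cuts, n)
  segs <- lapply(seq_len(length(bounds) - 1L), function(i) {
    (bounds[i] + 1L):bounds[i + 1L]
  })
  k <- length(segs)
  perm <- sample.int(k)
  while (all(perm == seq_len(k))) perm <- sample.int(k)
  unlist(segs[perm], use.names = FALSE)
}

# exon structure for a gene span: 1..4 exons inside [start, end]
.exon_chain <- function(start, end, max_exons = 4L) {
  len <- end - start + 1L
  n_ex <- sample.int(max_exons, 1L)
  if (n_ex == 1L || len < n_ex * 60L + (n_ex - 1L) * 30L) {
    return(data.frame(start = start, end = end))
  }
  # cut the span into exon/intron alternation with minimum widths
  inner <- sort(sample.int(len - 2L, 2L * (n_ex - 1L))) + start
  s <- c(start, inner[seq(2L, length(inner), by = 2L)] + 1L)
  e <- c(inner[seq(1L, length(inner), by = 2L)], end)
  ok <- s <= e
  s <- s[ok]; e <- e[ok]
  if (length(s) > 1L && any(s[-1L] <= e[-length(e)])) {
    return(data.frame(start = start, end = end))
  }
  data.frame(start = s, end = e)
}

#' Simulate a pair of genomes with conserved gene order and planted lncRNAs
#'
#' Species A and B share gene symbols in conserved order except where
#' segmental translocation (rate \code{rearrangement_rate}) reorders species
#' B. Each planted lncRNA occupies one internal intergenic gap of species A;
#' its species-B copy, substituted at rate \code{divergence_mu} (and indel'd
#' at \code{indel_rate}), is embedded in the corresponding species-B gap.
#' Background intergenic sequence is i.i.d. uniform A/C/G/T and independent
#' between species, so only planted copies are homologous. A lncRNA appears
#' in a species' annotation (as a mono-exonic, unknown-strand, single
#' transcript gene model) only where its per-species capture Bernoulli draw
#' succeeded.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @return list with \code{a}, \code{b} (each: \code{annotation},
#'   \code{genome}) and \code{truth}: \code{ortholog_pairs} (per-pair
#'   coordinates in both species, divergence, capture flags, the species-A
#'   sequence and its diverged species-B copy, and the flanking gene symbols)
#'   and \code{gene_order_b}.
#' @export
simulate_genome_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(.derive_seed(cfg$seed, "genome_pair"), {
    n_gaps_total <- cfg$n_chroms * (cfg$genes_per_chrom - 1L)
    if (cfg$n_planted_lncrnas > n_gaps_total) {
      stop("not enough internal intergenic gaps (", n_gaps_total,
           ") for ", cfg$n_planted_lncrnas, " planted lncRNAs")
    }
    rint <- function(n, range) sample(seq(range[1L], range[2L]), n, replace = TRUE)

    # gene scaffold shared by both species: symbols and per-species lengths
    chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
    scaffold <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(ci) {
      data.frame(chrom = chroms[ci], idx = seq_len(cfg$genes_per_chrom),
                 symbol = sprintf("S%dG%03d", ci, seq_len(cfg$genes_per_chrom)),
                 strand = sample(c("+", "-"), cfg$genes_per_chrom, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))

    # choose planted gaps: (chrom index, gap index = between gene i and i+1)
    gap_tab <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(ci) {
      data.frame(ci = ci, gap = seq_len(cfg$genes_per_chrom - 1L))
    }))
    planted <- gap_tab[sample.int(nrow(gap_tab), cfg$n_planted_lncrnas), , drop = FALSE]
    planted <- planted[order(planted$ci, planted$gap), , drop = FALSE]
    planted$lnc_id <- sprintf("LNC%04d", seq_len(nrow(planted)))
    lnc_len <- rint(nrow(planted), cfg$lncrna_len)
    lnc_seq_a <- vapply(lnc_len, .random_dna, character(1L))
    lnc_seq_b <- vapply(lnc_seq_a, .mutate_seq, character(1L),
                        mu = cfg$divergence_mu, indel_rate = cfg$indel_rate,
                        USE.NAMES = FALSE)
    cap_a <- stats::runif(nrow(planted)) < cfg$p_capture
    cap_b <- stats::runif(nrow(planted)) < cfg$p_capture

    build_species <- function(order_by_chrom, lnc_seqs, species) {
      genes <- list(); lgenes <- list(); seqs <- character(0)
      lnc_rows <- list()
      for (ci in seq_len(cfg$n_chroms)) {
        ord <- order_by_chrom[[ci]]
        sc <- scaffold[scaffold$chrom == chroms[ci], , drop = FALSE][ord, , drop = FALSE]
        n <- nrow(sc)
        glen <- rint(n, cfg$gene_len)
        ilen <- rint(n + 1L, cfg$intergenic_len)
        # planted lncRNAs on this chromosome: the gap after scaffold gene idx
        pl <- planted[planted$ci == ci, , drop = FALSE]
        # a gap is identified by the ordered pair of flanking original indices
        gap_after <- match(pl$gap, ord)  # position in current order of gene "gap"
        # only gaps whose flanking genes are still adjacent in this order
        adjacent <- !is.na(gap_after) & gap_after < n &
          ord[pmin(gap_after + 1L, n)] == pl$gap + 1L
        # grow gaps that must hold planted lncRNAs
        for (gi in seq_len(n - 1L)) {
          hit <- which(adjacent & gap_after == gi)
          if (length(hit)) {
            need <- sum(nchar(lnc_seqs[pl$lnc_id[hit]])) + 250L * length(hit)
            if (ilen[gi + 1L] < need) ilen[gi + 1L] <- need
          }
        }
        chrom_parts <- character(0); pos <- 0L
        gene_start <- integer(n); gene_end <- integer(n)
        for (gi in seq_len(n)) {
          chrom_parts <- c(chrom_parts, .random_dna(ilen[gi]))
          pos <- pos + ilen[gi]
          gene_start[gi] <- pos + 1L
          chrom_parts <- c(chrom_parts, .random_dna(glen[gi]))
          pos <- pos + glen[gi]
          gene_end[gi] <- pos
          hit <- which(adjacent & gap_after == gi)
          if (length(hit)) {
            margin <- sample(20:200, length(hit), replace = TRUE)
            at <- pos + cumsum(c(0L, utils::head(nchar(lnc_seqs[pl$lnc_id[hit]]) +
                                                   margin, -1L))) + margin
            for (k in seq_along(hit)) {
              lid <- pl$lnc_id[hit[k]]
              lnc_rows[[lid]] <- data.frame(
                lnc_id = lid, chrom = chroms[ci], start = at[k],
                end = at[k] + nchar(lnc_seqs[lid]) - 1L, stringsAsFactors = FALSE)
            }
          }
        }
        chrom_seq <- paste(chrom_parts, collapse = "")
        chrom_seq <- paste0(chrom_seq, .random_dna(ilen[n + 1L]))
        # splice the planted sequences into the gap background
        for (lid in names(lnc_rows)) {
          lr <- lnc_rows[[lid]]
          if (lr$chrom != chroms[ci]) next
          substr(chrom_seq, lr$start, lr$end) <- lnc_seqs[[lid]]
        }
        seqs[[chroms[ci]]] <- chrom_seq
        genes[[ci]] <- data.frame(
          gene_id = paste0(species, "_", sc$symbol), symbol = sc$symbol,
          chrom = chroms[ci], start = gene_start, end = gene_end,
          strand = sc$strand, biotype = "protein_coding", stringsAsFactors = FALSE)
      }
      list(genes = do.call(rbind, genes), seqs = seqs,
           lnc = if (length(lnc_rows)) do.call(rbind, lnc_rows) else NULL)
    }

    order_a <- replicate(cfg$n_chroms, seq_len(cfg$genes_per_chrom), simplify = FALSE)
    order_b <- lapply(seq_len(cfg$n_chroms), function(ci) {
      .rearranged_order(cfg$genes_per_chrom, cfg$rearrangement_rate)
    })
    names(lnc_seq_a) <- names(lnc_seq_b) <- planted$lnc_id
    sp_a <- build_species(order_a, lnc_seq_a, "A")
    sp_b <- build_species(order_b, lnc_seq_b, "B")

    make_ann <- function(sp, captured, species) {
      lnc <- sp$lnc
      lnc_genes <- if (!is.null(lnc)) {
        li <- match(lnc$lnc_id, planted$lnc_id)
        sel <- captured[li]
        lnc <- lnc[sel, , drop = FALSE]
        if (nrow(lnc)) data.frame(
          gene_id = lnc$lnc_id, symbol = "", chrom = lnc$chrom,
          start = lnc$start, end = lnc$end, strand = "*",
          biotype = "lncRNA", stringsAsFactors = FALSE)
        else NULL
      } else NULL
      genes <- rbind(sp$genes, lnc_genes)
      tx <- data.frame(transcript_id = paste0(genes$gene_id, ".t1"),
                       gene_id = genes$gene_id, chrom = genes$chrom,
                       strand = genes$strand, stringsAsFactors = FALSE)
      exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
        ch <- if (genes$biotype[i] == "protein_coding") {
          .exon_chain(genes$start[i], genes$end[i])
        } else data.frame(start = genes$start[i], end = genes$end[i])
        data.frame(transcript_id = tx$transcript_id[i], start = ch$start,
                   end = ch$end, stringsAsFactors = FALSE)
      }))
      annotation(genes, tx, exons)
    }
    ann_a <- make_ann(sp_a, cap_a, "A")
    ann_b <- make_ann(sp_b, cap_b, "B")

    coord <- function(sp, what) {
      if (is.null(sp$lnc)) {
        return(if (what == "chrom") rep(NA_character_, nrow(planted))
               else rep(NA_integer_, nrow(planted)))
      }
      sp$lnc[match(planted$lnc_id, sp$lnc$lnc_id), what]
    }
    truth_pairs <- data.frame(
      lnc_id = planted$lnc_id,
      a_chrom = coord(sp_a, "chrom"), a_start = coord(sp_a, "start"),
      a_end = coord(sp_a, "end"),
      b_chrom = coord(sp_b, "chrom"), b_start = coord(sp_b, "start"),
      b_end = coord(sp_b, "end"),
      divergence = cfg$divergence_mu,
      captured_a = cap_a & !is.na(coord(sp_a, "start")),
      captured_b = cap_b & !is.na(coord(sp_b, "start")),
      seq_a = unname(lnc_seq_a), seq_b = unname(lnc_seq_b),
      left_symbol = sprintf("S%dG%03d", planted$ci, planted$gap),
      right_symbol = sprintf("S%dG%03d", planted$ci, planted$gap + 1L),
      stringsAsFactors = FALSE)

    list(a = list(annotation = ann_a, genome = sp_a$seqs),
         b = list(annotation = ann_b, genome = sp_b$seqs),
         truth = list(ortholog_pairs = truth_pairs, gene_order_b = order_b))
  })
}

#' Simulate a tissue-atlas expression dataset with planted structure
#'
#' Transcript-level TPM tables with known ground truth: housekeeping genes
#' with a flat tissue profile, tissue-specific genes expressed in one tissue
#' only, and enhancer-like co-expressed lncRNA/mRNA pairs sharing a
#' per-sample latent profile (pairs cycle over \code{n_programs} distinct
#' single-tissue programmes). All remaining genes get independent "mixed"
#' profiles. Noise is lognormal with scale \code{noise_sd}; every sample's
#' TPM column is normalised to 1e6, and est_counts are consistent with
#' tpm and eff_length up to a per-sample sequencing-depth scale.
#'
#' Co-expressed pairs are chosen as a captured lncRNA plus its nearest
#' protein-coding gene on the same chromosome (the enhancer-like geometry
#' the proximity tests look for).
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param ann an \code{lnc_annotation} (typically species A from
#'   \code{\link{simulate_genome_pair}}).
#' @return list: \code{tpm} and \code{counts} (transcripts x samples),
#'   \code{metadata} (sample, tissue, replicate, group), \code{tx2gene},
#'   and \code{truth} (specific_genes: gene -> intended category;
#'   coexpressed_pairs: lnc_id, partner_gene, program, program_tissue).
#' @export
simulate_expression <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(.derive_seed(cfg$seed, "expression"), {
    tissues <- names(cfg$tissues)
    nt <- length(tissues); nr <- cfg$replicates_per_tissue
    md <- data.frame(
      sample = sprintf("%s_r%d", rep(tissues, each = nr), rep(seq_len(nr), nt)),
      tissue = rep(tissues, each = nr),
      replicate = rep(seq_len(nr), nt),
      group = rep(unname(cfg$tissues), each = nr),
      stringsAsFactors = FALSE)
    ns <- nrow(md)

    genes <- ann$genes
    coding <- genes[genes$biotype == "protein_coding", , drop = FALSE]
    lnc <- genes[genes$biotype == "lncRNA", , drop = FALSE]
    n_cat <- cfg$n_housekeeping + cfg$n_tissue_specific
    if (nrow(coding) < n_cat + cfg$n_coexpressed_pairs) {
      stop("fewer protein-coding genes than planted categories")
    }

    # co-expressed pairs: lncRNA + nearest coding gene on its chromosome;
    # lncRNAs whose nearest gene already partners another pair are skipped so
    # every pair has a distinct partner
    want <- min(cfg$n_coexpressed_pairs, nrow(lnc))
    cand_order <- if (nrow(lnc)) sample.int(nrow(lnc)) else integer(0)
    pair_idx <- integer(0); partner <- character(0)
    for (i in cand_order) {
      if (length(pair_idx) >= want) break
      cand <- coding[coding$chrom == lnc$chrom[i], , drop = FALSE]
      if (!nrow(cand)) next
      d <- .gap_dist(lnc$start[i], lnc$end[i], cand$start, cand$end)
      p <- cand$gene_id[which.min(d)]
      if (p %in% partner) next
      pair_idx <- c(pair_idx, i); partner <- c(partner, p)
    }
    n_pairs <- length(pair_idx)
    pair_lnc <- lnc[pair_idx, , drop = FALSE]
    program <- if (n_pairs) rep(seq_len(cfg$n_programs), length.out = n_pairs) else integer(0)
    program_tissue <- tissues[program]

    pool <- setdiff(coding$gene_id, partner)
    hk <- pool[seq_len(cfg$n_housekeeping)]
    ts <- pool[cfg$n_housekeeping + seq_len(cfg$n_tissue_specific)]
    ts_tissue <- sample(tissues, length(ts), replace = TRUE)

    all_genes <- genes$gene_id
    base <- matrix(0, length(all_genes), ns,
                   dimnames = list(all_genes, md$sample))
    noise <- function(n) exp(stats::rnorm(n, 0, cfg$noise_sd))

    # mixed background: random moderate tissue means
    for (g in all_genes) {
      mt <- stats::runif(nt, 2, 30)
      base[g, ] <- mt[match(md$tissue, tissues)] * noise(ns)
    }
    for (g in hk) {
      lvl <- stats::runif(1L, 30, 80)
      base[g, ] <- lvl * noise(ns)
    }
    for (k in seq_along(ts)) {
      v <- numeric(ns)
      v[md$tissue == ts_tissue[k]] <- stats::runif(1L, 60, 200) *
        noise(sum(md$tissue == ts_tissue[k]))
      base[ts[k], ] <- v
    }
    # shared latent per-program profiles: spike in the programme tissue with
    # sample-level latent variation shared by all members
    if (n_pairs) {
      latent <- lapply(seq_len(cfg$n_programs), function(p) {
        v <- numeric(ns)
        on <- md$tissue == tissues[p]
        v[on] <- stats::runif(1L, 150, 300) * exp(stats::rnorm(sum(on), 0, 1.2))
        v
      })
      for (k in seq_len(n_pairs)) {
        base[pair_lnc$gene_id[k], ] <- latent[[program[k]]] * noise(ns)
        base[partner[k], ] <- latent[[program[k]]] * noise(ns)
      }
    }
    # uncaptured-in-expression lncRNAs keep their mixed background

    # transcript level: coding genes may carry 2 transcripts (split TPM)
    tx <- ann$transcripts
    tx2gene <- stats::setNames(tx$gene_id, tx$transcript_id)
    split2 <- coding$gene_id[seq_len(nrow(coding)) %% 5L == 0L]
    tx_ids <- tx$transcript_id
    extra <- sprintf("%s.t2", split2)
    tx_ids <- c(tx_ids, extra)
    tx2gene <- c(tx2gene, stats::setNames(split2, extra))
    frac <- stats::setNames(rep(1, length(tx_ids)), tx_ids)
    frac[paste0(split2, ".t1")] <- 0.6
    frac[extra] <- 0.4

    tpm <- base[tx2gene[tx_ids], , drop = FALSE] * frac[tx_ids]
    rownames(tpm) <- tx_ids
    tpm <- sweep(tpm, 2L, colSums(tpm), "/") * 1e6

    tx_len <- integer(length(tx_ids))
    known <- match(tx_ids, tx$transcript_id)
    lens <- transcript_lengths(ann)
    tx_len <- ifelse(!is.na(known), lens[tx$transcript_id[known]],
                     lens[paste0(tx2gene[tx_ids], ".t1")])
    names(tx_len) <- tx_ids
    eff_len <- pmax(tx_len - 150L, 1L)
    depth <- stats::runif(ns, 1e6, 3e6)
    raw <- tpm * eff_len
    counts <- sweep(raw, 2L, colSums(raw), "/") * rep(depth, each = nrow(raw))

    list(tpm = tpm, counts = counts, metadata = md, tx2gene = tx2gene,
         lengths = tx_len, eff_lengths = eff_len,
         truth = list(
           specific_genes = rbind(
             data.frame(gene_id = hk, category = "housekeeping",
                        tissue = NA_character_, stringsAsFactors = FALSE),
             data.frame(gene_id = ts, category = "tissue_specific",
                        tissue = ts_tissue, stringsAsFactors = FALSE)),
           coexpressed_pairs = data.frame(
             lnc_id = pair_lnc$gene_id, partner_gene = partner,
             program = program, program_tissue = program_tissue,
             stringsAsFactors = FALSE)))
  })
}

#' Write Kallisto-style abundance tables and sample metadata
#'
#' One \code{<sample>.tsv} per sample with columns exactly target_id, length,
#' eff_length, est_counts, tpm, plus \code{samples.tsv} (sample, tissue,
#' replicate, group).
#'
#' @param expr result of \code{\link{simulate_expression}}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_abundance_tables <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in colnames(expr$tpm)) {
    df <- data.frame(target_id = rownames(expr$tpm),
                     length = as.integer(expr$lengths[rownames(expr$tpm)]),
                     eff_length = as.numeric(expr$eff_lengths[rownames(expr$tpm)]),
                     est_counts = expr$counts[, s], tpm = expr$tpm[, s])
    utils::write.table(df, file.path(dir, paste0(s, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(expr$metadata, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a coding-potential score table with planted contaminants
#'
#' Clean candidates receive scores that satisfy all five shortlist criteria;
#' each planted coding contaminant violates at least one (uniformly chosen),
#' possibly several.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param candidate_ids model ids to score.
#' @param planted_coding_ids subset of \code{candidate_ids} that are coding
#'   contaminants.
#' @return data.frame in the coding-score table layout (NA = absent E-value).
#' @export
simulate_coding_scores <- function(cfg, candidate_ids, planted_coding_ids = character(0)) {
  stopifnot(inherits(cfg, "sim_config"),
            all(planted_coding_ids %in% candidate_ids))
  .with_seed(.derive_seed(cfg$seed, "coding_scores"), {
    n <- length(candidate_ids)
    df <- data.frame(
      model_id = candidate_ids,
      cpc_score = stats::runif(n, -2, -0.6),
      cpat_prob = stats::runif(n, 0.01, 0.4),
      plek_label = "noncoding",
      blastp_best_evalue = NA_real_,
      hmmer_best_evalue = NA_real_,
      stringsAsFactors = FALSE)
    for (id in planted_coding_ids) {
      i <- match(id, candidate_ids)
      fail <- sample.int(5L, sample(1:2, 1L))
      if (1L %in% fail) df$cpc_score[i] <- stats::runif(1L, -0.5, 2)
      if (2L %in% fail) df$cpat_prob[i] <- stats::runif(1L, 0.7, 0.99)
      if (3L %in% fail) df$plek_label[i] <- "coding"
      if (4L %in% fail) df$blastp_best_evalue[i] <- 10^stats::runif(1L, -30, -6)
      if (5L %in% fail) df$hmmer_best_evalue[i] <- 10^stats::runif(1L, -30, -6)
    }
    # benign high E-value hits on some clean candidates (above threshold)
    clean <- setdiff(candidate_ids, planted_coding_ids)
    some <- clean[stats::runif(length(clean)) < 0.2]
    df$blastp_best_evalue[match(some, candidate_ids)] <- 10^stats::runif(length(some), -3, 1)
    df
  })
}

#' Simulate per-individual transcript captures with dropout
#'
#' Every annotation transcript is fully present in an individual's library
#' with probability \code{1 - dropout_p}; otherwise it is absent or truncated
#' (a terminal exon dropped, or a mono-exon extent shrunk to 70%) with equal
#' probability. Truth records full presence per transcript per individual.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param ann an \code{lnc_annotation} providing the reference transcripts.
#' @return list: \code{individual_sets} (named list of transcript-set
#'   data.frames), \code{reference} (the full transcript set) and
#'   \code{presence} (transcripts x individuals logical matrix: fully
#'   present).
#' @export
simulate_library_captures <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_individuals < 2L) stop("need at least 2 individuals")
  .with_seed(.derive_seed(cfg$seed, "library_captures"), {
    ref <- transcript_set(ann)
    inds <- sprintf("ind%02d", seq_len(cfg$n_individuals))
    presence <- matrix(FALSE, nrow(ref), cfg$n_individuals,
                       dimnames = list(ref$transcript_id, inds))
    sets <- stats::setNames(vector("list", length(inds)), inds)
    for (j in seq_along(inds)) {
      rows <- list()
      for (i in seq_len(nrow(ref))) {
        u <- stats::runif(1L)
        if (u >= cfg$dropout_p) {
          presence[i, j] <- TRUE
          rows[[length(rows) + 1L]] <- ref[i, , drop = FALSE]
        } else if (u < cfg$dropout_p / 2) {
          next  # absent
        } else {
          s <- as.integer(strsplit(ref$exon_starts[i], ",")[[1L]])
          e <- as.integer(strsplit(ref$exon_ends[i], ",")[[1L]])
          if (length(s) > 1L) {
            drop_last <- stats::runif(1L) < 0.5
            keep <- if (drop_last) seq_len(length(s) - 1L) else 2:length(s)
            s <- s[keep]; e <- e[keep]
          } else {
            len <- e - s + 1L
            e <- s + as.integer(0.7 * len) - 1L
          }
          tr <- ref[i, , drop = FALSE]
          tr$transcript_id <- paste0(tr$transcript_id, ".part")
          tr$exon_starts <- paste(s, collapse = ",")
          tr$exon_ends <- paste(e, collapse = ",")
          rows[[length(rows) + 1L]] <- tr
        }
      }
      sets[[j]] <- if (length(rows)) do.call(rbind, rows) else ref[0, , drop = FALSE]
    }
    list(individual_sets = sets, reference = ref, presence = presence)
  })
}
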