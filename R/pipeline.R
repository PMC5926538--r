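#' Run the full synthetic demonstration pipeline
#'
#' Chains every stage end-to-end on generated data with known ground truth,
#' mirroring the analysis order: simulate genomes and expression; longlist
#' and shortlist filtering with simulated coding-potential scores; positional
#' classification; synteny-block detection; cross-species mapping; gene-level
#' expression summary; co-expression graph and Markov clustering; proximity
#' randomisation tests; subset-reconstruction analysis. Stage outputs are
#' written as TSV/BED/FASTA/GTF under \code{out_dir} together with a manifest
#' recording parameters and output checksums; a rerun with the same config is
#' byte-identical.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param out_dir output directory (created; stage files overwritten).
#' @param min_run gapless-run acceptance threshold (default 20).
#' @param r_threshold co-expression edge threshold (default 0.95).
#' @param inflation MCL inflation (default 2.2).
#' @param s randomisations per proximity test (default 1000).
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a list with the main in-memory results per stage.
#' @export
run_demo_pipeline <- function(cfg = simulation_config(), out_dir = tempfile("syntelnc_demo_"),
                              min_run = 20L, r_threshold = 0.95, inflation = 2.2,
                              s = 1000L, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  written <- character(0)

  say("[simulate] genomes, expression, scores, captures (seed %d)", cfg$seed)
  gp <- simulate_genome_pair(cfg)
  write_gtf(gp$a$annotation, file.path(out_dir, "species_a.gtf"))
  write_gtf(gp$b$annotation, file.path(out_dir, "species_b.gtf"))
  write_genome_fasta(gp$a$genome, file.path(out_dir, "species_a.fa"))
  write_genome_fasta(gp$b$genome, file.path(out_dir, "species_b.fa"))
  written <- c(written, "species_a.gtf", "species_b.gtf", "species_a.fa", "species_b.fa")
  expr <- simulate_expression(cfg, gp$a$annotation)

  say("[filter] longlist + shortlist, species A")
  ann_a <- gp$a$annotation
  lnc_models_a <- ann_a$genes$gene_id[ann_a$genes$biotype == "lncRNA"]
  models_a <- annotation(ann_a$genes[ann_a$genes$gene_id %in% lnc_models_a, , drop = FALSE],
                         ann_a$transcripts[ann_a$transcripts$gene_id %in% lnc_models_a, , drop = FALSE],
                         ann_a$exons[ann_a$exons$transcript_id %in%
                                       ann_a$transcripts$transcript_id[
                                         ann_a$transcripts$gene_id %in% lnc_models_a], , drop = FALSE])
  reference_a <- annotation(ann_a$genes[ann_a$genes$biotype != "lncRNA", , drop = FALSE],
                            ann_a$transcripts[!ann_a$transcripts$gene_id %in% lnc_models_a, , drop = FALSE],
                            ann_a$exons[ann_a$exons$transcript_id %in%
                                          ann_a$transcripts$transcript_id[
                                            !ann_a$transcripts$gene_id %in% lnc_models_a], , drop = FALSE])
  long <- build_longlist(models_a, reference_a)
  contaminants <- .with_seed(.derive_seed(cfg$seed, "contaminant_pick"), {
    sample(long$retained, min(cfg$n_coding_contaminants, length(long$retained)))
  })
  scores <- simulate_coding_scores(cfg, long$retained, contaminants)
  short <- build_shortlist(long$retained, scores)
  decisions <- rbind(long$decisions, short$decisions)
  written <- c(written, tsv(decisions, "filter_decisions.tsv"),
               tsv(scores, "coding_scores.tsv"))
  filt <- summarize_filters(decisions)
  written <- c(written, tsv(filt$summary, "filter_summary.tsv"))

  say("[classify] positional classes, species A")
  classes <- classify_lncrnas(models_a, reference_a)
  written <- c(written, tsv(classes, "positional_classes.tsv"))

  say("[synteny] gene triples and shared blocks")
  tri_a <- enumerate_triples(gp$a$annotation)
  tri_b <- enumerate_triples(gp$b$annotation)
  blocks <- match_blocks(tri_a, tri_b)
  lnc_tab <- function(ann) {
    g <- ann$genes[ann$genes$biotype == "lncRNA", c("gene_id", "chrom", "start", "end")]
    rownames(g) <- NULL
    g
  }
  presence <- assign_lncrnas_to_blocks(blocks, lnc_tab(gp$a$annotation), lnc_tab(gp$b$annotation))
  syn_rep <- synteny_report(blocks, presence)
  written <- c(written, tsv(blocks, "synteny_blocks.tsv"),
               tsv(presence, "block_presence.tsv"), tsv(syn_rep, "synteny_report.tsv"))

  say("[crossmap] inferring lncRNAs across the pair (min run %d)", min_run)
  seq_of <- function(ann, genome) {
    lg <- ann$genes[ann$genes$biotype == "lncRNA", , drop = FALSE]
    tx <- paste0(lg$gene_id, ".t1")
    stats::setNames(vapply(tx, function(t) extract_transcript_sequence(ann, t, genome),
                           character(1L)), lg$gene_id)
  }
  inferred_b <- crossmap_lncrnas(blocks, presence, "a", "b",
                                 seq_of(gp$a$annotation, gp$a$genome),
                                 target_genome = gp$b$genome, min_run = min_run)
  inferred_a <- crossmap_lncrnas(blocks, presence, "b", "a",
                                 seq_of(gp$b$annotation, gp$b$genome),
                                 target_genome = gp$a$genome, min_run = min_run)
  crossmap_rows <- rbind(
    cbind(source = "a", target = "b",
          crossmap_report_row(attr(inferred_b, "n_attempted"), nrow(inferred_b),
                              2L * nrow(blocks),
                              length(unique(paste(inferred_b$block_id, inferred_b$position))))),
    cbind(source = "b", target = "a",
          crossmap_report_row(attr(inferred_a, "n_attempted"), nrow(inferred_a),
                              2L * nrow(blocks),
                              length(unique(paste(inferred_a$block_id, inferred_a$position))))))
  written <- c(written, tsv(inferred_b[, setdiff(names(inferred_b), "sequence")],
                            "inferred_lncrnas_b.tsv"),
               tsv(crossmap_rows, "crossmap_report.tsv"))
  if (nrow(inferred_b)) {
    write_bed(data.frame(chrom = inferred_b$chrom, start = inferred_b$start,
                         end = inferred_b$end, name = inferred_b$id,
                         strand = inferred_b$strand),
              file.path(out_dir, "inferred_lncrnas_b.bed"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(inferred_b$sequence, inferred_b$id)),
      file.path(out_dir, "inferred_lncrnas_b.fa"))
    written <- c(written, "inferred_lncrnas_b.bed", "inferred_lncrnas_b.fa")
  }

  say("[summarize] gene-level expression statistics")
  gene_tpm <- aggregate_to_genes(expr$tpm, expr$tx2gene)
  gene_counts <- aggregate_to_genes(expr$counts, expr$tx2gene)
  summary <- summarize_expression(gene_tpm, expr$metadata, counts = gene_counts)
  written <- c(written, tsv(summary, "expression_summary.tsv"))

  say("[network] r >= %.2f graph + MCL (inflation %.1f)", r_threshold, inflation)
  program_genes <- c(expr$truth$coexpressed_pairs$lnc_id,
                     expr$truth$coexpressed_pairs$partner_gene)
  graph <- build_coexpression_graph(gene_tpm, threshold = r_threshold)
  clusters <- mcl_cluster(graph, inflation = inflation)
  biotypes <- stats::setNames(gp$a$annotation$genes$biotype, gp$a$annotation$genes$gene_id)
  comp <- cluster_composition(clusters$membership, biotypes, pem = attr(summary, "pem"))
  written <- c(written, tsv(data.frame(gene = names(clusters$membership),
                                       cluster = clusters$membership), "clusters.tsv"),
               tsv(comp, "cluster_composition.tsv"))

  say("[proximity] randomisation tests (s = %d)", s)
  coding_tab <- gp$a$annotation$genes[gp$a$annotation$genes$biotype == "protein_coding",
                                      c("gene_id", "chrom", "start", "end")]
  prox <- list()
  for (k in seq_len(nrow(expr$truth$coexpressed_pairs))) {
    pr <- expr$truth$coexpressed_pairs[k, ]
    lrow <- gp$a$annotation$genes[gp$a$annotation$genes$gene_id == pr$lnc_id, ]
    if (!nrow(lrow)) next
    cl_id <- clusters$membership[[pr$lnc_id]]
    members <- names(clusters$membership)[clusters$membership == cl_id]
    cl_genes <- coding_tab[coding_tab$gene_id %in% members, , drop = FALSE]
    if (!nrow(cl_genes[cl_genes$chrom == lrow$chrom, ])) next
    prox[[length(prox) + 1L]] <- cluster_distance_test(
      lrow, cl_genes, coding_tab, s = s, seed = cfg$seed, lnc_id = pr$lnc_id)
  }
  prox <- if (length(prox)) do.call(rbind, prox) else NULL
  if (!is.null(prox)) written <- c(written, tsv(prox, "proximity_tests.tsv"))

  say("[reconstruct] %d individuals, %d subsets", cfg$n_individuals,
      2L^cfg$n_individuals - 1L)
  caps <- simulate_library_captures(cfg, models_a)
  recon <- subset_reproducibility(caps$individual_sets, caps$reference)
  written <- c(written, tsv(recon, "reconstruction.tsv"))

  manifest <- data.frame(
    file = written,
    md5 = unname(tools::md5sum(file.path(out_dir, written))),
    stringsAsFactors = FALSE)
  params <- data.frame(key = c("seed", "min_run", "r_threshold", "inflation", "s"),
                       value = c(cfg$seed, min_run, r_threshold, inflation, s))
  tsv(params, "parameters.tsv")
  tsv(manifest, "manifest.tsv")
  say("[done] %d artifacts in %s", length(written) + 2L, out_dir)

  invisible(list(genome_pair = gp, expression = expr, longlist = long,
                 shortlist = short, filter_summary = filt, classes = classes,
                 blocks = blocks, presence = presence, synteny_report = syn_rep,
                 inferred_a = inferred_a, inferred_b = inferred_b,
                 crossmap_report = crossmap_rows, expression_summary = summary,
                 graph = graph, clusters = clusters, proximity = prox,
                 reconstruction = recon, out_dir = out_dir))
}
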