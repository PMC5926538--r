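ref_fixture <- function() {
  toy_annotation(rbind(
    gene_row("PC1", "chr1", 10000, 12000, "+", "protein_coding", "PC1"),
    gene_row("PS1", "chr1", 30000, 31000, "-", "pseudogene", "PS1"),
    gene_row("OT1", "chr1", 50000, 51000, "+", "other")))
}

test_that("longlist length thresholds follow the multi/mono-exon rules", {
  models <- toy_annotation(rbind(
    gene_row("M180", "chr1", 1000, 1400, "+", "other"),    # 180 bp over 2 exons
    gene_row("M450", "chr1", 2000, 2449, "*", "other"),    # 450 bp mono-exon
    gene_row("M500", "chr1", 3000, 3499, "*", "other"),    # 500 bp mono-exon boundary
    gene_row("M201", "chr1", 4000, 4500, "+", "other")),   # 201 bp over 2 exons
    list(cbind(c(1000, 1311), c(1089, 1400)),
         cbind(2000, 2449), cbind(3000, 3499),
         cbind(c(4000, 4400), c(4099, 4500))))
  res <- build_longlist(models, ref_fixture())
  d <- res$decisions
  expect_equal(d$reason[d$model_id == "M180"], "too_short")
  expect_equal(d$reason[d$model_id == "M450"], "single_exon_too_short")
  expect_true("M500" %in% res$retained)   # >= 500 retained (non-strict boundary)
  expect_true("M201" %in% res$retained)   # > 200 strict
})

test_that("overlap rule excludes only same-strand overlaps above 1 bp", {
  models <- toy_annotation(rbind(
    # overlaps PC1 by exactly 1 bp on the same strand: retained
    gene_row("EDGE", "chr1", 9401, 10000, "+", "other"),
    # overlaps PC1 by 2 bp on the same strand: excluded
    gene_row("OVER", "chr1", 9402, 10001, "+", "other"),
    # overlaps PC1 heavily but on the opposite strand: retained
    gene_row("ANTI", "chr1", 10000, 11000, "-", "other"),
    # unknown strand overlapping the pseudogene: tested on both strands
    gene_row("UNKN", "chr1", 29500, 30100, "*", "other"),
    # overlaps the biotype-"other" gene: not a coding overlap
    gene_row("OTHR", "chr1", 50000, 50700, "+", "other")))
  res <- build_longlist(models, ref_fixture())
  d <- res$decisions
  expect_true("EDGE" %in% res$retained)
  expect_equal(d$reason[d$model_id == "OVER"], "overlaps_coding")
  expect_true("ANTI" %in% res$retained)
  expect_equal(d$reason[d$model_id == "UNKN"], "overlaps_coding")
  expect_true("OTHR" %in% res$retained)
})

test_that("multi-transcript loci and exclusion-list genes are rejected with those reasons", {
  genes <- rbind(gene_row("MT", "chr1", 1000, 2000, "+", "other"),
                 gene_row("EX", "chr1", 5000, 5900, "+", "other"))
  tx <- data.frame(transcript_id = c("MT.t1", "MT.t2", "EX.t1"),
                   gene_id = c("MT", "MT", "EX"), chrom = "chr1", strand = "+",
                   stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = c("MT.t1", "MT.t2", "EX.t1"),
                      start = c(1000, 1000, 5000), end = c(2000, 1800, 5900))
  models <- annotation(genes, tx, exons)
  res <- build_longlist(models, ref_fixture(), exclusion_ids = "EX")
  expect_equal(res$decisions$reason[res$decisions$model_id == "MT"], "multi_transcript")
  expect_equal(res$decisions$reason[res$decisions$model_id == "EX"], "previously_coding")
})

test_that("models on chromosomes absent from the reference raise an error", {
  models <- toy_annotation(gene_row("M", "chrZ", 1000, 2000, "+", "other"))
  expect_error(build_longlist(models, ref_fixture()), "chrZ")
})

test_that("longest ORF matches a brute-force enumeration of ATG..stop spans", {
  brute_orf_len <- function(seq) {
    best <- 0L
    for (i in seq_len(max(nchar(seq) - 5, 0))) {
      if (substr(seq, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= nchar(seq)) {
        if (substr(seq, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, j + 2 - i + 1)
          break
        }
        j <- j + 3
      }
    }
    best
  }
  orf <- find_longest_orf("ATGAAATAA")
  expect_equal(orf$length, 9L)
  expect_equal(orf$peptide, "MK")
  expect_null(find_longest_orf("CCCCCC"))

  two <- paste0("ATG", strrep("GCA", 8), "TAA",          # 30 nt
                "TT", "ATG", strrep("GCA", 13), "TGA")   # 45 nt
  expect_equal(find_longest_orf(two)$length, 45L)

  set.seed(21)
  for (k in 1:40) {
    s <- random_dna(sample(30:120, 1))
    got <- find_longest_orf(s)
    expect_equal(if (is.null(got)) 0L else got$length, brute_orf_len(s))
  }
  # reverse-complement search finds ORFs on the minus strand
  fwd_none <- "CCCCCCCCCCCC"
  with_rev <- paste0(fwd_none, revcomp("ATGAAATAA"))
  expect_equal(find_longest_orf(with_rev, search_reverse = TRUE)$strand, "-")
})

test_that("shortlist gate enforces three-way agreement and strict thresholds", {
  scores <- data.frame(
    model_id = c("A", "B", "C", "D", "E", "F"),
    cpc_score = c(-0.9, -0.5, -1, -1, -1, -1),
    cpat_prob = c(0.1, 0.1, 0.9, 0.1, 0.1, 0.1),
    plek_label = c("noncoding", "noncoding", "noncoding", "coding", "noncoding", "noncoding"),
    blastp_best_evalue = c(NA, NA, NA, NA, 1e-6, 0.1),
    hmmer_best_evalue = c(NA, NA, NA, NA, NA, 1e-6),
    stringsAsFactors = FALSE)
  res <- build_shortlist(scores$model_id, scores)
  d <- res$decisions
  expect_equal(res$retained, "A")
  expect_equal(d$reason[d$model_id == "B"], "cpc_fail")      # -0.5 exactly: strict
  expect_equal(d$reason[d$model_id == "C"], "cpat_fail")
  expect_equal(d$reason[d$model_id == "D"], "plek_fail")
  expect_equal(d$reason[d$model_id == "E"], "blastp_hit")
  expect_equal(d$reason[d$model_id == "F"], "hmmer_hit")
  # literal reading of the CPAT direction flips which models pass
  res2 <- build_shortlist(scores$model_id, scores, cpat_higher_is_noncoding = TRUE)
  expect_true("C" %in% res2$retained)
  expect_error(build_shortlist(c("A", "ZZ"), scores), "ZZ")
})

test_that("the cascade is order-deterministic under input permutation", {
  cfg <- simulation_config(seed = 3, n_planted_lncrnas = 15, genes_per_chrom = 25)
  gp <- simulate_genome_pair(cfg)
  ann <- gp$a$annotation
  is_lnc <- ann$genes$biotype == "lncRNA"
  models <- annotation(ann$genes[is_lnc, ],
                       ann$transcripts[ann$transcripts$gene_id %in% ann$genes$gene_id[is_lnc], ],
                       ann$exons[grepl("^LNC", ann$exons$transcript_id), ])
  reference <- annotation(ann$genes[!is_lnc, ],
                          ann$transcripts[!ann$transcripts$gene_id %in% ann$genes$gene_id[is_lnc], ],
                          ann$exons[!grepl("^LNC", ann$exons$transcript_id), ])
  r1 <- build_longlist(models, reference)
  perm <- annotation(models$genes[rev(seq_len(nrow(models$genes))), ],
                     models$transcripts[rev(seq_len(nrow(models$transcripts))), ],
                     models$exons)
  r2 <- build_longlist(perm, reference)
  m <- match(r1$decisions$model_id, r2$decisions$model_id)
  expect_equal(r1$decisions$verdict, r2$decisions$verdict[m])
  expect_equal(r1$decisions$reason, r2$decisions$reason[m])
})

test_that("summaries report sizes, rounded percentages and per-reason counts", {
  d <- rbind(
    data.frame(model_id = sprintf("L%02d", 1:30), stage = "longlist",
               verdict = c(rep("retained", 25), rep("excluded", 5)),
               reason = c(rep(NA, 25), rep("too_short", 5))),
    data.frame(model_id = sprintf("L%02d", 1:25), stage = "shortlist",
               verdict = c(rep("retained", 10), rep("excluded", 15)),
               reason = c(rep(NA, 10), rep("cpc_fail", 15))))
  s <- summarize_filters(d, mono_exon_ids = sprintf("L%02d", 1:6))
  expect_equal(s$summary$n_longlist, 25)
  expect_equal(s$summary$n_shortlist, 10)
  expect_equal(s$summary$pct_shortlisted, 40)
  expect_equal(s$summary$pct_mono_exonic, 60)
  expect_setequal(s$by_reason$reason, c("too_short", "cpc_fail"))
  empty <- summarize_filters(d[0, ])
  expect_equal(empty$summary$n_longlist, 0)
  expect_equal(empty$summary$pct_shortlisted, 0)
})
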