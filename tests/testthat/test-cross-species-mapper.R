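test_that("alignment of trivial pairs matches hand-computed expectations", {
  a <- needleman_wunsch("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 40)
  expect_equal(a$identity_pct, 100)
  expect_equal(a$longest_gapless_identity_run, 8L)

  b <- needleman_wunsch("AAAA", "TTTT")
  expect_equal(b$identity_pct, 0)
  expect_equal(b$longest_gapless_identity_run, 0L)
  expect_gte(b$score, 0)  # free end gaps admit the staggered null alignment

  expect_error(needleman_wunsch("", "ACGT"), "empty")
  expect_error(needleman_wunsch("ACGU", "ACGT"), "A/C/G/T/N")
})

test_that("alignment scores agree with an independent ends-free implementation", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(17)
  for (k in 1:100) {
    q <- random_dna(sample(1:40, 1)); t <- random_dna(sample(1:40, 1))
    s2 <- Biostrings::score(Biostrings::pairwiseAlignment(
      q, t, type = "overlap", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5))
    expect_equal(needleman_wunsch(q, t)$score, s2)
  }
})

test_that("aligned strings are consistent: valid gapping, reproducible score", {
  rescore <- function(aln) {
    a <- strsplit(aln$aligned_query, "")[[1]]
    b <- strsplit(aln$aligned_target, "")[[1]]
    gaps_a <- rle(a == "-"); gaps_b <- rle(b == "-")
    s <- 0
    for (k in which(!(a == "-" | b == "-"))) {
      s <- s + if (a[k] == b[k] && a[k] != "N") 5 else -4
    }
    pen <- function(x) {
      r <- rle(x == "-")
      runs <- which(r$values)
      interior <- setdiff(runs, c(1, length(r$values)))
      sum(10 + r$lengths[interior] * 0.5)
    }
    s - pen(a) - pen(b)
  }
  set.seed(23)
  for (k in 1:40) {
    q <- random_dna(sample(3:25, 1)); t <- random_dna(sample(3:25, 1))
    aln <- needleman_wunsch(q, t)
    expect_equal(gsub("-", "", aln$aligned_query, fixed = TRUE), q)
    expect_equal(gsub("-", "", aln$aligned_target, fixed = TRUE), t)
    expect_equal(nchar(aln$aligned_query), nchar(aln$aligned_target))
    expect_equal(rescore(aln), aln$score)
  }
})

test_that("identity runs require exact matches, break on gaps, and never count N", {
  expect_equal(longest_identity_run(paste0("T", strrep("A", 20), "T"),
                                    paste0("G", strrep("A", 20), "G")), 20L)
  left <- strrep("A", 19); right <- strrep("C", 19)
  expect_equal(longest_identity_run(paste0(left, "-", right),
                                    paste0(left, "G", right)), 19L)
  expect_equal(longest_identity_run("ANNA", "ANNA"), 1L)
  expect_error(longest_identity_run("AC", "ACG"), "length")
  set.seed(29)
  for (k in 1:50) {
    n <- sample(5:60, 1)
    mk <- function() {
      x <- sample(c("A", "C", "G", "T", "N", "-"), n, TRUE,
                  prob = c(rep(0.21, 4), 0.06, 0.1))
      paste(x, collapse = "")
    }
    aq <- mk(); at <- mk()
    expect_equal(longest_identity_run(aq, at), scan_identity_run(aq, at))
  }
})

test_that("run length is strand-consistent under joint reverse complement", {
  set.seed(37)
  # homologous pairs: substitution-only divergence gives an essentially
  # unique optimum, so the run length itself must match across strands
  for (k in 1:12) {
    q <- random_dna(300)
    t <- paste0(random_dna(100), syntelnc:::.mutate_seq(q, 0.05), random_dna(100))
    r1 <- needleman_wunsch(q, t)$longest_gapless_identity_run
    r2 <- needleman_wunsch(revcomp(q), revcomp(t))$longest_gapless_identity_run
    expect_equal(r1, r2)
  }
  # unrelated pairs have co-optimal alignments whose tie-broken tracebacks may
  # differ slightly, but the >= 20 acceptance decision must agree
  for (k in 1:15) {
    q <- random_dna(80); t <- random_dna(200)
    r1 <- needleman_wunsch(q, t)$longest_gapless_identity_run
    r2 <- needleman_wunsch(revcomp(q), revcomp(t))$longest_gapless_identity_run
    expect_equal(r1 >= 20, r2 >= 20)
  }
})

test_that("an identical planted sequence maps back exactly; empty intervals return NULL", {
  set.seed(43)
  lnc <- random_dna(300)
  genome <- c(chr1 = paste0(random_dna(500), lnc, random_dna(400)))
  hit <- map_lncrna_into_interval(lnc, list(chrom = "chr1", start = 1, end = 1200),
                                  genome)
  expect_false(is.null(hit))
  expect_equal(hit$sequence, lnc)
  expect_equal(hit$start, 501)
  expect_equal(hit$end, 800)
  expect_equal(hit$run_length, 300L)
  expect_null(map_lncrna_into_interval(lnc, list(chrom = "chr1", start = 10, end = 9),
                                       genome))
  # reverse-complement planting is found on the minus strand
  genome2 <- c(chr1 = paste0(random_dna(200), revcomp(lnc), random_dna(200)))
  hit2 <- map_lncrna_into_interval(lnc, list(chrom = "chr1", start = 1, end = 700),
                                   genome2)
  expect_equal(hit2$aligned_strand, "-")
  expect_equal(hit2$run_length, 300L)
})

test_that("acceptance rate is non-increasing in sequence divergence", {
  set.seed(47)
  n <- 60
  rate_at <- function(mu) {
    hits <- 0
    for (k in 1:n) {
      lnc <- random_dna(400)
      mutated <- syntelnc:::.mutate_seq(lnc, mu)
      genome <- c(chr1 = paste0(random_dna(300), mutated, random_dna(300)))
      h <- map_lncrna_into_interval(lnc, list(chrom = "chr1", start = 1,
                                              end = nchar(genome[["chr1"]])), genome)
      if (!is.null(h)) hits <- hits + 1
    }
    hits / n
  }
  rates <- vapply(c(0, 0.05, 0.3), rate_at, numeric(1))
  expect_equal(rates[1], 1)
  expect_lte(rates[3], rates[2] + 0.05)
  expect_lte(rates[2], rates[1] + 0.05)
  expect_lt(rates[3], 0.1)
})

test_that("crossmap drives one-sided instances through the block intervals", {
  cfg <- simulation_config(seed = 53, n_planted_lncrnas = 25, genes_per_chrom = 40,
                           divergence_mu = 0.02, p_capture = 0.6,
                           rearrangement_rate = 0)
  gp <- simulate_genome_pair(cfg)
  blocks <- match_blocks(enumerate_triples(gp$a$annotation),
                         enumerate_triples(gp$b$annotation))
  lnc_tab <- function(ann) {
    g <- ann$genes[ann$genes$biotype == "lncRNA",
                   c("gene_id", "chrom", "start", "end")]
    rownames(g) <- NULL
    g
  }
  pres <- assign_lncrnas_to_blocks(blocks, lnc_tab(gp$a$annotation),
                                   lnc_tab(gp$b$annotation))
  seqs <- gp$truth$ortholog_pairs$seq_a
  names(seqs) <- gp$truth$ortholog_pairs$lnc_id
  inf <- crossmap_lncrnas(blocks, pres, "a", "b", seqs,
                          target_genome = gp$b$genome)
  expect_gt(attr(inf, "n_attempted"), 0)
  expect_true(all(inf$run_length >= 20))
  # inferred loci lie inside species-b intergenic space and carry the source id
  expect_true(all(inf$source_lnc_id %in% gp$truth$ortholog_pairs$lnc_id))
  expect_true(all(nchar(inf$sequence) == inf$end - inf$start + 1))
  # every accepted inference shares an exact 20-mer with its source
  for (i in seq_len(nrow(inf))) {
    expect_true(shares_kmer(seqs[[inf$source_lnc_id[i]]], inf$sequence[i], 20))
  }
})

test_that("crossmap accounting rows compute the printed percentages", {
  row <- crossmap_report_row(2593, 1213, 5964, 1213)
  expect_equal(row$pct_mapped, 46.78)
  expect_equal(row$pct_regions_with_inference, 20.34)
  zero <- crossmap_report_row(0, 0, 10, 0)
  expect_true(is.na(zero$pct_mapped))
  expect_equal(zero$pct_regions_with_inference, 0)
  tot <- crossmap_target_totals(data.frame(
    source = c("goat", "human", "sheep"), target = "cattle",
    n_mapped = c(286, 16, 775)))
  expect_equal(tot$n_inferred_total, 1077)
})
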