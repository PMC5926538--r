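five_gene_ann <- function(prefix = "A", symbols = sprintf("G%d", 1:5),
                          chrom = "chr1") {
  toy_annotation(do.call(rbind, lapply(seq_along(symbols), function(i) {
    s <- i * 10000
    gene_row(paste0(prefix, i), chrom, s, s + 2000, "+", "protein_coding",
             symbols[i])
  })))
}

test_that("triples slide over each chromosome, excluding terminal genes", {
  tr <- enumerate_triples(five_gene_ann())
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$symbols, c("G1|G2|G3", "G2|G3|G4", "G3|G4|G5"))
  two <- toy_annotation(rbind(
    gene_row("x1", "chr1", 100, 200, "+", "protein_coding", "X1"),
    gene_row("x2", "chr1", 400, 500, "+", "protein_coding", "X2")))
  expect_equal(nrow(enumerate_triples(two)), 0L)
})

test_that("symbol-less and off-biotype genes are skipped without breaking adjacency", {
  genes <- rbind(
    gene_row("a", "chr1", 1000, 2000, "+", "protein_coding", "A"),
    gene_row("skip1", "chr1", 3000, 4000, "+", "protein_coding", ""),
    gene_row("b", "chr1", 5000, 6000, "+", "protein_coding", "B"),
    gene_row("skip2", "chr1", 7000, 8000, "+", "lncRNA", "L"),
    gene_row("c", "chr1", 9000, 10000, "+", "protein_coding", "C"))
  tr <- enumerate_triples(toy_annotation(genes))
  expect_equal(tr$symbols, "A|B|C")
})

test_that("triple enumeration equals brute force on a random annotation", {
  set.seed(41)
  n <- 300
  genes <- do.call(rbind, lapply(1:n, function(i) {
    s <- i * 5000 + sample(0:1000, 1)
    gene_row(sprintf("g%03d", i), sample(c("chr1", "chr2", "chr3"), 1),
             s, s + 2000, sample(c("+", "-"), 1), "protein_coding",
             sprintf("SYM%03d", i))
  }))
  ann <- toy_annotation(genes)
  tr <- enumerate_triples(ann)
  brute <- unlist(lapply(split(genes, genes$chrom), function(gc) {
    gc <- gc[order(gc$start), ]
    if (nrow(gc) < 3) return(character(0))
    sapply(2:(nrow(gc) - 1), function(i) {
      paste(gc$symbol[i - 1], gc$symbol[i], gc$symbol[i + 1], sep = "|")
    })
  }), use.names = FALSE)
  expect_setequal(tr$symbols, brute)
  expect_equal(nrow(tr), length(brute))
})

test_that("matching is exact on ordered symbols, symmetric, and drops duplicates", {
  a <- five_gene_ann("A")
  b <- five_gene_ann("B")
  bl <- match_blocks(enumerate_triples(a), enumerate_triples(b))
  expect_equal(nrow(bl), 3L)
  expect_true(all(bl$orientation == "same"))
  # symmetry up to species-slot swap
  ba <- match_blocks(enumerate_triples(b), enumerate_triples(a))
  expect_setequal(bl$symbols, ba$symbols)
  # duplicated symbol triples are ambiguous and dropped
  dup <- toy_annotation(do.call(rbind, lapply(1:8, function(i) {
    s <- i * 10000
    gene_row(sprintf("d%d", i), "chr1", s, s + 2000, "+", "protein_coding",
             c("G1", "G2", "G3", "G1", "G2", "G3", "G4", "G5")[i])
  })))
  expect_warning(bl2 <- match_blocks(enumerate_triples(dup), enumerate_triples(b)),
                 "duplicate")
  expect_false("G1|G2|G3" %in% bl2$symbols)
})

test_that("reversed-order triples match only when allowed, with symbol-space intervals", {
  a <- five_gene_ann("A")
  b_rev <- five_gene_ann("B", symbols = sprintf("G%d", 5:1))
  tr_a <- enumerate_triples(a)
  tr_b <- enumerate_triples(b_rev)
  expect_equal(nrow(match_blocks(tr_a, tr_b)), 0L)
  bl <- match_blocks(tr_a, tr_b, allow_reversed = TRUE)
  expect_equal(nrow(bl), 3L)
  expect_true(all(bl$orientation == "reversed"))
  # the upstream interval of G1|G2|G3 in species b lies between the G1 and G2
  # genes whatever their genomic order
  blk <- bl[bl$symbols == "G1|G2|G3", ]
  expect_equal(blk$b_upstream_ivl_start, 42001)  # after gene at 40000-42000
  expect_equal(blk$b_upstream_ivl_end, 49999)    # before gene at 50000
})

test_that("lncRNA assignment requires containment and feeds the synteny report", {
  a <- five_gene_ann("A")
  b <- five_gene_ann("B")
  bl <- match_blocks(enumerate_triples(a), enumerate_triples(b))
  lnc_a <- data.frame(gene_id = c("lncIn", "lncStraddle"),
                      chrom = "chr1", start = c(13000, 11500),
                      end = c(14000, 12500), stringsAsFactors = FALSE)
  lnc_b <- data.frame(gene_id = "lncB", chrom = "chr1", start = 13200,
                      end = 13900, stringsAsFactors = FALSE)
  pres <- assign_lncrnas_to_blocks(bl, lnc_a, lnc_b)
  # gap 12001..19999 is the upstream interval of G1|G2|G3: lncIn sits inside,
  # lncStraddle crosses the gene-1 boundary and is dropped at containment 1
  expect_true(any(pres$lnc_id == "lncIn" & pres$species == "a"))
  expect_false("lncStraddle" %in% pres$lnc_id)
  expect_true(any(pres$lnc_id == "lncB" & pres$species == "b"))
  # straddling models are assigned under a relaxed containment
  relaxed <- assign_lncrnas_to_blocks(bl, lnc_a, lnc_b, containment = 0.4)
  expect_true("lncStraddle" %in% relaxed$lnc_id)

  rep <- synteny_report(bl, pres)
  expect_equal(rep$n_blocks, 3)
  expect_equal(rep$n_unique_genes, 5)
  expect_equal(rep$n_conserved_positions, 1)  # lncIn/lncB share block+position
  expect_equal(rep$pct_blocks_with_conserved, round(100 / 3, 2))
  none <- synteny_report(bl, pres[0, ])
  expect_equal(none$n_conserved_positions, 0)
  expect_equal(none$pct_blocks_with_conserved, 0)
})

test_that("matched-block fraction tracks the rearrangement rate", {
  rates <- c(0, 0.15, 1)
  fracs <- vapply(rates, function(r) {
    cfg <- simulation_config(seed = 99, n_chroms = 2, genes_per_chrom = 60,
                             n_planted_lncrnas = 5, rearrangement_rate = r)
    gp <- simulate_genome_pair(cfg)
    tr_a <- enumerate_triples(gp$a$annotation)
    tr_b <- enumerate_triples(gp$b$annotation)
    nrow(match_blocks(tr_a, tr_b)) / nrow(tr_a)
  }, numeric(1))
  expect_equal(fracs[1], 1)
  expect_equal(fracs[3], 0)
  expect_gt(fracs[2], 0.6)
  expect_lt(fracs[2], 1)
})
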