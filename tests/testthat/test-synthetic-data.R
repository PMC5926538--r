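test_that("generators are byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 113, n_planted_lncrnas = 10, genes_per_chrom = 25)
  gp1 <- simulate_genome_pair(cfg)
  gp2 <- simulate_genome_pair(cfg)
  expect_identical(gp1$a$genome, gp2$a$genome)
  expect_identical(gp1$b$genome, gp2$b$genome)
  expect_identical(gp1$truth, gp2$truth)
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gp1$a$annotation, f1); write_gtf(gp2$a$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
  e1 <- simulate_expression(cfg, gp1$a$annotation)
  e2 <- simulate_expression(cfg, gp2$a$annotation)
  expect_identical(e1$tpm, e2$tpm)
  # a different seed changes the output
  gp3 <- simulate_genome_pair(simulation_config(seed = 114,
                                                n_planted_lncrnas = 10,
                                                genes_per_chrom = 15))
  expect_false(identical(gp1$a$genome, gp3$a$genome))
})

test_that("zero divergence with full capture yields identical planted pairs in both species", {
  cfg <- simulation_config(seed = 127, n_planted_lncrnas = 12, genes_per_chrom = 20,
                           divergence_mu = 0, p_capture = 1, rearrangement_rate = 0)
  gp <- simulate_genome_pair(cfg)
  tp <- gp$truth$ortholog_pairs
  expect_true(all(tp$captured_a & tp$captured_b))
  expect_identical(tp$seq_a, tp$seq_b)
  # planted sequences really are embedded at the recorded coordinates
  for (i in seq_len(nrow(tp))) {
    expect_equal(substring(gp$a$genome[[tp$a_chrom[i]]], tp$a_start[i], tp$a_end[i]),
                 tp$seq_a[i])
    expect_equal(substring(gp$b$genome[[tp$b_chrom[i]]], tp$b_start[i], tp$b_end[i]),
                 tp$seq_b[i])
  }
  # captured lncRNAs appear in the annotation as mono-exonic unknown-strand genes
  lnc <- gp$a$annotation$genes[gp$a$annotation$genes$biotype == "lncRNA", ]
  expect_equal(nrow(lnc), nrow(tp))
  expect_true(all(lnc$strand == "*"))
})

test_that("divergence perturbs the species-B copy at roughly the requested rate", {
  cfg <- simulation_config(seed = 131, n_planted_lncrnas = 20, genes_per_chrom = 25,
                           divergence_mu = 0.1, rearrangement_rate = 0)
  gp <- simulate_genome_pair(cfg)
  tp <- gp$truth$ortholog_pairs
  mismatch <- mapply(function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, tp$seq_a, tp$seq_b)
  expect_gt(mean(mismatch), 0.07)
  expect_lt(mean(mismatch), 0.13)
})

test_that("TPM columns are normalised and est_counts track tpm * eff_length", {
  cfg <- simulation_config(seed = 137, n_planted_lncrnas = 8, genes_per_chrom = 20,
                           replicates_per_tissue = 2)
  gp <- simulate_genome_pair(cfg)
  expr <- simulate_expression(cfg, gp$a$annotation)
  expect_equal(unname(colSums(expr$tpm)), rep(1e6, ncol(expr$tpm)),
               tolerance = 1e-9)
  # per sample, counts are proportional to tpm * eff_length
  for (s in sample(colnames(expr$tpm), 4)) {
    raw <- expr$tpm[, s] * expr$eff_lengths[rownames(expr$tpm)]
    nz <- raw > 0
    ratio <- expr$counts[nz, s] / raw[nz]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  }
  md <- expr$metadata
  expect_setequal(md$tissue, names(cfg$tissues))
  expect_equal(nrow(md), length(cfg$tissues) * 2)
})

test_that("planted expression categories are recovered downstream", {
  cfg <- simulation_config(seed = 139, n_planted_lncrnas = 10, genes_per_chrom = 25,
                           n_coexpressed_pairs = 5)
  gp <- simulate_genome_pair(cfg)
  expr <- simulate_expression(cfg, gp$a$annotation)
  gm <- aggregate_to_genes(expr$tpm, expr$tx2gene)
  tm <- tissue_means(gm, expr$metadata$tissue)
  ts <- expr$truth$specific_genes
  for (g in ts$gene_id[ts$category == "tissue_specific"]) {
    expect_equal(compute_tau(tm[g, ]), 1)
  }
  for (g in ts$gene_id[ts$category == "housekeeping"]) {
    expect_lt(max(abs(compute_pem(tm[g, ]))), 1)
  }
  # co-expressed pairs correlate tightly; different programmes do not
  pairs <- expr$truth$coexpressed_pairs
  for (k in seq_len(nrow(pairs))) {
    expect_gt(cor(gm[pairs$lnc_id[k], ], gm[pairs$partner_gene[k], ]), 0.95)
  }
  if (nrow(pairs) >= 2) {
    expect_lt(cor(gm[pairs$lnc_id[1], ], gm[pairs$lnc_id[2], ]), 0.5)
  }
})

test_that("coding-score tables pass clean candidates and fail every contaminant", {
  cfg <- simulation_config(seed = 149)
  ids <- sprintf("M%03d", 1:60)
  bad <- sample(ids, 12)
  sc <- simulate_coding_scores(cfg, ids, bad)
  res <- build_shortlist(ids, sc)
  expect_setequal(res$retained, setdiff(ids, bad))
  d <- res$decisions
  expect_true(all(!is.na(d$reason[d$model_id %in% bad])))
})

test_that("library captures record truth presence consistent with the GTF content", {
  cfg <- simulation_config(seed = 151, n_planted_lncrnas = 6, genes_per_chrom = 10,
                           n_chroms = 1, n_individuals = 3, dropout_p = 0.5)
  gp <- simulate_genome_pair(cfg)
  caps <- simulate_library_captures(cfg, gp$a$annotation)
  expect_equal(dim(caps$presence), c(nrow(caps$reference), 3L))
  for (j in seq_len(3)) {
    set_ids <- caps$individual_sets[[j]]$transcript_id
    full <- rownames(caps$presence)[caps$presence[, j]]
    expect_true(all(full %in% set_ids))
    # absent-or-truncated transcripts never appear under their own id
    expect_false(any(setdiff(rownames(caps$presence), full) %in% set_ids))
  }
})
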