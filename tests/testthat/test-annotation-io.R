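test_that("GTF round-trips through write_gtf/read_annotation coordinate-exactly", {
  genes <- rbind(
    gene_row("G1", "chr1", 100, 500, "+", "protein_coding", "ABC1"),
    gene_row("G2", "chr1", 900, 1500, "-", "lncRNA"))
  ann <- toy_annotation(genes, list(cbind(c(100, 300), c(180, 500)),
                                    cbind(900, 1500)))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  back <- read_annotation(path)
  back_g <- back$genes[match(ann$genes$gene_id, back$genes$gene_id), ]
  expect_equal(back_g$start, ann$genes$start)
  expect_equal(back_g$end, ann$genes$end)
  expect_equal(back_g$strand, ann$genes$strand)
  expect_equal(back_g$biotype, ann$genes$biotype)
  back_e <- back$exons[order(back$exons$transcript_id, back$exons$start), ]
  expect_equal(back_e$start, ann$exons$start)
  expect_equal(back_e$end, ann$exons$end)
  expect_equal(nrow(back$transcripts), 2L)
})

test_that("GFF3 parsing follows ID/Parent chains and sums exon lengths", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t2000\t.\t+\t.\tID=gene1;gene_biotype=protein_coding;Name=FOO",
    "chr1\tsrc\tmRNA\t100\t2000\t.\t+\t.\tID=tx1;Parent=gene1",
    "chr1\tsrc\texon\t100\t499\t.\t+\t.\tID=e1;Parent=tx1",
    "chr1\tsrc\texon\t700\t1199\t.\t+\t.\tID=e2;Parent=tx1",
    "chr1\tsrc\texon\t1701\t2000\t.\t+\t.\tID=e3;Parent=tx1"), path)
  ann <- read_annotation(path)
  expect_equal(nrow(ann$genes), 1L)
  expect_equal(ann$genes$biotype, "protein_coding")
  expect_equal(ann$genes$symbol, "FOO")
  expect_equal(unname(transcript_lengths(ann)[["tx1"]]), 1200L)
})

test_that("exons listed in descending order are stored ascending", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t10\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tsrc\texon\t80\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tsrc\texon\t10\t30\t.\t+\t.\tgene_id "g"; transcript_id "t";'), path)
  ann <- read_annotation(path)
  expect_equal(ann$exons$start, c(10L, 80L))
  expect_false(is.unsorted(ann$exons$start))
})

test_that("malformed annotation lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1\t10\t.\t+\t.\tgene_id "g";',
    "chr1 this line has no tabs"), path)
  expect_error(read_annotation(path), "line 2")
})

test_that("transcripts with exons on multiple chromosomes are rejected with a warning", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t50\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr2\tsrc\texon\t1\t50\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t100\t150\t.\t+\t.\tgene_id "g2"; transcript_id "t2";'), path)
  expect_warning(ann <- read_annotation(path), "multiple chromosomes")
  expect_equal(ann$transcripts$transcript_id, "t2")
})

test_that("transcript sequence extraction concatenates, reverse-complements and checks bounds", {
  genome <- c(chr1 = "ACGTTT", chr2 = "ACGTTA")
  plus <- toy_annotation(gene_row("g1", "chr1", 1, 4, "+", "lncRNA"))
  minus <- toy_annotation(gene_row("g2", "chr1", 1, 4, "-", "lncRNA"))
  expect_equal(extract_transcript_sequence(plus, "g1.t1", genome), "ACGT")
  # ACGT is its own reverse complement: palindrome chosen on purpose
  expect_equal(extract_transcript_sequence(minus, "g2.t1", genome), "ACGT")

  spliced <- toy_annotation(gene_row("g3", "chr2", 1, 6, "+", "lncRNA"),
                            list(cbind(c(1, 5), c(2, 6))))
  expect_equal(extract_transcript_sequence(spliced, "g3.t1", genome), "ACTA")

  unknown <- toy_annotation(gene_row("g4", "chr2", 1, 6, "*", "lncRNA"),
                            list(cbind(c(1, 5), c(2, 6))))
  expect_equal(extract_transcript_sequence(unknown, "g4.t1", genome), "ACTA")

  oob <- toy_annotation(gene_row("g5", "chr1", 3, 9, "+", "lncRNA"))
  expect_error(extract_transcript_sequence(oob, "g5.t1", genome), "bounds")
})

test_that("sequence length equals summed exon length on random transcripts", {
  set.seed(11)
  genome <- c(chr1 = random_dna(5000))
  for (k in 1:20) {
    n_ex <- sample(1:4, 1)
    bounds <- sort(sample(1:4999, 2 * n_ex))
    s <- bounds[seq(1, 2 * n_ex, 2)]; e <- bounds[seq(2, 2 * n_ex, 2)]
    ok <- c(TRUE, s[-1] > e[-n_ex])
    s <- s[ok]; e <- e[ok]
    ann <- toy_annotation(gene_row("g", "chr1", min(s), max(e),
                                   sample(c("+", "-", "*"), 1), "lncRNA"),
                          list(cbind(s, e)))
    expect_equal(nchar(extract_transcript_sequence(ann, "g.t1", genome)),
                 sum(e - s + 1))
  }
})

test_that("BED writer and reader compose to the identity on coordinates and strand", {
  expect_equal(
    readLines(write_bed(data.frame(chrom = "chr1", start = 1, end = 10, name = "x"),
                        withr::local_tempfile(fileext = ".bed")))[1],
    "chr1\t0\t10\tx\t0\t.")
  expect_match(
    readLines(write_bed(data.frame(chrom = "chr1", start = 100, end = 100, name = "y"),
                        withr::local_tempfile(fileext = ".bed")))[1],
    "^chr1\t99\t100\t")
  set.seed(5)
  n <- 50
  loci <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                     start = sample.int(1e6, n), name = sprintf("L%02d", 1:n),
                     score = 0, strand = sample(c("+", "-", "*"), n, TRUE),
                     stringsAsFactors = FALSE)
  loci$end <- loci$start + sample.int(5000, n)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(loci, path)
  back <- read_bed(path)
  expect_equal(back$start, loci$start)
  expect_equal(back$end, loci$end)
  expect_equal(back$strand, loci$strand)
  expect_equal(back$name, loci$name)
})
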