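#' Build an annotation object from gene/transcript/exon tables
#'
#' The internal annotation container used throughout the package. Coordinates
#' are 1-based inclusive (GTF convention); conversion to 0-based half-open
#' happens only at the BED boundary. Strand is one of \code{"+"}, \code{"-"},
#' \code{"*"} (unknown; mono-exonic models assembled from unstranded evidence
#' carry \code{"*"}).
#'
#' @param genes data.frame with columns gene_id, symbol, chrom, start, end,
#'   strand, biotype. \code{biotype} must be one of protein_coding,
#'   pseudogene, lncRNA, other. An empty symbol (\code{""}) means the gene has
#'   no cross-species matching key.
#' @param transcripts data.frame with columns transcript_id, gene_id, chrom,
#'   strand.
#' @param exons data.frame with columns transcript_id, start, end.
#' @return An object of class \code{lnc_annotation}: a list with the three
#'   validated tables, exons sorted ascending within each transcript.
#' @export
annotation <- function(genes, transcripts, exons) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table missing column(s): ", paste(miss, collapse = ", "))
  }
  need(genes, c("gene_id", "symbol", "chrom", "start", "end", "strand", "biotype"), "genes")
  need(transcripts, c("transcript_id", "gene_id", "chrom", "strand"), "transcripts")
  need(exons, c("transcript_id", "start", "end"), "exons")

  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  if (anyDuplicated(transcripts$transcript_id)) stop("duplicate transcript_id in annotation")
  .check_strand(genes$strand); .check_strand(transcripts$strand)
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (any(exons$start > exons$end)) stop("exon with start > end")
  ok <- exons$transcript_id %in% transcripts$transcript_id
  if (!all(ok)) stop("exon references unknown transcript_id: ",
                     paste(unique(exons$transcript_id[!ok]), collapse = ", "))
  bad <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(bad)) stop("transcript references unknown gene_id: ", paste(bad, collapse = ", "))

  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start, exons$end), , drop = FALSE]
  # pairwise non-overlap within a transcript
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    s <- exons$start[idx]; e <- exons$end[idx]
    if (length(idx) > 1L && any(s[-1L] <= e[-length(e)])) {
      stop("overlapping exons within transcript ", exons$transcript_id[idx[1L]])
    }
  }
  rownames(genes) <- rownames(transcripts) <- rownames(exons) <- NULL
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "lnc_annotation")
}

#' @export
print.lnc_annotation <- function(x, ...) {
  cat(sprintf("<lnc_annotation> %d genes, %d transcripts, %d exons on %d sequence(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Summed exon length per transcript
#'
#' @param ann an \code{lnc_annotation}.
#' @return Named integer vector, transcript_id -> summed exon length (bp).
#' @export
transcript_lengths <- function(ann) {
  len <- tapply(ann$exons$end - ann$exons$start + 1L, ann$exons$transcript_id, sum)
  out <- as.integer(len[ann$transcripts$transcript_id])
  names(out) <- ann$transcripts$transcript_id
  out
}

# Default translation from common Ensembl/NCBI biotype strings to the closed
# internal set. Anything unmapped becomes "other".
#' @export
default_biotype_map <- function() {
  c(protein_coding = "protein_coding",
    pseudogene = "pseudogene", processed_pseudogene = "pseudogene",
    unprocessed_pseudogene = "pseudogene", transcribed_pseudogene = "pseudogene",
    lncRNA = "lncRNA", lincRNA = "lncRNA", lnc_RNA = "lncRNA",
    antisense = "lncRNA", sense_intronic = "lncRNA", sense_overlapping = "lncRNA")
}

.map_biotype <- function(x, biotype_map) {
  out <- unname(biotype_map[x])
  out[is.na(out)] <- "other"
  out[is.na(x) | x == ""] <- "other"
  out
}

# Quick structural pre-scan so parse failures carry a line number.
.prescan_gxf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nfield < 8L)) {
    bad <- which(keep)[which(nfield < 8L)[1L]]
    stop("malformed annotation line ", bad, " in ", path,
         ": expected 9 tab-separated columns, found ", nfield[which(nfield < 8L)[1L]])
  }
  invisible(TRUE)
}

#' Read a GTF or GFF3 annotation into the internal model
#'
#' Both Ensembl-style GTF (attributes \code{gene_id}/\code{transcript_id})
#' and NCBI-style GFF3 (ID/Parent chains) are supported; dialect differences
#' in biotype vocabulary are absorbed by \code{biotype_map} rather than by
#' hard-coded logic. Gene spans absent from the file are computed as the
#' min/max over the gene's transcripts. Transcripts whose exons span multiple
#' chromosomes are rejected and reported with a warning.
#'
#' @param path GTF (\code{.gtf}) or GFF3 (\code{.gff}/\code{.gff3}) file.
#' @param biotype_map named character vector translating source biotype
#'   strings into \code{protein_coding}/\code{pseudogene}/\code{lncRNA}/
#'   \code{other}; unmapped values become \code{other}.
#' @return An \code{lnc_annotation}.
#' @export
read_annotation <- function(path, biotype_map = default_biotype_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  .prescan_gxf(path)
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)

  get_attr <- function(col) if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, nrow(df))

  if (fmt == "gtf") {
    gene_id <- get_attr("gene_id")
    tx_id <- get_attr("transcript_id")
  }
  biotype_raw <- get_attr("gene_biotype")
  if (all(is.na(biotype_raw))) biotype_raw <- get_attr("biotype")
  symbol <- get_attr("gene_name")
  if (all(is.na(symbol))) symbol <- get_attr("Name")

  tx_types <- c("transcript", "mRNA", "lnc_RNA", "lincRNA", "ncRNA",
                "pseudogenic_transcript", "transcript_region")
  is_gene <- df$type == "gene"
  is_tx <- df$type %in% tx_types
  is_exon <- df$type == "exon"

  if (fmt == "gtf") {
    exon_tx <- tx_id[is_exon]
    tx_tab <- data.frame(
      transcript_id = c(tx_id[is_tx], exon_tx),
      gene_id = c(gene_id[is_tx], gene_id[is_exon]),
      stringsAsFactors = FALSE)
    tx_tab <- tx_tab[!is.na(tx_tab$transcript_id), , drop = FALSE]
    tx_tab <- tx_tab[!duplicated(tx_tab$transcript_id), , drop = FALSE]
  } else {
    # GFF3: exon Parent -> transcript ID, transcript Parent -> gene ID
    parent_of <- vapply(seq_len(nrow(df)), function(i) {
      p <- df$Parent[[i]]
      if (length(p)) as.character(p[[1L]]) else NA_character_
    }, character(1L))
    exon_tx <- parent_of[is_exon]
    tx_tab <- data.frame(transcript_id = get_attr("ID")[is_tx],
                         gene_id = parent_of[is_tx], stringsAsFactors = FALSE)
    tx_tab <- tx_tab[!is.na(tx_tab$transcript_id), , drop = FALSE]
  }

  exon_df <- data.frame(
    transcript_id = exon_tx,
    chrom = df$seqnames[is_exon],
    start = df$start[is_exon], end = df$end[is_exon],
    strand = df$strand[is_exon], stringsAsFactors = FALSE)
  exon_df <- exon_df[!is.na(exon_df$transcript_id), , drop = FALSE]

  # reject transcripts whose exons sit on more than one chromosome
  n_chrom <- tapply(exon_df$chrom, exon_df$transcript_id, function(x) length(unique(x)))
  bad_tx <- names(n_chrom)[n_chrom > 1L]
  if (length(bad_tx)) {
    warning("rejected transcript(s) with exons on multiple chromosomes: ",
            paste(bad_tx, collapse = ", "))
    exon_df <- exon_df[!exon_df$transcript_id %in% bad_tx, , drop = FALSE]
    tx_tab <- tx_tab[!tx_tab$transcript_id %in% bad_tx, , drop = FALSE]
  }

  first_of <- function(v, g) tapply(v, g, function(x) x[1L])
  tx_chrom <- first_of(exon_df$chrom, exon_df$transcript_id)
  tx_strand <- first_of(exon_df$strand, exon_df$transcript_id)
  tx_tab <- tx_tab[tx_tab$transcript_id %in% names(tx_chrom), , drop = FALSE]
  tx_tab$chrom <- unname(tx_chrom[tx_tab$transcript_id])
  tx_tab$strand <- unname(tx_strand[tx_tab$transcript_id])
  tx_tab$strand[!tx_tab$strand %in% c("+", "-")] <- "*"

  # gene table: explicit gene rows where present, else derived from transcripts
  g_have <- data.frame(
    gene_id = if (fmt == "gtf") gene_id[is_gene] else get_attr("ID")[is_gene],
    symbol = ifelse(is.na(symbol[is_gene]), "", symbol[is_gene]),
    chrom = df$seqnames[is_gene],
    start = df$start[is_gene], end = df$end[is_gene],
    strand = ifelse(df$strand[is_gene] %in% c("+", "-"), df$strand[is_gene], "*"),
    biotype = .map_biotype(biotype_raw[is_gene], biotype_map),
    stringsAsFactors = FALSE)
  g_have <- g_have[!is.na(g_have$gene_id) & !duplicated(g_have$gene_id), , drop = FALSE]

  span_lo <- tapply(exon_df$start, exon_df$transcript_id, min)
  span_hi <- tapply(exon_df$end, exon_df$transcript_id, max)
  tx_tab$lo <- unname(span_lo[tx_tab$transcript_id])
  tx_tab$hi <- unname(span_hi[tx_tab$transcript_id])
  g_derived <- data.frame(
    gene_id = names(tapply(tx_tab$lo, tx_tab$gene_id, min)),
    symbol = "",
    chrom = unname(first_of(tx_tab$chrom, tx_tab$gene_id)),
    start = unname(tapply(tx_tab$lo, tx_tab$gene_id, min)),
    end = unname(tapply(tx_tab$hi, tx_tab$gene_id, max)),
    strand = unname(first_of(tx_tab$strand, tx_tab$gene_id)),
    biotype = "other", stringsAsFactors = FALSE)
  extra <- g_derived[!g_derived$gene_id %in% g_have$gene_id, , drop = FALSE]
  genes <- rbind(g_have, extra)

  # biotype fallback via per-transcript biotype attributes (GTF without gene rows)
  annotation(genes,
             tx_tab[, c("transcript_id", "gene_id", "chrom", "strand")],
             exon_df[, c("transcript_id", "start", "end")])
}

#' Write the internal annotation as GTF
#'
#' Emits gene, transcript and exon rows with \code{gene_id},
#' \code{transcript_id}, \code{gene_name} and \code{gene_biotype} attributes;
#' round-trips through \code{\link{read_annotation}} coordinate-exactly.
#'
#' @param ann an \code{lnc_annotation}.
#' @param path output file.
#' @param source value for the GTF source column.
#' @export
write_gtf <- function(ann, path, source = "syntelnc") {
  g <- ann$genes; tx <- ann$transcripts; ex <- ann$exons
  fmt_strand <- function(s) ifelse(s %in% c("+", "-"), s, ".")
  lines <- character(0)
  gl <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                g$chrom, source, g$start, g$end, fmt_strand(g$strand),
                g$gene_id, g$symbol, g$biotype)
  tx_lo <- tapply(ex$start, ex$transcript_id, min)[tx$transcript_id]
  tx_hi <- tapply(ex$end, ex$transcript_id, max)[tx$transcript_id]
  tl <- sprintf('%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                tx$chrom, source, as.integer(tx_lo), as.integer(tx_hi),
                fmt_strand(tx$strand), tx$gene_id, tx$transcript_id)
  exg <- tx$gene_id[match(ex$transcript_id, tx$transcript_id)]
  exc <- tx$chrom[match(ex$transcript_id, tx$transcript_id)]
  exs <- fmt_strand(tx$strand[match(ex$transcript_id, tx$transcript_id)])
  el <- sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                exc, source, ex$start, ex$end, exs, exg, ex$transcript_id)
  writeLines(c(gl, tl, el), path)
  invisible(path)
}

#' Extract the transcript sequence from a genome
#'
#' Concatenates the exon substrings 5'->3'; minus-strand transcripts are
#' reverse-complemented; unknown-strand transcripts return the plus-strand
#' concatenation.
#'
#' @param ann an \code{lnc_annotation}.
#' @param transcript_id transcript to extract.
#' @param genome named character vector or \code{Biostrings::DNAStringSet},
#'   chrom -> sequence.
#' @return Nucleotide string.
#' @export
extract_transcript_sequence <- function(ann, transcript_id, genome) {
  i <- match(transcript_id, ann$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript_id: ", transcript_id)
  chrom <- ann$transcripts$chrom[i]
  strand <- ann$transcripts$strand[i]
  seqs <- if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
  if (!chrom %in% names(seqs)) stop("chromosome absent from genome: ", chrom)
  chrom_seq <- toupper(seqs[[chrom]])
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (any(ex$end > nchar(chrom_seq)) || any(ex$start < 1L)) {
    stop("exon exceeds chromosome bounds for transcript ", transcript_id)
  }
  s <- paste(substring(chrom_seq, ex$start, ex$end), collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Write genomic intervals as BED6
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. \code{\link{read_bed}} inverts the conversion exactly.
#'
#' @param loci data.frame with columns chrom, start, end, name, and optionally
#'   score and strand (unknown strand written as \code{.}).
#' @param path output file.
#' @export
write_bed <- function(loci, path) {
  score <- loci$score %||% rep(0, nrow(loci))
  strand <- loci$strand %||% rep("*", nrow(loci))
  strand <- ifelse(strand %in% c("+", "-"), strand, ".")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     loci$chrom, as.integer(loci$start) - 1L, as.integer(loci$end),
                     loci$name, format(score, trim = TRUE), strand),
             path)
  invisible(path)
}

#' Read a BED6 file into 1-based inclusive intervals
#'
#' @param path BED file written by \code{\link{write_bed}} or any BED6.
#' @return data.frame chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name", "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "character", "character"))
  df$start <- df$start + 1L
  df$strand[!df$strand %in% c("+", "-")] <- "*"
  df
}

#' Write a chrom -> sequence mapping as FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(genome)), path)
  invisible(path)
}

#' Read a FASTA genome into a named character vector (uppercase)
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}
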