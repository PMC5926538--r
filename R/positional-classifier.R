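#' Classify candidate lncRNAs by position relative to annotated genes
#'
#' Each model receives exactly one label. Models overlapping a known gene are
#' \code{sense} (same strand), \code{antisense} (opposite strand) or
#' \code{overlap_strand_unknown} (model strand unknown). Non-overlapping
#' models within 5 kb of the nearest transcription start site are
#' \code{upstream_*}/\code{downstream_*} relative to that gene's
#' transcription direction (a model 5' of the gene's TSS is upstream), with
#' the \code{_same}/\code{_opposite} suffix from the strand relation
#' (unknown-strand models take \code{_same}; their relation is unresolvable
#' and the positional part is what matters). Everything else is
#' \code{intergenic}, binned by distance to the nearest TSS into half-open
#' bins [5,10), [10,20), [20,50), [50,100), [100,500) kb, [500 kb, 1 Mb),
#' [1 Mb, Inf), irrespective of strand.
#'
#' The TSS set comes either from per-transcript start sites (Ensembl-style
#' annotations that provide them) or from gene starts (NCBI-style); the
#' default uses transcript starts when the reference carries transcripts.
#'
#' @param models an \code{lnc_annotation} of candidate lncRNA models.
#' @param reference an \code{lnc_annotation} of known genes.
#' @param tss_source "transcript_starts", "gene_start" or "auto" (default).
#' @param tss_window distance below which a model is upstream/downstream
#'   rather than intergenic (default 5000 bp).
#' @return data.frame: model_id, label, intergenic_bin, nearest_tss_distance,
#'   nearest_gene_id.
#' @export
classify_lncrnas <- function(models, reference, tss_source = c("auto", "transcript_starts", "gene_start"),
                             tss_window = 5000L) {
  tss_source <- match.arg(tss_source)
  if (tss_source == "auto") {
    tss_source <- if (nrow(reference$transcripts)) "transcript_starts" else "gene_start"
  }
  g <- models$genes
  ref <- reference$genes

  # TSS table: position + owning gene (strand-aware: start on "+", end on "-")
  if (tss_source == "transcript_starts" && nrow(reference$transcripts)) {
    tx <- reference$transcripts
    lo <- tapply(reference$exons$start, reference$exons$transcript_id, min)[tx$transcript_id]
    hi <- tapply(reference$exons$end, reference$exons$transcript_id, max)[tx$transcript_id]
    tss <- data.frame(chrom = tx$chrom,
                      pos = ifelse(tx$strand == "-", as.integer(hi), as.integer(lo)),
                      gene_id = tx$gene_id, stringsAsFactors = FALSE)
  } else {
    tss <- data.frame(chrom = ref$chrom,
                      pos = ifelse(ref$strand == "-", ref$end, ref$start),
                      gene_id = ref$gene_id, stringsAsFactors = FALSE)
  }
  ref_strand <- stats::setNames(ref$strand, ref$gene_id)
  ref_tss <- stats::setNames(ifelse(ref$strand == "-", ref$end, ref$start), ref$gene_id)

  mod_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  ref_gr <- GenomicRanges::GRanges(ref$chrom, IRanges::IRanges(ref$start, ref$end))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(mod_gr, ref_gr, ignore.strand = TRUE))

  out <- data.frame(model_id = g$gene_id, label = NA_character_,
                    intergenic_bin = "none", nearest_tss_distance = NA_real_,
                    nearest_gene_id = "", stringsAsFactors = FALSE)

  ov_q <- S4Vectors::queryHits(ov); ov_s <- S4Vectors::subjectHits(ov)
  for (i in seq_len(nrow(g))) {
    hits <- ov_s[ov_q == i]
    # nearest TSS (linear scan over the chromosome's TSS table)
    same_chrom <- tss$chrom == g$chrom[i]
    if (any(same_chrom)) {
      pos <- tss$pos[same_chrom]
      d <- ifelse(pos >= g$start[i] & pos <= g$end[i], 0,
                  pmin(abs(pos - g$start[i]), abs(pos - g$end[i])))
      j <- which.min(d)
      out$nearest_tss_distance[i] <- d[j]
      out$nearest_gene_id[i] <- tss$gene_id[same_chrom][j]
    }
    if (length(hits)) {
      hit_gene <- ref$gene_id[hits[1L]]
      out$label[i] <-
        if (g$strand[i] == "*") "overlap_strand_unknown"
        else if (ref_strand[[hit_gene]] == "*") "overlap_strand_unknown"
        else if (g$strand[i] == ref_strand[[hit_gene]]) "sense"
        else "antisense"
      # overlapped gene reported as nearest
      out$nearest_gene_id[i] <- hit_gene
      tssp <- ref_tss[[hit_gene]]
      out$nearest_tss_distance[i] <-
        if (tssp >= g$start[i] && tssp <= g$end[i]) 0
        else min(abs(tssp - g$start[i]), abs(tssp - g$end[i]))
      next
    }
    if (!any(same_chrom)) {
      warning("model ", g$gene_id[i], " on chromosome without reference genes; ",
              "classified intergenic, bin >=1 Mb")
      out$label[i] <- "intergenic"
      out$intergenic_bin[i] <- ">=1Mb"
      out$nearest_tss_distance[i] <- Inf
      next
    }
    d <- out$nearest_tss_distance[i]
    near_gene <- out$nearest_gene_id[i]
    if (d < tss_window) {
      gs <- ref_strand[[near_gene]]
      tssp <- ref_tss[[near_gene]]
      upstream <- if (gs == "-") g$start[i] > tssp else g$end[i] < tssp
      rel <- if (g$strand[i] == "*" || gs == "*") "same"
             else if (g$strand[i] == gs) "same" else "opposite"
      out$label[i] <- paste0(if (upstream) "upstream_" else "downstream_", rel)
    } else {
      out$label[i] <- "intergenic"
      out$intergenic_bin[i] <- intergenic_bin(d)
    }
  }
  out
}

#' Half-open intergenic distance bin
#'
#' @param d distance to the nearest TSS in bp (>= 5000).
#' @return One of "5-10kb", "10-20kb", "20-50kb", "50-100kb", "100-500kb",
#'   "500kb-1Mb", ">=1Mb".
#' @export
intergenic_bin <- function(d) {
  edges <- c(5e3, 1e4, 2e4, 5e4, 1e5, 5e5, 1e6, Inf)
  labels <- c("5-10kb", "10-20kb", "20-50kb", "50-100kb", "100-500kb",
              "500kb-1Mb", ">=1Mb")
  vapply(d, function(x) {
    if (is.na(x) || x < 5e3) return(NA_character_)
    labels[min(findInterval(x, edges), length(labels))]
  }, character(1L))
}
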