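#' Needleman-Wunsch global alignment with EMBOSS-needle default scoring
#'
#' Optimal global alignment under match/mismatch scoring (+5/-4), affine gap
#' penalties (open 10, extend 0.5; a gap run of length L costs
#' \code{open + L * extend}) and unpenalised end gaps, i.e. the default
#' parameterisation of the EMBOSS \code{needle} tool for nucleotides, pinned
#' here explicitly so results are reproducible without EMBOSS. Traceback is
#' deterministic (ties: diagonal, then gap-in-target, then gap-in-query).
#'
#' @param query,target nucleotide strings over A/C/G/T/N (case-insensitive).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return A list with \code{score}, \code{aligned_query}, \code{aligned_target}
#'   (equal-length gapped strings), \code{identity_pct} (percent of alignment
#'   columns that are exact base matches), \code{longest_gapless_identity_run}
#'   (see \code{\link{longest_identity_run}}) and \code{target_aligned_span},
#'   the 1-based target interval covered after trimming terminal gap columns
#'   (NA when no column pairs two residues).
#' @export
needleman_wunsch <- function(query, target, match = 5, mismatch = -4,
                             gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.character(query), is.character(target),
            length(query) == 1L, length(target) == 1L)
  query <- toupper(query); target <- toupper(target)
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  if (grepl("[^ACGTN]", query) || grepl("[^ACGTN]", target)) {
    stop("sequences must be over A/C/G/T/N")
  }
  aln <- .nw_align_cpp(query, target, match, mismatch, gap_open, gap_extend)
  aq <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1L]]
  at <- strsplit(aln$aligned_target, "", fixed = TRUE)[[1L]]
  matches <- aq == at & aq != "-" & aq != "N"
  both <- aq != "-" & at != "-"
  tpos <- cumsum(at != "-")
  span <- if (any(both)) {
    c(start = tpos[which(both)[1L]], end = tpos[which(both)[sum(both)]])
  } else c(start = NA_integer_, end = NA_integer_)
  list(score = aln$score,
       aligned_query = aln$aligned_query,
       aligned_target = aln$aligned_target,
       identity_pct = 100 * sum(matches) / length(aq),
       longest_gapless_identity_run = .identity_run_cpp(aln$aligned_query, aln$aligned_target),
       target_aligned_span = span)
}

#' Longest gapless identity run of an alignment
#'
#' Length of the longest stretch of alignment columns that are exact base
#' matches with no gap character in either row. \code{N} never matches
#' anything, including \code{N}: a run is evidence of sequence identity.
#'
#' @param aligned_query,aligned_target equal-length gapped strings.
#' @return Integer run length (0 when no column matches).
#' @export
longest_identity_run <- function(aligned_query, aligned_target) {
  if (nchar(aligned_query) != nchar(aligned_target)) {
    stop("aligned strings differ in length")
  }
  .identity_run_cpp(toupper(aligned_query), toupper(aligned_target))
}

#' Infer a lncRNA in a target genome by alignment into a syntenic interval
#'
#' Implements the cross-species inference step: a lncRNA captured by RNA-seq
#' in the source species, occupying an intergenic position of a conserved
#' gene-triple block where the target species has none, is globally aligned
#' (both strands) to the target species' corresponding intergenic sequence.
#' The alignment is accepted when it contains a gapless run of at least
#' \code{min_run} identical residues -- the lncRNA is effectively treated as a
#' CAGE-tag-like anchor, since the probability of 20 consecutive identical
#' residues arising by chance in a pre-defined region is very low. On
#' acceptance the target extract covered by the alignment (terminal gap
#' columns trimmed) is reported as a novel lncRNA locus.
#'
#' @param lnc_seq source lncRNA sequence (concatenated exon sequence).
#' @param interval list/row with \code{chrom}, \code{start}, \code{end} of the
#'   target intergenic interval (1-based inclusive, genome coordinates).
#' @param target_genome named character vector, chrom -> sequence.
#' @param min_run acceptance threshold on the gapless identity run (default 20).
#' @param source_strand strand of the source model ("+", "-", "*").
#' @return \code{NULL} when rejected; else a list with genome coordinates
#'   (\code{chrom}, \code{start}, \code{end}), \code{strand} of the inferred
#'   locus, \code{sequence} (plus-strand extract), \code{run_length},
#'   \code{identity_pct} and \code{aligned_strand} ("+" when the query aligned
#'   directly, "-" when its reverse complement did).
#' @export
map_lncrna_into_interval <- function(lnc_seq, interval, target_genome,
                                     min_run = 20, source_strand = "*") {
  chrom <- interval$chrom
  if (!chrom %in% names(target_genome)) stop("chromosome absent from target genome: ", chrom)
  if (is.na(interval$start) || is.na(interval$end) || interval$start > interval$end) {
    return(NULL)  # empty intergenic interval
  }
  tseq <- toupper(substring(target_genome[[chrom]], interval$start, interval$end))
  if (!nzchar(tseq) || !nzchar(lnc_seq)) return(NULL)
  fwd <- needleman_wunsch(lnc_seq, tseq)
  rev <- needleman_wunsch(revcomp(lnc_seq), tseq)
  best <- if (rev$longest_gapless_identity_run > fwd$longest_gapless_identity_run) {
    list(aln = rev, strand = "-")
  } else list(aln = fwd, strand = "+")  # tie -> plus strand
  if (best$aln$longest_gapless_identity_run < min_run) return(NULL)
  span <- best$aln$target_aligned_span
  if (anyNA(span)) return(NULL)
  g_start <- interval$start + span[["start"]] - 1L
  g_end <- interval$start + span[["end"]] - 1L
  strand <- if (source_strand == "*") "*"
            else if (best$strand == "+") source_strand
            else c("+" = "-", "-" = "+")[[source_strand]]
  list(chrom = chrom, start = g_start, end = g_end, strand = strand,
       sequence = substring(target_genome[[chrom]], g_start, g_end),
       run_length = best$aln$longest_gapless_identity_run,
       identity_pct = best$aln$identity_pct,
       aligned_strand = best$strand)
}

#' Cross-map all one-sided lncRNAs of a species pair
#'
#' Drives \code{\link{map_lncrna_into_interval}} over every (block, position)
#' where the source species has a contained lncRNA and the target species has
#' none, for a block set produced by \code{\link{match_blocks}} and a presence
#' table from \code{\link{assign_lncrnas_to_blocks}}.
#'
#' @param blocks block table from \code{\link{match_blocks}}.
#' @param presence presence table from \code{\link{assign_lncrnas_to_blocks}}.
#' @param source,target species slot names ("a" or "b").
#' @param lnc_sequences named character vector, source lncRNA gene_id -> sequence.
#' @param lnc_strands optional named strand vector for the source models.
#' @param target_genome named character vector, chrom -> sequence.
#' @param min_run acceptance threshold (default 20).
#' @return data.frame of inferred lncRNA loci (one row per accepted mapping)
#'   with attribute \code{n_attempted}, the number of one-sided
#'   (block, position, lncRNA) instances that were aligned.
#' @export
crossmap_lncrnas <- function(blocks, presence, source, target,
                             lnc_sequences, lnc_strands = NULL,
                             target_genome, min_run = 20) {
  stopifnot(source %in% c("a", "b"), target %in% c("a", "b"), source != target)
  res <- list(); attempted <- 0L
  for (k in seq_len(nrow(presence))) {
    row <- presence[k, ]
    if (row$species != source) next
    # one-sided: source occupies (block, position), target does not
    occ_target <- any(presence$species == target &
                      presence$block_id == row$block_id &
                      presence$position == row$position)
    if (occ_target) next
    b <- blocks[blocks$block_id == row$block_id, , drop = FALSE]
    if (!nrow(b)) next
    # block intervals are stored in symbol space, so positions correspond
    # across species for both orientations
    interval <- list(
      chrom = b[[paste0(target, "_chrom")]],
      start = b[[paste0(target, "_", row$position, "_ivl_start")]],
      end = b[[paste0(target, "_", row$position, "_ivl_end")]])
    seq <- lnc_sequences[[row$lnc_id]]
    if (is.null(seq)) next
    attempted <- attempted + 1L
    strand <- if (!is.null(lnc_strands)) lnc_strands[[row$lnc_id]] %||% "*" else "*"
    hit <- map_lncrna_into_interval(seq, interval, target_genome,
                                    min_run = min_run, source_strand = strand)
    if (is.null(hit)) next
    res[[length(res) + 1L]] <- data.frame(
      id = sprintf("XLNC_%s_%s_%s", target, row$block_id, row$lnc_id),
      source_species = source, source_lnc_id = row$lnc_id,
      target_species = target, chrom = hit$chrom,
      start = hit$start, end = hit$end, strand = hit$strand,
      sequence = hit$sequence, block_id = row$block_id,
      position = row$position, run_length = hit$run_length,
      identity_pct = hit$identity_pct, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else data.frame(
    id = character(0), source_species = character(0), source_lnc_id = character(0),
    target_species = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), sequence = character(0),
    block_id = character(0), position = character(0), run_length = integer(0),
    identity_pct = numeric(0), stringsAsFactors = FALSE)
  attr(out, "n_attempted") <- attempted
  out
}

#' Cross-mapping summary in the style of a per-species-pair accounting table
#'
#' @param n_one_sided number of lncRNA models detected within conserved
#'   synteny in the source species but not captured in the target.
#' @param n_mapped number of those models accepted by the alignment criterion.
#' @param n_intergenic_regions number of intergenic regions in the shared
#'   blocks (two per block).
#' @param n_regions_with_inference number of those regions receiving at least
#'   one inferred lncRNA.
#' @return One-row data.frame with counts and percentages (2 decimals).
#' @export
crossmap_report_row <- function(n_one_sided, n_mapped,
                                n_intergenic_regions = NA_integer_,
                                n_regions_with_inference = NA_integer_) {
  pct <- function(num, den) if (is.na(num) || is.na(den) || den == 0) NA_real_
                            else round(100 * num / den, 2)
  data.frame(n_one_sided = n_one_sided, n_mapped = n_mapped,
             pct_mapped = pct(n_mapped, n_one_sided),
             n_intergenic_regions = n_intergenic_regions,
             pct_regions_with_inference = pct(n_regions_with_inference,
                                              n_intergenic_regions))
}

#' Aggregate per-target inferred-lncRNA totals over source species
#'
#' @param rows data.frame with columns \code{source}, \code{target},
#'   \code{n_mapped} (one row per ordered species pair).
#' @return data.frame \code{target}, \code{n_inferred_total}: the number of
#'   additional lncRNAs predicted in each target genome, summed over sources.
#' @export
crossmap_target_totals <- function(rows) {
  tot <- tapply(rows$n_mapped, rows$target, sum)
  data.frame(target = names(tot), n_inferred_total = as.integer(tot),
             row.names = NULL, stringsAsFactors = FALSE)
}
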