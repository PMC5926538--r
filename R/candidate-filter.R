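#' Longlist filter cascade for candidate lncRNA gene models
#'
#' Retains assembled gene models that look like credible lncRNA candidates:
#' summed exon length above 200 bp (multi-exon) or at least 500 bp
#' (mono-exon; the lower threshold could be met by a single read pair),
#' no same-strand overlap of more than 1 bp with any protein-coding or
#' pseudogene span in the reference, a single transcript model per gene
#' (multi-transcript loci are more likely spurious), and absence from an
#' explicit previously-protein-coding exclusion list. Length is transcript
#' (summed exon) length, not genomic span, consistent with the "more than
#' 200 nt" lncRNA definition. Unknown-strand models are screened against both
#' reference strands (conservative).
#'
#' An excluded model carries exactly one reason: the first failing rule in
#' the fixed order too_short / single_exon_too_short / overlaps_coding /
#' multi_transcript / previously_coding.
#'
#' @param models an \code{lnc_annotation} of assembled gene models.
#' @param reference an \code{lnc_annotation} with populated biotypes.
#' @param exclusion_ids gene ids previously considered protein-coding.
#' @param min_len,min_len_mono retention thresholds: summed exon length must
#'   exceed \code{min_len} (strict) for multi-exon models and reach
#'   \code{min_len_mono} (non-strict) for mono-exon models.
#' @param max_overlap maximum tolerated same-strand overlap (bp) with a
#'   protein_coding/pseudogene span (default 1).
#' @return list with \code{retained} (character gene ids, input order) and
#'   \code{decisions} (data.frame model_id, stage, verdict, reason).
#' @export
build_longlist <- function(models, reference, exclusion_ids = character(0),
                           min_len = 200L, min_len_mono = 500L, max_overlap = 1L) {
  g <- models$genes
  ref <- reference$genes
  bad_chrom <- setdiff(g$chrom, ref$chrom)
  if (length(bad_chrom)) {
    stop("model(s) reference chromosome(s) absent from the reference annotation: ",
         paste(bad_chrom, collapse = ", "))
  }

  tx_len <- transcript_lengths(models)
  n_exons <- table(models$exons$transcript_id)
  per_gene <- split(models$transcripts$transcript_id, models$transcripts$gene_id)

  # longest transcript defines length/exon structure; multi-transcript loci
  # are excluded later in the cascade anyway
  gene_len <- vapply(per_gene, function(tx) max(tx_len[tx]), numeric(1L))[g$gene_id]
  gene_tx <- vapply(per_gene, function(tx) tx[which.max(tx_len[tx])], character(1L))[g$gene_id]
  gene_mono <- as.integer(n_exons[gene_tx]) == 1L
  gene_ntx <- lengths(per_gene)[g$gene_id]

  coding <- ref[ref$biotype %in% c("protein_coding", "pseudogene"), , drop = FALSE]
  ref_gr <- GenomicRanges::GRanges(coding$chrom,
                                   IRanges::IRanges(coding$start, coding$end),
                                   strand = coding$strand)
  mod_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                   strand = g$strand)  # "*" hits both strands
  suppressWarnings({
    ov <- GenomicRanges::findOverlaps(mod_gr, ref_gr,
                                      minoverlap = max_overlap + 1L,
                                      ignore.strand = FALSE)
  })
  overlaps <- logical(nrow(g))
  overlaps[unique(S4Vectors::queryHits(ov))] <- TRUE

  too_short <- !gene_mono & gene_len <= min_len
  mono_short <- gene_mono & gene_len < min_len_mono
  multi_tx <- gene_ntx > 1L
  prev_coding <- g$gene_id %in% exclusion_ids

  reason <- rep(NA_character_, nrow(g))
  reason[prev_coding] <- "previously_coding"
  reason[multi_tx] <- "multi_transcript"
  reason[overlaps] <- "overlaps_coding"
  reason[mono_short] <- "single_exon_too_short"
  reason[too_short] <- "too_short"  # assigned last = highest precedence

  verdict <- ifelse(is.na(reason), "retained", "excluded")
  decisions <- data.frame(model_id = g$gene_id, stage = "longlist",
                          verdict = verdict, reason = reason,
                          stringsAsFactors = FALSE)
  list(retained = g$gene_id[verdict == "retained"], decisions = decisions)
}

.translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.orfs_one_strand <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    if (n - frame < 6L) next
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    if (!any(is_start) || !any(is_stop)) next
    atg_idx <- which(is_start)
    stop_idx <- which(is_stop)
    # for each ATG, the first in-frame stop strictly after it
    nxt <- stop_idx[findInterval(atg_idx, stop_idx) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    atg_idx <- atg_idx[ok]; nxt <- nxt[ok]
    len <- (nxt - atg_idx + 1L) * 3L
    j <- which.max(len)  # which.max takes the first (5'-most) maximum
    cand <- list(start = starts[atg_idx[j]],
                 end = starts[nxt[j]] + 2L,
                 frame = frame,
                 length = len[j],
                 peptide = .translate_codons(codons[atg_idx[j]:(nxt[j] - 1L)]))
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$start < best$start)) {
      best <- cand
    }
  }
  best
}

#' Longest open reading frame of a transcript sequence
#'
#' Finds the longest ATG..stop span (stop codon included in the nucleotide
#' extent) under the standard genetic code; ties are broken by the 5'-most
#' start. For unknown-strand models the reverse complement is searched too.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @param search_reverse also search the reverse complement (default FALSE).
#' @return \code{NULL} when no ORF exists, else a list with \code{start},
#'   \code{end} (1-based inclusive on the searched strand), \code{frame}
#'   (0..2), \code{strand}, \code{length} (nt, stop included) and
#'   \code{peptide} (stop not included).
#' @export
find_longest_orf <- function(seq, search_reverse = FALSE) {
  seq <- toupper(seq)
  fwd <- .orfs_one_strand(seq)
  if (!is.null(fwd)) fwd$strand <- "+"
  if (!search_reverse) return(fwd)
  rev <- .orfs_one_strand(revcomp(seq))
  if (!is.null(rev)) rev$strand <- "-"
  if (is.null(rev)) return(fwd)
  if (is.null(fwd)) return(rev)
  if (rev$length > fwd$length) rev else fwd
}

#' Read a coding-potential score table
#'
#' Tab-delimited with a single header line and columns exactly: model_id,
#' cpc_score, cpat_prob, plek_label, blastp_best_evalue, hmmer_best_evalue.
#' Empty E-value cells mean "no hit".
#'
#' @param path TSV file.
#' @return data.frame with NA for absent E-values.
#' @export
read_coding_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("model_id", "cpc_score", "cpat_prob", "plek_label",
            "blastp_best_evalue", "hmmer_best_evalue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("scores table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Shortlist gate: three-way non-coding agreement plus no homology hits
#'
#' A longlisted model is shortlisted only when all five criteria hold:
#' CPC score strictly below \code{cpc_max}; CPAT verdict non-coding at the
#' 0.58 cut-off; PLEK label "noncoding"; and no blastp or HMMER hit at
#' E-value \code{<= evalue_max}. By default the CPAT verdict is non-coding
#' when the reported coding probability is \emph{below} the cut-off
#' (conventional CPAT semantics); \code{cpat_higher_is_noncoding = TRUE}
#' honours the alternative reading in which higher values mean non-coding.
#' An excluded model carries the first failing reason in the order
#' cpc_fail / cpat_fail / plek_fail / blastp_hit / hmmer_hit.
#'
#' @param longlist_ids character vector of longlisted model ids.
#' @param scores data.frame as from \code{\link{read_coding_scores}}.
#' @param cpc_max CPC threshold (default -0.5, strict).
#' @param cpat_cutoff CPAT probability cut-off (default 0.58).
#' @param cpat_higher_is_noncoding direction switch (default FALSE).
#' @param evalue_max homology-hit threshold (default 1e-5; hits with E-value
#'   at or below it exclude the model).
#' @return list with \code{retained} ids and \code{decisions} data.frame.
#' @export
build_shortlist <- function(longlist_ids, scores, cpc_max = -0.5,
                            cpat_cutoff = 0.58, cpat_higher_is_noncoding = FALSE,
                            evalue_max = 1e-5) {
  i <- match(longlist_ids, scores$model_id)
  if (anyNA(i)) {
    stop("missing coding-potential record(s) for: ",
         paste(longlist_ids[is.na(i)], collapse = ", "))
  }
  sc <- scores[i, , drop = FALSE]
  cpc_ok <- sc$cpc_score < cpc_max
  cpat_ok <- if (cpat_higher_is_noncoding) sc$cpat_prob > cpat_cutoff
             else sc$cpat_prob < cpat_cutoff
  plek_ok <- sc$plek_label == "noncoding"
  blast_ok <- is.na(sc$blastp_best_evalue) | sc$blastp_best_evalue > evalue_max
  hmmer_ok <- is.na(sc$hmmer_best_evalue) | sc$hmmer_best_evalue > evalue_max

  reason <- rep(NA_character_, length(longlist_ids))
  reason[!hmmer_ok] <- "hmmer_hit"
  reason[!blast_ok] <- "blastp_hit"
  reason[!plek_ok] <- "plek_fail"
  reason[!cpat_ok] <- "cpat_fail"
  reason[!cpc_ok] <- "cpc_fail"

  verdict <- ifelse(is.na(reason), "retained", "excluded")
  decisions <- data.frame(model_id = longlist_ids, stage = "shortlist",
                          verdict = verdict, reason = reason,
                          stringsAsFactors = FALSE)
  list(retained = longlist_ids[verdict == "retained"], decisions = decisions)
}

#' Summarise the filter cascade
#'
#' @param decisions row-bound decisions from \code{\link{build_longlist}} and
#'   \code{\link{build_shortlist}}.
#' @param mono_exon_ids optional character vector of mono-exonic model ids,
#'   used for the mono-exonic shortlist fraction.
#' @return list with \code{summary} (one row: longlist/shortlist sizes,
#'   shortlist percentage of the longlist and mono-exonic percentage of the
#'   shortlist, both nearest-integer) and \code{by_reason} (stage x reason
#'   exclusion counts).
#' @export
summarize_filters <- function(decisions, mono_exon_ids = NULL) {
  long_ret <- decisions$model_id[decisions$stage == "longlist" &
                                 decisions$verdict == "retained"]
  short_ret <- decisions$model_id[decisions$stage == "shortlist" &
                                  decisions$verdict == "retained"]
  n_long <- length(long_ret); n_short <- length(short_ret)
  pct_short <- if (n_long > 0) round(100 * n_short / n_long) else 0
  pct_mono <- if (!is.null(mono_exon_ids) && n_short > 0) {
    round(100 * sum(short_ret %in% mono_exon_ids) / n_short)
  } else NA_real_
  excl <- decisions[decisions$verdict == "excluded", , drop = FALSE]
  by_reason <- if (nrow(excl)) {
    as.data.frame(table(stage = excl$stage, reason = excl$reason),
                  responseName = "n", stringsAsFactors = FALSE)
  } else data.frame(stage = character(0), reason = character(0), n = integer(0))
  by_reason <- by_reason[by_reason$n > 0, , drop = FALSE]
  rownames(by_reason) <- NULL
  list(summary = data.frame(n_longlist = n_long, n_shortlist = n_short,
                            pct_shortlisted = pct_short,
                            pct_mono_exonic = pct_mono),
       by_reason = by_reason)
}

#' Shortlist/longlist percentage from raw counts (nearest integer)
#' @param n_longlist,n_shortlist raw counts.
#' @export
shortlist_pct <- function(n_longlist, n_shortlist) {
  round(100 * n_shortlist / n_longlist)
}
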