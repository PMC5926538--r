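# A transcript set here is a data.frame with one row per transcript:
# transcript_id, chrom, strand, exon_starts, exon_ends (comma-joined ascending
# coordinate lists). Helpers convert from an lnc_annotation.

#' Flatten an annotation into a transcript-set table
#'
#' @param ann an \code{lnc_annotation}.
#' @return data.frame transcript_id, chrom, strand, exon_starts, exon_ends.
#' @export
transcript_set <- function(ann) {
  ex <- split(ann$exons, ann$exons$transcript_id)
  tx <- ann$transcripts
  data.frame(
    transcript_id = tx$transcript_id, chrom = tx$chrom, strand = tx$strand,
    exon_starts = vapply(tx$transcript_id, function(id) {
      paste(ex[[id]]$start, collapse = ",")
    }, character(1L)),
    exon_ends = vapply(tx$transcript_id, function(id) {
      paste(ex[[id]]$end, collapse = ",")
    }, character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
}

.intron_chain <- function(starts, ends) {
  s <- as.integer(strsplit(starts, ",", fixed = TRUE)[[1L]])
  e <- as.integer(strsplit(ends, ",", fixed = TRUE)[[1L]])
  if (length(s) < 2L) return("")
  paste(paste(e[-length(e)] + 1L, s[-1L] - 1L, sep = "-"), collapse = ",")
}

.recip_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
}

#' Merge transcript sets into a non-redundant model set
#'
#' StringTie-merge-like convention: multi-exon transcripts sharing chrom,
#' strand and an identical intron chain collapse into one model whose termini
#' are the outermost observed; mono-exon transcripts are merged by
#' single-linkage clustering at >= \code{mono_overlap} reciprocal overlap,
#' with the merged extent being the union of members.
#'
#' @param sets list of transcript-set data.frames (see
#'   \code{\link{transcript_set}}).
#' @param mono_overlap reciprocal-overlap threshold for mono-exon merging
#'   (default 0.95).
#' @return A merged transcript-set data.frame.
#' @export
merge_models <- function(sets, mono_overlap = 0.95) {
  all <- do.call(rbind, sets)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(transcript_id = character(0), chrom = character(0),
                      strand = character(0), exon_starts = character(0),
                      exon_ends = character(0), stringsAsFactors = FALSE))
  }
  chain <- mapply(.intron_chain, all$exon_starts, all$exon_ends, USE.NAMES = FALSE)
  multi <- chain != ""
  out <- list()

  if (any(multi)) {
    mm <- all[multi, , drop = FALSE]
    key <- paste(mm$chrom, mm$strand, chain[multi], sep = "|")
    for (k in unique(key)) {
      grp <- mm[key == k, , drop = FALSE]
      s <- lapply(strsplit(grp$exon_starts, ","), as.integer)
      e <- lapply(strsplit(grp$exon_ends, ","), as.integer)
      # identical intron chain: only the outermost termini can differ
      first <- s[[1L]]; last <- e[[1L]]
      first[1L] <- min(vapply(s, `[`, integer(1L), 1L))
      nlast <- length(last)
      last[nlast] <- max(vapply(e, function(x) x[length(x)], integer(1L)))
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = grp$transcript_id[1L], chrom = grp$chrom[1L],
        strand = grp$strand[1L],
        exon_starts = paste(first, collapse = ","),
        exon_ends = paste(last, collapse = ","), stringsAsFactors = FALSE)
    }
  }

  if (any(!multi)) {
    mo <- all[!multi, , drop = FALSE]
    mo$s <- as.integer(mo$exon_starts); mo$e <- as.integer(mo$exon_ends)
    for (grp_key in unique(paste(mo$chrom, mo$strand, sep = "|"))) {
      sub <- mo[paste(mo$chrom, mo$strand, sep = "|") == grp_key, , drop = FALSE]
      sub <- sub[order(sub$s, sub$e), , drop = FALSE]
      n <- nrow(sub)
      comp <- seq_len(n)  # union-find by repeated relabelling (n is small)
      if (n > 1L) {
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
          if (sub$s[j] > sub$e[i]) break
          if (.recip_overlap(sub$s[i], sub$e[i], sub$s[j], sub$e[j]) >= mono_overlap) {
            comp[comp == comp[j]] <- comp[i]
          }
        }
      }
      for (k in unique(comp)) {
        members <- sub[comp == k, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = members$transcript_id[1L], chrom = members$chrom[1L],
          strand = members$strand[1L],
          exon_starts = as.character(min(members$s)),
          exon_ends = as.character(max(members$e)), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, as.integer(sub("[,].*", "", res$exon_starts))), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Is a reference model fully reconstructed by a merged set?
#'
#' Multi-exon: some merged transcript shares chrom, strand and the exact
#' intron chain (every splice site identical). Mono-exon: some merged
#' mono-exon transcript overlaps reciprocally by >= \code{mono_overlap}.
#'
#' @param model one row of a transcript-set data.frame.
#' @param merged merged transcript-set data.frame from
#'   \code{\link{merge_models}}.
#' @param mono_overlap reciprocal-overlap threshold (default 0.95).
#' @return logical.
#' @export
is_reconstructed <- function(model, merged, mono_overlap = 0.95) {
  if (!nrow(merged)) return(FALSE)
  chain <- .intron_chain(model$exon_starts, model$exon_ends)
  cand <- merged[merged$chrom == model$chrom & merged$strand == model$strand, , drop = FALSE]
  if (!nrow(cand)) return(FALSE)
  if (chain != "") {
    mchain <- mapply(.intron_chain, cand$exon_starts, cand$exon_ends, USE.NAMES = FALSE)
    return(any(mchain == chain))
  }
  s <- as.integer(model$exon_starts); e <- as.integer(model$exon_ends)
  mono <- !grepl(",", cand$exon_starts, fixed = TRUE)
  if (!any(mono)) return(FALSE)
  cs <- as.integer(cand$exon_starts[mono]); ce <- as.integer(cand$exon_ends[mono])
  any(vapply(seq_along(cs), function(i) {
    .recip_overlap(s, e, cs[i], ce[i]) >= mono_overlap
  }, logical(1L)))
}

#' Reconstruction reproducibility over all subsets of individuals
#'
#' Enumerates every non-empty subset of the n per-individual transcript sets
#' (2^n - 1 subsets; subset k corresponds to the binary representation of k,
#' bit i = individual i in sorted-id order), merges each subset's transcripts
#' and tests whether each reference model is fully reconstructed. The
#' per-library variant is the n singleton subsets.
#'
#' @param individual_sets named list of transcript-set data.frames, one per
#'   individual.
#' @param reference transcript-set data.frame of the models to assess.
#' @param mono_overlap reciprocal-overlap threshold (default 0.95).
#' @return data.frame, one row per reference model: model_id,
#'   n_subsets_total, n_subsets_reconstructed, reconstructed_in_all,
#'   reconstructed_in_any, n_singletons_reconstructed, plus a \code{per_subset}
#'   logical matrix attribute (models x subsets, canonical order).
#' @export
subset_reproducibility <- function(individual_sets, reference, mono_overlap = 0.95) {
  n <- length(individual_sets)
  if (n > 16L) stop("n > 16 individuals: enumerate 2^n - 1 subsets is not desk-scale; sample subsets instead")
  individual_sets <- individual_sets[order(names(individual_sets))]
  n_subsets <- 2L^n - 1L
  nmod <- nrow(reference)
  per_subset <- matrix(FALSE, nmod, n_subsets,
                       dimnames = list(reference$transcript_id,
                                       sprintf("S%d", seq_len(n_subsets))))
  singleton_cols <- 2L^(seq_len(n) - 1L)
  for (k in seq_len(n_subsets)) {
    members <- which(bitwAnd(k, 2L^(seq_len(n) - 1L)) > 0L)
    merged <- merge_models(individual_sets[members], mono_overlap = mono_overlap)
    for (m in seq_len(nmod)) {
      per_subset[m, k] <- is_reconstructed(reference[m, , drop = FALSE], merged,
                                           mono_overlap = mono_overlap)
    }
  }
  out <- data.frame(
    model_id = reference$transcript_id,
    n_subsets_total = n_subsets,
    n_subsets_reconstructed = rowSums(per_subset),
    reconstructed_in_all = rowSums(per_subset) == n_subsets,
    reconstructed_in_any = rowSums(per_subset) > 0L,
    n_singletons_reconstructed = rowSums(per_subset[, singleton_cols, drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "per_subset") <- per_subset
  out
}
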