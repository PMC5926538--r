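#' Enumerate gene triples along each chromosome
#'
#' Advances a sliding window gene-by-gene from the 5' end of each chromosome
#' and records, for every focal gene with both neighbours, the triple
#' (first upstream gene, focal gene, first downstream gene), irrespective of
#' strand. The first and last genes of a chromosome are never focal. Only
#' genes of the requested biotypes are considered, and (by default) only genes
#' carrying a symbol, since symbol-less genes cannot anchor a cross-species
#' match; skipped genes neither anchor nor break adjacency.
#'
#' @param ann an \code{lnc_annotation}.
#' @param biotypes biotypes eligible for the window (default protein_coding).
#' @param skip_unnamed drop genes with empty symbols before the scan
#'   (default TRUE). With FALSE, unnamed genes occupy window slots and their
#'   triples are emitted with empty symbol components.
#' @return data.frame, one row per triple: chrom, up/focal/down gene ids,
#'   symbols, starts and ends, plus \code{symbols} -- the ordered
#'   upper-cased symbol triple joined with \code{"|"} used as matching key.
#' @export
enumerate_triples <- function(ann, biotypes = "protein_coding", skip_unnamed = TRUE) {
  g <- ann$genes
  g <- g[g$biotype %in% biotypes, , drop = FALSE]
  if (skip_unnamed) g <- g[nzchar(g$symbol), , drop = FALSE]
  g <- g[order(g$chrom, g$start, g$end), , drop = FALSE]
  out <- list()
  for (chrom in unique(g$chrom)) {
    gc <- g[g$chrom == chrom, , drop = FALSE]
    n <- nrow(gc)
    if (n < 3L) next
    i <- 2:(n - 1L)
    out[[chrom]] <- data.frame(
      chrom = chrom,
      up_id = gc$gene_id[i - 1L], up_symbol = gc$symbol[i - 1L],
      up_start = gc$start[i - 1L], up_end = gc$end[i - 1L],
      focal_id = gc$gene_id[i], focal_symbol = gc$symbol[i],
      focal_start = gc$start[i], focal_end = gc$end[i],
      down_id = gc$gene_id[i + 1L], down_symbol = gc$symbol[i + 1L],
      down_start = gc$start[i + 1L], down_end = gc$end[i + 1L],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = character(0), up_id = character(0), up_symbol = character(0),
    up_start = integer(0), up_end = integer(0), focal_id = character(0),
    focal_symbol = character(0), focal_start = integer(0), focal_end = integer(0),
    down_id = character(0), down_symbol = character(0),
    down_start = integer(0), down_end = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res$symbols <- toupper(paste(res$up_symbol, res$focal_symbol, res$down_symbol, sep = "|"))
  res
}

# intergenic interval between two genes (possibly empty when they abut or
# overlap): returns c(start, end) with start > end meaning empty
.between <- function(s1, e1, s2, e2) {
  left_end <- if (s1 <= s2) e1 else e2
  right_start <- if (s1 <= s2) s2 else s1
  c(start = left_end + 1L, end = right_start - 1L)
}

#' Match gene triples across two species into syntenic blocks
#'
#' A syntenic block is a triple whose ordered (upper-cased) symbol key is
#' identical in both species: a region where gene order is conserved both up-
#' and downstream of a focal gene. Triples whose symbol key occurs more than
#' once within a species (tandem paralogue arrays) are ambiguous and dropped
#' with a warning. With \code{allow_reversed}, a triple matching the
#' reverse-order key also matches, flagged \code{orientation = "reversed"}.
#'
#' Each block carries, per species, the two intergenic intervals in symbol
#' space: the \emph{upstream} interval lies between the first-symbol gene and
#' the focal gene (whatever their genomic order), the \emph{downstream}
#' interval between the focal and third-symbol gene, so positions are
#' comparable across species regardless of orientation.
#'
#' @param triples_a,triples_b outputs of \code{\link{enumerate_triples}}.
#' @param allow_reversed also match reverse-ordered symbol triples
#'   (default FALSE: only identical order matches).
#' @return data.frame, one row per block: \code{block_id}, \code{symbols},
#'   \code{orientation}, and per species slot (\code{a_}/\code{b_}) the chrom,
#'   the three gene ids, and \code{*_upstream_ivl_start/end},
#'   \code{*_downstream_ivl_start/end}.
#' @export
match_blocks <- function(triples_a, triples_b, allow_reversed = FALSE) {
  drop_dups <- function(tr, label) {
    dup <- tr$symbols[duplicated(tr$symbols)]
    if (length(dup)) {
      warning(length(unique(dup)), " duplicate symbol triple(s) dropped in species ", label)
      tr <- tr[!tr$symbols %in% dup, , drop = FALSE]
    }
    tr
  }
  ta <- drop_dups(triples_a, "a")
  tb <- drop_dups(triples_b, "b")

  rev_key <- function(k) {
    vapply(strsplit(k, "|", fixed = TRUE),
           function(p) paste(rev(p), collapse = "|"), character(1L))
  }
  hits <- data.frame(ia = match(tb$symbols, ta$symbols),
                     ib = seq_len(nrow(tb)), orientation = "same",
                     stringsAsFactors = FALSE)
  hits <- hits[!is.na(hits$ia), , drop = FALSE]
  if (allow_reversed) {
    rhits <- data.frame(ia = match(rev_key(tb$symbols), ta$symbols),
                        ib = seq_len(nrow(tb)), orientation = "reversed",
                        stringsAsFactors = FALSE)
    rhits <- rhits[!is.na(rhits$ia) & !rhits$ib %in% hits$ib, , drop = FALSE]
    hits <- rbind(hits, rhits)
  }
  if (!nrow(hits)) {
    return(data.frame(block_id = character(0), symbols = character(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }

  species_cols <- function(tr, idx, slot, reversed = rep(FALSE, length(idx))) {
    up_ivl <- t(mapply(function(i, rv) {
      if (!rv) .between(tr$up_start[i], tr$up_end[i], tr$focal_start[i], tr$focal_end[i])
      else .between(tr$down_start[i], tr$down_end[i], tr$focal_start[i], tr$focal_end[i])
    }, idx, reversed))
    down_ivl <- t(mapply(function(i, rv) {
      if (!rv) .between(tr$focal_start[i], tr$focal_end[i], tr$down_start[i], tr$down_end[i])
      else .between(tr$focal_start[i], tr$focal_end[i], tr$up_start[i], tr$up_end[i])
    }, idx, reversed))
    df <- data.frame(tr$chrom[idx],
                     tr$up_id[idx], tr$focal_id[idx], tr$down_id[idx],
                     up_ivl[, 1L], up_ivl[, 2L], down_ivl[, 1L], down_ivl[, 2L],
                     stringsAsFactors = FALSE)
    names(df) <- paste0(slot, "_", c("chrom", "up_id", "focal_id", "down_id",
                                     "upstream_ivl_start", "upstream_ivl_end",
                                     "downstream_ivl_start", "downstream_ivl_end"))
    df
  }
  # in species b, a reversed match means the a-key's "up" symbol is b's "down"
  # gene; swap so intervals live in the shared (species-a key) symbol space
  revb <- hits$orientation == "reversed"
  blocks <- cbind(
    data.frame(block_id = sprintf("BLK%05d", seq_len(nrow(hits))),
               symbols = ta$symbols[hits$ia], orientation = hits$orientation,
               stringsAsFactors = FALSE),
    species_cols(ta, hits$ia, "a"),
    species_cols(tb, hits$ib, "b", reversed = revb))
  blocks <- blocks[order(blocks$symbols), , drop = FALSE]
  blocks$block_id <- sprintf("BLK%05d", seq_len(nrow(blocks)))
  rownames(blocks) <- NULL
  blocks
}

#' Assign lncRNA models to syntenic block intervals
#'
#' A lncRNA occupies a block position (upstream or downstream intergenic
#' interval) in a species when at least \code{containment} of its genomic
#' span lies within that interval; the default 1.0 requires full containment.
#'
#' @param blocks block table from \code{\link{match_blocks}}.
#' @param lnc_a,lnc_b data.frames of lncRNA gene spans (columns gene_id,
#'   chrom, start, end) for species a and b.
#' @param containment minimum contained fraction of the lncRNA span.
#' @return data.frame (block_id, species, position, lnc_id), one row per
#'   occupied (block, position, lncRNA) instance.
#' @export
assign_lncrnas_to_blocks <- function(blocks, lnc_a, lnc_b, containment = 1.0) {
  one_species <- function(lnc, slot) {
    if (is.null(lnc) || !nrow(lnc) || !nrow(blocks)) {
      return(data.frame(block_id = character(0), species = character(0),
                        position = character(0), lnc_id = character(0),
                        stringsAsFactors = FALSE))
    }
    res <- list()
    for (pos in c("upstream", "downstream")) {
      ivs <- blocks[[paste0(slot, "_", pos, "_ivl_start")]]
      ive <- blocks[[paste0(slot, "_", pos, "_ivl_end")]]
      ivc <- blocks[[paste0(slot, "_chrom")]]
      ok_iv <- !is.na(ivs) & !is.na(ive) & ivs <= ive
      for (k in which(ok_iv)) {
        same <- lnc$chrom == ivc[k]
        if (!any(same)) next
        ov <- pmax(0L, pmin(lnc$end[same], ive[k]) - pmax(lnc$start[same], ivs[k]) + 1L)
        frac <- ov / (lnc$end[same] - lnc$start[same] + 1L)
        hit <- frac >= containment & ov > 0L
        if (any(hit)) {
          res[[length(res) + 1L]] <- data.frame(
            block_id = blocks$block_id[k], species = slot, position = pos,
            lnc_id = lnc$gene_id[same][hit], stringsAsFactors = FALSE)
        }
      }
    }
    if (length(res)) do.call(rbind, res) else data.frame(
      block_id = character(0), species = character(0),
      position = character(0), lnc_id = character(0), stringsAsFactors = FALSE)
  }
  out <- rbind(one_species(lnc_a, "a"), one_species(lnc_b, "b"))
  rownames(out) <- NULL
  out
}

#' Synteny summary for one species pair
#'
#' Counts blocks, unique genes in the block set, positionally conserved
#' lncRNA instances (a (block, position) occupied in \emph{both} species,
#' upstream and downstream counted separately) and the percentage of blocks
#' containing at least one such instance (2 decimals).
#'
#' @param blocks block table from \code{\link{match_blocks}}.
#' @param presence presence table from \code{\link{assign_lncrnas_to_blocks}}.
#' @return One-row data.frame: n_blocks, n_unique_genes,
#'   n_conserved_positions, n_blocks_with_conserved, pct_blocks_with_conserved.
#' @export
synteny_report <- function(blocks, presence) {
  occ <- unique(presence[, c("block_id", "species", "position")])
  both <- merge(occ[occ$species == "a", c("block_id", "position")],
                occ[occ$species == "b", c("block_id", "position")])
  syms <- unlist(strsplit(blocks$symbols, "|", fixed = TRUE))
  synteny_report_row(
    n_blocks = nrow(blocks),
    n_unique_genes = length(unique(syms)),
    n_conserved_positions = nrow(both),
    n_blocks_with_conserved = length(unique(both$block_id)))
}

#' Assemble a synteny summary row from raw counts
#'
#' @param n_blocks,n_unique_genes,n_conserved_positions,n_blocks_with_conserved
#'   raw counts for one species pair.
#' @return One-row data.frame with \code{pct_blocks_with_conserved} rounded to
#'   2 decimals.
#' @export
synteny_report_row <- function(n_blocks, n_unique_genes,
                               n_conserved_positions, n_blocks_with_conserved) {
  data.frame(n_blocks = n_blocks, n_unique_genes = n_unique_genes,
             n_conserved_positions = n_conserved_positions,
             n_blocks_with_conserved = n_blocks_with_conserved,
             pct_blocks_with_conserved =
               if (n_blocks > 0) round(100 * n_blocks_with_conserved / n_blocks, 2)
               else 0)
}
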