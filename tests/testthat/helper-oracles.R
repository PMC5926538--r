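# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or by a different algorithmic route than the
# package implementation.

# ---- alignment ----

# All monotone lattice paths from (0,0) to (m,n) as strings over D/V/H
# (diagonal / vertical = consume query / horizontal = consume target).
all_paths <- function(m, n) {
  rec <- function(i, j) {
    if (i == m && j == n) return("")
    out <- character(0)
    if (i < m && j < n) out <- c(out, paste0("D", rec_memo(i + 1, j + 1)))
    if (i < m) out <- c(out, paste0("V", rec_memo(i + 1, j)))
    if (j < n) out <- c(out, paste0("H", rec_memo(i, j + 1)))
    out
  }
  memo <- new.env(parent = emptyenv())
  rec_memo <- function(i, j) {
    key <- paste(i, j)
    if (is.null(memo[[key]])) memo[[key]] <- rec(i, j)
    memo[[key]]
  }
  rec_memo(0, 0)
}

# Score one move string under EMBOSS-needle-style scoring with free end gaps:
# a gap run is free iff it is the first or the last run of the whole path.
score_path <- function(moves, q, t, match = 5, mismatch = -4,
                       open = 10, ext = 0.5) {
  mv <- strsplit(moves, "")[[1]]
  r <- rle(mv)
  qi <- 0; ti <- 0; score <- 0
  pos <- 1
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]; type <- r$values[k]
    if (type == "D") {
      for (u in seq_len(len)) {
        qi <- qi + 1; ti <- ti + 1
        qc <- substr(q, qi, qi); tc <- substr(t, ti, ti)
        score <- score + if (qc == tc && qc != "N") match else mismatch
      }
    } else {
      if (type == "V") qi <- qi + len else ti <- ti + len
      terminal <- (k == 1) || (k == length(r$lengths))
      if (!terminal) score <- score - (open + len * ext)
    }
    pos <- pos + len
  }
  score
}

# Brute-force optimal global alignment score by exhaustive path enumeration.
brute_nw_score <- function(q, t, ...) {
  max(vapply(all_paths(nchar(q), nchar(t)), score_path, numeric(1),
             q = q, t = t, ...))
}

# Regex-based longest gapless identity run (independent scan).
scan_identity_run <- function(aq, at) {
  a <- strsplit(aq, "")[[1]]; b <- strsplit(at, "")[[1]]
  ind <- ifelse(a == b & a != "-" & a != "N", "1", "0")
  runs <- regmatches(paste(ind, collapse = ""),
                     gregexpr("1+", paste(ind, collapse = "")))[[1]]
  if (!length(runs)) 0L else max(nchar(runs))
}

# Do two sequences share an exact common k-mer?
shares_kmer <- function(a, b, k = 20) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  kmers <- unique(substring(a, 1:(nchar(a) - k + 1), k:nchar(a)))
  any(vapply(kmers, function(km) grepl(km, b, fixed = TRUE), logical(1)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# ---- expression ----

# Independent HPA-style category evaluator: all rule conditions computed as
# booleans up front, category picked by fixed priority.
oracle_category <- function(x, groups = NULL, fold = 5) {
  conds <- c(
    not_detected = all(x < 1),
    tissue_specific = {
      top <- which.max(x); o <- x[-top]
      length(o) > 0 && all(o == 0) && any(x >= 1)
    },
    tissue_enriched = {
      top <- which.max(x); o <- x[-top]
      all(x[top] >= fold * o)
    },
    group_enriched = {
      hit <- FALSE
      if (!is.null(groups)) {
        gl <- groups[names(x)]
        for (gg in unique(gl)) {
          ins <- x[gl == gg]; outs <- x[gl != gg]
          if (length(ins) >= 2 && length(outs) > 0 &&
              min(ins) >= fold * max(outs)) hit <- TRUE
        }
      }
      hit
    },
    tissue_enhanced = {
      det <- x[x >= 1]
      length(det) > 0 && max(x) >= fold * mean(det)
    },
    expressed_in_all = all(x > 1)
  )
  nm <- names(conds)[which(conds)[1]]
  if (is.na(nm)) "mixed" else nm
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# ---- annotations ----

# Small hand-built annotation: genes as a data.frame with optional exon list.
toy_annotation <- function(genes, exons_per_tx = NULL) {
  tx <- data.frame(transcript_id = paste0(genes$gene_id, ".t1"),
                   gene_id = genes$gene_id, chrom = genes$chrom,
                   strand = genes$strand, stringsAsFactors = FALSE)
  if (is.null(exons_per_tx)) {
    exons <- data.frame(transcript_id = tx$transcript_id,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
  } else {
    exons <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
      e <- exons_per_tx[[i]]
      data.frame(transcript_id = tx$transcript_id[i],
                 start = e[, 1], end = e[, 2], stringsAsFactors = FALSE)
    }))
  }
  annotation(genes, tx, exons)
}

gene_row <- function(id, chrom, start, end, strand = "+",
                     biotype = "protein_coding", symbol = "") {
  data.frame(gene_id = id, symbol = symbol, chrom = chrom, start = start,
             end = end, strand = strand, biotype = biotype,
             stringsAsFactors = FALSE)
}
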