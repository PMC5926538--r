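#' Read a Kallisto-style abundance table
#'
#' Tab-delimited with a single header line and columns exactly: target_id,
#' length, eff_length, est_counts, tpm.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_abundance <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("target_id", "length", "eff_length", "est_counts", "tpm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("abundance table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Aggregate transcript abundances to gene level
#'
#' Gene TPM is the sum of member-transcript TPM within each sample (the
#' standard transcript-to-gene summarisation of within-sample-normalised
#' abundances).
#'
#' @param tpm transcripts x samples numeric matrix (rownames = transcript ids).
#' @param tx2gene named character vector, transcript id -> gene id.
#' @return genes x samples matrix.
#' @export
aggregate_to_genes <- function(tpm, tx2gene) {
  unmapped <- setdiff(rownames(tpm), names(tx2gene))
  if (length(unmapped)) {
    stop("unmapped transcript id(s): ", paste(unmapped, collapse = ", "))
  }
  gene <- tx2gene[rownames(tpm)]
  out <- rowsum(tpm, group = gene, reorder = TRUE)
  out[order(rownames(out)), , drop = FALSE]
}

#' Per-tissue mean TPM
#'
#' @param mat genes x samples matrix.
#' @param tissue character vector, tissue of each sample column.
#' @return genes x tissues matrix of replicate means, tissue columns sorted.
#' @export
tissue_means <- function(mat, tissue) {
  stopifnot(ncol(mat) == length(tissue))
  t(rowsum(t(mat), group = tissue, reorder = TRUE) / as.vector(table(tissue)[sort(unique(tissue))]))
}

#' Tissue-specificity index tau
#'
#' tau = sum_i (1 - x_i / max(x)) / (N - 1) on per-tissue mean TPM: 0 for a
#' flat (housekeeping) profile, 1 for expression confined to a single tissue.
#' All-zero profiles are undefined and return NA.
#'
#' @param x numeric vector of per-tissue mean TPM (length >= 2, all >= 0).
#' @return tau in [0, 1], or NA for an all-zero profile.
#' @export
compute_tau <- function(x) {
  stopifnot(length(x) >= 2L, all(x >= 0))
  if (all(x == 0)) return(NA_real_)
  sum(1 - x / max(x)) / (length(x) - 1L)
}

#' Mean/median expression ratio
#'
#' Mean TPM across all samples divided by the median of the per-tissue mean
#' TPM; a zero median is floored at 0.01 to avoid undefined values. Larger
#' ratios indicate more sample-specific (right-skewed) expression.
#'
#' @param sample_tpm per-sample TPM values of one gene.
#' @param tissue_mean_tpm per-tissue mean TPM values of the same gene.
#' @return The ratio.
#' @export
compute_mean_median_ratio <- function(sample_tpm, tissue_mean_tpm) {
  med <- stats::median(tissue_mean_tpm)
  if (med == 0) med <- 0.01
  mean(sample_tpm) / med
}

#' Preferential expression measure (PEM) per tissue
#'
#' Per-tissue mean TPM is floored at 1, log2-transformed (S), and centred by
#' the across-tissue mean of S (A): PEM(t) = S_t - A. Values sum to zero
#' across tissues by construction; a positive PEM marks preferential
#' expression in that tissue.
#'
#' @param x numeric vector of per-tissue mean TPM (length >= 2).
#' @return Named numeric vector of PEM values (names kept from \code{x}).
#' @export
compute_pem <- function(x) {
  stopifnot(length(x) >= 2L)
  s <- log2(pmax(x, 1))
  s - mean(s)
}

#' Expression level bin from average TPM
#'
#' Half-open bins making the partition total: not_detected [0,1), low [1,10),
#' medium [10,50), high [50, Inf).
#'
#' @param avg_tpm average TPM value(s).
#' @return Character vector of bins.
#' @export
expression_level_bin <- function(avg_tpm) {
  cut(avg_tpm, breaks = c(-Inf, 1, 10, 50, Inf), right = FALSE,
      labels = c("not_detected", "low", "medium", "high")) |> as.character()
}

#' Human-Protein-Atlas-style expression category
#'
#' Evaluation order: \code{not_detected} (all tissues < 1 TPM);
#' \code{tissue_specific} (top tissue at least five-fold above all others,
#' all others at 0 TPM); \code{tissue_enriched} (top tissue at least
#' five-fold above every other tissue); \code{group_enriched} (a group of
#' >= 2 tissues, each at least five-fold above every out-group tissue);
#' \code{tissue_enhanced} (some tissue at least five-fold above the mean of
#' tissues with detectable expression, mean TPM >= 1); \code{expressed_in_all}
#' (> 1 TPM in every tissue); else \code{mixed}.
#'
#' @param x named numeric vector of per-tissue mean TPM.
#' @param groups named character vector, tissue -> group (organ system);
#'   must cover every tissue in \code{x}.
#' @param fold fold-change threshold (default 5).
#' @return Category string.
#' @export
categorize_expression <- function(x, groups = NULL, fold = 5) {
  if (all(x < 1)) return("not_detected")
  mx <- max(x)
  top <- which.max(x)
  others <- x[-top]
  if (all(others == 0)) return("tissue_specific")
  if (all(mx >= fold * others)) return("tissue_enriched")
  if (!is.null(groups)) {
    if (!all(names(x) %in% names(groups))) stop("groups must cover every tissue")
    gl <- groups[names(x)]
    for (grp in unique(gl)) {
      inside <- x[gl == grp]; outside <- x[gl != grp]
      if (length(inside) >= 2L && length(outside) > 0L &&
          all(min(inside) >= fold * outside)) {
        return("group_enriched")
      }
    }
  }
  detected <- x[x >= 1]
  if (length(detected) && any(x >= fold * mean(detected))) return("tissue_enhanced")
  if (all(x > 1)) return("expressed_in_all")
  "mixed"
}

#' Reproducible-detection flag for one gene
#'
#' Two modes mirror the two analyses: \code{count1_all_reps} requires at
#' least one read (est_counts >= 1) in every replicate of the tissue where
#' the gene's mean TPM is highest (ties broken lexicographically by tissue
#' name); \code{tpm_gt_0.01_all_individuals} requires TPM > 0.01 in every
#' individual.
#'
#' @param tpm per-sample TPM vector of the gene.
#' @param counts per-sample est_counts vector (mode count1_all_reps).
#' @param tissue per-sample tissue labels.
#' @param individual per-sample individual labels (mode tpm_gt_0.01...).
#' @param mode which criterion to apply.
#' @return logical.
#' @export
flag_reproducible <- function(tpm, counts = NULL, tissue = NULL, individual = NULL,
                              mode = c("count1_all_reps", "tpm_gt_0.01_all_individuals")) {
  mode <- match.arg(mode)
  if (mode == "count1_all_reps") {
    stopifnot(!is.null(counts), !is.null(tissue))
    mean_by_tissue <- tapply(tpm, tissue, mean)
    top <- sort(names(mean_by_tissue)[mean_by_tissue == max(mean_by_tissue)])[1L]
    all(counts[tissue == top] >= 1)
  } else {
    stopifnot(!is.null(individual))
    max_by_ind <- tapply(tpm, individual, max)
    all(max_by_ind > 0.01)
  }
}

#' Per-gene expression summary table
#'
#' Computes, for every gene: per-tissue mean TPM, level bin (on the average
#' TPM over all samples), tau, mean/median ratio, PEM per tissue with the
#' top-PEM tissue, HPA-style category, and the reproducibility flag.
#'
#' @param mat genes x samples TPM matrix.
#' @param metadata data.frame with columns sample, tissue, replicate, group,
#'   rows matching the matrix columns (by \code{sample} name).
#' @param counts optional genes x samples est_counts matrix for the
#'   reproducibility flag.
#' @return data.frame, one row per gene, plus a \code{pem} matrix attribute.
#' @export
summarize_expression <- function(mat, metadata, counts = NULL) {
  stopifnot(all(colnames(mat) %in% metadata$sample))
  md <- metadata[match(colnames(mat), metadata$sample), , drop = FALSE]
  tm <- tissue_means(mat, md$tissue)
  groups <- stats::setNames(md$group, md$tissue)[colnames(tm)]
  avg <- rowMeans(mat)
  pem <- t(apply(tm, 1L, compute_pem))
  colnames(pem) <- colnames(tm)
  out <- data.frame(
    gene_id = rownames(mat),
    level_bin = expression_level_bin(avg),
    tau = apply(tm, 1L, compute_tau),
    mean_median_ratio = vapply(seq_len(nrow(mat)), function(i) {
      compute_mean_median_ratio(mat[i, ], tm[i, ])
    }, numeric(1L)),
    max_pem_tissue = colnames(pem)[max.col(pem, ties.method = "first")],
    category = vapply(seq_len(nrow(tm)), function(i) {
      categorize_expression(tm[i, ], groups = groups)
    }, character(1L)),
    stringsAsFactors = FALSE)
  if (!is.null(counts)) {
    out$reproducible <- vapply(seq_len(nrow(mat)), function(i) {
      flag_reproducible(mat[i, ], counts = counts[i, ], tissue = md$tissue)
    }, logical(1L))
  }
  attr(out, "tissue_means") <- tm
  attr(out, "pem") <- pem
  out
}
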