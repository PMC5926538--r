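#' Build a thresholded Pearson co-expression graph
#'
#' Pearson correlation over per-sample TPM (no transformation by default,
#' optionally log2(x+1)); an undirected edge is kept when the signed r is at
#' least the threshold, so negative correlations are always discarded.
#' Zero-variance genes cannot be correlated and are excluded with a message.
#'
#' @param mat genes x samples TPM matrix (>= 3 samples).
#' @param threshold minimum Pearson r (default 0.95).
#' @param node_filter optional character vector restricting the node set
#'   (e.g. reproducibly expressed lncRNAs plus protein-coding genes).
#' @param log2p1 correlate log2(TPM + 1) instead of raw TPM.
#' @return list with \code{edges} (data.frame gene_a, gene_b, r; gene_a <
#'   gene_b), \code{nodes} (all retained gene ids, sorted) and
#'   \code{threshold}.
#' @export
build_coexpression_graph <- function(mat, threshold = 0.95, node_filter = NULL,
                                     log2p1 = FALSE) {
  if (ncol(mat) < 3L) stop("need at least 3 samples to correlate")
  if (!is.null(node_filter)) mat <- mat[rownames(mat) %in% node_filter, , drop = FALSE]
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  v <- apply(mat, 1L, stats::var)
  if (any(v == 0)) {
    message(sum(v == 0), " zero-variance gene(s) excluded from the graph")
    mat <- mat[v > 0, , drop = FALSE]
  }
  if (log2p1) mat <- log2(mat + 1)
  cm <- stats::cor(t(mat))
  cm[lower.tri(cm, diag = TRUE)] <- NA  # keep each unordered pair once
  keep <- which(cm >= threshold, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(cm)[keep[, 1L]],
                      gene_b = colnames(cm)[keep[, 2L]],
                      r = cm[keep], stringsAsFactors = FALSE)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]; edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, nodes = rownames(mat), threshold = threshold)
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Standard MCL: edge weights (plus unit self-loops) are column-normalised,
#' then expansion (matrix power) and inflation (elementwise power followed by
#' renormalisation) alternate, pruning entries below \code{prune}, until the
#' matrix change falls below \code{tol} or \code{max_iter} is reached.
#' Clusters are the connected components of the non-zero pattern of the limit
#' matrix. Nodes are processed in sorted-id order, so the result is
#' independent of input order.
#'
#' @param graph list with \code{edges} and \code{nodes} as produced by
#'   \code{\link{build_coexpression_graph}}.
#' @param inflation inflation exponent (cluster granularity; default 2.2).
#' @param expansion expansion power (default 2).
#' @param prune entries below this are zeroed each iteration (default 1e-5).
#' @param max_iter,tol convergence controls.
#' @return list with \code{membership} (named integer vector, gene ->
#'   cluster id; ids ordered by decreasing cluster size then lexicographic
#'   smallest member), \code{sizes}, \code{inflation}, \code{converged}.
#' @export
mcl_cluster <- function(graph, inflation = 2.2, expansion = 2L, prune = 1e-5,
                        max_iter = 100L, tol = 1e-6) {
  nodes <- sort(graph$nodes)
  n <- length(nodes)
  if (n == 0L) stop("empty graph")
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    ia <- match(graph$edges$gene_a, nodes)
    ib <- match(graph$edges$gene_b, nodes)
    M[cbind(ia, ib)] <- graph$edges$r
    M[cbind(ib, ia)] <- graph$edges$r
  }
  diag(M) <- 1  # unit self-loops, standard MCL practice
  normalize <- function(m) sweep(m, 2L, colSums(m), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (k in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune] <- 0
    dead <- colSums(Minf) == 0
    if (any(dead)) diag(Minf)[dead] <- 1  # resurrect fully pruned columns
    Minf <- normalize(Minf)
    if (max(abs(Minf - M)) < tol) {
      M <- Minf
      converged <- TRUE
      break
    }
    M <- Minf
  }
  if (!converged) warning("MCL did not converge within ", max_iter, " iterations")
  adj <- (M > 0) | (t(M) > 0)
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(gr)$membership
  # canonical cluster ids: decreasing size, ties by smallest member id
  tabs <- table(comp)
  first_member <- tapply(nodes, comp, min)
  ord <- order(-as.integer(tabs), first_member)
  relabel <- stats::setNames(seq_along(ord), names(tabs)[ord])
  membership <- stats::setNames(as.integer(relabel[as.character(comp)]), nodes)
  list(membership = membership,
       sizes = as.integer(table(membership)),
       inflation = inflation, converged = converged)
}

#' Per-cluster biotype composition
#'
#' @param membership named integer vector from \code{\link{mcl_cluster}}.
#' @param biotypes named character vector, gene id -> biotype.
#' @param pem optional genes x tissues PEM matrix; when given, each cluster
#'   reports the tissue with the highest mean PEM over members.
#' @return data.frame: cluster, size, n_lncRNA, n_protein_coding, top_tissue.
#' @export
cluster_composition <- function(membership, biotypes, pem = NULL) {
  if (!length(membership)) {
    return(data.frame(cluster = integer(0), size = integer(0),
                      n_lncRNA = integer(0), n_protein_coding = integer(0),
                      top_tissue = character(0), stringsAsFactors = FALSE))
  }
  bt <- biotypes[names(membership)]
  cl <- sort(unique(membership))
  rows <- lapply(cl, function(k) {
    members <- names(membership)[membership == k]
    top <- NA_character_
    if (!is.null(pem)) {
      hit <- intersect(members, rownames(pem))
      if (length(hit)) {
        mp <- colMeans(pem[hit, , drop = FALSE])
        top <- names(mp)[which.max(mp)]
      }
    }
    data.frame(cluster = k, size = length(members),
               n_lncRNA = sum(bt[members] == "lncRNA", na.rm = TRUE),
               n_protein_coding = sum(bt[members] == "protein_coding", na.rm = TRUE),
               top_tissue = top, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
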