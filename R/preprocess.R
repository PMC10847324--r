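#' Filter cells by number of detected genes
#'
#' Cells with fewer than `min_genes` genes detected (count > 0) are removed;
#' the gene set is unchanged.
#'
#' @param m count matrix (genes x cells).
#' @param min_genes minimum detected genes to retain a cell (default 400).
#' @return the retained columns of `m`.
#' @export
filter_cells <- function(m, min_genes = 400L) {
  stopifnot(min_genes >= 0)
  detected <- Matrix::colSums(m > 0)
  keep <- detected >= min_genes
  if (!any(keep)) warning("all cells removed by the gene-count filter")
  m[, keep, drop = FALSE]
}

#' TP10K log-normalization
#'
#' Each cell's counts are scaled to 10,000 total and log-transformed with a
#' pseudocount of one: `value = ln(count / cell_total * 10000 + 1)`. Zero
#' counts map to exactly zero, so sparsity is preserved.
#'
#' @param m count matrix (genes x cells) with no zero-total cells.
#' @return sparse `NormalizedMatrix` of the same shape.
#' @export
lognormalize_tp10k <- function(m) {
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stop("zero-total cell(s): ",
         paste(utils::head(colnames(m)[tot == 0], 5), collapse = ", "))
  nm <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  percell <- rep.int(1e4 / tot, diff(nm@p))
  nm@x <- log1p(nm@x * percell)
  attr(nm, "normalization") <- "tp10k_log"
  nm
}

#' Select highly variable genes
#'
#' Dispersion is the gene's variance of normalized expression divided by the
#' mean variance of its expression bin (20 equal-frequency bins on the gene
#' mean), a trend-normalized criterion that does not require a smoother.
#' Ties are broken by gene id so the selection is deterministic.
#'
#' @param nm normalized matrix (genes x cells).
#' @param n_hvg number of genes to select.
#' @param n_bins bins for the mean-variance trend (default 20).
#' @return character vector of `n_hvg` gene ids.
#' @export
select_hvg <- function(nm, n_hvg, n_bins = 20L) {
  stopifnot(n_hvg <= nrow(nm))
  mu <- Matrix::rowMeans(nm)
  v <- Matrix::rowMeans(nm^2) - mu^2
  v <- v * ncol(nm) / max(1, ncol(nm) - 1)
  ord <- order(mu, rownames(nm))
  bin <- integer(nrow(nm))
  bin[ord] <- ceiling(seq_len(nrow(nm)) * n_bins / nrow(nm))
  binmean <- tapply(v, bin, mean)
  expected <- as.numeric(binmean[as.character(bin)])
  disp <- ifelse(expected > 0, v / expected, 0)
  disp[v == 0] <- -Inf   # constant genes last
  rownames(nm)[order(-disp, rownames(nm))][seq_len(n_hvg)]
}

#' Center and scale genes
#'
#' Per-gene linear transformation to mean 0 and unit variance (constant genes
#' become all zeros), with values clipped to `c(-clip, clip)`.
#'
#' @param nm normalized matrix (genes x cells).
#' @param genes gene subset to scale (default all).
#' @param clip magnitude cap (default 10).
#' @return dense genes x cells matrix.
#' @export
scale_center <- function(nm, genes = rownames(nm), clip = 10) {
  stopifnot(length(genes) > 0)
  x <- as.matrix(nm[genes, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  sdv[sdv == 0] <- Inf  # constant gene -> all zeros
  x <- (x - mu) / sdv
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  x
}

#' PCA embedding of cells
#'
#' Principal components of the scaled matrix (cells as observations).
#' Component signs are fixed so the largest-magnitude gene loading of each
#' component is positive.
#'
#' @param scaled genes x cells matrix from [scale_center()].
#' @param n_pcs number of components (default 16).
#' @return cells x n_pcs matrix with attributes `sdev` (component standard
#'   deviations) and `rotation` (gene loadings).
#' @export
pca_embed <- function(scaled, n_pcs = 16L) {
  stopifnot(n_pcs <= min(dim(scaled)))
  pc <- stats::prcomp(t(scaled), center = FALSE, scale. = FALSE,
                      rank. = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  emb <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
  rownames(emb) <- colnames(scaled)
  attr(emb, "sdev") <- pc$sdev
  attr(emb, "rotation") <- sweep(pc$rotation, 2, flip, "*")
  emb
}

# kNN index matrix (self included in the neighbor set, Seurat-style)
knn_index <- function(emb, k) {
  d <- as.matrix(stats::dist(emb))
  n <- nrow(d)
  t(vapply(seq_len(n), function(i) order(d[i, ])[seq_len(k + 1)],
           integer(k + 1)))
}

#' Shared-nearest-neighbor modularity clustering
#'
#' Builds a kNN graph (Euclidean distance in the embedding), weights each
#' neighbor pair by the Jaccard overlap of their neighbor sets (edges with
#' overlap below `prune` are dropped), and partitions the graph by
#' resolution-parametrised Louvain modularity optimization. Cluster ids are
#' integers from 0, ordered by decreasing size.
#'
#' @param embedding cells x PCs matrix with cell ids as rownames.
#' @param k_neighbors neighbors per cell (default 20).
#' @param resolution modularity resolution (default 0.2).
#' @param prune minimum Jaccard weight for an SNN edge (default 1/15).
#' @param seed RNG seed for the modularity optimizer.
#' @return `ClusterAssignment`: list with `cluster` (named integer vector),
#'   `sizes` (N_i per cluster), `resolution`.
#' @export
snn_cluster <- function(embedding, k_neighbors = 20L, resolution = 0.2,
                        prune = 1 / 15, seed = 0L) {
  n <- nrow(embedding)
  if (n < 3) stop("need at least 3 cells to cluster")
  stopifnot(k_neighbors < n)
  nn <- knn_index(embedding, k_neighbors)
  k1 <- ncol(nn)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k1),
                              j = as.integer(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- methods::as(methods::as(shared, "generalMatrix"), "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L; s <- shared@x[keep]
  jac <- s / (2 * k1 - s)
  ok <- jac >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = jac[ok]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)[as.character(seq_len(n))]
  # relabel by decreasing size, ties by first occurrence
  tab <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(tab) - 1L, names(tab))
  cluster <- stats::setNames(as.integer(relab[as.character(memb)]),
                             rownames(embedding))
  structure(list(cluster = cluster,
                 sizes = table(cluster),
                 resolution = resolution),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment:", length(x$sizes), "clusters over",
      length(x$cluster), "cells (resolution", x$resolution, ")\n")
  print(x$sizes)
  invisible(x)
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene rank-sum test between two disjoint cell groups on the normalized
#' matrix, with the tie-corrected normal approximation and continuity
#' correction. The log fold change is computed on the de-logged scale:
#' `logFC = ln((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))`.
#'
#' @param nm normalized matrix (genes x cells).
#' @param group_a,group_b disjoint cell id vectors, each of size >= 3.
#' @param p_adjust `"bonferroni"` (default, over tested genes) or `"bh"`.
#' @return `DEResult` data.frame: gene, mean_a, mean_b, logFC, p, p_adj.
#' @export
wilcoxon_de <- function(nm, group_a, group_b,
                        p_adjust = c("bonferroni", "bh")) {
  p_adjust <- match.arg(p_adjust)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap")
  stopifnot(length(group_a) >= 3, length(group_b) >= 3)
  xa <- as.matrix(nm[, group_a, drop = FALSE])
  xb <- as.matrix(nm[, group_b, drop = FALSE])
  na <- ncol(xa); nb <- ncol(xb); N <- na + nb
  x <- cbind(xa, xb)
  res <- t(apply(x, 1, function(v) {
    r <- rank(v)
    Ra <- sum(r[seq_len(na)])
    U <- Ra - na * (na + 1) / 2
    mu <- na * nb / 2
    ties <- table(v)
    sig2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(c(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    c(U = U, p = min(1, 2 * stats::pnorm(-abs(z))))
  }))
  mean_a <- rowMeans(expm1(xa))
  mean_b <- rowMeans(expm1(xb))
  out <- data.frame(gene = rownames(nm),
                    mean_a = mean_a, mean_b = mean_b,
                    logFC = log((mean_a + 1) / (mean_b + 1)),
                    p = res[, "p"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adj <- stats::p.adjust(out$p,
                               method = if (p_adjust == "bh") "BH" else "bonferroni")
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Optional per-sample gene-mean centering
#'
#' A lightweight batch stress-test device: subtracts each sample's per-gene
#' mean from its cells (no anchor-based integration is performed).
#'
#' @param nm normalized matrix (genes x cells).
#' @param sample_of named character vector cell_id -> sample_id.
#' @return dense centered matrix.
#' @export
center_by_sample <- function(nm, sample_of) {
  x <- as.matrix(nm)
  for (s in unique(sample_of)) {
    idx <- colnames(x) %in% names(sample_of)[sample_of == s]
    x[, idx] <- x[, idx] - rowMeans(x[, idx, drop = FALSE])
  }
  x
}
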