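#' Highly variable genes by binned dispersion
#'
#' Per-gene dispersion (variance / mean of the normalized values) is
#' z-scored within equal-width bins of mean expression, and genes are
#' ranked by the normalized dispersion. Genes with zero mean are never
#' selected.
#'
#' @param nm a \code{normalized_matrix}
#' @param n_hvg number of genes to select, default 2000
#' @param n_mean_bins number of mean-expression bins, default 20
#' @return character vector of gene ids, ordered by decreasing
#'   normalized dispersion.
#' @export
select_hvgs <- function(nm, n_hvg = 2000L, n_mean_bins = 20L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  v <- nm$values
  mu <- Matrix::rowMeans(v)
  m2 <- Matrix::rowMeans(v^2)
  va <- pmax(m2 - mu^2, 0) * ncol(v) / max(ncol(v) - 1, 1)
  disp <- ifelse(mu > 0, va / mu, NA_real_)
  ok <- which(!is.na(disp))
  bins <- cut(mu[ok], breaks = n_mean_bins, labels = FALSE)
  z <- disp[ok]
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(z[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (z[i] - mean(z[i])) / s
  }
  ord <- ok[order(z, decreasing = TRUE)]
  nm$gene_meta$gene_id[head(ord, min(n_hvg, length(ord)))]
}

# symmetric kNN adjacency (union of neighborhoods) in PC space
knn_graph <- function(pcs, k = 15L) {
  n <- nrow(pcs)
  k <- min(k, n - 1L)
  d <- as.matrix(dist(pcs))
  diag(d) <- Inf
  idx <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(idx))
  adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  adj <- (adj + Matrix::t(adj)) > 0
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' PCA embedding and graph-based clustering
#'
#' Selects highly variable genes, runs PCA on the centered HVG submatrix,
#' builds a k-nearest-neighbor graph in PC space and partitions it with
#' seeded Louvain community detection.
#'
#' @param nm a \code{normalized_matrix}
#' @param n_hvg number of highly variable genes, default 2000
#' @param n_pcs number of principal components, default 40 (reduced with a
#'   warning when it exceeds the matrix rank)
#' @param resolution Louvain resolution parameter
#' @param k neighbors for the kNN graph, default 15
#' @param seed RNG seed making the partition deterministic
#' @return list with \code{hvg_ids}, \code{pc_coordinates}
#'   (cells x n_pcs), \code{cluster_labels} (integer per cell, named by
#'   barcode) and \code{resolution}.
#' @export
embed_and_cluster <- function(nm, n_hvg = 2000L, n_pcs = 40L,
                              resolution = 1, k = 15L, seed = 1L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  hvg <- select_hvgs(nm, n_hvg)
  x <- t(as.matrix(nm$values[match(hvg, nm$gene_meta$gene_id), ,
                             drop = FALSE]))
  max_pc <- min(dim(x)) - 1L
  if (n_pcs > max_pc) {
    warning(sprintf("n_pcs reduced from %d to matrix rank bound %d",
                    n_pcs, max_pc))
    n_pcs <- max_pc
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pcs <- pc$x[, seq_len(n_pcs), drop = FALSE]
  g <- knn_graph(pcs, k)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm))
  names(labels) <- nm$cell_meta$barcode
  list(hvg_ids = hvg, pc_coordinates = pcs, cluster_labels = labels,
       resolution = resolution)
}
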