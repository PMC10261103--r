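#' DEPTH2 intratumor-heterogeneity score on pseudo-bulk profiles
#'
#' Each gene is z-scored across samples (sample sd, ddof = 1;
#' zero-variance genes contribute z = 0), and a sample's score is the
#' standard deviation over genes of its absolute z-scores. Input is a
#' pseudo-bulk matrix, e.g. per-sample mean expression over cells.
#'
#' @param pseudobulk numeric matrix, genes x samples (>= 2 samples)
#' @return named numeric vector of per-sample scores.
#' @export
depth2 <- function(pseudobulk) {
  x <- as.matrix(pseudobulk)
  assert_that(ncol(x) >= 2, "need >= 2 samples")
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  setNames(apply(abs(z), 2, sd), colnames(x))
}

#' Pseudo-bulk profile: per-sample mean expression over cells
#'
#' @param nm a \code{normalized_matrix}
#' @param sample_ids per-cell sample labels; defaults to
#'   \code{nm$cell_meta$sample_id}
#' @return genes x samples matrix of mean expression.
#' @export
pseudobulk_means <- function(nm, sample_ids = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  ids <- sample_ids %||% nm$cell_meta$sample_id
  u <- sort(unique(ids))
  out <- vapply(u, function(s)
    Matrix::rowMeans(nm$values[, ids == s, drop = FALSE]),
    numeric(nrow(nm$values)))
  rownames(out) <- nm$gene_meta$gene_id
  out
}

#' Hill-number diversity profile
#'
#' Generalized diversity of order q over cluster (or clone) frequencies:
#' \code{D_q = (sum p_i^q)^(1/(1-q))} for q != 1 and the exponential
#' Shannon limit \code{D_1 = exp(-sum p_i log p_i)}. q = 0 gives richness
#' and q = 2 the inverse Simpson index. Counts are renormalized and
#' zero-frequency classes excluded.
#'
#' @param p nonnegative frequency or count vector (nonempty, positive sum)
#' @param q_grid orders at which to evaluate, default c(0, 1, 2)
#' @return named numeric vector \code{D_q} over the grid.
#' @export
hill_diversity <- function(p, q_grid = c(0, 1, 2)) {
  assert_that(length(p) > 0, "empty frequency vector")
  assert_that(all(p >= 0) && sum(p) > 0,
              "frequencies must be nonnegative with positive sum")
  p <- p[p > 0]
  p <- p / sum(p)
  d <- vapply(q_grid, function(q) {
    if (abs(q - 1) < 1e-9) exp(-sum(p * log(p)))
    else sum(p^q)^(1 / (1 - q))
  }, 0)
  setNames(d, paste0("q", q_grid))
}
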