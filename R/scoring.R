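#' Binned-control gene signature score
#'
#' For every cell, the mean normalized expression of the signature genes
#' minus the mean over a pooled expression-matched control set: genes are
#' binned into \code{n_bins} equal-frequency bins of mean expression
#' across cells, and each signature gene contributes \code{ctrl_per_gene}
#' control genes sampled without replacement from its bin (signature
#' genes excluded; the pooled control set keeps unique genes). The
#' sampling is seeded and iterates signature genes in the order given.
#'
#' @param nm a \code{normalized_matrix} with at least \code{n_bins} genes
#' @param gene_set character vector of signature gene ids; absent genes
#'   are dropped with a warning (error if all absent)
#' @param n_bins expression bins, default 25
#' @param ctrl_per_gene controls sampled per signature gene, default 50
#' @param seed RNG seed for control sampling
#' @param signature_name label attached to the result
#' @return named numeric vector of per-cell scores with attributes
#'   \code{"signature_name"} and \code{"control_genes"}.
#' @export
score_signature <- function(nm, gene_set, n_bins = 25L,
                            ctrl_per_gene = 50L, seed = 1L,
                            signature_name = "signature") {
  stopifnot(inherits(nm, "normalized_matrix"))
  genes <- nm$gene_meta$gene_id
  assert_that(length(genes) >= n_bins, "need genes >= n_bins")
  present <- gene_set[gene_set %in% genes]
  if (!length(present)) stop("no signature genes present", call. = FALSE)
  if (length(present) < length(gene_set))
    warning("dropping absent signature genes: ",
            paste(head(setdiff(gene_set, present), 10), collapse = ", "))
  v <- nm$values
  mu <- Matrix::rowMeans(v)
  # equal-frequency bins of mean expression (ranked, ties by gene order)
  bin <- ceiling(rank(mu, ties.method = "first") / length(mu) * n_bins)
  names(bin) <- genes
  set.seed(seed)
  ctrl <- character(0)
  for (g in present) {
    cand <- genes[bin == bin[[g]]]
    cand <- setdiff(cand, gene_set)
    if (!length(cand)) next
    take <- min(ctrl_per_gene, length(cand))
    ctrl <- c(ctrl, sample(cand, take))
  }
  ctrl <- unique(ctrl)
  sig_mean <- Matrix::colMeans(v[match(present, genes), , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) {
    Matrix::colMeans(v[match(ctrl, genes), , drop = FALSE])
  } else rep(0, ncol(v))
  score <- sig_mean - ctrl_mean
  names(score) <- nm$cell_meta$barcode
  attr(score, "signature_name") <- signature_name
  attr(score, "control_genes") <- ctrl
  score
}

#' Call signature-positive cells and per-sample proportions
#'
#' Cells whose score strictly exceeds the threshold are flagged. The
#' default threshold is mean + 2 sd of the score vector; studies often
#' pick per-signature thresholds by hand (e.g. 0.9 for a plasmablast-like
#' program), which the \code{threshold} argument accepts.
#'
#' @param scores per-cell score vector from \code{\link{score_signature}}
#' @param threshold numeric cutoff; \code{NULL} for mean + 2 sd
#' @param sample_ids per-cell sample labels (same order as scores);
#'   \code{NULL} yields a single pooled proportion
#' @return list with \code{threshold}, \code{cells} (character barcodes
#'   flagged), \code{proportions} (named per-sample fraction flagged).
#' @export
call_mp_cells <- function(scores, threshold = NULL, sample_ids = NULL) {
  assert_that(is.numeric(scores) && length(scores) > 0,
              "scores must be a nonempty numeric vector")
  if (is.null(threshold)) threshold <- mean(scores) + 2 * sd(scores)
  assert_that(!is.na(threshold), "threshold must not be NA")
  flag <- scores > threshold
  props <- if (is.null(sample_ids)) {
    c(all = mean(flag))
  } else {
    vapply(split(flag, sample_ids), mean, 0)
  }
  list(threshold = threshold,
       cells = names(scores)[flag],
       proportions = props)
}
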