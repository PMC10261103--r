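#' ABC/GCB signature gene sets
#'
#' @param abc_genes,gcb_genes disjoint, nonempty gene-id vectors marking
#'   the activated-B-cell-like and germinal-center-B-cell-like subtypes.
#'   Published marker lists are supplied by the user; the package ships a
#'   synthetic example pair for the bundled generator
#'   (\code{\link{sim_gene_sets}}).
#' @return A \code{coo_gene_sets}.
#' @export
coo_gene_sets <- function(abc_genes, gcb_genes) {
  assert_that(length(abc_genes) > 0 && length(gcb_genes) > 0,
              "both gene sets must be nonempty")
  assert_that(length(intersect(abc_genes, gcb_genes)) == 0,
              "ABC and GCB gene sets must be disjoint")
  structure(list(abc_genes = as.character(abc_genes),
                 gcb_genes = as.character(gcb_genes)),
            class = "coo_gene_sets")
}

#' Quantile-normalize cells to a common distribution
#'
#' Columns (cells) are mapped onto the mean order-statistic profile: each
#' cell's values are replaced by the across-cell mean of the sorted values
#' at the corresponding rank; tied values receive the average of the
#' reference values at the tied positions.
#'
#' @param x numeric matrix, genes x cells (>= 2 cells; a single cell is
#'   returned unchanged with a warning)
#' @return matrix of the same shape.
#' @export
quantile_normalize_cells <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    warning("single cell: quantile normalization is the identity")
    return(x)
  }
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    pos <- integer(nrow(x))
    pos[ord] <- seq_len(nrow(x))
    val <- ref[pos]
    # ties: average the reference values occupying the tied positions
    tied <- ave(val, x[, j], FUN = mean)
    out[, j] <- tied
  }
  dimnames(out) <- dimnames(x)
  out
}

#' Per-cell ABC/GCB cell-of-origin scores
#'
#' Four-step per-cell classifier on malignant cells: restrict the raw
#' counts to the signature genes, quantile-normalize cells, log2(x+1)
#' transform, z-score each gene across cells (sample sd, ddof = 1;
#' zero-variance genes get z = 0), then average the z-scores over the ABC
#' and over the GCB genes. The combined score is exactly
#' \code{abc_score - gcb_score}.
#'
#' @param m a \code{count_matrix} restricted to malignant cells
#'   (>= 2 cells)
#' @param sets a \code{\link{coo_gene_sets}}
#' @return data.frame (barcode, sample_id, abc_score, gcb_score,
#'   combined_score) of class \code{coo_call}.
#' @export
coo_scores <- function(m, sets) {
  stopifnot(inherits(m, "count_matrix"), inherits(sets, "coo_gene_sets"))
  assert_that(ncol(m$counts) >= 2, "need >= 2 malignant cells")
  sig <- c(sets$abc_genes, sets$gcb_genes)
  present <- sig[sig %in% m$gene_meta$gene_id]
  missing <- setdiff(sig, present)
  if (!any(sets$abc_genes %in% present) ||
      !any(sets$gcb_genes %in% present))
    stop("no signature genes present in matrix; missing: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  x <- as.matrix(m$counts[match(present, m$gene_meta$gene_id), ,
                          drop = FALSE])
  qn <- quantile_normalize_cells(x)
  lg <- log2(qn + 1)
  mu <- rowMeans(lg)
  s <- apply(lg, 1, sd)
  z <- (lg - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  abc <- colMeans(z[rownames(z) %in% sets$abc_genes, , drop = FALSE])
  gcb <- colMeans(z[rownames(z) %in% sets$gcb_genes, , drop = FALSE])
  out <- data.frame(barcode = m$cell_meta$barcode,
                    sample_id = m$cell_meta$sample_id,
                    abc_score = abc, gcb_score = gcb,
                    combined_score = abc - gcb,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("coo_call", "data.frame")
  out
}

#' Classify cells and samples from COO scores
#'
#' A cell is ABC when its combined score exceeds \code{combined_threshold}
#' and its GCB score is below \code{guard}; GCB when the combined score is
#' below \code{-combined_threshold} and its ABC score below \code{guard};
#' otherwise Unclassified. The per-sample dominant label is the modal
#' per-cell label.
#'
#' @param call a \code{coo_call} from \code{\link{coo_scores}}
#' @param combined_threshold default 0.25
#' @param guard score guard on the opposing subtype, default 0.75
#' @return the input with a \code{label} column plus attribute
#'   \code{"sample_labels"} (named character vector).
#' @export
coo_classify <- function(call, combined_threshold = 0.25, guard = 0.75) {
  stopifnot(inherits(call, "coo_call"))
  lab <- rep("Unclassified", nrow(call))
  lab[call$combined_score > combined_threshold &
        call$gcb_score < guard] <- "ABC"
  lab[call$combined_score < -combined_threshold &
        call$abc_score < guard] <- "GCB"
  call$label <- lab
  dom <- vapply(split(lab, call$sample_id), function(l) {
    names(sort(table(l), decreasing = TRUE))[1]
  }, "")
  attr(call, "sample_labels") <- dom
  call
}
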