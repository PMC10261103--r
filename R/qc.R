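#' Quality-control thresholds
#'
#' Defaults follow the standard droplet scRNA-seq recipe for this tissue:
#' genes kept when expressed (count > 0) in at least \code{min_cells_per_gene}
#' cells; cells kept when their expressed-gene count lies in
#' \code{genes_per_cell_range} (inclusive), their mitochondrial fraction is
#' strictly below \code{max_mito_fraction} and their total counts strictly
#' below \code{max_total_counts}.
#'
#' @param min_cells_per_gene integer, default 50
#' @param genes_per_cell_range inclusive integer interval, default c(500, 6000)
#' @param max_mito_fraction default 0.15 (exclusive upper bound)
#' @param max_total_counts default 50000 (exclusive upper bound)
#' @return A \code{qc_params}.
#' @export
qc_params <- function(min_cells_per_gene = 50L,
                      genes_per_cell_range = c(500L, 6000L),
                      max_mito_fraction = 0.15,
                      max_total_counts = 50000L) {
  assert_that(genes_per_cell_range[1] < genes_per_cell_range[2],
              "genes_per_cell_range must be an increasing interval")
  assert_that(max_mito_fraction >= 0 && max_mito_fraction <= 1,
              "max_mito_fraction must be in [0, 1]")
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 genes_per_cell_range = genes_per_cell_range,
                 max_mito_fraction = max_mito_fraction,
                 max_total_counts = max_total_counts),
            class = "qc_params")
}

#' Apply quality-control filters
#'
#' The gene filter (expressed in >= \code{min_cells_per_gene} cells,
#' evaluated on the raw matrix) is applied first; the three cell filters
#' are then evaluated jointly on the gene-filtered matrix, as a
#' conjunction, so their order is immaterial.
#'
#' @param m a \code{count_matrix} with mito flags set
#' @param p a \code{\link{qc_params}}
#' @return list with \code{filtered} (the surviving \code{count_matrix})
#'   and \code{report} (a data.frame of per-rule failure counts:
#'   \code{genes_min_cells}, \code{cells_low_genes},
#'   \code{cells_high_genes}, \code{cells_mito}, \code{cells_total_counts},
#'   \code{cells_removed}).
#' @export
apply_qc <- function(m, p = qc_params()) {
  stopifnot(inherits(m, "count_matrix"), inherits(p, "qc_params"))
  expressed <- m$counts > 0
  gene_keep <- Matrix::rowSums(expressed) >= p$min_cells_per_gene
  n_gene_rm <- sum(!gene_keep)
  mf <- subset_counts(m, genes = which(gene_keep))

  n_genes <- Matrix::colSums(mf$counts > 0)
  totals <- Matrix::colSums(mf$counts)
  mito_tot <- Matrix::colSums(mf$counts[mf$gene_meta$is_mito, , drop = FALSE])
  mito_frac <- ifelse(totals > 0, mito_tot / totals, 0)

  low <- n_genes < p$genes_per_cell_range[1]
  high <- n_genes > p$genes_per_cell_range[2]
  mito_bad <- mito_frac >= p$max_mito_fraction
  count_bad <- totals >= p$max_total_counts
  keep <- !(low | high | mito_bad | count_bad)

  report <- data.frame(
    rule = c("genes_min_cells", "cells_low_genes", "cells_high_genes",
             "cells_mito", "cells_total_counts", "cells_removed"),
    n = c(n_gene_rm, sum(low), sum(high), sum(mito_bad), sum(count_bad),
          sum(!keep)),
    stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("all cells removed by QC")
    return(list(filtered = subset_counts(mf, cells = integer(0)),
                report = report))
  }
  list(filtered = subset_counts(mf, cells = which(keep)), report = report)
}

#' Library-size normalization and log transform
#'
#' Each cell is scaled to \code{target_sum} total counts and the result
#' log1p-transformed: \code{value = log(1 + count * target_sum / total)}.
#' All-zero cells are left as zero columns.
#'
#' @param m a \code{count_matrix}
#' @param target_sum per-cell total after scaling, default 10000
#' @return A \code{normalized_matrix}: list with \code{values} (sparse
#'   genes x cells), \code{target_sum}, \code{gene_meta}, \code{cell_meta}.
#' @export
normalize_log <- function(m, target_sum = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  assert_that(ncol(m$counts) > 0, "empty matrix")
  totals <- Matrix::colSums(m$counts)
  sf <- ifelse(totals > 0, target_sum / totals, 0)
  v <- m$counts %*% Matrix::Diagonal(x = sf)
  v <- as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m$counts)
  structure(list(values = v, target_sum = target_sum,
                 gene_meta = m$gene_meta, cell_meta = m$cell_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (target_sum %g)\n",
              nrow(x$values), ncol(x$values), x$target_sum))
  invisible(x)
}
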