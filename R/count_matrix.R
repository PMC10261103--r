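#' Gene-by-cell count matrix with genomic and cell annotation
#'
#' The central container of the package: a sparse integer matrix of UMI
#' counts (genes in rows, cells in columns) together with per-gene genomic
#' annotation (chromosome, start coordinate, mitochondrial flag) and
#' per-cell metadata (barcode, sample of origin, optional labels).
#'
#' @param counts integer matrix or \code{Matrix::dgCMatrix}, genes x cells,
#'   nonnegative integers. Dimnames are taken from \code{gene_meta$gene_id}
#'   and \code{cell_meta$barcode}.
#' @param gene_meta data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start} and optionally \code{is_mito}; one row per matrix row.
#' @param cell_meta data.frame with columns \code{barcode}, \code{sample_id}
#'   (plus any extra labels); one row per matrix column.
#' @param mito_prefix gene-id prefix used to flag mitochondrial genes when
#'   \code{gene_meta$is_mito} is absent (default \code{"MT-"}).
#' @return An object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, gene_meta, cell_meta, mito_prefix = "MT-") {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  assert_that(all(counts@x >= 0), "counts must be nonnegative")
  assert_that(all(counts@x == round(counts@x)), "counts must be integers")
  assert_that(nrow(gene_meta) == nrow(counts),
              "gene_meta rows must match matrix rows")
  assert_that(nrow(cell_meta) == ncol(counts),
              "cell_meta rows must match matrix columns")
  assert_that(all(c("gene_id", "chromosome", "start") %in% names(gene_meta)),
              "gene_meta needs gene_id, chromosome, start")
  assert_that(all(c("barcode", "sample_id") %in% names(cell_meta)),
              "cell_meta needs barcode, sample_id")
  assert_that(!anyDuplicated(gene_meta$gene_id), "duplicate gene ids")
  assert_that(!anyDuplicated(cell_meta$barcode), "duplicate barcodes")
  if (is.null(gene_meta$is_mito)) {
    gene_meta$is_mito <- startsWith(gene_meta$gene_id, mito_prefix)
  }
  rownames(counts) <- gene_meta$gene_id
  colnames(counts) <- cell_meta$barcode
  rownames(gene_meta) <- NULL
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, gene_meta = gene_meta,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d samples)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id))))
  invisible(x)
}

#' Subset a count matrix by gene and/or cell
#'
#' @param x a \code{count_matrix}
#' @param genes,cells logical, integer or character index vectors (character
#'   indices match gene ids / barcodes); \code{NULL} keeps everything.
#' @return A \code{count_matrix} restricted to the selection.
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else {
    if (is.character(genes)) match(genes, x$gene_meta$gene_id) else genes
  }
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else {
    if (is.character(cells)) match(cells, x$cell_meta$barcode) else cells
  }
  if (is.numeric(gi)) assert_that(!anyNA(gi), "unknown gene ids in subset")
  if (is.numeric(ci)) assert_that(!anyNA(ci), "unknown barcodes in subset")
  count_matrix(x$counts[gi, ci, drop = FALSE],
               x$gene_meta[gi, , drop = FALSE],
               x$cell_meta[ci, , drop = FALSE])
}

#' Read a 10x-style MTX triplet into a count matrix
#'
#' Expects a MatrixMarket coordinate file of genes x cells, a features TSV
#' with columns (gene_id, chromosome, start) and a barcodes TSV with one
#' barcode per line. Inverse of \code{\link{write_counts}}.
#'
#' @param path_matrix path to the \code{.mtx} file
#' @param path_features path to the features TSV (no header)
#' @param path_barcodes path to the barcodes TSV (no header)
#' @param sample_id sample label to assign when the barcodes file has a
#'   single column; a second column, when present, is used instead.
#' @return A \code{count_matrix}.
#' @export
load_counts <- function(path_matrix, path_features, path_barcodes,
                        sample_id = "sample1") {
  m <- Matrix::readMM(path_matrix)
  if (any(m@x != round(m@x)))
    stop("non-integer entries in ", path_matrix, call. = FALSE)
  feats <- read.delim(path_features, header = FALSE,
                      stringsAsFactors = FALSE)
  if (ncol(feats) < 3L)
    stop("features file needs 3 columns (gene_id, chromosome, start): ",
         path_features, call. = FALSE)
  names(feats)[1:3] <- c("gene_id", "chromosome", "start")
  bcs <- read.delim(path_barcodes, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stop(sprintf("features file has %d lines but matrix has %d rows",
                 nrow(feats), nrow(m)), call. = FALSE)
  if (nrow(bcs) != ncol(m))
    stop(sprintf("barcodes file has %d lines but matrix has %d columns",
                 nrow(bcs), ncol(m)), call. = FALSE)
  dup <- feats$gene_id[duplicated(feats$gene_id)]
  if (length(dup))
    stop("duplicate gene ids in features file: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  cell_meta <- data.frame(
    barcode = bcs[[1]],
    sample_id = if (ncol(bcs) >= 2L) bcs[[2]] else sample_id,
    stringsAsFactors = FALSE)
  count_matrix(m, feats[, c("gene_id", "chromosome", "start")], cell_meta)
}

#' Write a count matrix as MTX plus TSV sidecars
#'
#' @param x a \code{count_matrix}
#' @param dir output directory (created if absent); writes
#'   \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}.
#' @return Invisibly, the directory.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write.table(x$gene_meta[, c("gene_id", "chromosome", "start")],
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(x$cell_meta[, c("barcode", "sample_id")],
              file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read gene sets from a two-column TSV
#'
#' Plain two-column format (set_name, gene_id), no header; returns a named
#' list of character vectors.
#' @param path TSV path
#' @return named list of gene-id vectors
#' @export
read_gene_sets <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(d) >= 2L, "gene-set file needs 2 columns")
  split(d[[2]], d[[1]])
}

#' Write gene sets to a two-column TSV
#' @param sets named list of gene-id vectors
#' @param path output TSV path
#' @export
write_gene_sets <- function(sets, path) {
  d <- data.frame(set = rep(names(sets), lengths(sets)),
                  gene = unlist(sets, use.names = FALSE))
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
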