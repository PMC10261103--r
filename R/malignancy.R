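#' Light-chain allelic-exclusion evidence of malignancy
#'
#' A B-cell clone expresses predominantly one immunoglobulin light chain.
#' For every cell the maximum normalized expression over the kappa genes
#' and over the lambda genes is taken, and the kappa fraction
#' \code{kappa_max / (kappa_max + lambda_max)} computed; cells with both
#' maxima zero are flagged missing and excluded from cluster medians. A
#' cluster is called kappa-restricted when its median fraction is at least
#' \code{kappa_threshold}, lambda-restricted when at most
#' \code{lambda_threshold}, otherwise balanced.
#'
#' @param nm a \code{normalized_matrix}
#' @param kappa_genes,lambda_genes nonempty gene-id vectors present in the
#'   matrix
#' @param clusters per-cell cluster labels (any vector coercible to factor)
#' @param kappa_threshold,lambda_threshold restriction thresholds,
#'   defaults 0.9 and 0.1
#' @return list with \code{cells} (data.frame barcode, kappa_max,
#'   lambda_max, kappa_fraction) and \code{clusters} (data.frame cluster,
#'   median_fraction, n_informative, restricted_label).
#' @export
allelic_exclusion <- function(nm, kappa_genes, lambda_genes, clusters,
                              kappa_threshold = 0.9,
                              lambda_threshold = 0.1) {
  stopifnot(inherits(nm, "normalized_matrix"))
  assert_that(length(kappa_genes) > 0 && length(lambda_genes) > 0,
              "both gene lists must be nonempty")
  ki <- match(kappa_genes, nm$gene_meta$gene_id)
  li <- match(lambda_genes, nm$gene_meta$gene_id)
  assert_that(!anyNA(ki) && !anyNA(li),
              "kappa/lambda genes missing from matrix")
  kmax <- apply(as.matrix(nm$values[ki, , drop = FALSE]), 2, max)
  lmax <- apply(as.matrix(nm$values[li, , drop = FALSE]), 2, max)
  denom <- kmax + lmax
  frac <- ifelse(denom > 0, kmax / denom, NA_real_)
  cells <- data.frame(barcode = nm$cell_meta$barcode,
                      kappa_max = kmax, lambda_max = lmax,
                      kappa_fraction = frac, stringsAsFactors = FALSE)
  cl <- factor(clusters)
  assert_that(length(cl) == ncol(nm$values),
              "clusters length must match cells")
  med <- tapply(frac, cl, median, na.rm = TRUE)
  ninf <- tapply(!is.na(frac), cl, sum)
  lab <- ifelse(is.na(med), "balanced",
                ifelse(med >= kappa_threshold, "kappa",
                       ifelse(med <= lambda_threshold, "lambda",
                              "balanced")))
  list(cells = cells,
       clusters = data.frame(cluster = levels(cl),
                             median_fraction = as.numeric(med),
                             n_informative = as.integer(ninf),
                             restricted_label = as.character(lab),
                             stringsAsFactors = FALSE))
}

#' Windowed expression-based copy-number profile
#'
#' A simplified re-implementation of expression-derived CNV inference:
#' per-gene expression relative to the mean over reference cells, smoothed
#' by a centered moving average over \code{window} genes within each
#' chromosome (shrinking at the edges), clipped to [-3, 3], then centered
#' per cell. Chromosomes with fewer than \code{window/4} genes are
#' excluded with a warning. Detects block gains/losses; it performs no HMM
#' state calling.
#'
#' @param nm a \code{normalized_matrix}
#' @param reference_cells barcodes (or column indices) of the reference
#'   population; at least 20 required
#' @param window moving-average width in genes, default 101
#' @return list with \code{profile} (cells x windows matrix, windows in
#'   genomic order), \code{windows} (data.frame chromosome,
#'   first_gene_start, last_gene_start, window_index, gene_id) and
#'   \code{reference_cells}.
#' @export
cnv_windowed <- function(nm, reference_cells, window = 101L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (is.character(reference_cells))
    reference_cells <- match(reference_cells, nm$cell_meta$barcode)
  assert_that(!anyNA(reference_cells) && length(reference_cells) >= 20,
              "need >= 20 reference cells present in the matrix")
  gm <- nm$gene_meta
  assert_that(all(c("chromosome", "start") %in% names(gm)),
              "gene_meta needs chromosome and start")
  ord <- order(gm$chromosome, gm$start, gm$gene_id)
  v <- as.matrix(nm$values[ord, , drop = FALSE])
  gm <- gm[ord, , drop = FALSE]
  chr_sizes <- table(gm$chromosome)
  small <- names(chr_sizes)[chr_sizes < window / 4]
  if (length(small)) {
    warning("excluding chromosomes with too few genes: ",
            paste(small, collapse = ", "))
    keep <- !(gm$chromosome %in% small)
    v <- v[keep, , drop = FALSE]
    gm <- gm[keep, , drop = FALSE]
  }
  rel <- v - rowMeans(v[, reference_cells, drop = FALSE])
  half <- (window - 1L) %/% 2L
  sm <- matrix(0, nrow(rel), ncol(rel))
  for (ch in unique(gm$chromosome)) {
    i <- which(gm$chromosome == ch)
    n <- length(i)
    cs <- rbind(0, apply(rel[i, , drop = FALSE], 2, cumsum))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sm[i, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  sm <- pmin(pmax(sm, -3), 3)
  prof <- t(sm)                 # cells x windows
  prof <- prof - rowMeans(prof) # per-cell centering

  colnames(prof) <- gm$gene_id
  rownames(prof) <- nm$cell_meta$barcode
  list(profile = prof,
       windows = data.frame(chromosome = gm$chromosome,
                            first_gene_start = pmax(gm$start, 0),
                            last_gene_start = gm$start,
                            window_index = seq_len(nrow(gm)),
                            gene_id = gm$gene_id,
                            stringsAsFactors = FALSE),
       reference_cells = nm$cell_meta$barcode[reference_cells])
}

#' Upper-tail hypergeometric overlap test
#'
#' Tests whether the overlap k between two subsets of a finite universe is
#' larger than expected: \code{p = P(X >= k)} for
#' \code{X ~ Hypergeometric(N, K, n)}, computed by exact tail summation in
#' log space (stable down to astronomically small p).
#'
#' @param universe character vector (or its size) of the universe
#' @param set_a,set_b subsets of the universe
#' @return list with \code{universe_size}, \code{size_a}, \code{size_b},
#'   \code{overlap}, \code{p_value}.
#' @export
hypergeometric_overlap <- function(universe, set_a, set_b) {
  if (length(universe) == 1L && is.numeric(universe)) {
    stop("pass the universe as a vector of ids")
  }
  assert_that(length(universe) > 0, "empty universe")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  assert_that(all(set_a %in% universe) && all(set_b %in% universe),
              "sets must be subsets of the universe")
  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  kmax <- min(K, n)
  lp <- stats::dhyper(k:kmax, K, N - K, n, log = TRUE)
  p <- exp(logsumexp(lp))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(universe_size = N, size_a = K, size_b = n, overlap = k, p_value = p)
}
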