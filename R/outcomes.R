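#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene, a two-sided Mann-Whitney test using the normal approximation
#' with tie-corrected variance and 0.5 continuity correction (matching
#' \code{wilcox.test(exact = FALSE, correct = TRUE)}), Benjamini-Hochberg
#' adjustment over tested genes, and a fold change computed on de-logged
#' means: \code{(mean(expm1 a) + eps) / (mean(expm1 b) + eps)} with
#' \code{eps = 1e-9}. A gene passes when its adjusted p is at most
#' \code{adj_p} and its fold change at least \code{min_fc}.
#'
#' @param nm a \code{normalized_matrix} (or any log1p-scale expression
#'   layer, e.g. normalized spliced/unspliced counts)
#' @param group_a,group_b barcodes or column indices of the two groups
#'   (>= 3 cells each)
#' @param adj_p adjusted-p threshold, default 0.01
#' @param min_fc fold-change threshold, default 1.5
#' @return data.frame (gene_id, log2_fc, fold_change, p_value, adj_p,
#'   pass) ordered as the input genes.
#' @export
deg_wilcoxon <- function(nm, group_a, group_b, adj_p = 0.01,
                         min_fc = 1.5) {
  stopifnot(inherits(nm, "normalized_matrix"))
  to_idx <- function(g) {
    if (is.character(g)) match(g, nm$cell_meta$barcode) else g
  }
  a <- to_idx(group_a); b <- to_idx(group_b)
  assert_that(!anyNA(a) && !anyNA(b), "unknown barcodes in groups")
  assert_that(length(a) >= 3 && length(b) >= 3,
              "both groups need >= 3 cells")
  xa <- as.matrix(nm$values[, a, drop = FALSE])
  xb <- as.matrix(nm$values[, b, drop = FALSE])
  n1 <- ncol(xa); n2 <- ncol(xb); n <- n1 + n2
  xx <- cbind(xa, xb)
  p <- numeric(nrow(xx))
  for (g in seq_len(nrow(xx))) {
    r <- rank(xx[g, ])
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(xx[g, ])
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (v <= 0) { p[g] <- 1; next }
    z <- u - n1 * n2 / 2
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(v)
    p[g] <- 2 * pnorm(-abs(z))
  }
  eps <- 1e-9
  fc <- (rowMeans(expm1(xa)) + eps) / (rowMeans(expm1(xb)) + eps)
  padj <- p.adjust(p, method = "BH")
  data.frame(gene_id = nm$gene_meta$gene_id,
             log2_fc = log2(fc), fold_change = fc,
             p_value = p, adj_p = padj,
             pass = padj <= adj_p & fc >= min_fc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exhaustion signature scores with pairwise group comparisons
#'
#' Scores every cell with the binned-control signature score for an
#' exhaustion gene set (inhibitory-receptor markers, user-supplied) and
#' compares groups pairwise by two-sided Wilcoxon rank-sum tests. Groups
#' with fewer than 3 cells are excluded with a warning.
#'
#' @param nm a \code{normalized_matrix}
#' @param exhaustion_set character vector of gene ids
#' @param groups per-cell group labels
#' @param ... passed to \code{\link{score_signature}}
#' @return list with \code{scores} (per-cell vector), \code{groups},
#'   \code{pairwise} (data.frame group_a, group_b, p_value; NULL when a
#'   single group is supplied).
#' @export
exhaustion_scores <- function(nm, exhaustion_set, groups, ...) {
  sc <- score_signature(nm, exhaustion_set,
                        signature_name = "exhaustion", ...)
  tab <- table(groups)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("excluding groups with < 3 cells: ",
            paste(small, collapse = ", "))
  }
  keep <- setdiff(names(tab), small)
  pw <- NULL
  if (length(keep) >= 2) {
    combs <- utils::combn(keep, 2)
    pw <- data.frame(group_a = combs[1, ], group_b = combs[2, ],
                     p_value = apply(combs, 2, function(gp) {
                       wilcox.test(sc[groups == gp[1]],
                                   sc[groups == gp[2]],
                                   exact = FALSE)$p.value
                     }), stringsAsFactors = FALSE)
  }
  list(scores = sc, groups = groups, pairwise = pw)
}
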