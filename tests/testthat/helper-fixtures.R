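# Shared fixtures and independent oracles for the test suite.

# Build a normalized_matrix directly from a dense matrix (unit-test shim).
make_nm <- function(values, gene_ids = NULL, barcodes = NULL,
                    chromosome = NULL, start = NULL, sample_id = "S1") {
  values <- as.matrix(values)
  g <- nrow(values); n <- ncol(values)
  gene_ids <- gene_ids %||% sprintf("g%03d", seq_len(g))
  barcodes <- barcodes %||% sprintf("c%03d", seq_len(n))
  gm <- data.frame(gene_id = gene_ids,
                   chromosome = chromosome %||% rep("1", g),
                   start = start %||% seq_len(g) * 1000L,
                   is_mito = startsWith(gene_ids, "MT-"),
                   stringsAsFactors = FALSE)
  cm <- data.frame(barcode = barcodes,
                   sample_id = rep(sample_id, length.out = n),
                   stringsAsFactors = FALSE)
  dimnames(values) <- list(gene_ids, barcodes)
  structure(list(values = Matrix::Matrix(values, sparse = TRUE),
                 target_sum = NA_real_, gene_meta = gm, cell_meta = cm),
            class = "normalized_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adjusted Rand index (closed form over the contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  sa <- sum(ch2(rowSums(tab)))
  sb <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- sa * sb / n
  (sij - exp_idx) / ((sa + sb) / 2 - exp_idx)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Straight-line oracle for the four-step cell-of-origin pipeline:
# quantile-normalize cells -> log2(x+1) -> per-gene z (ddof 1) -> mean z.
coo_oracle <- function(counts, abc_genes, gcb_genes) {
  x <- as.matrix(counts)
  n <- ncol(x)
  sorted <- apply(x, 2, sort)
  ref <- rowMeans(sorted)
  qn <- x
  for (j in seq_len(n)) {
    ord <- order(x[, j])
    val <- numeric(nrow(x))
    val[ord] <- ref
    for (u in unique(x[, j])) {
      idx <- which(x[, j] == u)
      val[idx] <- mean(val[idx])
    }
    qn[, j] <- val
  }
  lg <- log2(qn + 1)
  z <- lg
  for (g in seq_len(nrow(lg))) {
    s <- sd(lg[g, ])
    z[g, ] <- if (is.na(s) || s == 0) 0 else (lg[g, ] - mean(lg[g, ])) / s
  }
  abc <- colMeans(z[rownames(x) %in% abc_genes, , drop = FALSE])
  gcb <- colMeans(z[rownames(x) %in% gcb_genes, , drop = FALSE])
  list(abc = abc, gcb = gcb, combined = abc - gcb)
}

# Two-pass oracle of the binned-control signature score, written as plain
# loops over the documented procedure (same seeding contract).
score_oracle <- function(nm, gene_set, n_bins, ctrl_per_gene, seed) {
  v <- as.matrix(nm$values)
  genes <- nm$gene_meta$gene_id
  rownames(v) <- genes
  mu <- rowMeans(v)
  bin <- ceiling(rank(mu, ties.method = "first") / length(mu) * n_bins)
  names(bin) <- genes
  present <- gene_set[gene_set %in% genes]
  set.seed(seed)
  ctrl <- character(0)
  for (g in present) {
    cand <- genes[bin == bin[[g]]]
    cand <- setdiff(cand, gene_set)
    if (!length(cand)) next
    ctrl <- c(ctrl, sample(cand, min(ctrl_per_gene, length(cand))))
  }
  ctrl <- unique(ctrl)
  sig <- colMeans(v[present, , drop = FALSE])
  cm <- if (length(ctrl)) colMeans(v[ctrl, , drop = FALSE]) else 0
  sig - cm
}

# Exhaustive hypergeometric tail by enumerating every size-n draw.
hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_a <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% in_a) >= k)
  mean(hits)
}

# Small cohort configuration reused across tests (cheap but nontrivial).
small_cfg <- function(seed = 11, ...) {
  sclymph::sim_config(
    seed = seed, n_samples = 2, genes = 500,
    cells_per_sample = c(malignant = 60, nonmalignant_B = 30, cd8_T = 30),
    ...)
}
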