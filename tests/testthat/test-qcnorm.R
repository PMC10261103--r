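test_that("MTX round trip is an exact identity", {
  dir <- withr::local_tempdir()
  ch <- generate_cohort(small_cfg(seed = 1))
  write_counts(ch$counts, dir)
  m <- load_counts(file.path(dir, "matrix.mtx"),
                   file.path(dir, "features.tsv"),
                   file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(m$counts), as.matrix(ch$counts$counts))
  expect_equal(m$gene_meta$gene_id, ch$counts$gene_meta$gene_id)
  expect_equal(m$cell_meta$barcode, ch$counts$cell_meta$barcode)
})

test_that("a hand-written coordinate MTX is read densely as expected", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 2"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA\t1\t100", "gB\t1\t200", "gC\t1\t300"),
             file.path(dir, "features.tsv"))
  writeLines(c("bc1", "bc2"), file.path(dir, "barcodes.tsv"))
  m <- load_counts(file.path(dir, "matrix.mtx"),
                   file.path(dir, "features.tsv"),
                   file.path(dir, "barcodes.tsv"))
  expect_equal(unname(as.matrix(m$counts)),
               matrix(c(5, 0, 0, 0, 0, 2), 3, 2))
})

test_that("sidecar dimension mismatches raise format errors", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "1 1 5"), file.path(dir, "matrix.mtx"))
  writeLines(c("gA\t1\t1", "gB\t1\t2", "gC\t1\t3"),
             file.path(dir, "features.tsv"))
  writeLines(c("bc1", "bc2", "bc3"), file.path(dir, "barcodes.tsv"))
  expect_error(load_counts(file.path(dir, "matrix.mtx"),
                           file.path(dir, "features.tsv"),
                           file.path(dir, "barcodes.tsv")),
               "barcodes file has 3 lines")
  writeLines(c("bc1", "bc2"), file.path(dir, "barcodes.tsv"))
  writeLines(c("gA\t1\t1", "gA\t1\t2", "gC\t1\t3"),
             file.path(dir, "features.tsv"))
  expect_error(load_counts(file.path(dir, "matrix.mtx"),
                           file.path(dir, "features.tsv"),
                           file.path(dir, "barcodes.tsv")),
               "duplicate gene ids")
})

test_that("QC removes rule violators with the default thresholds", {
  # 60 cells x 700 genes: cell 1 expresses 450 genes, cell 2 has 20% mito
  set.seed(42)
  g <- 700; n <- 60
  ids <- c(sprintf("MT-%d", 1:10), sprintf("g%03d", 1:(g - 10)))
  x <- matrix(rpois(g * n, 5), g, n)
  x[, 1] <- 0
  x[11:460, 1] <- 1                     # 450 expressed genes
  tot2 <- sum(x[11:g, 2])
  x[1:10, 2] <- ceiling(0.25 * tot2 / 10)  # mito fraction >= 0.2
  m <- count_matrix(x, data.frame(gene_id = ids, chromosome = "1",
                                  start = seq_len(g)),
                    data.frame(barcode = sprintf("c%02d", 1:n),
                               sample_id = "S1"))
  res <- apply_qc(m, qc_params(min_cells_per_gene = 1))
  kept <- res$filtered$cell_meta$barcode
  expect_false("c01" %in% kept)   # gene-count rule, 450 < 500
  expect_false("c02" %in% kept)   # mito rule, 0.2 >= 0.15
  expect_equal(res$report$n[res$report$rule == "cells_low_genes"], 1)
  expect_equal(res$report$n[res$report$rule == "cells_mito"], 1)
})

test_that("QC report equals brute-force enumeration on a violator fixture", {
  cfg <- sim_config(seed = 13, n_samples = 2, genes = 1200,
                    cells_per_sample = c(malignant = 80,
                                         nonmalignant_B = 30, cd8_T = 30),
                    qc_violators = 3)
  ch <- generate_cohort(cfg)
  res <- apply_qc(ch$counts)
  # independent pass over the raw matrix
  x <- as.matrix(ch$counts$counts)
  p <- qc_params()
  gene_keep <- rowSums(x > 0) >= p$min_cells_per_gene
  xf <- x[gene_keep, , drop = FALSE]
  mito <- ch$counts$gene_meta$is_mito[gene_keep]
  ng <- colSums(xf > 0); tot <- colSums(xf)
  mf <- colSums(xf[mito, , drop = FALSE]) / pmax(tot, 1)
  expect_equal(res$report$n,
               c(sum(!gene_keep),
                 sum(ng < 500), sum(ng > 6000),
                 sum(mf >= 0.15), sum(tot >= 50000),
                 sum(ng < 500 | ng > 6000 | mf >= 0.15 | tot >= 50000)))
  # the planted violators are among the removed cells
  removed <- setdiff(ch$counts$cell_meta$barcode,
                     res$filtered$cell_meta$barcode)
  expect_true(all(ch$truth$qc_violators$barcode %in% removed))
})

test_that("normalization matches its closed form and invariances", {
  x <- matrix(0, 3, 3)
  x[, 1] <- c(10, 40, 50)             # total 100
  x[, 3] <- c(2, 4, 6)
  m <- count_matrix(x, data.frame(gene_id = c("a", "b", "c"),
                                  chromosome = "1", start = 1:3),
                    data.frame(barcode = c("x", "y", "z"),
                               sample_id = "S"))
  nm <- normalize_log(m)
  expect_equal(nm$values[1, 1], log(1 + 10 * 1e4 / 100))
  expect_equal(as.numeric(nm$values[, 2]), c(0, 0, 0))  # all-zero cell
  # scale invariance: doubling a cell's counts leaves its column unchanged
  x2 <- x; x2[, 3] <- x2[, 3] * 2
  m2 <- count_matrix(x2, m$gene_meta, m$cell_meta)
  expect_equal(as.numeric(normalize_log(m2)$values[, 3]),
               as.numeric(nm$values[, 3]))
  # permuting cells permutes output columns identically
  perm <- c(3, 1, 2)
  mp <- subset_counts(m, cells = perm)
  expect_equal(as.matrix(normalize_log(mp)$values),
               as.matrix(nm$values[, perm]))
})

test_that("clustering recovers well-separated populations", {
  set.seed(7)
  g <- 320; per <- 50
  base <- matrix(rpois(g * 3 * per, 3), g, 3 * per)
  for (k in 1:3) {                       # disjoint 100-gene upshifts
    rows <- ((k - 1) * 100 + 1):(k * 100)
    cols <- ((k - 1) * per + 1):(k * per)
    base[rows, cols] <- rpois(length(rows) * per, 3 * exp(2))
  }
  m <- count_matrix(base,
                    data.frame(gene_id = sprintf("g%03d", 1:g),
                               chromosome = "1", start = 1:g),
                    data.frame(barcode = sprintf("c%03d", 1:(3 * per)),
                               sample_id = "S"))
  nm <- normalize_log(m)
  emb <- embed_and_cluster(nm, n_hvg = 300, n_pcs = 10, seed = 5)
  truth <- rep(1:3, each = per)
  expect_equal(length(unique(emb$cluster_labels)), 3L)
  expect_gt(ari(emb$cluster_labels, truth), 0.95)
  # determinism under the same seed
  emb2 <- embed_and_cluster(nm, n_hvg = 300, n_pcs = 10, seed = 5)
  expect_identical(emb$cluster_labels, emb2$cluster_labels)
})

test_that("identical cells collapse to a single cluster", {
  x <- matrix(rep(c(5, 1, 3, 0, 2), 30), 5, 30)
  m <- count_matrix(x, data.frame(gene_id = letters[1:5],
                                  chromosome = "1", start = 1:5),
                    data.frame(barcode = sprintf("c%02d", 1:30),
                               sample_id = "S"))
  nm <- normalize_log(m)
  suppressWarnings(
    emb <- embed_and_cluster(nm, n_hvg = 5, n_pcs = 3, seed = 1))
  expect_equal(length(unique(emb$cluster_labels)), 1L)
})
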