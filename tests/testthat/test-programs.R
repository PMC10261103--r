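test_that("NMF recovers an exact low-rank nonnegative factorization", {
  set.seed(9)
  w <- matrix(0, 40, 2)
  w[1:20, 1] <- runif(20, 1, 2)        # distinct supports
  w[21:40, 2] <- runif(20, 1, 2)
  h <- matrix(runif(2 * 60, 0, 3), 2, 60)
  x <- w %*% h
  fit <- nmf_factorize(x, 2, max_iter = 2000, tol = 1e-12, seed = 4)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- sapply(1:2, function(i) sapply(1:2, function(j)
    cosine(w[, i], fit$w[, j])))
  best <- max(sims[1, 1] + sims[2, 2], sims[1, 2] + sims[2, 1]) / 2
  expect_gt(best, 0.99)
  expect_lt(fit$objective / sum(x^2), 1e-6)
})

test_that("rank-1 consensus recovers the dominant factor", {
  set.seed(10)
  w <- runif(30, 0.5, 2)
  h <- runif(25, 0.1, 1)
  nm <- make_nm(outer(w, h), sample_id = "S1")
  mods <- nmf_consensus_sample(nm, k = 1, n_restarts = 4, n_hvg = 30,
                               seed = 2)
  expect_length(mods, 1L)
  sp <- mods[[1]]$spectra
  cosine <- sum(sp * w[match(names(sp), sprintf("g%03d", 1:30))]) /
    sqrt(sum(sp^2) * sum(w^2))
  expect_gt(cosine, 0.99)
  expect_equal(sqrt(sum(sp^2)), 1)          # unit L2 spectra
  expect_true(all(sp >= 0) && all(mods[[1]]$usage >= -1e-12))
})

test_that("consensus NMF is deterministic under a fixed seed", {
  set.seed(11)
  x <- matrix(rpois(50 * 80, 3), 50, 80)
  nm <- make_nm(log1p(x), sample_id = "S1")
  a <- nmf_consensus_sample(nm, k = 3, n_restarts = 5, n_hvg = 50, seed = 7)
  b <- nmf_consensus_sample(nm, k = 3, n_restarts = 5, n_hvg = 50, seed = 7)
  expect_identical(lapply(a, `[[`, "spectra"),
                   lapply(b, `[[`, "spectra"))
})

# hand-made program modules with controlled correlation structure
fake_module <- function(sample, top, genes, seed, noise = 0.05) {
  set.seed(seed)
  w <- setNames(abs(rnorm(length(genes), 0, noise)), genes)
  w[top] <- w[top] + 1
  w <- w / sqrt(sum(w^2))
  structure(list(sample_id = sample, spectra = w,
                 usage = setNames(numeric(0), character(0)), rank_k = 2L),
            class = "program_module")
}

test_that("meta-programs keep recurrent clusters and drop the rest", {
  genes <- sprintf("g%03d", 1:120)
  shared_top <- genes[1:20]
  three_top <- genes[41:60]
  mods <- c(
    lapply(1:5, function(s) fake_module(sprintf("S%02d", s), shared_top,
                                        genes, seed = 100 + s)),
    lapply(1:3, function(s) fake_module(sprintf("S%02d", s), three_top,
                                        genes, seed = 200 + s)),
    # sample-private noise modules, mutually unrelated
    lapply(1:5, function(s) fake_module(sprintf("S%02d", s),
                                        genes[60 + s * 10 + 1:8],
                                        genes, seed = 300 + s)))
  mps <- build_metaprograms(mods, min_recurrence = 4, top_n_genes = 20)
  expect_length(mps, 1L)
  expect_equal(mps[[1]]$recurrence, 5L)
  expect_gte(jaccard(mps[[1]]$gene_list, shared_top), 0.6)
  # the 3-sample cluster was dropped by the recurrence rule
  expect_false(any(vapply(mps, function(m)
    jaccard(m$gene_list, three_top) > 0.5, TRUE)))
  # mutually orthogonal modules produce no meta-programs
  ortho <- lapply(1:6, function(s) {
    w <- setNames(numeric(120), genes)
    w[(s - 1) * 20 + 1:20] <- 1
    structure(list(sample_id = sprintf("S%02d", s),
                   spectra = w / sqrt(sum(w^2)),
                   usage = numeric(0), rank_k = 1L),
              class = "program_module")
  })
  expect_length(build_metaprograms(ortho, min_recurrence = 4), 0L)
  expect_length(build_metaprograms(mods[1]), 0L)   # single module
})

test_that("signature scores vanish on constant matrices", {
  nm <- make_nm(matrix(3, 60, 15))
  sc <- score_signature(nm, sprintf("g%03d", 1:5), n_bins = 10,
                        ctrl_per_gene = 10, seed = 1)
  expect_equal(as.numeric(sc), rep(0, 15))
})

test_that("signature scores equal the two-pass oracle under a seed", {
  set.seed(12)
  nm <- make_nm(matrix(rpois(30 * 10, 5), 30, 10))
  set_genes <- sprintf("g%03d", c(2, 9, 17, 25))
  sc <- score_signature(nm, set_genes, n_bins = 5, ctrl_per_gene = 4,
                        seed = 99)
  orc <- score_oracle(nm, set_genes, n_bins = 5, ctrl_per_gene = 4,
                      seed = 99)
  expect_equal(as.numeric(sc), as.numeric(orc), tolerance = 1e-12)
})

test_that("signature scores track a planted shift", {
  set.seed(13)
  g <- 200; n <- 100
  base <- matrix(2, g, n)
  active <- 1:50
  set_genes <- sprintf("g%03d", 1:10)
  delta <- 1.5
  base[1:10, active] <- 2 + delta
  nm <- make_nm(base)
  sc <- score_signature(nm, set_genes, n_bins = 10, ctrl_per_gene = 20,
                        seed = 3)
  expect_equal(as.numeric(sc[active]), rep(delta, 50), tolerance = 1e-9)
  expect_equal(as.numeric(sc[-active]), rep(0, 50), tolerance = 1e-9)
  # translation equivariance: shifting the set genes shifts the score
  base2 <- base
  base2[1:10, ] <- base2[1:10, ] + 0.7
  sc2 <- score_signature(make_nm(base2), set_genes, n_bins = 10,
                         ctrl_per_gene = 20, seed = 3)
  expect_equal(as.numeric(sc2 - sc), rep(0.7, n), tolerance = 1e-9)
})

test_that("MP cell calling applies thresholds and proportions", {
  scores <- setNames(c(rep(1.2, 3), rep(0.1, 17)), sprintf("c%02d", 1:20))
  res <- call_mp_cells(scores, threshold = 0.9)
  expect_equal(unname(res$proportions["all"]), 0.15)
  expect_equal(length(res$cells), 3L)
  res_inf <- call_mp_cells(scores, threshold = Inf)
  expect_equal(length(res_inf$cells), 0L)
  expect_equal(unname(res_inf$proportions["all"]), 0)
  # per-sample proportions
  res_s <- call_mp_cells(scores, threshold = 0.9,
                         sample_ids = rep(c("A", "B"), each = 10))
  expect_equal(unname(res_s$proportions), c(0.3, 0))
})

test_that("DEPTH2 matches hand computation and invariances", {
  pb <- rbind(g1 = c(1, 3), g2 = c(2, 2))
  expect_equal(unname(depth2(pb)), c(0.5, 0.5), tolerance = 1e-12)
  # identical samples give zero
  expect_equal(unname(depth2(cbind(c(1, 5), c(1, 5)))), c(0, 0))
  # per-gene affine maps a_g + b x leave scores unchanged
  set.seed(14)
  pb2 <- matrix(runif(40), 10, 4)
  a <- runif(10); b <- 2.5
  expect_equal(depth2(pb2), depth2(a + b * pb2), tolerance = 1e-12)
})

test_that("Hill diversity profiles match closed forms", {
  p <- c(0.5, 0.25, 0.25)
  d <- hill_diversity(p, c(0, 1, 2))
  expect_equal(unname(d["q0"]), 3)
  expect_equal(unname(d["q1"]), exp(-sum(p * log(p))), tolerance = 1e-12)
  expect_equal(unname(d["q1"]), 2.8284, tolerance = 1e-4)
  expect_equal(unname(d["q2"]), 1 / sum(p^2), tolerance = 1e-12)
  expect_equal(unname(d["q2"]), 2.6667, tolerance = 1e-4)
  # uniform over K clusters gives K at every order
  expect_equal(unname(hill_diversity(rep(1 / 7, 7), c(0, 0.5, 1, 2, 4))),
               rep(7, 5), tolerance = 1e-12)
  expect_equal(unname(hill_diversity(1, c(0, 1, 2))), rep(1, 3))
  # monotone non-increasing in q on random simplex draws
  set.seed(15)
  qs <- c(0, 0.5, 1, 1.5, 2, 3, 5)
  for (i in 1:200) {
    p <- rexp(sample(2:12, 1)); p <- p / sum(p)
    d <- hill_diversity(p, qs)
    expect_true(all(diff(d) <= 1e-9))
  }
  expect_error(hill_diversity(numeric(0)), "empty")
})
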