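#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius objective \code{||X - W H||_F} over nonnegative
#' factors with Lee-Seung multiplicative updates from a seeded uniform
#' initialization.
#'
#' @param x nonnegative matrix, genes x cells
#' @param k factorization rank
#' @param max_iter iteration budget, default 400
#' @param tol relative objective change declaring convergence
#' @param seed RNG seed for the initialization
#' @return list with \code{w} (genes x k), \code{h} (k x cells),
#'   \code{converged}, \code{objective}.
#' @export
nmf_factorize <- function(x, k, max_iter = 400L, tol = 1e-6, seed = 1L) {
  x <- as.matrix(x)
  assert_that(all(x >= 0), "matrix must be nonnegative")
  set.seed(seed)
  eps <- 1e-10
  w <- matrix(runif(nrow(x) * k, 0.1, 1), nrow(x), k)
  h <- matrix(runif(k * ncol(x), 0.1, 1), k, ncol(x))
  obj_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, x) / (crossprod(w, w %*% h) + eps))
    w <- w * (tcrossprod(x, h) / (w %*% tcrossprod(h) + eps))
    if (it %% 10L == 0L) {
      obj <- sum((x - w %*% h)^2)
      if (is.finite(obj_prev) && abs(obj_prev - obj) <=
          tol * max(obj_prev, eps)) {
        converged <- TRUE
        obj_prev <- obj
        break
      }
      obj_prev <- obj
    }
  }
  list(w = w, h = h, converged = converged,
       objective = sum((x - w %*% h)^2))
}

# Lawson-Hanson style nonnegative least squares for small k:
# min ||a - B z||, z >= 0, solved per column by active-set iteration
nnls_solve <- function(B, a, max_iter = 200L) {
  k <- ncol(B)
  passive <- logical(k)
  z <- numeric(k)
  BtB <- crossprod(B)
  Bta <- crossprod(B, a)
  for (it in seq_len(max_iter)) {
    w <- Bta - BtB %*% z
    cand <- which(!passive & w > 1e-10)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      zp <- numeric(k)
      idx <- which(passive)
      zp[idx] <- solve(BtB[idx, idx, drop = FALSE] +
                         diag(1e-12, length(idx)),
                       Bta[idx])
      if (all(zp[idx] > 0)) { z <- zp; break }
      neg <- idx[zp[idx] <= 0]
      alpha <- min(z[neg] / (z[neg] - zp[neg]))
      z <- z + alpha * (zp - z)
      passive[idx][zp[idx] <= 1e-12 & z[idx] <= 1e-12] <- FALSE
      z[!passive] <- 0
    }
  }
  z
}

l2norm <- function(m) {
  n <- sqrt(colSums(m^2))
  sweep(m, 2, ifelse(n > 0, n, 1), "/")
}

#' Consensus NMF programs for one sample
#'
#' Runs \code{n_restarts} seeded NMF factorizations of the nonnegative
#' highly-variable-gene submatrix of one sample's malignant cells, pools
#' and L2-normalizes all spectra, removes density outliers (spectra whose
#' mean distance to their nearest neighbors falls in the top
#' \code{density_quantile} tail), clusters the survivors into k groups
#' (seeded k-means), takes the componentwise median per cluster as the
#' consensus spectrum, renormalizes, and refits cell usages by
#' nonnegative least squares.
#'
#' @param nm a \code{normalized_matrix} holding one sample's malignant
#'   cells
#' @param k number of programs (>= 1; cells must number >= 10 k for k >= 2)
#' @param n_restarts NMF restarts, default 50
#' @param density_quantile fraction of pooled spectra discarded as density
#'   outliers, default 0.25
#' @param n_hvg HVGs used for the factorization, default 2000
#' @param seed master seed; restart r uses a derived child seed
#' @return list of program modules, each with \code{sample_id},
#'   \code{spectra} (named nonnegative unit-L2 gene weights),
#'   \code{usage} (named per-cell weights) and \code{rank_k}.
#' @export
nmf_consensus_sample <- function(nm, k, n_restarts = 50L,
                                 density_quantile = 0.25,
                                 n_hvg = 2000L, seed = 1L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  assert_that(k >= 1, "k must be >= 1")
  if (k >= 2)
    assert_that(ncol(nm$values) >= 10 * k, "need >= 10k cells")
  sample_id <- unique(nm$cell_meta$sample_id)
  assert_that(length(sample_id) == 1L,
              "nmf_consensus_sample expects a single sample")
  hvg <- select_hvgs(nm, n_hvg)
  x <- as.matrix(nm$values[match(hvg, nm$gene_meta$gene_id), ,
                           drop = FALSE])
  keep <- rowSums(x) > 0
  x <- x[keep, , drop = FALSE]
  spectra <- list()
  for (r in seq_len(n_restarts)) {
    fit <- nmf_factorize(x, k, seed = child_seed(seed, paste0("nmf", r)))
    if (!all(is.finite(fit$w))) {
      warning("dropping non-convergent restart ", r)
      next
    }
    spectra[[length(spectra) + 1L]] <- l2norm(fit$w)
  }
  assert_that(length(spectra) > 0, "all NMF restarts failed")
  pool <- do.call(cbind, spectra)          # genes x (restarts*k)
  if (ncol(pool) > k) {
    d <- as.matrix(dist(t(pool)))
    diag(d) <- Inf
    nn <- max(1L, min(k, ncol(pool) - 1L))
    mean_nn <- apply(d, 1, function(r) mean(sort(r)[seq_len(nn)]))
    cutoff <- quantile(mean_nn, 1 - density_quantile)
    pool <- pool[, mean_nn <= cutoff, drop = FALSE]
  }
  set.seed(child_seed(seed, "kmeans"))
  cl <- if (ncol(pool) > k) {
    kmeans(t(pool), centers = k, nstart = 10, iter.max = 100)$cluster
  } else seq_len(ncol(pool))
  w_cons <- vapply(seq_len(k), function(g) {
    cols <- which(cl == g)
    if (!length(cols)) return(rep(0, nrow(pool)))
    apply(pool[, cols, drop = FALSE], 1, median)
  }, numeric(nrow(pool)))
  w_cons <- l2norm(w_cons)
  h <- apply(x, 2, function(a) nnls_solve(w_cons, a))
  if (k == 1L) h <- matrix(h, nrow = 1L)
  lapply(seq_len(k), function(g) {
    structure(list(sample_id = sample_id,
                   spectra = setNames(w_cons[, g], rownames(x)),
                   usage = setNames(h[g, ], nm$cell_meta$barcode),
                   rank_k = k),
              class = "program_module")
  })
}

#' Cross-sample consensus meta-programs
#'
#' Correlates all per-sample program spectra over the union gene space
#' (genes absent from a module weighted 0), hierarchically clusters the
#' modules on distance 1 - Pearson r (average linkage), cuts the tree at
#' \code{cut_height} and keeps clusters recurring in at least
#' \code{min_recurrence} distinct samples. Each retained meta-program's
#' gene list is the \code{top_n_genes} genes with the best mean
#' within-module weight rank across members.
#'
#' @param modules list of program modules from
#'   \code{\link{nmf_consensus_sample}} (>= 2)
#' @param min_recurrence minimum number of distinct samples, default 4
#' @param top_n_genes genes per meta-program list, default 50
#' @param cut_height tree cut on 1 - r, default 0.7
#' @return list of meta-programs (possibly empty), each with \code{mp_id},
#'   \code{member_samples}, \code{member_index}, \code{recurrence},
#'   \code{gene_list}.
#' @export
build_metaprograms <- function(modules, min_recurrence = 4L,
                               top_n_genes = 50L, cut_height = 0.7) {
  if (length(modules) < 2L) return(list())
  genes <- sort(unique(unlist(lapply(modules, function(m)
    names(m$spectra)))))
  S <- vapply(modules, function(m) {
    v <- setNames(numeric(length(genes)), genes)
    v[names(m$spectra)] <- m$spectra
    v
  }, numeric(length(genes)))
  r <- suppressWarnings(cor(S))
  r[is.na(r)] <- 0
  d <- as.dist(1 - r)
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = cut_height)
  samples <- vapply(modules, `[[`, "", "sample_id")
  mps <- list()
  for (g in sort(unique(cl))) {
    idx <- which(cl == g)
    rec <- length(unique(samples[idx]))
    if (rec < min_recurrence) next
    # mean rank of each gene's weight across member modules (1 = heaviest)
    rk <- vapply(idx, function(i) rank(-S[, i], ties.method = "average"),
                 numeric(length(genes)))
    mean_rk <- rowMeans(rk)
    top <- genes[order(mean_rk)][seq_len(min(top_n_genes, length(genes)))]
    mps[[length(mps) + 1L]] <- structure(
      list(mp_id = sprintf("MP%d", length(mps) + 1L),
           member_samples = samples[idx],
           member_index = idx,
           recurrence = rec,
           gene_list = top),
      class = "meta_program")
  }
  mps
}

#' Export meta-programs as a GMT-like gene-set file plus JSON metadata
#'
#' @param mps list of meta-programs from \code{\link{build_metaprograms}}
#' @param gmt_path,json_path output paths
#' @export
write_metaprograms <- function(mps, gmt_path, json_path) {
  lines <- vapply(mps, function(mp)
    paste(c(mp$mp_id, "consensus", mp$gene_list), collapse = "\t"), "")
  writeLines(lines, gmt_path)
  meta <- lapply(mps, function(mp)
    list(mp_id = mp$mp_id, recurrence = mp$recurrence,
         member_samples = mp$member_samples))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE)
  invisible(gmt_path)
}
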