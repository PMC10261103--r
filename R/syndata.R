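#' Specification of a planted expression program
#'
#' A program is a gene set that a latent subset of malignant cells
#' co-expresses above baseline: the synthetic analogue of an intratumor
#' expression meta-program.
#'
#' @param gene_ids character vector of gene ids (may overlap other programs)
#' @param log_effect additive shift on the log mean for active cells
#' @param active_fraction fraction of malignant cells active, in (0, 1]
#' @param samples_active sample ids in which the program occurs
#' @param name optional program name
#' @return A \code{program_spec}.
#' @export
program_spec <- function(gene_ids, log_effect, active_fraction,
                         samples_active, name = NULL) {
  assert_that(is.finite(log_effect), "log_effect must be finite")
  assert_that(active_fraction > 0 && active_fraction <= 1,
              "active_fraction must be in (0, 1]")
  structure(list(gene_ids = as.character(gene_ids),
                 log_effect = log_effect,
                 active_fraction = active_fraction,
                 samples_active = as.character(samples_active),
                 name = name %||% "program"),
            class = "program_spec")
}

#' Specification of a contiguous copy-number block
#'
#' @param chromosome chromosome id the block lies on
#' @param gene_range half-open index interval \code{[from, to)} into that
#'   chromosome's genes in genomic order
#' @param fold_change multiplicative change of the gene means (> 0);
#'   2 emulates a single-copy gain, 0.5 a loss
#' @param clone_fraction fraction of malignant cells carrying the block
#' @param samples sample ids affected (default: all)
#' @return A \code{cnv_block_spec}.
#' @export
cnv_block_spec <- function(chromosome, gene_range, fold_change,
                           clone_fraction, samples = NULL) {
  assert_that(fold_change > 0, "fold_change must be > 0")
  assert_that(clone_fraction > 0 && clone_fraction <= 1,
              "clone_fraction must be in (0, 1]")
  assert_that(length(gene_range) == 2L && gene_range[1] < gene_range[2],
              "gene_range must be a non-degenerate half-open interval")
  structure(list(chromosome = as.character(chromosome),
                 gene_range = as.integer(gene_range),
                 fold_change = fold_change,
                 clone_fraction = clone_fraction,
                 samples = samples),
            class = "cnv_block_spec")
}

#' Specification of a clone-size-skewed receptor repertoire
#'
#' @param n_clones number of distinct clonotypes
#' @param clone_size_law \code{"geometric"} or \code{"powerlaw"}
#' @param law_param geometric success probability, or power-law exponent
#' @param cdr3_length_range integer range of CDR3 nucleotide lengths
#' @param multi_chain_fraction fraction of cells given a second contig of
#'   the same locus (removed by the clonotyping QC downstream)
#' @return A \code{repertoire_spec}.
#' @export
repertoire_spec <- function(n_clones = 40,
                            clone_size_law = c("geometric", "powerlaw"),
                            law_param = 0.15,
                            cdr3_length_range = c(30L, 45L),
                            multi_chain_fraction = 0.02) {
  clone_size_law <- match.arg(clone_size_law)
  assert_that(n_clones >= 1, "n_clones must be >= 1")
  assert_that(multi_chain_fraction >= 0 && multi_chain_fraction < 1,
              "multi_chain_fraction must be in [0, 1)")
  structure(list(n_clones = as.integer(n_clones),
                 clone_size_law = clone_size_law,
                 law_param = law_param,
                 cdr3_length_range = as.integer(cdr3_length_range),
                 multi_chain_fraction = multi_chain_fraction),
            class = "repertoire_spec")
}

#' Specification of threshold-effect survival times
#'
#' Exponential event times whose hazard is multiplied by
#' \code{hazard_ratio} for patients whose score exceeds the true cutpoint,
#' with independent uniform censoring.
#'
#' @param n_patients cohort size
#' @param true_cutpoint score threshold carrying the hazard effect
#' @param hazard_ratio hazard multiplier above the cutpoint (> 0)
#' @param baseline_scale mean event time below the cutpoint
#' @param censor_rate probability an observation is censored, in [0, 1)
#' @return A \code{survival_spec}.
#' @export
survival_spec <- function(n_patients = 200, true_cutpoint = 0.5,
                          hazard_ratio = 4, baseline_scale = 10,
                          censor_rate = 0.1) {
  assert_that(hazard_ratio > 0, "hazard_ratio must be > 0")
  assert_that(censor_rate >= 0 && censor_rate < 1,
              "censor_rate must be in [0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 true_cutpoint = true_cutpoint,
                 hazard_ratio = hazard_ratio,
                 baseline_scale = baseline_scale,
                 censor_rate = censor_rate),
            class = "survival_spec")
}

# Gene universe layout shared by the generator and its ground truth.
# Regular genes, mito genes, light-chain constant+variable genes, and
# ABC/GCB marker genes all live in one ordered annotation table.
sim_gene_table <- function(genes, n_mito = 13L, n_coo = 30L) {
  special <- c(paste0("MT-", seq_len(n_mito)),
               "IGKC1", "IGKC2", "IGLC1", "IGLC2",
               paste0("IGKV", 1:5), paste0("IGLV", 1:5),
               sprintf("ABC-like-%02d", seq_len(n_coo)),
               sprintf("GCB-like-%02d", seq_len(n_coo)))
  n_reg <- genes - length(special)
  assert_that(n_reg >= 100, "genes too small for the built-in gene layout")
  ids <- c(sprintf("G%04d", seq_len(n_reg)), special)
  n <- length(ids)
  chrom <- as.character(rep(1:22, length.out = 22)[
    cut(seq_len(n), 22, labels = FALSE)])
  # mito genes live on their own "MT" chromosome, as in real annotation
  chrom[startsWith(ids, "MT-")] <- "MT"
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- seq_along(i) * 10000L
  }
  data.frame(gene_id = ids, chromosome = chrom, start = start,
             is_mito = startsWith(ids, "MT-"), stringsAsFactors = FALSE)
}

#' Configuration of a synthetic multi-sample cohort
#'
#' Bundles every knob of the generator: negative-binomial count model,
#' planted expression programs, light-chain restriction per tumor,
#' subclonal CNV blocks, ABC/GCB signature shifts, repertoire and survival
#' specs, and deliberate QC violators. Identical configurations (including
#' the seed) produce byte-identical outputs.
#'
#' The default cohort is a desk-scale stand-in for a multi-patient
#' single-cell study: 5 tumors, ~1200 genes, 300 malignant plus 100
#' non-malignant B plus 100 CD8 T cells each, with three expression
#' programs shared across all tumors and two sample-private ones.
#'
#' @param seed master seed; per-stage child streams are derived from it
#' @param n_samples number of tumors
#' @param genes total gene universe size (includes mito, light-chain and
#'   ABC/GCB marker genes)
#' @param cells_per_sample named integer vector with entries
#'   \code{malignant}, \code{nonmalignant_B}, \code{cd8_T}
#' @param baseline_log_mean,baseline_log_mean_sd normal prior of per-gene
#'   baseline log means
#' @param dispersion negative-binomial inverse dispersion theta (> 0),
#'   \code{Var = m + m^2/theta}
#' @param library_size_log_mean,library_size_log_sd log-normal per-cell
#'   scaling factor
#' @param programs list of \code{\link{program_spec}}; \code{NULL} for the
#'   default three-shared-two-private layout
#' @param lightchain_restriction named character vector sample -> "kappa" or
#'   "lambda"; \code{NULL} alternates
#' @param cnv_blocks list of \code{\link{cnv_block_spec}}
#' @param coo_subtype named character vector sample -> "ABC"/"GCB";
#'   \code{NULL} alternates
#' @param coo_delta log-mean upshift of the subtype's marker genes in
#'   malignant cells
#' @param repertoire a \code{\link{repertoire_spec}}
#' @param survival a \code{\link{survival_spec}}
#' @param mito_fraction expected fraction of counts on mito genes
#' @param qc_violators number of extra cells planted per QC violation type
#' @param emit_layers also draw spliced/unspliced count layers: two
#'   independent NB draws whose means split the total mean by
#'   \code{unspliced_fraction} (no kinetic splicing model)
#' @param unspliced_fraction expected fraction of mass on the unspliced
#'   layer, default 0.3
#' @return A \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 5L,
                       genes = 1200L,
                       cells_per_sample = c(malignant = 300L,
                                            nonmalignant_B = 100L,
                                            cd8_T = 100L),
                       baseline_log_mean = -1,
                       baseline_log_mean_sd = 1,
                       dispersion = 2,
                       library_size_log_mean = log(4),
                       library_size_log_sd = 0.3,
                       programs = NULL,
                       lightchain_restriction = NULL,
                       cnv_blocks = list(),
                       coo_subtype = NULL,
                       coo_delta = 1.0,
                       repertoire = repertoire_spec(),
                       survival = survival_spec(),
                       mito_fraction = 0.05,
                       qc_violators = 0L,
                       emit_layers = FALSE,
                       unspliced_fraction = 0.3) {
  assert_that(dispersion > 0 && is.finite(dispersion),
              "dispersion must be finite and > 0")
  assert_that(all(cells_per_sample >= 0), "cell counts must be >= 0")
  assert_that(all(c("malignant", "nonmalignant_B", "cd8_T") %in%
                    names(cells_per_sample)),
              "cells_per_sample needs malignant, nonmalignant_B, cd8_T")
  assert_that(mito_fraction >= 0 && mito_fraction <= 1,
              "mito_fraction must be in [0, 1]")
  samples <- sprintf("S%02d", seq_len(n_samples))
  gene_tab <- sim_gene_table(genes)
  reg <- gene_tab$gene_id[startsWith(gene_tab$gene_id, "G")]
  if (is.null(programs)) {
    programs <- list(
      program_spec(reg[1:50], 1.0, 0.25, samples, name = "MP-A"),
      program_spec(reg[51:100], 1.0, 0.25, samples, name = "MP-B"),
      program_spec(reg[101:150], 1.0, 0.25, samples, name = "MP-C"))
    if (n_samples >= 2) {
      programs <- c(programs, list(
        program_spec(reg[151:200], 1.0, 0.2, samples[1], name = "private-1"),
        program_spec(reg[201:250], 1.0, 0.2, samples[2], name = "private-2")))
    }
  }
  pn <- vapply(programs, `[[`, "", "name")
  if (anyDuplicated(pn))
    for (i in seq_along(programs)) programs[[i]]$name <- sprintf("P%02d", i)
  if (is.null(lightchain_restriction)) {
    lightchain_restriction <- setNames(
      rep(c("kappa", "lambda"), length.out = n_samples), samples)
  }
  assert_that(all(lightchain_restriction %in% c("kappa", "lambda")),
              "lightchain_restriction values must be kappa or lambda")
  if (is.null(coo_subtype)) {
    coo_subtype <- setNames(rep(c("ABC", "GCB"), length.out = n_samples),
                            samples)
  }
  assert_that(all(coo_subtype %in% c("ABC", "GCB")),
              "coo_subtype values must be ABC or GCB")
  for (b in cnv_blocks) {
    ng <- sum(gene_tab$chromosome == b$chromosome)
    assert_that(b$gene_range[2] <= ng + 1L && b$gene_range[1] >= 1L,
                "cnv block gene_range exceeds chromosome bounds")
  }
  structure(list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    samples = samples, genes = as.integer(genes),
    gene_table = gene_tab,
    cells_per_sample = cells_per_sample,
    baseline_log_mean = baseline_log_mean,
    baseline_log_mean_sd = baseline_log_mean_sd,
    dispersion = dispersion,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    programs = programs,
    lightchain_restriction = lightchain_restriction,
    cnv_blocks = cnv_blocks,
    coo_subtype = coo_subtype, coo_delta = coo_delta,
    repertoire = repertoire, survival = survival,
    mito_fraction = mito_fraction,
    qc_violators = as.integer(qc_violators),
    emit_layers = isTRUE(emit_layers),
    unspliced_fraction = unspliced_fraction),
    class = "sim_config")
}

#' Marker gene sets baked into the synthetic gene universe
#'
#' Returns the synthetic light-chain, B/T lineage and ABC/GCB marker gene
#' sets that \code{\link{generate_cohort}} plants (all names synthetic).
#'
#' @param config a \code{sim_config}
#' @return named list of gene-id vectors
#' @export
sim_gene_sets <- function(config) {
  ids <- config$gene_table$gene_id
  reg <- ids[startsWith(ids, "G")]
  list(kappa = ids[startsWith(ids, "IGK")],
       lambda = ids[startsWith(ids, "IGL")],
       kappa_constant = c("IGKC1", "IGKC2"),
       lambda_constant = c("IGLC1", "IGLC2"),
       abc = ids[startsWith(ids, "ABC-like")],
       gcb = ids[startsWith(ids, "GCB-like")],
       b_marker = reg[(length(reg) - 99):(length(reg) - 50)],
       t_marker = reg[(length(reg) - 49):length(reg)])
}

#' Generate a synthetic multi-sample cohort with exact ground truth
#'
#' Counts follow \code{NB(mean = s_c * exp(mu_g + sum_p a_cp * delta_p) *
#' cnv_g(c), theta)} where \code{s_c} is a log-normal cell factor,
#' \code{mu_g} a normal baseline, \code{a_cp} Bernoulli program activity
#' and \code{cnv_g(c)} the multiplicative block effect of the cell's
#' subclone. Light-chain constant genes follow the tumor's restriction
#' (the off-class chain has near-zero mean 0.01), designated MT- genes
#' carry \code{mito_fraction} of the expected mass, malignant cells of
#' ABC/GCB tumors carry the corresponding marker-set upshift, and
#' \code{qc_violators} extra cells per type deliberately breach the QC
#' rules (low gene count, high mito fraction, high total counts; plus
#' rare genes expressed in fewer than 50 cells).
#'
#' @param config a \code{\link{sim_config}}
#' @return list with elements \code{counts} (a \code{count_matrix}),
#'   \code{truth} (latent assignments: program activity, subclone
#'   membership, per-cell light chain, per-sample COO label, marker gene
#'   sets, QC violator barcodes) and, when \code{emit_layers} is set,
#'   \code{layers} (spliced/unspliced \code{count_matrix} pair).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gt <- config$gene_table
  G <- nrow(gt)
  sets <- sim_gene_sets(config)
  gi <- setNames(seq_len(G), gt$gene_id)

  set.seed(child_seed(config$seed, "baseline"))
  mu <- rnorm(G, config$baseline_log_mean, config$baseline_log_mean_sd)
  names(mu) <- gt$gene_id
  # scale mito genes to carry mito_fraction of the expected baseline mass
  if (config$mito_fraction > 0 && any(gt$is_mito)) {
    tgt <- config$mito_fraction / (1 - config$mito_fraction)
    fac <- tgt * sum(exp(mu[!gt$is_mito])) / sum(exp(mu[gt$is_mito]))
    mu[gt$is_mito] <- mu[gt$is_mito] + log(fac)
  }

  roles <- rep(names(config$cells_per_sample),
               times = config$cells_per_sample)
  cell_meta <- do.call(rbind, lapply(config$samples, function(s) {
    data.frame(barcode = sprintf("%s_%s_%04d", s, roles, seq_along(roles)),
               sample_id = s, role = roles, stringsAsFactors = FALSE)
  }))
  N <- nrow(cell_meta)
  malig <- cell_meta$role == "malignant"
  bcell <- cell_meta$role %in% c("malignant", "nonmalignant_B")

  set.seed(child_seed(config$seed, "cells"))
  s_c <- rlnorm(N, config$library_size_log_mean, config$library_size_log_sd)

  # log-mean matrix: baseline + lineage markers + programs + COO shift
  logm <- matrix(mu, nrow = G, ncol = N)
  logm[gi[sets$b_marker], bcell] <- logm[gi[sets$b_marker], bcell] + 2
  logm[gi[sets$t_marker], !bcell] <- logm[gi[sets$t_marker], !bcell] + 2

  prog_act <- matrix(0L, N, length(config$programs),
                     dimnames = list(cell_meta$barcode,
                                     vapply(config$programs, `[[`, "",
                                            "name")))
  set.seed(child_seed(config$seed, "programs"))
  for (p in seq_along(config$programs)) {
    ps <- config$programs[[p]]
    elig <- which(malig & cell_meta$sample_id %in% ps$samples_active)
    act <- elig[runif(length(elig)) < ps$active_fraction]
    prog_act[act, p] <- 1L
    rows <- gi[ps$gene_ids]
    logm[rows, act] <- logm[rows, act] + ps$log_effect
  }

  for (s in config$samples) {
    sub <- config$coo_subtype[[s]]
    cells <- which(malig & cell_meta$sample_id == s)
    rows <- gi[if (sub == "ABC") sets$abc else sets$gcb]
    logm[rows, cells] <- logm[rows, cells] + config$coo_delta
  }

  mean_mat <- exp(logm) * rep(s_c, each = G)

  # light chain: restricted malignant cells boost the on-class genes and
  # draw every off-class gene from a near-zero mean; non-malignant B cells
  # express both chains at comparable levels so their cluster statistic
  # reads balanced (per-cell exclusion of normal B cells is not emulated)
  lc <- rep(NA_character_, N)
  lc[malig] <- config$lightchain_restriction[cell_meta$sample_id[malig]]
  kap <- gi[sets$kappa]; lam <- gi[sets$lambda]
  for (cls in c("kappa", "lambda")) {
    on <- if (cls == "kappa") kap else lam
    off <- if (cls == "kappa") lam else kap
    cells <- which(!is.na(lc) & lc == cls)
    mean_mat[on, cells] <- mean_mat[on, cells] * 50
    mean_mat[off, cells] <- 0.01
  }
  nb <- which(cell_meta$role == "nonmalignant_B")
  mean_mat[c(kap, lam), nb] <- mean_mat[c(kap, lam), nb] * 10
  tcells <- which(!bcell)
  mean_mat[c(kap, lam), tcells] <- 0.01

  # subclonal CNV blocks act multiplicatively on malignant subclone cells
  set.seed(child_seed(config$seed, "cnv"))
  cnv_member <- matrix(0L, N, length(config$cnv_blocks))
  if (length(config$cnv_blocks)) {
    colnames(cnv_member) <- sprintf("block%d", seq_along(config$cnv_blocks))
    rownames(cnv_member) <- cell_meta$barcode
    for (b in seq_along(config$cnv_blocks)) {
      bs <- config$cnv_blocks[[b]]
      smp <- bs$samples %||% config$samples
      elig <- which(malig & cell_meta$sample_id %in% smp)
      memb <- elig[runif(length(elig)) < bs$clone_fraction]
      cnv_member[memb, b] <- 1L
      chr_genes <- which(gt$chromosome == bs$chromosome)
      chr_genes <- chr_genes[order(gt$start[chr_genes], gt$gene_id[chr_genes])]
      rows <- chr_genes[bs$gene_range[1]:(bs$gene_range[2] - 1L)]
      mean_mat[rows, memb] <- mean_mat[rows, memb] * bs$fold_change
    }
  }

  set.seed(child_seed(config$seed, "counts"))
  counts <- matrix(rnbinom(G * N, mu = mean_mat, size = config$dispersion),
                   nrow = G, ncol = N)

  layers <- NULL
  if (config$emit_layers) {
    # spliced/unspliced: two independent NB layers splitting the mean;
    # deliberately no kinetic model (see methods vignette)
    uf <- config$unspliced_fraction
    set.seed(child_seed(config$seed, "spliced"))
    spl <- matrix(rnbinom(G * N, mu = mean_mat * (1 - uf),
                          size = config$dispersion), G, N)
    set.seed(child_seed(config$seed, "unspliced"))
    uns <- matrix(rnbinom(G * N, mu = mean_mat * uf,
                          size = config$dispersion), G, N)
    layers <- list(spliced = spl, unspliced = uns)
  }

  qc_viol <- data.frame(barcode = character(), type = character(),
                        stringsAsFactors = FALSE)
  rare_genes <- character()
  if (config$qc_violators > 0L) {
    set.seed(child_seed(config$seed, "qc"))
    nv <- config$qc_violators
    mk <- function(type, j) {
      data.frame(barcode = sprintf("QC_%s_%03d", type, j), type = type,
                 stringsAsFactors = FALSE)
    }
    vcols <- list()
    vmeta <- list()
    template <- which(malig)
    for (type in c("low_genes", "high_mito", "high_counts")) {
      for (j in seq_len(nv)) {
        src <- sample(template, 1)
        col <- rnbinom(G, mu = mean_mat[, src], size = config$dispersion)
        if (type == "low_genes") {
          nz <- which(col > 0)
          if (length(nz) > 450) col[nz[-seq_len(450L)]] <- 0L
        } else if (type == "high_mito") {
          nonmito <- sum(col[!gt$is_mito])
          need <- ceiling(0.25 / 0.75 * max(nonmito, 1))
          mrows <- which(gt$is_mito)
          col[mrows] <- as.integer(ceiling(need / length(mrows)))
        } else {
          tot <- max(sum(col), 1)
          col <- as.integer(col * ceiling(60000 / tot))
        }
        vcols[[length(vcols) + 1L]] <- col
        meta <- mk(type, j)
        vmeta[[length(vmeta) + 1L]] <- meta
        qc_viol <- rbind(qc_viol, meta)
      }
    }
    counts <- cbind(counts, do.call(cbind, vcols))
    extra <- do.call(rbind, vmeta)
    cell_meta <- rbind(cell_meta,
                       data.frame(barcode = extra$barcode,
                                  sample_id = config$samples[1],
                                  role = "qc_violator",
                                  stringsAsFactors = FALSE))
    # rare genes: expressed in fewer than 50 cells
    reg_ids <- gt$gene_id[startsWith(gt$gene_id, "G")]
    rare_genes <- reg_ids[seq(length(reg_ids) - nv + 1L, length(reg_ids))]
    for (g in rare_genes) {
      counts[gi[g], ] <- 0L
      counts[gi[g], sample(ncol(counts), 10)] <- 1L
    }
  }

  cm <- count_matrix(counts, gt, cell_meta)
  if (!is.null(layers)) {
    base_meta <- cell_meta[seq_len(N), , drop = FALSE]
    layers <- lapply(layers, count_matrix, gene_meta = gt,
                     cell_meta = base_meta)
  }
  truth <- list(
    program_activity = prog_act,
    program_gene_sets = setNames(
      lapply(config$programs, `[[`, "gene_ids"),
      vapply(config$programs, `[[`, "", "name")),
    cnv_membership = cnv_member,
    cnv_blocks = config$cnv_blocks,
    lightchain = setNames(lc, cell_meta$barcode[seq_len(N)]),
    coo_subtype = config$coo_subtype,
    marker_sets = sets,
    qc_violators = qc_viol,
    rare_genes = rare_genes,
    baseline_log_mean = mu,
    cell_factor = setNames(s_c, cell_meta$barcode[seq_len(N)]))
  list(counts = cm, truth = truth, layers = layers)
}

DNA <- c("A", "C", "G", "T")

random_cdr3 <- function(n, len_range) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(DNA, l, replace = TRUE), collapse = ""), "")
}

#' Generate a synthetic TCR contig table for the cohort's CD8 T cells
#'
#' Emits one contig row per chain per cell in the 10x
#' \code{filtered_contig_annotations.csv} dialect (TRA + TRB per cell,
#' clonotype defined by shared CDR3 nucleotide sequences). Clone sizes
#' follow the configured geometric or power-law skew;
#' \code{multi_chain_fraction} of cells receive a second TRB contig and are
#' flagged in the ground truth.
#'
#' @param config a \code{\link{sim_config}}
#' @return list with \code{contigs} (data.frame in 10x dialect) and
#'   \code{truth} (per-cell clone id, clone sizes, multi-chain flags).
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rs <- config$repertoire
  n_t <- config$cells_per_sample[["cd8_T"]]
  barcodes <- unlist(lapply(config$samples, function(s) {
    roles <- rep(names(config$cells_per_sample),
                 times = config$cells_per_sample)
    sprintf("%s_%s_%04d", s, roles, seq_along(roles))[roles == "cd8_T"]
  }))
  n <- length(barcodes)
  assert_that(n > 0, "no cd8_T cells configured")
  set.seed(child_seed(config$seed, "repertoire"))
  w <- switch(rs$clone_size_law,
              geometric = rs$law_param * (1 - rs$law_param)^
                (seq_len(rs$n_clones) - 1),
              powerlaw = seq_len(rs$n_clones)^(-rs$law_param))
  clone <- sample.int(rs$n_clones, n, replace = TRUE, prob = w / sum(w))
  cdr3a <- random_cdr3(rs$n_clones, rs$cdr3_length_range)
  cdr3b <- random_cdr3(rs$n_clones, rs$cdr3_length_range)
  multi <- runif(n) < rs$multi_chain_fraction
  rows <- list()
  for (i in seq_len(n)) {
    chains <- c("TRA", "TRB")
    nts <- c(cdr3a[clone[i]], cdr3b[clone[i]])
    if (multi[i]) {
      chains <- c(chains, "TRB")
      nts <- c(nts, random_cdr3(1, rs$cdr3_length_range))
    }
    rows[[i]] <- data.frame(
      barcode = barcodes[i], is_cell = "True",
      contig_id = sprintf("%s_contig_%d", barcodes[i], seq_along(chains)),
      chain = chains,
      v_gene = paste0(chains, "V1"), j_gene = paste0(chains, "J1"),
      cdr3 = substr(nts, 1, 12), cdr3_nt = nts,
      reads = 1000L, umis = 10L, stringsAsFactors = FALSE)
  }
  contigs <- do.call(rbind, rows)
  sizes <- table(factor(clone, levels = seq_len(rs$n_clones)))
  truth <- data.frame(barcode = barcodes, clone_id = clone,
                      multi_chain = multi, stringsAsFactors = FALSE)
  list(contigs = contigs, truth = truth,
       clone_sizes = as.integer(sizes))
}

#' Generate a synthetic survival cohort with a planted score threshold
#'
#' Event times are exponential with hazard \code{1/baseline_scale},
#' multiplied by \code{hazard_ratio} when the (uniform) score exceeds the
#' true cutpoint; a \code{censor_rate} fraction of observations is censored
#' uniformly before the event.
#'
#' @param config a \code{\link{sim_config}}
#' @return data.frame (patient_id, time, event, score) with attribute
#'   \code{"group"} holding the true high/low assignment.
#' @export
generate_survival <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ss <- config$survival
  assert_that(ss$censor_rate < 1, "censor_rate must be < 1")
  set.seed(child_seed(config$seed, "survival"))
  n <- ss$n_patients
  score <- runif(n)
  high <- score > ss$true_cutpoint
  rate <- (1 / ss$baseline_scale) * ifelse(high, ss$hazard_ratio, 1)
  time <- rexp(n, rate)
  event <- rep(1L, n)
  cens <- runif(n) < ss$censor_rate
  time[cens] <- runif(sum(cens), 0, time[cens])
  event[cens] <- 0L
  d <- data.frame(patient_id = sprintf("PT%03d", seq_len(n)),
                  time = time, event = event, score = score,
                  stringsAsFactors = FALSE)
  attr(d, "group") <- ifelse(high, "high", "low")
  d
}

#' Write a full synthetic cohort to disk
#'
#' MTX + features/barcodes TSV for the counts, 10x-style contig CSV,
#' survival CSV, and TSV sidecars for every ground-truth table.
#'
#' @param config a \code{\link{sim_config}}
#' @param dir output directory
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- generate_cohort(config)
  write_counts(ch$counts, dir)
  rep <- generate_repertoire(config)
  write.csv(rep$contigs, file.path(dir, "filtered_contig_annotations.csv"),
            row.names = FALSE, quote = FALSE)
  sv <- generate_survival(config)
  write.csv(sv, file.path(dir, "survival.csv"), row.names = FALSE,
            quote = FALSE)
  tw <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  tw(data.frame(barcode = rownames(ch$truth$program_activity),
                ch$truth$program_activity, check.names = FALSE),
     "truth_program_activity.tsv")
  tw(rep$truth, "truth_clonotypes.tsv")
  tw(data.frame(barcode = names(ch$truth$lightchain),
                lightchain = unname(ch$truth$lightchain)),
     "truth_lightchain.tsv")
  write_gene_sets(ch$truth$program_gene_sets,
                  file.path(dir, "truth_program_genes.tsv"))
  invisible(dir)
}
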