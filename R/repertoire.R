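#' Read a 10x-style filtered contig annotation CSV
#'
#' Requires columns \code{barcode}, \code{chain}, \code{cdr3_nt}; rows
#' with \code{is_cell}/\code{high_confidence} equal to "False" are
#' dropped when those columns are present.
#'
#' @param path CSV path
#' @return data.frame of contig records.
#' @export
read_contigs <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("barcode", "chain", "cdr3_nt")
  miss <- setdiff(need, names(d))
  assert_that(length(miss) == 0,
              paste("contig file missing columns:",
                    paste(miss, collapse = ", ")))
  for (col in c("is_cell", "high_confidence")) {
    if (col %in% names(d))
      d <- d[!(tolower(as.character(d[[col]])) %in% c("false", "f")), ,
             drop = FALSE]
  }
  d
}

#' Assemble clonotypes from contig records
#'
#' Cells carrying more than one contig of the same chain locus (e.g. two
#' productive TRB chains) are removed; surviving cells are keyed by the
#' sorted set of (chain, CDR3 nucleotide) pairs, so clonotypes are defined
#' by the CDR3-nt sequences of all chains. With \code{chain_mode =
#' "TRB"}, only the TRB chain keys TCR clonotypes.
#'
#' @param contigs data.frame with \code{barcode}, \code{chain},
#'   \code{cdr3_nt}
#' @param receptor \code{"TCR"} (chains TRA/TRB) or \code{"BCR"} (chains
#'   IGH/IGK/IGL)
#' @param chain_mode \code{"paired"} (default) or \code{"TRB"}
#' @return data.frame of class \code{clonotype_table}: one row per kept
#'   cell (barcode, clone_id, clonotype_key, clone_size); attribute
#'   \code{"removed_multichain"} lists excluded barcodes.
#' @export
assemble_clonotypes <- function(contigs, receptor = c("TCR", "BCR"),
                                chain_mode = c("paired", "TRB")) {
  receptor <- match.arg(receptor)
  chain_mode <- match.arg(chain_mode)
  allowed <- switch(receptor, TCR = c("TRA", "TRB"),
                    BCR = c("IGH", "IGK", "IGL"))
  bad <- setdiff(unique(contigs$chain), allowed)
  if (length(bad))
    stop("unknown chain labels for ", receptor, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  per <- table(contigs$barcode, contigs$chain)
  multi <- rownames(per)[apply(per, 1, function(r) any(r > 1))]
  kept <- contigs[!(contigs$barcode %in% multi), , drop = FALSE]
  if (chain_mode == "TRB")
    kept <- kept[kept$chain == "TRB", , drop = FALSE]
  if (nrow(kept) == 0L) {
    out <- data.frame(barcode = character(), clone_id = integer(),
                      clonotype_key = character(), clone_size = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("clonotype_table", "data.frame")
    attr(out, "removed_multichain") <- multi
    return(out)
  }
  keys <- vapply(split(kept, kept$barcode), function(d) {
    paste(sort(paste(d$chain, d$cdr3_nt, sep = ":")), collapse = ";")
  }, "")
  clone_id <- as.integer(factor(keys, levels = unique(keys)))
  sizes <- table(clone_id)
  out <- data.frame(barcode = names(keys), clone_id = clone_id,
                    clonotype_key = unname(keys),
                    clone_size = as.integer(sizes[as.character(clone_id)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("clonotype_table", "data.frame")
  attr(out, "removed_multichain") <- multi
  out
}

#' Clonal expansion fraction
#'
#' Fraction of assigned cells belonging to clonally expanded clones
#' ("clone size of more than 10", i.e. size >= \code{min_clone}).
#'
#' @param t a \code{clonotype_table}
#' @param groups optional per-cell group labels (same order as rows);
#'   \code{NULL} pools all cells
#' @param min_clone minimum expanded clone size, default 11
#' @return named numeric vector of per-group fractions (NA for empty
#'   groups).
#' @export
expansion_fraction <- function(t, groups = NULL, min_clone = 11L) {
  stopifnot(inherits(t, "clonotype_table"))
  if (is.null(groups)) groups <- rep("all", nrow(t))
  f <- function(i) {
    if (!length(i)) return(NA_real_)
    cl <- t$clone_id[i]
    sz <- table(cl)
    mean(sz[as.character(cl)] >= min_clone)
  }
  vapply(split(seq_len(nrow(t)), groups), f, 0)
}

#' Morisita-Horn overlap between two clone count vectors
#'
#' \code{MH = 2 sum(x_i y_i) / ((sum x_i^2 / X^2 + sum y_i^2 / Y^2) X Y)}
#' over the union of clones; symmetric, in [0, 1], 1 iff the relative
#' frequencies coincide, 0 for disjoint supports.
#'
#' @param x,y nonnegative count vectors over the same clone universe
#'   (recycled zero-padding is the caller's job; equal length required)
#' @return scalar overlap index.
#' @export
morisita_horn <- function(x, y) {
  assert_that(length(x) == length(y),
              "x and y must cover the same clone universe")
  X <- sum(x); Y <- sum(y)
  assert_that(X > 0 && Y > 0, "zero-total clone vector")
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' Clone count vectors for two groups over their union of clonotypes
#'
#' @param t a \code{clonotype_table}
#' @param groups per-cell group labels
#' @param a,b the two group labels to compare
#' @return list of two aligned count vectors \code{x}, \code{y}.
#' @export
clone_counts_pair <- function(t, groups, a, b) {
  stopifnot(inherits(t, "clonotype_table"))
  keys <- unique(t$clonotype_key[groups %in% c(a, b)])
  cnt <- function(g) {
    tab <- table(factor(t$clonotype_key[groups == g], levels = keys))
    as.integer(tab)
  }
  list(x = cnt(a), y = cnt(b))
}

#' Berger-Parker dominance index
#'
#' Relative abundance of the single most dominant clone:
#' \code{max(x) / sum(x)}.
#'
#' @param x nonnegative clone count vector with positive sum
#' @return scalar in (0, 1].
#' @export
berger_parker <- function(x) {
  assert_that(length(x) > 0 && sum(x) > 0, "empty clone count vector")
  max(x) / sum(x)
}
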