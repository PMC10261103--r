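#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.dist ave cor cutree dhyper dist hclust kmeans
#'   median p.adjust pchisq pnorm prcomp quantile rexp rlnorm rnbinom
#'   rnorm runif sd setNames wilcox.test
#' @importFrom utils read.csv read.delim write.csv write.table head
#' @importFrom methods as is
NULL

# Deterministic child seed derived from a master seed and a stage label.
# Keeps every derived seed strictly below 2^31 - 1.
child_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(what))
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483587 + 1)
}

# log(sum(exp(x))) without overflow; used for exact tail sums in log space
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
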