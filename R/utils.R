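# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_image <- function(x) is.matrix(x) && is.numeric(x)

assert_image <- function(x, what = "image") {
  if (!is_image(x)) stopf("%s must be a 2D numeric matrix", what)
  invisible(x)
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stopf("%s must have identical dimensions (%s vs %s)",
          what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  }
  invisible(NULL)
}

#' Column-wise z-scoring with a constant-column guard
#'
#' Centers and scales each column; columns with zero variance are centered
#' only (scale treated as 1) so downstream distances stay finite.
#' @param x numeric matrix or data frame of numeric columns.
#' @return numeric matrix of the same shape.
#' @keywords internal
#' @noRd
zscore_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

#' Rand index (pair-agreement fraction) between two partitions
#'
#' Plain (unadjusted) Rand index: the fraction of all point pairs on whose
#' co-assignment the two partitions agree.
#' @param a,b integer/character label vectors of equal length.
#' @return scalar in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors must have equal length")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

#' Adjusted Rand index
#'
#' Chance-corrected partition agreement; wraps the mclust implementation.
#' @param a,b label vectors of equal length.
#' @return scalar, 1 for identical partitions, about 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors must have equal length")
  mclust::adjustedRandIndex(a, b)
}

# Stable short hash of an R object (used for config fingerprinting).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

# Draw from an integer sub-seed stream so one global seed fans out to stages.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101, correct = 211, segment = 307, features = 401,
               normalize = 503, cluster_eval = 601, atlas = 701, evaluate = 809)
  off <- offsets[[stage]] %||% 997
  (as.integer(seed) * 1009L + as.integer(off)) %% .Machine$integer.max
}
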