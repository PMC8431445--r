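# Feature-set validation by consensus-clustering stability.
#
# A feature subset is scored by repeatedly (R times) subsampling 80% of its
# feature columns, z-scoring, embedding to 2D by t-SNE and fitting a
# G-component Gaussian mixture on the embedding. The co-clustering
# frequency over repeats forms the consensus matrix; stability is
# summarized by PAC (proportion of ambiguous consensus entries), CON (mean
# Rand-index concordance between repeats and the consensus partition), MSS
# (mean silhouette of the consensus partition under distance 1 - consensus)
# and their mean MCS = ((1 - PAC) + CON + MSS) / 3.

#' Consensus clustering specification
#'
#' @param feature_columns character vector of feature columns to use (the
#'   feature-subset variant under evaluation).
#' @param n_repeats number of subsampled clustering repeats R (default 100).
#' @param subsample_rate fraction of feature columns drawn (without
#'   replacement) per repeat (default 0.8).
#' @param n_clusters mixture components G (default 10).
#' @param perplexity t-SNE perplexity (default 30).
#' @param pac_lower,pac_upper ambiguity band for PAC (defaults 0.1, 0.9).
#' @param seed integer seed.
#' @return a `consensus_spec` list.
#' @export
consensus_spec <- function(feature_columns = NULL, n_repeats = 100,
                           subsample_rate = 0.8, n_clusters = 10,
                           perplexity = 30, pac_lower = 0.1, pac_upper = 0.9,
                           seed = 1) {
  stopifnot(subsample_rate > 0, subsample_rate <= 1,
            pac_lower < pac_upper, n_clusters >= 2)
  structure(list(feature_columns = feature_columns, n_repeats = n_repeats,
                 subsample_rate = subsample_rate, n_clusters = n_clusters,
                 perplexity = perplexity, pac_lower = pac_lower,
                 pac_upper = pac_upper, seed = as.integer(seed)),
            class = "consensus_spec")
}

# Gaussian mixture fit evaluated inside the mclust namespace: mclust's
# model-selection helpers resolve each other by bare name in the calling
# frame, so a plain namespaced call fails from package code.
fit_gmm <- local({
  f <- function(emb, G) {
    bic <- mclustBIC(emb, G = G, verbose = FALSE)
    Mclust(emb, G = G, x = bic, verbose = FALSE)
  }
  function(emb, G) {
    environment(f) <- asNamespace("mclust")
    f(emb, G)
  }
})

tsne_embed <- function(x, perplexity) {
  n <- nrow(x)
  perp <- min(perplexity, floor((n - 1) / 3))
  if (perp < 1) stopf("too few cells (%d) for t-SNE", n)
  if (all(apply(x, 2, var) == 0)) {
    # degenerate input (all points identical): collapse to the origin
    return(matrix(0, n, 2))
  }
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perp,
                      check_duplicates = FALSE, pca = TRUE,
                      partial_pca = FALSE, max_iter = 500, verbose = FALSE)
  fit$Y
}

#' Run consensus clustering over feature subsamples
#'
#' @param table `feature_table` or numeric matrix (cells x features).
#' @param spec a [consensus_spec()]; `feature_columns` defaults to all
#'   feature columns of `table`.
#' @return a `consensus_result`: `consensus_matrix` (n x n, symmetric, unit
#'   diagonal), `repeat_partitions` (list of label vectors),
#'   `consensus_partition` (average-link cut of `1 - consensus_matrix` into
#'   G groups), `n_repeats_used`, `spec`.
#' @export
run_consensus <- function(table, spec = consensus_spec()) {
  if (inherits(table, "feature_table")) {
    cols <- spec$feature_columns %||% feature_columns(table)
    x <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  } else {
    x <- as.matrix(table)
    if (!is.null(spec$feature_columns)) {
      x <- x[, spec$feature_columns, drop = FALSE]
    }
  }
  n <- nrow(x)
  G <- spec$n_clusters
  if (n <= G) stopf("need more cells (%d) than clusters (%d)", n, G)
  nf <- ncol(x)
  n_draw <- max(1L, ceiling(spec$subsample_rate * nf))
  set.seed(spec$seed)
  co <- matrix(0, n, n)
  partitions <- list()
  for (r in seq_len(spec$n_repeats)) {
    sub <- sort(sample.int(nf, n_draw))
    z <- zscore_columns(x[, sub, drop = FALSE])
    emb <- tsne_embed(z, spec$perplexity)
    labels <- NULL
    for (try in 1:2) {
      fit <- tryCatch(fit_gmm(emb, G), error = function(e) NULL)
      if (!is.null(fit) && !is.null(fit$classification)) {
        labels <- fit$classification
        break
      }
    }
    if (is.null(labels)) {
      warnf("degenerate mixture fit in repeat %d; repeat skipped", r)
      next
    }
    partitions[[length(partitions) + 1L]] <- labels
    same <- outer(labels, labels, "==")
    co <- co + same
  }
  R_used <- length(partitions)
  if (R_used == 0) stopf("all consensus repeats failed")
  M <- co / R_used
  diag(M) <- 1
  hc <- hclust(as.dist(1 - M), method = "average")
  consensus <- cutree(hc, k = G)
  structure(list(consensus_matrix = M, repeat_partitions = partitions,
                 consensus_partition = consensus, n_repeats_used = R_used,
                 spec = spec),
            class = "consensus_result")
}

#' Stability metrics of a consensus result
#'
#' PAC = fraction of off-diagonal (i < j) consensus entries strictly inside
#' the ambiguity band; CON = mean Rand index between each repeat partition
#' and the consensus partition; MSS = mean silhouette width of the
#' consensus partition under distance `1 - consensus_matrix` (0 with a
#' warning if the consensus partition has a single cluster).
#'
#' @param result a [run_consensus()] result.
#' @param pac_lower,pac_upper ambiguity band; defaults from the result's
#'   spec.
#' @return a `stability_metrics` list: `PAC`, `CON`, `MSS`, `MCS`.
#' @export
stability_metrics <- function(result, pac_lower = NULL, pac_upper = NULL) {
  stopifnot(inherits(result, "consensus_result"))
  lo <- pac_lower %||% result$spec$pac_lower
  hi <- pac_upper %||% result$spec$pac_upper
  M <- result$consensus_matrix
  off <- M[upper.tri(M)]
  PAC <- mean(off > lo & off < hi)
  cons <- result$consensus_partition
  CON <- mean(vapply(result$repeat_partitions, rand_index, numeric(1), b = cons))
  if (length(unique(cons)) < 2) {
    warnf("single-cluster consensus partition; MSS defined as 0")
    MSS <- 0
  } else {
    sil <- cluster::silhouette(cons, dmatrix = 1 - M)
    MSS <- mean(sil[, "sil_width"])
  }
  structure(list(PAC = PAC, CON = CON, MSS = MSS,
                 MCS = compute_mcs(PAC, CON, MSS)),
            class = "stability_metrics")
}

#' @export
print.stability_metrics <- function(x, ...) {
  cat(sprintf("PAC = %.3f  CON = %.3f  MSS = %.3f  ->  MCS = %.3f\n",
              x$PAC, x$CON, x$MSS, x$MCS))
  invisible(x)
}

#' Mean clustering score
#'
#' `MCS = ((1 - PAC) + CON + MSS) / 3`. Accepts either the three components
#' or a `stability_metrics` object as first argument.
#' @param PAC proportion of ambiguous clustering in `[0, 1]`, or a
#'   `stability_metrics` object.
#' @param CON concordance in `[0, 1]`.
#' @param MSS mean silhouette score in `[-1, 1]`.
#' @return scalar in `[-1/3, 1]`.
#' @examples
#' compute_mcs(0, 1, 1)        # 1
#' compute_mcs(1, 0, 0)        # 0
#' compute_mcs(0.4, 0.8, 0.5)  # 0.6333...
#' @export
compute_mcs <- function(PAC, CON = NULL, MSS = NULL) {
  if (inherits(PAC, "stability_metrics")) {
    m <- PAC
    PAC <- m$PAC; CON <- m$CON; MSS <- m$MSS
  }
  stopifnot(PAC >= 0, PAC <= 1, CON >= 0, CON <= 1, MSS >= -1, MSS <= 1)
  ((1 - PAC) + CON + MSS) / 3
}

#' Per-feature significance of differences across clusters
#'
#' One-way ANOVA F-test per feature across cluster labels with
#' Benjamini-Hochberg adjustment, plus the maximal difference of z-scored
#' cluster means (max - min) as an effect size.
#'
#' @param table `feature_table` or numeric matrix.
#' @param labels cluster labels, one per row.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return data frame: `feature`, `F`, `p`, `p_adj`, `significant`,
#'   `max_difference`.
#' @export
feature_significance <- function(table, labels, alpha = 0.05) {
  x <- if (inherits(table, "feature_table")) {
    as.matrix(as.data.frame(table)[, feature_columns(table), drop = FALSE])
  } else as.matrix(table)
  stopifnot(nrow(x) == length(labels))
  g <- factor(labels)
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stopf("need at least 2 clusters with at least 2 cells each")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  out <- data.frame(feature = colnames(x), F = NA_real_, p = NA_real_)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (sd(v) == 0) {
      out$F[j] <- 0; out$p[j] <- 1
      next
    }
    a <- anova(lm(v ~ g))
    Fj <- a$`F value`[1]
    if (!is.finite(Fj)) Fj <- Inf  # zero within-cluster variance everywhere
    out$F[j] <- Fj
    out$p[j] <- if (is.infinite(Fj)) 0 else a$`Pr(>F)`[1]
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  z <- zscore_columns(x)
  out$max_difference <- vapply(seq_len(ncol(z)), function(j) {
    mns <- tapply(z[, j], g, mean)
    max(mns) - min(mns)
  }, numeric(1))
  out$max_difference[apply(x, 2, sd) == 0] <- 0
  out
}

#' PCA contributions of autoscaled features
#'
#' Columns are autoscaled (z-scored; constant columns dropped with a
#' warning), PCA is computed by SVD, and per-feature contributions are the
#' squared loadings normalized within each component (in percent), as in a
#' standard PCA biplot contribution analysis.
#'
#' @param table `feature_table` or numeric matrix.
#' @param n_components number of components to report (default all).
#' @return list: `loadings`, `variance_explained` (fractions),
#'   `contributions` (features x components, percent summing to 100 per
#'   component), `dropped` (constant columns).
#' @export
pca_contributions <- function(table, n_components = NULL) {
  x <- if (inherits(table, "feature_table")) {
    as.matrix(as.data.frame(table)[, feature_columns(table), drop = FALSE])
  } else as.matrix(table)
  if (ncol(x) < 2 || nrow(x) <= 2) stopf("need >= 2 features and > 2 rows")
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warnf("dropping constant feature(s) before scaling: %s",
          paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 1) stopf("no non-constant features left")
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  k <- n_components %||% ncol(fit$rotation)
  k <- min(k, ncol(fit$rotation))
  load <- fit$rotation[, seq_len(k), drop = FALSE]
  contrib <- sweep(load^2, 2, colSums(load^2), "/") * 100
  list(loadings = load,
       variance_explained = fit$sdev^2 / sum(fit$sdev^2),
       contributions = contrib, dropped = dropped)
}
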