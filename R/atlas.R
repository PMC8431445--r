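# Single-cell atlas: embedding, Gaussian mean-shift clustering, cluster
# profiles, hierarchical sub-clustering and per-sample composition.

#' Atlas parameters
#'
#' @param perplexity t-SNE perplexity (default 30).
#' @param gms_bandwidth Gaussian kernel bandwidth in embedding units;
#'   default `NULL` means "embedding extent / 15" (extent = larger axis
#'   range), a default calibrated once on the reference fixtures; cluster
#'   count is stable over roughly extent/20 to extent/8 there.
#' @param mode_merge_tol distance below which two density modes are merged;
#'   default equals the bandwidth.
#' @param grid_size density grid resolution per axis for the mean-shift
#'   (default 128).
#' @param min_cluster_size clusters smaller than this are reassigned to the
#'   nearest retained density mode; default `NULL` means
#'   `max(3, ceiling(0.01 n))`. Guards against sliver basins of an
#'   under-smoothed density estimate.
#' @param n_subclusters sub-cluster count k for hierarchical sub-clustering
#'   (default 30).
#' @param seed integer seed for the embedding.
#' @return an `atlas_params` list.
#' @export
atlas_params <- function(perplexity = 30, gms_bandwidth = NULL,
                         mode_merge_tol = NULL, grid_size = 128,
                         min_cluster_size = NULL, n_subclusters = 30,
                         seed = 1) {
  if (!is.null(gms_bandwidth) && gms_bandwidth <= 0) {
    stopf("gms_bandwidth must be > 0")
  }
  stopifnot(n_subclusters >= 1, grid_size >= 16)
  structure(list(perplexity = perplexity, gms_bandwidth = gms_bandwidth,
                 mode_merge_tol = mode_merge_tol, grid_size = grid_size,
                 min_cluster_size = min_cluster_size,
                 n_subclusters = as.integer(n_subclusters),
                 seed = as.integer(seed)),
            class = "atlas_params")
}

#' Embed cells into 2D by t-SNE
#'
#' Feature columns are z-scored, then embedded with t-SNE at the given
#' perplexity. Deterministic under the params' seed.
#'
#' @param table `feature_table` or numeric matrix (cells x features).
#' @param params an [atlas_params()].
#' @param columns feature columns to embed (default all feature columns).
#' @return n x 2 matrix of embedding coordinates.
#' @export
embed_cells <- function(table, params = atlas_params(), columns = NULL) {
  x <- if (inherits(table, "feature_table")) {
    cols <- columns %||% feature_columns(table)
    as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  } else as.matrix(table)
  n <- nrow(x)
  if (params$perplexity >= n) {
    stopf("perplexity (%s) must be smaller than the number of cells (%d)",
          params$perplexity, n)
  }
  z <- zscore_columns(x)
  set.seed(params$seed)
  emb <- tsne_embed(z, params$perplexity)
  colnames(emb) <- c("tsne1", "tsne2")
  emb
}

# Gaussian KDE on a regular grid over the embedding bounding box.
grid_density <- function(emb, bandwidth, grid_size, pad = 3) {
  lo <- apply(emb, 2, min) - pad * bandwidth
  hi <- apply(emb, 2, max) + pad * bandwidth
  gx <- seq(lo[1], hi[1], length.out = grid_size)
  gy <- seq(lo[2], hi[2], length.out = grid_size)
  # bin points, then smooth the histogram with a separable Gaussian kernel
  ix <- pmin(pmax(findInterval(emb[, 1], gx), 1L), grid_size)
  iy <- pmin(pmax(findInterval(emb[, 2], gy), 1L), grid_size)
  H <- matrix(0, grid_size, grid_size)
  for (i in seq_len(nrow(emb))) H[ix[i], iy[i]] <- H[ix[i], iy[i]] + 1
  step_x <- gx[2] - gx[1]
  step_y <- gy[2] - gy[1]
  kern <- function(step) {
    half <- max(1L, ceiling(3 * bandwidth / step))
    u <- (-half:half) * step
    k <- exp(-u^2 / (2 * bandwidth^2))
    k / sum(k)
  }
  smooth_1d <- function(M, k, along_rows) {
    half <- (length(k) - 1L) / 2
    n <- if (along_rows) nrow(M) else ncol(M)
    out <- M * 0
    for (o in -half:half) {
      w <- k[o + half + 1]
      src <- seq_len(n) - o
      ok <- src >= 1 & src <= n
      if (along_rows) {
        out[which(ok), ] <- out[which(ok), ] + w * M[src[ok], ]
      } else {
        out[, which(ok)] <- out[, which(ok)] + w * M[, src[ok]]
      }
    }
    out
  }
  D <- smooth_1d(H, kern(step_x), along_rows = TRUE)
  D <- smooth_1d(D, kern(step_y), along_rows = FALSE)
  list(density = D, gx = gx, gy = gy, ix = ix, iy = iy)
}

#' Gaussian mean-shift clustering of a 2D embedding
#'
#' Mode-seeking on a gridded Gaussian kernel-density estimate of the
#' embedding: every grid cell hill-climbs (steepest ascent over its 8
#' neighbors) to a local density maximum; maxima closer than
#' `mode_merge_tol` are merged; a point's cluster is the basin of
#' attraction of its grid cell. Deterministic for fixed inputs. Cluster
#' count is non-increasing in the bandwidth.
#'
#' @param embedding n x 2 matrix from [embed_cells()].
#' @param params an [atlas_params()]; a `NULL` bandwidth defaults to
#'   (embedding extent) / 15, extent being the larger axis range.
#' @return integer cluster labels (1..K, ordered by decreasing cluster
#'   size), with attributes `modes` (K x 2 mode coordinates) and
#'   `bandwidth`.
#' @export
gms_cluster <- function(embedding, params = atlas_params()) {
  emb <- as.matrix(embedding)
  if (!all(is.finite(emb))) stopf("embedding must be finite")
  extent <- max(apply(emb, 2, function(v) diff(range(v))))
  # default: extent/15 with a Silverman-type floor so sparse unimodal
  # embeddings are not shredded by an under-smoothed density estimate
  h <- params$gms_bandwidth %||%
    max(extent / 15, mean(apply(emb, 2, sd)) * nrow(emb)^(-1 / 6))
  if (!is.finite(h) || h <= 0) h <- 1  # degenerate embedding (all identical)
  tol <- params$mode_merge_tol %||% h
  gs <- params$grid_size
  gd <- grid_density(emb, h, gs)
  D <- gd$density
  # steepest-ascent successor of every grid cell (0 = local max)
  succ <- matrix(0L, gs, gs)
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]
  best <- D
  for (s in seq_len(nrow(shifts))) {
    dx <- shifts$dx[s]; dy <- shifts$dy[s]
    xs <- seq_len(gs); ys <- seq_len(gs)
    sx <- xs + dx; sy <- ys + dy
    okx <- sx >= 1 & sx <= gs; oky <- sy >= 1 & sy <= gs
    neigh <- matrix(-Inf, gs, gs)
    neigh[xs[okx], ys[oky]] <- D[sx[okx], sy[oky]]
    better <- neigh > best
    if (any(better)) {
      idx <- which(better)
      ii <- (idx - 1) %% gs + 1
      jj <- (idx - 1) %/% gs + 1
      succ[better] <- (jj + dy - 1L) * gs + (ii + dx)
      best[better] <- neigh[better]
    }
  }
  # path-compress each cell to its terminal mode
  root <- integer(gs * gs)
  resolve <- function(i) {
    path <- integer(0)
    while (succ[i] != 0L && root[i] == 0L) {
      path <- c(path, i)
      i <- succ[i]
    }
    r <- if (root[i] != 0L) root[i] else i
    if (length(path)) root[path] <<- r
    root[i] <<- r
    r
  }
  for (i in seq_len(gs * gs)) if (root[i] == 0L) resolve(i)
  # merge modes within tolerance
  mode_cells <- sort(unique(root))
  mx <- gd$gx[(mode_cells - 1) %% gs + 1]
  my <- gd$gy[(mode_cells - 1) %/% gs + 1]
  k <- length(mode_cells)
  mode_group <- seq_len(k)
  if (k > 1 && tol > 0) {
    hcl <- hclust(dist(cbind(mx, my)), method = "single")
    mode_group <- cutree(hcl, h = tol)
  }
  cell_idx <- (gd$iy - 1L) * gs + gd$ix
  point_mode <- root[cell_idx]
  labels <- mode_group[match(point_mode, mode_cells)]
  group_modes <- cbind(as.numeric(tapply(mx, mode_group, mean)),
                       as.numeric(tapply(my, mode_group, mean)))
  # reassign sliver clusters to the nearest retained mode
  min_size <- params$min_cluster_size %||% max(3, ceiling(0.01 * nrow(emb)))
  sizes <- tabulate(labels, nbins = nrow(group_modes))
  keep <- which(sizes >= min_size)
  if (length(keep) && length(keep) < nrow(group_modes)) {
    for (gidx in which(sizes > 0 & sizes < min_size)) {
      d2 <- (group_modes[keep, 1] - group_modes[gidx, 1])^2 +
        (group_modes[keep, 2] - group_modes[gidx, 2])^2
      labels[labels == gidx] <- keep[which.min(d2)]
    }
  }
  # relabel by decreasing size
  ord <- order(-tabulate(labels, nbins = nrow(group_modes)))
  ord <- ord[tabulate(labels, nbins = nrow(group_modes))[ord] > 0]
  relab <- match(labels, ord)
  modes <- group_modes[ord, , drop = FALSE]
  structure(as.integer(relab), modes = modes, bandwidth = h)
}

#' Scaled median cluster profiles (heatmap matrix)
#'
#' Per-cluster per-feature medians, then feature-wise min-max scaling to
#' `[0, 1]` across clusters; features whose cluster medians are all equal
#' map to 0. Scaling preserves the per-feature ranking of cluster medians.
#'
#' @param table `feature_table` or numeric matrix.
#' @param labels cluster labels, one per row.
#' @param columns feature columns to profile (default all).
#' @return clusters x features matrix in `[0, 1]`.
#' @export
cluster_profile_heatmap <- function(table, labels, columns = NULL) {
  x <- if (inherits(table, "feature_table")) {
    cols <- columns %||% feature_columns(table)
    as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  } else as.matrix(table)
  stopifnot(nrow(x) == length(labels))
  g <- factor(labels)
  med <- apply(x, 2, function(v) tapply(v, g, median))
  if (nlevels(g) == 1) med <- matrix(med, nrow = 1, dimnames = list(levels(g), colnames(x)))
  scaled <- apply(med, 2, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  })
  if (nlevels(g) == 1) scaled <- matrix(scaled, nrow = 1,
                                        dimnames = list(levels(g), colnames(med)))
  rownames(scaled) <- rownames(med)
  scaled
}

#' Hierarchical sub-clustering within a cluster
#'
#' Complete-linkage agglomeration on Euclidean distance over the selected
#' (normalized) feature columns, cut into k sub-clusters.
#'
#' @param table `feature_table` or numeric matrix, restricted to the cells
#'   of one cluster.
#' @param k number of sub-clusters (k <= number of cells).
#' @param columns feature columns (e.g. the tumor-marker subset); default
#'   all.
#' @return list: `labels` (1..k), `linkage` (the `hclust` object).
#' @export
hierarchical_subcluster <- function(table, k, columns = NULL) {
  x <- if (inherits(table, "feature_table")) {
    cols <- columns %||% feature_columns(table)
    as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  } else as.matrix(table)
  n <- nrow(x)
  if (k > n) stopf("k (%d) exceeds the number of cells (%d)", k, n)
  hc <- hclust(dist(x), method = "complete")
  list(labels = cutree(hc, k = k), linkage = hc)
}

#' Per-sample cluster composition
#'
#' Counts and proportions of each cluster per sample; proportions sum to 1
#' within each sample. An optional grouping factor (e.g. an infiltration
#' class per sample) aggregates proportions over its samples.
#'
#' @param labels per-cell cluster labels.
#' @param sample_ids per-cell sample identifiers.
#' @param group optional named vector mapping sample id -> group.
#' @return data frame: `sample_id` (or `group`), `cluster`, `n`,
#'   `proportion`, including zero rows for clusters absent from a sample.
#' @export
composition_summary <- function(labels, sample_ids, group = NULL) {
  stopifnot(length(labels) == length(sample_ids))
  if (!is.null(group)) {
    sample_ids <- unname(group[as.character(sample_ids)])
    if (anyNA(sample_ids)) stopf("every sample id needs a group")
  }
  tab <- table(sample_id = sample_ids, cluster = labels)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", "cluster", "n")
  totals <- rowSums(tab)
  df$proportion <- df$n / totals[df$sample_id]
  df[order(df$sample_id, df$cluster), , drop = FALSE]
}

#' Build the single-cell atlas
#'
#' Embedding plus Gaussian mean-shift clustering plus scaled median
#' profiles and per-sample composition, in one call.
#'
#' @param table normalized `feature_table`.
#' @param params an [atlas_params()].
#' @param columns feature columns used for the embedding.
#' @return an `atlas` list: `embedding`, `labels`, `profiles`,
#'   `composition`, `params`.
#' @export
build_atlas <- function(table, params = atlas_params(), columns = NULL) {
  emb <- embed_cells(table, params, columns = columns)
  labels <- gms_cluster(emb, params)
  profiles <- cluster_profile_heatmap(table, labels, columns = columns)
  comp <- composition_summary(labels, table$sample_id %||%
                                rep("sample", nrow(emb)))
  structure(list(embedding = emb, labels = as.integer(labels),
                 profiles = profiles, composition = comp, params = params),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("Single-cell atlas: %d cells in %d clusters\n",
              length(x$labels), length(unique(x$labels))))
  print(table(cluster = x$labels))
  invisible(x)
}
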