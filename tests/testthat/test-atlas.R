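# Embedding, Gaussian mean-shift clustering, profiles, sub-clustering,
# composition.

blob_embedding <- function(n_per = 60, centers = list(c(0, 0), c(20, 20)),
                           sd = 1, seed = 3) {
  set.seed(seed)
  do.call(rbind, lapply(centers, function(ce) {
    cbind(rnorm(n_per, ce[1], sd), rnorm(n_per, ce[2], sd))
  }))
}

test_that("identical points embed to a finite layout", {
  x <- matrix(1, 100, 4)
  emb <- embed_cells(x, atlas_params(perplexity = 10, seed = 1))
  expect_true(all(is.finite(emb)))
  expect_equal(dim(emb), c(100, 2))
})

test_that("well-separated blobs stay separated in the embedding", {
  set.seed(7)
  x <- rbind(matrix(rnorm(80 * 10, 0), ncol = 10),
             matrix(rnorm(80 * 10, 20), ncol = 10))
  labs <- rep(1:2, each = 80)
  emb <- embed_cells(x, atlas_params(seed = 2))
  sil <- cluster::silhouette(labs, dist(emb))
  expect_gte(mean(sil[, "sil_width"]), 0.5)
})

test_that("perplexity must be below the cell count", {
  x <- matrix(rnorm(100 * 3), ncol = 3)
  expect_error(embed_cells(x, atlas_params(perplexity = 200)), "perplexity")
})

test_that("embedding is deterministic under a fixed seed", {
  x <- matrix(rnorm(120 * 5), ncol = 5)
  e1 <- embed_cells(x, atlas_params(perplexity = 15, seed = 9))
  e2 <- embed_cells(x, atlas_params(perplexity = 15, seed = 9))
  expect_identical(e1, e2)
})

test_that("mean shift separates two blobs and merges one", {
  emb <- blob_embedding()
  truth <- rep(1:2, each = 60)
  labs <- gms_cluster(emb, atlas_params(gms_bandwidth = 2))
  expect_equal(length(unique(labs)), 2)
  expect_equal(adjusted_rand_index(labs, truth), 1)
  one <- blob_embedding(centers = list(c(0, 0)))
  expect_equal(length(unique(gms_cluster(one, atlas_params()))), 1)
  # very large bandwidth collapses everything into one basin
  labs_big <- gms_cluster(emb, atlas_params(gms_bandwidth = 1000))
  expect_equal(length(unique(labs_big)), 1)
  expect_error(gms_cluster(emb, atlas_params(gms_bandwidth = -1)),
               "gms_bandwidth")
})

test_that("cluster count is non-increasing in bandwidth", {
  emb <- blob_embedding(centers = list(c(0, 0), c(8, 0), c(0, 8), c(15, 15)),
                        seed = 11)
  ks <- vapply(c(0.5, 1, 2, 4, 8, 16, 32), function(h) {
    length(unique(gms_cluster(emb, atlas_params(gms_bandwidth = h))))
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("profile heatmap scales feature-wise to [0, 1]", {
  x <- cbind(f = c(1, 1, 3, 3), g = c(5, 5, 5, 5))
  labs <- c(1, 1, 2, 2)
  p <- cluster_profile_heatmap(x, labs)
  expect_equal(unname(p[, "f"]), c(0, 1))
  expect_equal(unname(p[, "g"]), c(0, 0))  # degenerate feature maps to 0
  # single cluster -> all zero
  p1 <- cluster_profile_heatmap(x, c(1, 1, 1, 1))
  expect_true(all(p1 == 0))
  # medians: odd-count cluster {2, 5, 9} has median 5
  x2 <- cbind(f = c(2, 5, 9, 0, 0, 0))
  p2 <- cluster_profile_heatmap(x2, c(1, 1, 1, 2, 2, 2))
  med <- tapply(x2[, 1], c(1, 1, 1, 2, 2, 2), median)
  expect_equal(unname(med["1"]), 5)
  expect_equal(unname(p2[, 1]), c(1, 0))
  # scaling preserves the ranking of cluster medians
  set.seed(13)
  x3 <- matrix(rnorm(90), ncol = 3)
  l3 <- rep(1:3, each = 10)
  p3 <- cluster_profile_heatmap(x3, l3)
  med3 <- apply(x3, 2, function(v) tapply(v, l3, median))
  for (j in 1:3) expect_equal(order(p3[, j]), order(med3[, j]))
})

test_that("hierarchical sub-clustering covers k = 1, k = n and planted types", {
  set.seed(19)
  x <- rbind(matrix(rnorm(20 * 4, 0), ncol = 4),
             matrix(rnorm(20 * 4, 10), ncol = 4),
             matrix(rnorm(20 * 4, 20), ncol = 4))
  truth <- rep(1:3, each = 20)
  expect_equal(length(unique(hierarchical_subcluster(x, k = 1)$labels)), 1)
  expect_equal(length(unique(hierarchical_subcluster(x, k = 60)$labels)), 60)
  sub <- hierarchical_subcluster(x, k = 3)
  expect_equal(adjusted_rand_index(sub$labels, truth), 1)
  expect_s3_class(sub$linkage, "hclust")
  expect_equal(sub$linkage$method, "complete")
  expect_error(hierarchical_subcluster(x, k = 61), "exceeds")
})

test_that("composition proportions are per-sample and sum to one", {
  labs <- c(rep("c1", 2), rep("c2", 8), rep("c1", 5))
  samp <- c(rep("s1", 10), rep("s2", 5))
  comp <- composition_summary(labs, samp)
  expect_equal(comp$proportion[comp$sample_id == "s1" & comp$cluster == "c1"],
               0.2)
  # cluster absent from a sample has proportion 0
  expect_equal(comp$proportion[comp$sample_id == "s2" & comp$cluster == "c2"],
               0)
  set.seed(23)
  for (i in 1:5) {
    labs2 <- sample(1:6, 100, replace = TRUE)
    samp2 <- sample(c("a", "b", "c"), 100, replace = TRUE)
    comp2 <- composition_summary(labs2, samp2)
    sums <- as.numeric(tapply(comp2$proportion, comp2$sample_id, sum))
    expect_equal(sums, rep(1, 3))
  }
})
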