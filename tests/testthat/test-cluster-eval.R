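# Consensus-clustering stability, F-tests, PCA contributions.

two_blob_data <- function(n_per = 100, d = 10, sep = 8, seed = 42) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * d, 0), ncol = d),
        matrix(rnorm(n_per * d, sep), ncol = d))
}

test_that("mean clustering score corner cases and arithmetic", {
  expect_equal(compute_mcs(0, 1, 1), 1)
  expect_equal(compute_mcs(1, 0, 0), 0)
  expect_equal(compute_mcs(0.4, 0.8, 0.5), (0.6 + 0.8 + 0.5) / 3)
  expect_equal(compute_mcs(0.4, 0.8, 0.5), 0.6333333, tolerance = 1e-6)
  # bounds of the score
  expect_equal(compute_mcs(1, 0, -1), -1 / 3)
  expect_error(compute_mcs(1.2, 0, 0))
})

test_that("MCS strictly decreases in PAC at fixed CON and MSS", {
  pacs <- seq(0, 1, by = 0.1)
  vals <- vapply(pacs, compute_mcs, numeric(1), CON = 0.7, MSS = 0.4)
  expect_true(all(diff(vals) < 0))
})

test_that("PAC trivial cases from hand-built consensus matrices", {
  fake_result <- function(M, partitions, consensus) {
    structure(list(consensus_matrix = M, repeat_partitions = partitions,
                   consensus_partition = consensus,
                   spec = consensus_spec(n_clusters = 2)),
              class = "consensus_result")
  }
  bin <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  cons <- c(1, 1, 2, 2)
  m <- stability_metrics(fake_result(bin, list(cons), cons))
  expect_equal(m$PAC, 0)
  expect_equal(m$CON, 1)  # every repeat equals the consensus
  half <- matrix(0.5, 4, 4); diag(half) <- 1
  m2 <- stability_metrics(fake_result(half, list(cons), cons))
  expect_equal(m2$PAC, 1)
  # single-cluster consensus partition: MSS defined as 0 with warning
  expect_warning(
    m3 <- stability_metrics(fake_result(bin, list(rep(1, 4)), rep(1, 4))),
    "single-cluster")
  expect_equal(m3$MSS, 0)
})

test_that("a single repeat gives a binary consensus and PAC 0", {
  x <- two_blob_data(40, d = 5, seed = 2)
  res <- run_consensus(x, consensus_spec(n_repeats = 1, n_clusters = 2,
                                         perplexity = 10, seed = 3))
  expect_true(all(res$consensus_matrix %in% c(0, 1)))
  expect_equal(stability_metrics(res)$PAC, 0)
})

test_that("consensus matrix is symmetric with unit diagonal", {
  x <- two_blob_data(30, d = 5, seed = 6)
  res <- run_consensus(x, consensus_spec(n_repeats = 5, n_clusters = 2,
                                         perplexity = 8, seed = 1))
  M <- res$consensus_matrix
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 1))
  expect_true(all(M >= 0 & M <= 1))
})

test_that("well-separated blobs are stable; isotropic noise is not", {
  x <- two_blob_data(100, d = 10, sep = 8)
  res_blob <- run_consensus(x, consensus_spec(n_repeats = 20, n_clusters = 2,
                                              seed = 1))
  m_blob <- stability_metrics(res_blob)
  off <- res_blob$consensus_matrix[upper.tri(res_blob$consensus_matrix)]
  expect_true(all(off < 0.05 | off > 0.95))
  expect_lte(m_blob$PAC, 0.05)

  set.seed(101)
  noise <- matrix(rnorm(200 * 10), ncol = 10)
  res_noise <- run_consensus(noise, consensus_spec(n_repeats = 20,
                                                   n_clusters = 10, seed = 1))
  m_noise <- stability_metrics(res_noise)
  expect_gt(m_noise$PAC, 0.2)
  expect_gt(m_noise$PAC, m_blob$PAC)
  expect_gt(m_blob$MCS, m_noise$MCS)
  assign("consensus_separation",
         list(blob = m_blob, noise = m_noise), envir = .fixture_cache)
})

test_that("F statistics match a hand-computed one-way ANOVA", {
  x <- cbind(v = c(1, 2, 3, 11, 12, 13))
  labs <- c(1, 1, 1, 2, 2, 2)
  out <- feature_significance(x, labs)
  # SSB = 150 on 1 df, MSW = 1 on 4 df -> F = 150
  expect_equal(out$F[1], 150)
  expect_lt(out$p_adj[1], 0.05)
})

test_that("constant features are never significant; planted shifts are", {
  set.seed(33)
  n_per <- 100
  labs <- rep(1:5, each = n_per)
  shifted <- rnorm(5 * n_per) + ifelse(labs == 3, 5, 0)  # 5 sigma shift
  x <- cbind(const = rep(2, 5 * n_per), shifted = shifted,
             noise = rnorm(5 * n_per))
  out <- feature_significance(x, labs)
  expect_false(out$significant[out$feature == "const"])
  expect_equal(out$max_difference[out$feature == "const"], 0)
  expect_true(out$significant[out$feature == "shifted"])
  expect_gt(out$max_difference[out$feature == "shifted"], 1)
  expect_error(feature_significance(x, rep(1, 5 * n_per)), "at least 2")
})

test_that("PCA contributions: single informative feature takes 100% of PC1", {
  set.seed(4)
  x <- cbind(a = rnorm(50), b = rep(1, 50), c = rep(3, 50))
  expect_warning(out <- pca_contributions(x), "constant")
  expect_equal(sort(out$dropped), c("b", "c"))
  # with the constants dropped, the lone varying feature owns PC1 entirely
  expect_equal(unname(out$contributions["a", 1]), 100)
  # autoscaled total variance equals the number of retained features
  x3 <- matrix(rnorm(300), ncol = 3)
  fit <- prcomp(x3, scale. = TRUE)
  expect_equal(sum(fit$sdev^2), 3)
})

test_that("isotropic Gaussians spread variance evenly across components", {
  set.seed(12)
  x <- matrix(rnorm(2000 * 5), ncol = 5)
  out <- pca_contributions(x)
  expect_true(all(abs(out$variance_explained - 0.2) < 0.03))
  # contributions sum to 100 per component
  expect_equal(unname(colSums(out$contributions)), rep(100, 5))
})

test_that("informative feature sets cluster more stably than pure noise", {
  fx <- easy_fixture()
  tab <- fx$result$normalized
  cols <- feature_columns(tab)
  m20 <- grep("_M20_", cols, value = TRUE)
  m20 <- m20[!grepl("^PI_", m20)]
  spec_inf <- consensus_spec(feature_columns = m20, n_repeats = 8,
                             n_clusters = 4, seed = 2)
  res_inf <- run_consensus(tab, spec_inf)
  mcs_inf <- stability_metrics(res_inf)$MCS
  set.seed(55)
  noise_tab <- matrix(rnorm(nrow(tab) * length(m20)), nrow = nrow(tab))
  res_noise <- run_consensus(noise_tab,
                             consensus_spec(n_repeats = 8, n_clusters = 4,
                                            seed = 2))
  mcs_noise <- stability_metrics(res_noise)$MCS
  expect_gt(mcs_inf, mcs_noise)
})
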