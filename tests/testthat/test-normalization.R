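# Negative-control ratio and exclusive-counterpart background normalization.

test_that("NC-ratio normalization divides by the matched NC feature", {
  tab <- fake_table(10)
  tab$A_ME_cell <- 8
  tab$NCA_ME_cell <- 2
  cfg <- normalization_config(nc_pairs = c(A = "NCA"), eps = 1e-9)
  out <- nc_ratio_normalize(tab, cfg)
  expect_equal(out$A_ME_cell, rep(4, 10), tolerance = 1e-8)
  expect_false(any(grepl("^NCA_", names(out))))  # NC columns dropped
  # NC == 1 is the identity
  tab2 <- fake_table(5)
  for (s in melcpipe:::stat_suffixes()) tab2[[paste0("NCA_", s)]] <- 1
  out2 <- nc_ratio_normalize(tab2, cfg)
  expect_equal(out2$A_M20_cyto, tab2$A_M20_cyto)
  # morphology untouched, unpaired marker untouched
  expect_equal(out2$B_ME_cell, tab2$B_ME_cell)
})

test_that("zero NC features are guarded and flagged", {
  tab <- fake_table(4)
  for (s in melcpipe:::stat_suffixes()) tab[[paste0("NCA_", s)]] <- 0
  cfg <- normalization_config(nc_pairs = c(A = "NCA"), eps = 1e-6)
  out <- nc_ratio_normalize(tab, cfg)
  expect_true(all(is.finite(out$A_ME_cell)))
  expect_true(all(out$nc_zero))
})

test_that("missing NC columns are a config error", {
  tab <- fake_table(4)
  cfg <- normalization_config(nc_pairs = c(B = "NCB"))
  expect_error(nc_ratio_normalize(tab, cfg), "missing")
})

test_that("background level separates planted positive and negative cells", {
  # counterpart-positive cells carry marker ~ N(10, 1); true positives
  # ~ N(100, 5); threshold must fall between and classify with >= 0.99
  tab <- fake_table(500, seed = 3, a_pos_mean = 100, a_neg_mean = 10)
  cfg <- normalization_config(exclusive_pairs = c(A = "B"))
  lev <- estimate_background_levels(tab, cfg)
  expect_equal(nrow(lev), 1)
  b <- lev$b[1]
  expect_gt(b, 10)
  expect_lt(b, 100)
  pred_pos <- tab$A_M20_cyto > b
  truth <- attr(tab, "positive")
  # every true positive clears the background level; false-positive rate
  # among negatives is bounded by the 1 - q_background tail by construction
  expect_equal(mean(pred_pos[truth]), 1)
  expect_gte(mean(pred_pos == truth), 0.95)
})

test_that("insufficient reference populations warn and pass through", {
  tab <- fake_table(10)
  cfg <- normalization_config(exclusive_pairs = c(A = "B"),
                              min_reference_cells = 20)
  expect_warning(lev <- estimate_background_levels(tab, cfg), "insufficient")
  expect_true(all(is.na(lev$b)))
  expect_warning(out <- apply_background_normalization(tab, lev),
                 "passed through")
  expect_equal(out$A_ME_cell, tab$A_ME_cell)
})

test_that("an identically-zero marker in reference cells hits the eps floor", {
  tab <- fake_table(100)
  for (s in melcpipe:::stat_suffixes()) tab[[paste0("A_", s)]] <- 0
  cfg <- normalization_config(exclusive_pairs = c(A = "B"))
  lev <- estimate_background_levels(tab, cfg)
  expect_equal(lev$b, cfg$eps)
  expect_true(lev$flagged)
})

test_that("a feature equal to its background level maps to 1", {
  tab <- fake_table(50)
  lev <- data.frame(sample_id = "s1", fov_id = "f1", marker = "A",
                    b = 7, n_reference = 25, flagged = FALSE)
  tab$A_ME_cell <- 7
  out <- suppressWarnings(apply_background_normalization(tab, lev))
  expect_equal(out$A_ME_cell, rep(1, 50))
})

test_that("a planted x3 batch gain is removed by per-image normalization", {
  t1 <- fake_table(400, sample_id = "s1", seed = 11)
  t2 <- fake_table(400, sample_id = "s2", seed = 11)
  suf <- melcpipe:::stat_suffixes()
  for (s in suf) {  # planted multiplicative batch effect on image 2
    t2[[paste0("A_", s)]] <- t2[[paste0("A_", s)]] * 3
    t2[[paste0("B_", s)]] <- t2[[paste0("B_", s)]] * 3
  }
  tab <- rbind(t1, t2)
  class(tab) <- c("feature_table", "data.frame")
  cfg <- normalization_config(exclusive_pairs = c(A = "B"))
  lev <- estimate_background_levels(tab, cfg)
  out <- suppressWarnings(apply_background_normalization(tab, lev))
  pos <- rep(attr(t1, "positive"), 2)
  med1 <- median(out$A_M20_cyto[out$sample_id == "s1" & pos])
  med2 <- median(out$A_M20_cyto[out$sample_id == "s2" & pos])
  expect_lt(abs(med1 - med2) / med1, 0.10)
  # pre-normalization disagreement was ~3x
  pre1 <- median(tab$A_M20_cyto[tab$sample_id == "s1" & pos])
  pre2 <- median(tab$A_M20_cyto[tab$sample_id == "s2" & pos])
  expect_gt(abs(pre1 - pre2) / pre1, 1.5)
})

test_that("normalization is scale-equivariant within an image", {
  tab <- fake_table(300, seed = 5)
  cfg <- normalization_config(nc_pairs = c(A = "NCA"),
                              exclusive_pairs = c(A = "B"), eps = 1e-12)
  norm1 <- normalize_features(tab, cfg)
  tab2 <- tab
  for (col in grep("_(ME|TO|M20)_", names(tab2), value = TRUE)) {
    tab2[[col]] <- tab2[[col]] * 4.2
  }
  norm2 <- normalize_features(tab2, cfg)
  expect_equal(norm2$table$A_M20_cyto, norm1$table$A_M20_cyto,
               tolerance = 1e-9)
})

test_that("per-image normalization preserves within-image cell ordering", {
  tab <- fake_table(200, seed = 6)
  cfg <- normalization_config(nc_pairs = c(A = "NCA"),
                              exclusive_pairs = c(A = "B"))
  out <- normalize_features(tab, cfg)$table
  expect_equal(order(out$A_TO_cell), order(tab$A_TO_cell))
})

test_that("batch CV of positive-cell medians strictly decreases", {
  gains <- c(0.5, 1, 2, 3)
  tabs <- lapply(seq_along(gains), function(i) {
    t <- fake_table(300, sample_id = paste0("s", i), seed = 20)
    for (s in melcpipe:::stat_suffixes()) {
      t[[paste0("A_", s)]] <- t[[paste0("A_", s)]] * gains[i]
      t[[paste0("B_", s)]] <- t[[paste0("B_", s)]] * gains[i]
    }
    t
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("feature_table", "data.frame")
  pos <- rep(attr(tabs[[1]], "positive"), length(gains))
  cfg <- normalization_config(exclusive_pairs = c(A = "B"))
  lev <- estimate_background_levels(tab, cfg)
  out <- suppressWarnings(apply_background_normalization(tab, lev))
  cv <- function(t) {
    meds <- tapply(t$A_M20_cyto[pos], t$sample_id[pos], median)
    sd(meds) / mean(meds)
  }
  expect_lt(cv(out), cv(tab))
})
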