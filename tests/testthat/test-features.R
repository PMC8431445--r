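# Morphology and compartment-resolved intensity features.

test_that("morphology closed forms: square, single pixel, plus shape", {
  d <- c(12L, 12L)
  sq <- as.vector(outer(3:6, (3:6 - 1) * d[1], "+"))  # 4x4 square
  m <- compute_morphology(sq, sq, d)
  expect_equal(unname(m["nucleus_size"]), 16)
  expect_equal(unname(m["nucleus_perimeter"]), 16)
  expect_equal(unname(m["nucleus_roundness"]), pi / 4)
  expect_equal(unname(m["nucleus_solidity"]), 1)

  px <- 5L + (5L - 1L) * d[1]
  m1 <- compute_morphology(px, px, d)
  expect_equal(unname(m1["nucleus_size"]), 1)
  expect_equal(unname(m1["nucleus_perimeter"]), 4)
  expect_equal(unname(m1["nucleus_roundness"]), pi / 4)
  expect_equal(unname(m1["nucleus_solidity"]), 1)

  # plus-shaped cross: convex hull of the unit squares is the 3x3 square
  # minus four corner triangles of area 1/2 -> hull area 7
  plus <- c(5L + 5L * d[1], 4L + 6L * d[1], 5L + 6L * d[1], 6L + 6L * d[1],
            5L + 7L * d[1])
  mp <- compute_morphology(plus, plus, d)
  expect_equal(unname(mp["nucleus_size"]), 5)
  expect_equal(unname(mp["nucleus_solidity"]), 5 / 7)
  expect_error(compute_morphology(integer(0), plus, d), "nonempty")
})

test_that("intensity statistics match their closed forms", {
  img <- matrix(0, 10, 10)
  nucpx <- 1:10
  img[nucpx] <- 1:10
  f <- compute_intensity(img, nucpx, nucpx)
  expect_equal(unname(f["ME_nucleus"]), 5.5)
  expect_equal(unname(f["TO_nucleus"]), 55)
  expect_equal(unname(f["M20_nucleus"]), 9.5)  # mean of {9, 10}
  # constant compartment: ME = M20 = c, TO = c*n
  img2 <- matrix(3, 6, 6)
  f2 <- compute_intensity(img2, 1:12, 1:4)
  expect_equal(unname(f2["ME_cell"]), 3)
  expect_equal(unname(f2["TO_cell"]), 36)
  expect_equal(unname(f2["M20_cell"]), 3)
})

test_that("total intensity is additive over compartments", {
  set.seed(8)
  img <- matrix(runif(64), 8, 8)
  cellpx <- 1:12
  nucpx <- 3:6
  f <- compute_intensity(img, cellpx, nucpx)
  expect_equal(unname(f["TO_cell"]), unname(f["TO_nucleus"] + f["TO_cyto"]))
  # empty cytoplasm flags and zeroes
  f0 <- compute_intensity(img, nucpx, nucpx)
  expect_true(attr(f0, "cyto_empty"))
  expect_equal(unname(f0["TO_cyto"]), 0)
})

test_that("feature table has 6 + 9 * n_markers feature columns", {
  sc <- tiny_scene(n = 6, size = 128)
  run <- render_run(sc)
  tab <- reconcile_masks(sc$true_cell_mask, sc$true_nucleus_mask)
  ft1 <- build_feature_table(run, tab, sc$true_cell_mask,
                             sc$true_nucleus_mask, markers = "CD45")
  expect_equal(length(feature_columns(ft1)), 15)
  ft_all <- build_feature_table(run, tab, sc$true_cell_mask,
                                sc$true_nucleus_mask)
  n_markers <- length(run$cycles)
  expect_equal(length(feature_columns(ft_all)), 6 + 9 * n_markers)
  expect_equal(nrow(ft_all), 6)
  # 20 markers -> 186 feature columns (arithmetic contract)
  expect_equal(6 + 9 * 20, 186)
  expect_error(build_feature_table(run, tab, sc$true_cell_mask,
                                   sc$true_nucleus_mask, markers = "CD99"),
               "missing from run")
})

test_that("zero kept cells yield an empty table with a complete header", {
  sc <- tiny_scene(n = 3, size = 128)
  run <- render_run(sc)
  empty_tab <- reconcile_masks(matrix(0L, 128, 128), matrix(0L, 128, 128))
  ft <- build_feature_table(run, empty_tab, matrix(0L, 128, 128),
                            matrix(0L, 128, 128))
  expect_equal(nrow(ft), 0)
  expect_equal(length(feature_columns(ft)), 6 + 9 * length(run$cycles))
})

test_that("features match a naive per-pixel oracle on random masks", {
  set.seed(77)
  for (case in 1:100) {
    size <- sample(12:24, 1)
    cellm <- random_blob_mask(size, sample(1:3, 1), seed = 1000 + case)
    channel <- matrix(runif(size * size, 0, 100), size, size)
    for (lab in setdiff(unique(as.vector(cellm)), 0)) {
      px <- which(cellm == lab)
      # intensity oracle
      got <- compute_intensity(channel, px, px[1])
      want <- oracle_intensity(channel, px)
      expect_equal(unname(got["ME_cell"]), unname(want["ME"]))
      expect_equal(unname(got["TO_cell"]), unname(want["TO"]))
      expect_equal(unname(got["M20_cell"]), unname(want["M20"]))
      # perimeter oracle
      m <- compute_morphology(px, px, c(size, size))
      expect_equal(unname(m["cell_perimeter"]),
                   oracle_perimeter(cellm == lab))
    }
  }
})

test_that("M20 >= ME with equality only for constant compartments", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    img <- matrix(runif(100, 0, 10), 10, 10)
    px <- sample(100, n)
    f <- compute_intensity(img, px, px)
    expect_gte(f[["M20_cell"]], f[["ME_cell"]])
    if (n > 5) expect_gt(f[["M20_cell"]], f[["ME_cell"]])
  }
})

test_that("morphology ignores intensities; intensities ignore label ids", {
  sc <- tiny_scene(n = 5, size = 128)
  run <- render_run(sc)
  tab <- reconcile_masks(sc$true_cell_mask, sc$true_nucleus_mask)
  ft <- build_feature_table(run, tab, sc$true_cell_mask, sc$true_nucleus_mask)
  # relabel masks (reverse order): intensity features per cell unchanged
  remap <- c(0L, rev(seq_len(5)))
  cm2 <- matrix(remap[sc$true_cell_mask + 1L], 128, 128)
  nm2 <- matrix(remap[sc$true_nucleus_mask + 1L], 128, 128)
  tab2 <- reconcile_masks(cm2, nm2)
  ft2 <- build_feature_table(run, tab2, cm2, nm2)
  cols <- feature_columns(ft)
  a <- ft[order(ft$cell_label), cols]
  b <- ft2[order(ft2$cell_label, decreasing = TRUE), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
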