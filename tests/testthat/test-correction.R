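# Registration, flat-field, bleach subtraction and vignetting correction.

test_that("registration of identical cycles yields zero shifts", {
  sc <- tiny_scene(n = 8, size = 128)
  run <- render_run(sc)
  reg <- register_run(run)
  expect_true(all(reg$shifts$dx == 0))
  expect_true(all(reg$shifts$dy == 0))
  expect_equal(reg$run$cycles[[2]]$tag_image, run$cycles[[2]]$tag_image)
})

test_that("planted rigid shifts are recovered exactly on noiseless cycles", {
  sc <- tiny_scene(n = 12, size = 128)
  shifts <- matrix(0L, nrow(sc$panel), 2)
  shifts[2, ] <- c(3L, -2L)
  shifts[4, ] <- c(-5L, 7L)
  run <- render_run(sc, shifts = shifts)
  reg <- register_run(run)
  expect_equal(reg$shifts$dx[2], -3L)
  expect_equal(reg$shifts$dy[2], 2L)
  expect_equal(reg$shifts$dx[4], 5L)
  expect_equal(reg$shifts$dy[4], -7L)
  # residual misalignment is zero away from the filled border
  ref <- render_run(sc)
  inner <- 20:108
  expect_equal(reg$run$cycles[[2]]$tag_image[inner, inner],
               ref$cycles[[2]]$tag_image[inner, inner], tolerance = 1e-9)
})

test_that("shifts beyond max_shift flag registration failure", {
  sc <- tiny_scene(n = 10, size = 128)
  shifts <- matrix(0L, nrow(sc$panel), 2)
  shifts[3, ] <- c(40L, 0L)
  run <- render_run(sc, shifts = shifts)
  expect_error(register_run(run, max_shift = 30), "registration failed")
  expect_warning(reg <- register_run(run, max_shift = 30, on_fail = "drop"),
                 "registration failed")
  expect_equal(length(reg$run$cycles), length(run$cycles) - 1)
})

test_that("flat-field correction matches its closed forms", {
  calib <- calibration_images(brightfield = matrix(190, 8, 8),
                              darkframe = matrix(10, 8, 8))
  out <- flat_field_correct(matrix(100, 8, 8), calib)
  expect_equal(out, matrix(90, 8, 8))
  expect_equal(flat_field_correct(matrix(10, 8, 8), calib), matrix(0, 8, 8))
  expect_error(flat_field_correct(matrix(1, 4, 4), calib), "dimensions")
})

test_that("flat-field recovers a planted signal under nonuniform gain", {
  set.seed(3)
  g <- melcpipe:::vignette_field(64, 0.5) * runif(1, 80, 120)
  dark <- matrix(7, 64, 64)
  s <- matrix(rep(seq(1, 5, length.out = 64), each = 64), 64, 64)
  calib <- calibration_images(brightfield = g + dark, darkframe = dark)
  out <- flat_field_correct(dark + g * s, calib)
  expect_equal(out, s * mean(g), tolerance = 1e-12)
})

test_that("bleach subtraction clips at zero and passes through first cycle", {
  expect_equal(subtract_bleach(matrix(50, 4, 4), matrix(20, 4, 4)),
               matrix(30, 4, 4))
  expect_equal(subtract_bleach(matrix(10, 4, 4), matrix(15, 4, 4)),
               matrix(0, 4, 4))
  expect_equal(subtract_bleach(matrix(10, 4, 4), NULL), matrix(10, 4, 4))
  expect_error(subtract_bleach(matrix(1, 4, 4), matrix(1, 5, 5)), "dimensions")
})

test_that("gain estimation recovers a planted radial vignette", {
  stack <- render_gain_stack(alpha = 0.4, n_images = 20, image_size = 256,
                             seed = 0)
  vc <- correct_vignetting(stack$images)
  expect_gte(cor(as.vector(vc$gain), as.vector(stack$true_gain)), 0.95)
  flat <- matrix(100, 256, 256) * stack$true_gain
  cc <- correct_vignetting(list(flat), gain = vc$gain)
  cv <- sd(cc$corrected[[1]]) / mean(cc$corrected[[1]])
  expect_lt(cv, 0.05)
})

test_that("gain estimation near-identity on an unshaded stack", {
  stack <- render_gain_stack(alpha = 0, n_images = 20, image_size = 128,
                             seed = 1)
  vc <- correct_vignetting(stack$images)
  rel <- abs(vc$corrected[[1]] - stack$images[[1]]) /
    pmax(stack$images[[1]], 1e-9)
  expect_lt(max(rel), 0.01)
})

test_that("gain estimation refuses a single image", {
  expect_error(correct_vignetting(list(matrix(1, 16, 16))),
               "insufficient images")
  expect_warning(out <- correct_vignetting(list(matrix(2, 16, 16)),
                                           estimate = FALSE),
                 "disabled")
  expect_equal(out$corrected[[1]], matrix(2, 16, 16))
})

test_that("corrections are nonnegative and idempotent in the flat limit", {
  sc <- tiny_scene(alpha = 0.3, rho = 0.2, n = 15)
  run <- render_run(sc)
  corr <- correct_run(run, register = FALSE)
  for (cy in corr$run$cycles) expect_true(all(cy$tag_image >= 0))
  # already-flat input (no shading, no dark offset): correction is identity
  flat_calib <- calibration_images(brightfield = matrix(180, 64, 64),
                                   darkframe = matrix(0, 64, 64))
  img <- matrix(runif(64 * 64, 0, 50), 64, 64)
  once <- flat_field_correct(img, flat_calib)
  expect_equal(once, img, tolerance = 1e-12)
  expect_equal(flat_field_correct(once, flat_calib), once, tolerance = 1e-12)
})

test_that("noiseless correction chain recovers planted signal to 1e-6", {
  sc <- tiny_scene(alpha = 0.4, rho = 0.3, n = 20)
  run <- render_run(sc)
  corr <- correct_run(run, register = FALSE)
  g <- melcpipe:::vignette_field(sc$params$image_size, 0.4)
  scale_factor <- mean(sc$params$brightfield_level * g) /
    sc$params$brightfield_level
  for (k in seq_along(run$cycles)) {
    S <- melcpipe:::scene_signal_image(sc, run$cycles[[k]]$marker)
    expected <- S * scale_factor
    denom <- max(expected)
    if (denom == 0) next
    rel <- max(abs(corr$run$cycles[[k]]$tag_image - expected)) / denom
    expect_lt(rel, 1e-6)
  }
})

test_that("registration commutes with flat-field on translation-free runs", {
  sc <- tiny_scene(n = 10, size = 128)
  run <- render_run(sc)
  a <- correct_run(run, register = TRUE)$run$cycles[[3]]$tag_image
  reg_first <- register_run(run)$run
  b <- correct_run(reg_first, register = FALSE)$run$cycles[[3]]$tag_image
  expect_equal(a, b, tolerance = 1e-6)
})
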