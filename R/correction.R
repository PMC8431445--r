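# Image correction: registration, flat-field, post-bleach background
# subtraction and vignetting correction.

#' Estimate a rigid translation by phase correlation
#'
#' Integer-pixel phase correlation between two images of identical shape.
#' @param reference,moving numeric matrices.
#' @return integer vector `c(dx, dy)`: the translation that maps
#'   `reference` onto `moving` (i.e. `moving` appears shifted by `(dx, dy)`).
#' @export
phase_correlation_shift <- function(reference, moving) {
  assert_same_shape(reference, moving, "registration images")
  f1 <- stats::fft(reference)
  f2 <- stats::fft(moving)
  cross <- f2 * Conj(f1)
  denom <- Mod(cross)
  denom[denom < .Machine$double.eps] <- 1
  corr <- Re(stats::fft(cross / denom, inverse = TRUE))
  peak <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  d <- dim(reference)
  wrap <- function(i, n) {
    s <- i - 1L
    if (s > n / 2) s - n else s
  }
  # rows = y, columns = x
  c(dx = wrap(peak[2], d[2]), dy = wrap(peak[1], d[1]))
}

#' Register a MELC run against a reference cycle
#'
#' One rigid integer translation is estimated per cycle from the
#' phase-contrast images against the reference cycle's phase image and
#' applied identically to that cycle's tag, post-bleach and phase images.
#' Out-of-frame pixels are filled with 0 and recorded in a per-cycle
#' validity mask.
#'
#' @param run a `melc_run` with at least 2 cycles.
#' @param reference_cycle index (position in the cycle list) of the
#'   reference cycle; default first.
#' @param max_shift maximum plausible |shift| per axis in pixels; a larger
#'   estimate flags the cycle as failed.
#' @param on_fail `"error"` (default), `"drop"` (remove the cycle) or
#'   `"keep"` (keep unregistered, flagged).
#' @return list with `run` (registered), `shifts` (data frame: `index`,
#'   `marker`, `dx`, `dy`, `failed` — `dx`/`dy` are the applied correction,
#'   the negative of the apparent displacement), and `validity` (logical
#'   matrix, TRUE where every kept cycle has real data).
#' @export
register_run <- function(run, reference_cycle = 1, max_shift = 30,
                         on_fail = c("error", "drop", "keep")) {
  on_fail <- match.arg(on_fail)
  stopifnot(inherits(run, "melc_run"))
  if (length(run$cycles) < 2) stopf("registration needs at least 2 cycles")
  if (reference_cycle < 1 || reference_cycle > length(run$cycles)) {
    stopf("reference cycle %s does not exist", reference_cycle)
  }
  ref <- run$cycles[[reference_cycle]]$phase_image
  validity <- matrix(TRUE, nrow(ref), ncol(ref))
  rows <- list()
  new_cycles <- list()
  for (k in seq_along(run$cycles)) {
    cy <- run$cycles[[k]]
    s <- phase_correlation_shift(ref, cy$phase_image)
    failed <- any(abs(s) > max_shift)
    if (failed && on_fail == "error") {
      stopf("registration failed for cycle %d (%s): estimated shift (%d, %d) exceeds max_shift %d",
            cy$index, cy$marker, s[1], s[2], max_shift)
    }
    apply_shift <- !failed && any(s != 0)
    if (apply_shift) {
      for (field in c("tag_image", "postbleach_image", "phase_image")) {
        cy[[field]] <- shift_image(cy[[field]], -s[1], -s[2], fill = 0)
      }
      validity <- validity & shift_image(matrix(TRUE, nrow(ref), ncol(ref)),
                                         -s[1], -s[2], fill = FALSE)
    }
    rows[[k]] <- data.frame(index = cy$index, marker = cy$marker,
                            dx = if (failed) NA_integer_ else -s[1],
                            dy = if (failed) NA_integer_ else -s[2],
                            failed = failed)
    if (!(failed && on_fail == "drop")) new_cycles[[length(new_cycles) + 1L]] <- cy
  }
  shifts <- do.call(rbind, rows)
  if (any(shifts$failed) && on_fail != "error") {
    warnf("%d cycle(s) flagged 'registration failed'", sum(shifts$failed))
  }
  run$cycles <- new_cycles
  list(run = run, shifts = shifts, validity = validity)
}

#' Flat-field correction from calibration images
#'
#' `corrected = (image - dark) / max(bright - dark, eps) * mean(bright - dark)`,
#' with negatives clipped to 0. The rescaling by `mean(bright - dark)`
#' preserves the input's intensity scale.
#'
#' @param image numeric matrix.
#' @param calibration a [calibration_images()] pair, same shape as `image`.
#' @param eps guard for near-zero flat-field denominators; default `1e-6`
#'   of the brightfield dynamic range.
#' @return corrected image (nonnegative).
#' @export
flat_field_correct <- function(image, calibration, eps = NULL) {
  assert_image(image)
  assert_same_shape(image, calibration$brightfield, "image and calibration")
  flat <- calibration$brightfield - calibration$darkframe
  if (is.null(eps)) {
    eps <- 1e-6 * max(diff(range(calibration$brightfield)), 1)
  }
  corrected <- (image - calibration$darkframe) / pmax(flat, eps) * mean(flat)
  pmax(corrected, 0)
}

#' Subtract residual post-bleach background
#'
#' Removes accumulative background from incompletely bleached previous
#' cycles: `max(tag - postbleach_prev, 0)`, pixelwise. The first cycle of a
#' run has no prior post-bleach image and passes through unchanged (handled
#' by [correct_run()]).
#'
#' @param tag_image fluorescence tag image of cycle c.
#' @param postbleach_prev post-bleach image of cycle c - 1, or `NULL` for
#'   the first cycle (identity).
#' @return corrected image (nonnegative).
#' @export
subtract_bleach <- function(tag_image, postbleach_prev = NULL) {
  assert_image(tag_image)
  if (is.null(postbleach_prev)) return(pmax(tag_image, 0))
  assert_same_shape(tag_image, postbleach_prev, "tag and post-bleach images")
  pmax(tag_image - postbleach_prev, 0)
}

#' Construct a gain field
#'
#' A strictly positive multiplicative shading field, mean-normalized to 1.
#' @param gain positive numeric matrix.
#' @return a `gain_field` matrix (mean exactly 1 up to 1e-9).
#' @export
gain_field <- function(gain) {
  assert_image(gain, "gain")
  if (any(gain <= 0)) stopf("gain field must be strictly positive")
  g <- gain / mean(gain)
  structure(g, class = c("gain_field", "matrix", "array"))
}

# Least-squares polynomial surface fit used as the heavy smoothing step of
# gain estimation; degree 2 spans the radial-falloff family exactly.
fit_polynomial_surface <- function(z, degree = 2) {
  d <- dim(z)
  ys <- (rep(seq_len(d[1]), times = d[2]) - (d[1] + 1) / 2) / d[1]
  xs <- (rep(seq_len(d[2]), each = d[1]) - (d[2] + 1) / 2) / d[2]
  terms <- list(rep(1, length(xs)))
  for (total in seq_len(degree)) {
    for (i in 0:total) terms[[length(terms) + 1L]] <- xs^(total - i) * ys^i
  }
  X <- do.call(cbind, terms)
  beta <- qr.coef(qr(X), as.vector(z))
  matrix(X %*% beta, d[1], d[2])
}

#' Estimate and correct multiplicative vignetting from an image stack
#'
#' Retrospective shading correction standing in for regularized
#' energy-minimization methods: each image is normalized by its mean, a
#' per-pixel median across the stack gives a robust raw shading estimate,
#' and a low-order polynomial surface fit supplies the heavy smoothing. The
#' resulting mean-normalized gain divides every image. A precomputed gain
#' map can be supplied instead of estimating.
#'
#' @param images list of numeric matrices (the fluorescence tag stack).
#' @param gain optional precomputed [gain_field()] (or positive matrix);
#'   skips estimation.
#' @param min_images minimum stack size for estimation (default 8).
#' @param degree degree of the smoothing polynomial surface (default 2,
#'   matching a radial quadratic falloff).
#' @param estimate set `FALSE` to disable estimation: images pass through
#'   unchanged with a warning and a unit gain is returned.
#' @return list with `corrected` (list of images) and `gain` (`gain_field`).
#' @export
correct_vignetting <- function(images, gain = NULL, min_images = 8,
                               degree = 2, estimate = TRUE) {
  if (is_image(images)) images <- list(images)
  stopifnot(length(images) >= 1)
  d <- dim(images[[1]])
  if (is.null(gain)) {
    if (!estimate) {
      warnf("vignetting estimation disabled; images passed through uncorrected")
      gain <- gain_field(matrix(1, d[1], d[2]))
    } else {
      if (length(images) < min_images) {
        stopf("insufficient images for gain estimation: %d < %d",
              length(images), min_images)
      }
      stack <- vapply(images, function(im) {
        m <- mean(im)
        as.vector(im / max(m, .Machine$double.eps))
      }, numeric(prod(d)))
      raw <- matrix(apply(stack, 1, median), d[1], d[2])
      smooth <- fit_polynomial_surface(raw, degree = degree)
      smooth <- pmax(smooth, 0.05 * max(smooth))
      gain <- gain_field(smooth)
    }
  } else if (!inherits(gain, "gain_field")) {
    gain <- gain_field(gain)
  }
  corrected <- lapply(images, function(im) im / gain)
  list(corrected = corrected, gain = gain)
}

#' Run all image corrections on a MELC run
#'
#' Stages, in order: (1) registration of all cycles to a reference cycle
#' (phase correlation on phase-contrast images); (2) flat-field correction
#' of tag and post-bleach images from the calibration pair; (3) post-bleach
#' background subtraction (cycle c tag minus cycle c-1 post-bleach, first
#' cycle unchanged); (4) vignetting correction. With `vignette = "auto"`
#' (default), stack-based gain estimation runs only when flat-fielding was
#' skipped or no calibration exists — a calibration brightfield already
#' captures the multiplicative shading, and re-estimating residual gain from
#' corrected images would only add estimation noise.
#'
#' @param run a `melc_run`.
#' @param register register cycles first (default TRUE when >= 2 cycles).
#' @param reference_cycle,max_shift,on_fail see [register_run()].
#' @param flat_field apply calibration-based flat-fielding.
#' @param bleach apply post-bleach subtraction.
#' @param vignette `"auto"`, `"estimate"`, `"off"`, or a precomputed gain
#'   matrix.
#' @param min_images minimum stack size for gain estimation.
#' @return list with `run` (corrected; tag images replaced), `shifts`,
#'   `gain`, `validity`.
#' @export
correct_run <- function(run, register = length(run$cycles) >= 2,
                        reference_cycle = 1, max_shift = 30,
                        on_fail = "error", flat_field = TRUE, bleach = TRUE,
                        vignette = "auto", min_images = 8) {
  stopifnot(inherits(run, "melc_run"))
  shifts <- NULL
  validity <- NULL
  if (register && length(run$cycles) >= 2) {
    reg <- register_run(run, reference_cycle = reference_cycle,
                        max_shift = max_shift, on_fail = on_fail)
    run <- reg$run
    shifts <- reg$shifts
    validity <- reg$validity
  }
  if (flat_field) {
    for (k in seq_along(run$cycles)) {
      run$cycles[[k]]$tag_image <-
        flat_field_correct(run$cycles[[k]]$tag_image, run$calibration)
      run$cycles[[k]]$postbleach_image <-
        flat_field_correct(run$cycles[[k]]$postbleach_image, run$calibration)
    }
  }
  if (bleach) {
    tags <- lapply(run$cycles, function(cy) cy$tag_image)
    for (k in seq_along(run$cycles)) {
      prev <- if (k > 1) run$cycles[[k - 1]]$postbleach_image else NULL
      run$cycles[[k]]$tag_image <- subtract_bleach(tags[[k]], prev)
    }
  }
  gain <- NULL
  mode <- if (is.character(vignette)) vignette else "precomputed"
  if (mode == "auto") mode <- if (flat_field) "off" else "estimate"
  if (mode == "estimate" || mode == "precomputed") {
    tags <- lapply(run$cycles, function(cy) cy$tag_image)
    vc <- correct_vignetting(tags,
                             gain = if (mode == "precomputed") vignette else NULL,
                             min_images = min_images)
    for (k in seq_along(run$cycles)) run$cycles[[k]]$tag_image <- vc$corrected[[k]]
    gain <- vc$gain
  }
  list(run = run, shifts = shifts, gain = gain, validity = validity)
}
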