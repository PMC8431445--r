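# Synthetic MELC acquisition simulator.
#
# Generates scenes of planted cell types (elliptical nuclei + cytoplasm
# ring) with known expression, then renders cyclic acquisitions carrying the
# artifacts the correction stage must remove: multiplicative radial
# vignetting, additive darkframe offset, bleach residuals from the previous
# cycle, per-cell unspecific binding shared with negative-control channels,
# and Poisson/Gaussian noise. Ground truth (masks, labels, expression) is
# retained so every downstream stage can be scored.

#' Define a synthetic cell type
#'
#' @param name type name used in ground-truth labels.
#' @param marker_means named nonnegative vector: expected intensity per
#'   marker. Every measurement marker of the panel must appear.
#' @param nucleus_radius_range semi-major axis range in pixels (low, high).
#' @param nucleus_eccentricity_range eccentricity range in `[0, 1)`.
#' @param cell_ring_width cytoplasm ring width in pixels (>= 1).
#' @param concavity in `[0, 1]`: 0 keeps the nucleus convex; larger values
#'   carve a notch into the nucleus, lowering solidity and roundness
#'   (emulates banded nuclei of myelocytes).
#' @return a `cell_type_spec`.
#' @export
cell_type_spec <- function(name, marker_means,
                           nucleus_radius_range = c(4, 6),
                           nucleus_eccentricity_range = c(0, 0.5),
                           cell_ring_width = 2,
                           concavity = 0) {
  if (is.null(names(marker_means)) || any(names(marker_means) == "")) {
    stopf("marker_means must be a named vector")
  }
  if (any(marker_means < 0)) stopf("marker means must be >= 0")
  if (nucleus_radius_range[1] > nucleus_radius_range[2]) {
    stopf("nucleus_radius_range must be ordered low <= high")
  }
  if (any(nucleus_eccentricity_range < 0) || any(nucleus_eccentricity_range >= 1)) {
    stopf("eccentricity must be in [0, 1)")
  }
  if (concavity < 0 || concavity > 1) stopf("concavity must be in [0, 1]")
  if (cell_ring_width < 1) stopf("cell_ring_width must be >= 1")
  structure(list(name = name, marker_means = marker_means,
                 nucleus_radius_range = nucleus_radius_range,
                 nucleus_eccentricity_range = nucleus_eccentricity_range,
                 cell_ring_width = cell_ring_width, concavity = concavity),
            class = "cell_type_spec")
}

#' Simulation parameters
#'
#' @param vignette_alpha multiplicative radial falloff strength `[0, 1)`:
#'   the gain field is `g = 1 - alpha * (r / r_max)^2` with `r_max` the
#'   center-to-corner distance, so a corner pixel retains `1 - alpha` of the
#'   central brightness.
#' @param bleach_residual fraction `[0, 1)` of a cycle's specific signal that
#'   persists into the next tag image (and appears in the post-bleach image).
#' @param unspecific_sigma log-sd of the per-cell unspecific-binding factor
#'   `u` (log-normal, mean 1); `u` multiplies both a marker with a declared
#'   negative-control partner and its NC channel, so NC-ratio normalization
#'   is exactly corrective in expectation.
#' @param read_noise_sd Gaussian read noise sd in intensity counts.
#' @param poisson_noise apply Poisson shot noise to every acquired image.
#' @param seed integer seed controlling geometry, expression and noise.
#' @param image_size image side length in pixels.
#' @param pixel_size micrometres per pixel.
#' @param brightfield_level flat illumination level of the brightfield.
#' @param dark_level constant darkframe offset.
#' @param nc_base expected unspecific-binding intensity on NC channels.
#' @param nuclear_mean expected nuclear-stain intensity (used when a type's
#'   `marker_means` does not list the nuclear marker).
#' @param expression_sdlog log-sd of per-cell biological scatter around the
#'   type's marker mean.
#' @return a `synthetic_params` list.
#' @export
synthetic_params <- function(vignette_alpha = 0.3, bleach_residual = 0.2,
                             unspecific_sigma = 0.3, read_noise_sd = 2,
                             poisson_noise = TRUE, seed = 0,
                             image_size = 512, pixel_size = 0.45,
                             brightfield_level = 1000, dark_level = 100,
                             nc_base = 30, nuclear_mean = 500,
                             expression_sdlog = 0.15) {
  if (vignette_alpha < 0 || vignette_alpha >= 1) stopf("vignette_alpha must be in [0, 1)")
  if (bleach_residual < 0 || bleach_residual >= 1) stopf("bleach_residual must be in [0, 1)")
  if (unspecific_sigma < 0 || read_noise_sd < 0) stopf("noise parameters must be >= 0")
  if (image_size <= 0) stopf("image_size must be > 0")
  structure(list(vignette_alpha = vignette_alpha, bleach_residual = bleach_residual,
                 unspecific_sigma = unspecific_sigma, read_noise_sd = read_noise_sd,
                 poisson_noise = isTRUE(poisson_noise), seed = as.integer(seed),
                 image_size = as.integer(image_size), pixel_size = pixel_size,
                 brightfield_level = brightfield_level, dark_level = dark_level,
                 nc_base = nc_base, nuclear_mean = nuclear_mean,
                 expression_sdlog = expression_sdlog),
            class = "synthetic_params")
}

#' Build a synthetic imaging panel
#'
#' Cycles are ordered: negative-control channels first (as acquired prior to
#' their partner's staining), then measurement markers, then the nuclear
#' stain last.
#' @param markers character vector of measurement marker names.
#' @param nc_pairs named character vector mapping a marker to its
#'   negative-control channel name, e.g. `c(FAIM2 = "NC-FITC")`.
#' @param exclusive_pairs named character vector mapping a marker to its
#'   mutually exclusive counterpart marker.
#' @param nuclear_marker name of the nuclear stain cycle.
#' @return a `panel_config` with an extra logical `is_nuclear` column.
#' @export
synthetic_panel <- function(markers, nc_pairs = character(),
                            exclusive_pairs = character(),
                            nuclear_marker = "PI") {
  nc_channels <- unique(unname(nc_pairs))
  all_markers <- c(nc_channels, markers, nuclear_marker)
  if (anyDuplicated(all_markers)) stopf("panel markers must be unique")
  n <- length(all_markers)
  tab <- data.frame(step = seq_len(n), marker = all_markers,
                    conjugate = NA_character_,
                    is_negative_control = all_markers %in% nc_channels,
                    nc_partner = NA_character_,
                    exclusive_partner = NA_character_,
                    is_nuclear = all_markers == nuclear_marker,
                    stringsAsFactors = FALSE)
  tab$nc_partner[match(names(nc_pairs), tab$marker)] <- unname(nc_pairs)
  if (length(exclusive_pairs)) {
    tab$exclusive_partner[match(names(exclusive_pairs), tab$marker)] <-
      unname(exclusive_pairs)
  }
  as_panel_config(tab)
}

panel_measurement_markers <- function(panel) {
  nuc <- if (!is.null(panel$is_nuclear)) panel$is_nuclear else rep(FALSE, nrow(panel))
  panel$marker[!panel$is_negative_control & !nuc]
}

# Pixel linear indices of one cell's nucleus and cell footprint.
render_cell_geometry <- function(cx, cy, a, b, theta, ring, concavity, size) {
  rmax <- ceiling(a + ring + 1)
  xs <- max(1, floor(cx - rmax)):min(size, ceiling(cx + rmax))
  ys <- max(1, floor(cy - rmax)):min(size, ceiling(cy + rmax))
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  in_nuc <- (u / a)^2 + (v / b)^2 <= 1
  in_cell <- (u / (a + ring))^2 + (v / (b + ring))^2 <= 1
  if (concavity > 0) {
    # bite a circular notch at the major-axis tip to lower solidity
    nr <- concavity * a
    d2 <- (u - a)^2 + v^2
    keep <- d2 > nr^2
    if (any(in_nuc & keep)) in_nuc <- in_nuc & keep
  }
  # linear index: matrices are indexed [row = y, col = x]
  lin <- function(sel) {
    (rep(xs, each = length(ys))[sel] - 1L) * size + rep(ys, times = length(xs))[sel]
  }
  list(nucleus = lin(in_nuc), cell = lin(in_cell))
}

#' Generate a synthetic scene with ground truth
#'
#' Places `n_cells` non-overlapping cells (nucleus ellipse plus cytoplasm
#' ring) of the given types on an `image_size`-square canvas and draws
#' per-cell expression around each type's marker means.
#'
#' @param n_cells number of cells to place (>= 0).
#' @param type_specs list of [cell_type_spec()] objects.
#' @param mixing type proportions summing to 1 (default uniform).
#' @param params a [synthetic_params()] object.
#' @param panel optional `panel_config`; defaults to a [synthetic_panel()]
#'   over the union of the types' markers (no NC channels).
#' @return a `scene_truth` list: `centers` (x, y), `type_labels`,
#'   `true_nucleus_mask` / `true_cell_mask` (integer label matrices, label i
#'   = cell i), `true_expression` (cell x marker), `u_factors`, `panel`,
#'   `params`, `geometry`.
#' @export
make_scene <- function(n_cells, type_specs, mixing = NULL,
                       params = synthetic_params(), panel = NULL) {
  if (n_cells < 0) stopf("n_cells must be >= 0")
  if (inherits(type_specs, "cell_type_spec")) type_specs <- list(type_specs)
  type_names <- vapply(type_specs, function(s) s$name, character(1))
  names(type_specs) <- type_names
  if (is.null(mixing)) mixing <- rep(1 / length(type_specs), length(type_specs))
  if (abs(sum(mixing) - 1) > 1e-8) stopf("mixing proportions must sum to 1")
  if (is.null(panel)) {
    mk <- unique(unlist(lapply(type_specs, function(s) names(s$marker_means))))
    panel <- synthetic_panel(mk)
  }
  markers <- panel_measurement_markers(panel)
  for (s in type_specs) {
    missing <- setdiff(markers, names(s$marker_means))
    missing <- setdiff(missing, panel$marker[panel$is_nuclear %||% FALSE])
    if (length(missing)) {
      stopf("cell type '%s' lacks means for panel markers: %s",
            s$name, paste(missing, collapse = ", "))
    }
  }
  size <- params$image_size
  set.seed(params$seed)

  labels <- if (n_cells > 0) {
    sample(type_names, n_cells, replace = TRUE, prob = mixing)
  } else character(0)
  na <- rep(NA_real_, n_cells)
  geom <- data.frame(cell_id = seq_len(n_cells), type = labels,
                     x = na, y = na, a = na, b = na,
                     theta = na, ring = na, conc = na,
                     stringsAsFactors = FALSE)
  if (n_cells > 0) {
    for (i in seq_len(n_cells)) {
      s <- type_specs[[labels[i]]]
      a <- runif(1, s$nucleus_radius_range[1], s$nucleus_radius_range[2])
      e <- runif(1, s$nucleus_eccentricity_range[1], s$nucleus_eccentricity_range[2])
      geom$a[i] <- a
      geom$b[i] <- a * sqrt(1 - e^2)
      geom$theta[i] <- runif(1, 0, pi)
      geom$ring[i] <- s$cell_ring_width
      geom$conc[i] <- s$concavity
    }
    # dart-throwing placement with hard non-overlap margin
    bound <- geom$a + geom$ring + 1
    max_attempts <- 200L * n_cells
    attempts <- 0L
    placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      lo <- bound[i] + 1
      hi <- size - bound[i]
      if (hi <= lo) stopf("scene too dense: cell radius exceeds image size")
      while (attempts < max_attempts) {
        attempts <- attempts + 1L
        x <- runif(1, lo, hi); y <- runif(1, lo, hi)
        if (!length(placed_x) ||
            all((placed_x - x)^2 + (placed_y - y)^2 >
                (placed_r + bound[i] + 1)^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stopf("scene too dense: could not place %d cells of this size on a %dx%d image",
                     n_cells, size, size)
      placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
      placed_r <- c(placed_r, bound[i])
      geom$x[i] <- x; geom$y[i] <- y
    }
  }

  nucleus_mask <- matrix(0L, size, size)
  cell_mask <- matrix(0L, size, size)
  nucleus_pixels <- vector("list", n_cells)
  cell_pixels <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    px <- render_cell_geometry(geom$x[i], geom$y[i], geom$a[i], geom$b[i],
                               geom$theta[i], geom$ring[i], geom$conc[i], size)
    nucleus_pixels[[i]] <- px$nucleus
    cell_pixels[[i]] <- px$cell
    nucleus_mask[px$nucleus] <- i
    cell_mask[px$cell] <- i
  }

  expr <- matrix(0, n_cells, length(markers), dimnames = list(NULL, markers))
  sdl <- params$expression_sdlog
  for (i in seq_len(n_cells)) {
    mu <- type_specs[[labels[i]]]$marker_means[markers]
    expr[i, ] <- mu * rlnorm(length(markers), meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  u <- if (n_cells > 0) {
    rlnorm(n_cells, meanlog = -params$unspecific_sigma^2 / 2,
           sdlog = params$unspecific_sigma)
  } else numeric(0)
  speckle <- matrix(runif(size * size, 0.5, 1.5), size, size)

  structure(list(centers = geom[, c("x", "y")], type_labels = labels,
                 true_nucleus_mask = nucleus_mask, true_cell_mask = cell_mask,
                 nucleus_pixels = nucleus_pixels, cell_pixels = cell_pixels,
                 true_expression = expr, u_factors = u, speckle = speckle,
                 panel = panel, type_specs = type_specs, geometry = geom,
                 params = params,
                 scene_id = paste0("scene-", params$seed, "-", n_cells)),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("Synthetic scene %s: %d cells, %d types, %dx%d px\n",
              x$scene_id, nrow(x$centers), length(unique(x$type_labels)),
              x$params$image_size, x$params$image_size))
  if (nrow(x$centers)) print(table(x$type_labels))
  invisible(x)
}

vignette_field <- function(size, alpha) {
  c0 <- (size + 1) / 2
  r2 <- outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, "+")
  rmax2 <- 2 * (size - c0)^2
  1 - alpha * r2 / rmax2
}

# Noiseless specific-signal image for one cycle (before gain/offset/bleach).
scene_signal_image <- function(scene, marker) {
  size <- scene$params$image_size
  S <- matrix(0, size, size)
  n <- length(scene$type_labels)
  if (n == 0) return(S)
  row <- scene$panel[scene$panel$marker == marker, ]
  if (nrow(row) != 1) stopf("marker '%s' not in scene panel", marker)
  is_nuc <- isTRUE(row$is_nuclear)
  if (row$is_negative_control) {
    vals <- scene$u_factors * scene$params$nc_base
    px <- scene$cell_pixels
  } else if (is_nuc) {
    vals <- rep(scene$params$nuclear_mean, n)
    for (i in seq_len(n)) {
      mm <- scene$type_specs[[scene$type_labels[i]]]$marker_means
      if (marker %in% names(mm)) vals[i] <- mm[[marker]]
    }
    px <- scene$nucleus_pixels
  } else {
    vals <- scene$true_expression[, marker]
    if (!is.na(row$nc_partner)) vals <- vals * scene$u_factors
    px <- scene$cell_pixels
  }
  idx <- unlist(px)
  if (length(idx)) S[idx] <- rep(vals, lengths(px))
  S
}

shift_image <- function(img, dx, dy, fill = 0) {
  # dx shifts +x (columns), dy shifts +y (rows)
  d <- dim(img)
  out <- matrix(fill, d[1], d[2])
  src_r <- seq_len(d[1]) - dy
  src_c <- seq_len(d[2]) - dx
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Render a scene into a MELC acquisition run
#'
#' Applies the artifact model cycle by cycle. With specific signal `S_c` of
#' cycle c, gain field `g`, darkframe `dark` and bleach residual `rho`:
#' `tag_c = g * (S_c + rho * S_{c-1}) + dark` and
#' `postbleach_c = g * (rho * S_c) + dark`. The brightfield is
#' `B * g + dark`, the darkframe `dark`, so calibration-based flat-fielding
#' is exactly invertible in the noiseless limit. Noise (Poisson, then
#' Gaussian read noise) is applied last when enabled.
#'
#' @param scene a [make_scene()] result.
#' @param shifts optional integer matrix/data frame (`dx`, `dy`) with one row
#'   per cycle: rigid stage shift applied to all three images of that cycle
#'   (used to exercise registration).
#' @param sample_id,fov_id identifiers stamped on the run.
#' @return a `melc_run`; the scene id is attached as attribute `scene_id`.
#' @export
render_run <- function(scene, shifts = NULL, sample_id = "sim", fov_id = "fov1") {
  stopifnot(inherits(scene, "scene_truth"))
  p <- scene$params
  size <- p$image_size
  g <- vignette_field(size, p$vignette_alpha)
  dark <- matrix(p$dark_level, size, size)
  phase_scene <- matrix(30, size, size)
  if (length(scene$cell_pixels)) {
    idx <- unlist(scene$cell_pixels)
    phase_scene[idx] <- 400 * scene$speckle[idx]
  }
  set.seed(derive_seed(p$seed, "simulate"))
  add_noise <- function(img) {
    if (p$poisson_noise) {
      img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
    }
    if (p$read_noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, p$read_noise_sd),
                          nrow(img), ncol(img))
    }
    pmax(img, 0)
  }
  cycles <- vector("list", nrow(scene$panel))
  S_prev <- matrix(0, size, size)
  for (k in seq_len(nrow(scene$panel))) {
    row <- scene$panel[k, ]
    S <- scene_signal_image(scene, row$marker)
    tag <- g * (S + p$bleach_residual * S_prev) + dark
    post <- g * (p$bleach_residual * S) + dark
    phase <- g * phase_scene + dark
    if (!is.null(shifts)) {
      dx <- as.integer(shifts[k, 1]); dy <- as.integer(shifts[k, 2])
      if (dx != 0 || dy != 0) {
        tag <- shift_image(tag, dx, dy, fill = p$dark_level)
        post <- shift_image(post, dx, dy, fill = p$dark_level)
        phase <- shift_image(phase, dx, dy, fill = p$dark_level)
      }
    }
    if (p$poisson_noise || p$read_noise_sd > 0) {
      tag <- add_noise(tag); post <- add_noise(post); phase <- add_noise(phase)
    }
    cycles[[k]] <- new_melc_cycle(
      index = row$step, marker = row$marker,
      is_negative_control = row$is_negative_control,
      nc_partner = if (is.na(row$nc_partner)) NULL else row$nc_partner,
      tag_image = tag, postbleach_image = post, phase_image = phase)
    S_prev <- S
  }
  calib <- calibration_images(brightfield = p$brightfield_level * g + dark,
                              darkframe = dark)
  run <- new_melc_run(cycles = cycles, calibration = calib,
                      pixel_size = p$pixel_size, sample_id = sample_id,
                      fov_id = fov_id)
  attr(run, "scene_id") <- scene$scene_id
  run
}

#' Default cell types for the reference fixture
#'
#' Four well-separated bone-marrow-like phenotypes over a 9-marker panel:
#' T cells (CD45/CD3, small round nuclei), B cells (CD45/CD20), myeloid
#' cells (CD45/CD14/VIM, banded nuclei via concavity), and tumor cells
#' (GD2/CD56/CD24/FAIM2, large nuclei). FAIM2 carries a negative-control
#' pairing; GD2 and CD45 are declared mutually exclusive counterparts.
#' @return list with `type_specs`, `mixing` and `panel`.
#' @export
reference_cell_types <- function() {
  base <- c(CD45 = 5, CD3 = 5, CD20 = 5, CD14 = 5, VIM = 5,
            GD2 = 5, CD56 = 5, CD24 = 5, FAIM2 = 5)
  mean_of <- function(...) {
    v <- base
    hi <- c(...)
    v[names(hi)] <- hi
    v
  }
  type_specs <- list(
    cell_type_spec("tcell", mean_of(CD45 = 400, CD3 = 350),
                   nucleus_radius_range = c(3.5, 5),
                   nucleus_eccentricity_range = c(0, 0.3),
                   cell_ring_width = 2),
    cell_type_spec("bcell", mean_of(CD45 = 400, CD20 = 350),
                   nucleus_radius_range = c(3.5, 5),
                   nucleus_eccentricity_range = c(0, 0.3),
                   cell_ring_width = 2),
    cell_type_spec("myeloid", mean_of(CD45 = 300, CD14 = 350, VIM = 200),
                   nucleus_radius_range = c(4.5, 6),
                   nucleus_eccentricity_range = c(0.5, 0.7),
                   cell_ring_width = 2.5, concavity = 0.6),
    cell_type_spec("tumor", mean_of(GD2 = 400, CD56 = 350, CD24 = 300,
                                    FAIM2 = 250),
                   nucleus_radius_range = c(6, 8),
                   nucleus_eccentricity_range = c(0, 0.3),
                   cell_ring_width = 2.5))
  panel <- synthetic_panel(names(base),
                           nc_pairs = c(FAIM2 = "NC-FITC"),
                           exclusive_pairs = c(GD2 = "CD45", CD45 = "GD2"))
  list(type_specs = type_specs, mixing = c(0.3, 0.2, 0.3, 0.2), panel = panel)
}

#' The default "easy" end-to-end fixture
#'
#' Roughly 400 well-separated cells of the four [reference_cell_types()] on
#' a 768 px field with all artifacts enabled at default strength.
#' @param seed integer seed (default 0).
#' @param n_cells number of cells.
#' @param image_size canvas side in pixels.
#' @param ... overrides passed to [synthetic_params()].
#' @return a `scene_truth`.
#' @export
easy_scene <- function(seed = 0, n_cells = 400, image_size = 768, ...) {
  ref <- reference_cell_types()
  params <- synthetic_params(seed = seed, image_size = image_size, ...)
  make_scene(n_cells, ref$type_specs, mixing = ref$mixing, params = params,
             panel = ref$panel)
}

#' Render a dense-signal image stack under a planted radial gain
#'
#' Fixture for exercising retrospective gain estimation: each image is a
#' smoothly textured, everywhere-positive field multiplied by the radial
#' vignette `g = 1 - alpha * (r / r_max)^2`. Unlike cells-on-black scenes,
#' every pixel carries signal, which is the regime shading estimators are
#' designed for.
#'
#' @param alpha vignette strength in `[0, 1)`.
#' @param n_images stack size.
#' @param image_size side length in pixels.
#' @param seed integer seed.
#' @return list with `images` (list of matrices) and `true_gain`
#'   (mean-normalized [gain_field()]).
#' @export
render_gain_stack <- function(alpha = 0.4, n_images = 20, image_size = 256,
                              seed = 0) {
  g <- vignette_field(image_size, alpha)
  set.seed(seed)
  images <- lapply(seq_len(n_images), function(i) {
    tex <- matrix(runif(image_size^2, 0, 100), image_size, image_size)
    base <- 100 + as.matrix(EBImage::imageData(EBImage::gblur(tex, sigma = 3)))
    base * g
  })
  list(images = images, true_gain = gain_field(g))
}

#' Write scene ground truth to disk
#'
#' Centers/labels and expression as CSV, masks as 16-bit label TIFFs and
#' parameters as YAML.
#' @param scene a `scene_truth`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scene_truth <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- data.frame(cell_id = seq_along(scene$type_labels),
                      x = scene$centers$x, y = scene$centers$y,
                      type = scene$type_labels)
  write.csv(cells, file.path(dir, "truth_cells.csv"), row.names = FALSE)
  write.csv(as.data.frame(scene$true_expression),
            file.path(dir, "truth_expression.csv"), row.names = FALSE)
  write_label_mask(scene$true_nucleus_mask, file.path(dir, "truth_nuclei.tif"))
  write_label_mask(scene$true_cell_mask, file.path(dir, "truth_cells.tif"))
  yaml::write_yaml(unclass(scene$params), file.path(dir, "truth_params.yaml"))
  invisible(dir)
}

#' Match two label masks by intersection-over-union
#'
#' @param pred,truth integer label masks of the same shape.
#' @param iou_threshold minimum IoU for a match (> 0.5 guarantees the
#'   matching is one-to-one).
#' @return data frame of matches (`pred`, `truth`, `iou`) plus attributes
#'   `n_pred`, `n_truth`.
#' @export
match_labels <- function(pred, truth, iou_threshold = 0.5) {
  assert_same_shape(pred, truth, "label masks")
  sel <- pred > 0 | truth > 0
  p <- pred[sel]; t <- truth[sel]
  inter <- table(p, t)
  sizes_p <- table(factor(p[p > 0]))
  sizes_t <- table(factor(t[t > 0]))
  pairs <- which(inter > 0, arr.ind = TRUE)
  pl <- as.integer(rownames(inter))[pairs[, 1]]
  tl <- as.integer(colnames(inter))[pairs[, 2]]
  keep <- pl > 0 & tl > 0
  pairs <- pairs[keep, , drop = FALSE]
  pl <- pl[keep]; tl <- tl[keep]
  ious <- numeric(length(pl))
  for (i in seq_along(pl)) {
    ov <- inter[pairs[i, 1], pairs[i, 2]]
    ious[i] <- ov / (sizes_p[[as.character(pl[i])]] +
                     sizes_t[[as.character(tl[i])]] - ov)
  }
  m <- data.frame(pred = pl, truth = tl, iou = ious)
  m <- m[m$iou > iou_threshold, , drop = FALSE]
  m <- m[order(-m$iou), , drop = FALSE]
  m <- m[!duplicated(m$pred) & !duplicated(m$truth), , drop = FALSE]
  attr(m, "n_pred") <- length(unique(p[p > 0]))
  attr(m, "n_truth") <- length(unique(t[t > 0]))
  m
}

#' Segmentation F1 score at an IoU threshold
#'
#' @inheritParams match_labels
#' @return list with `tp`, `precision`, `recall`, `f1`.
#' @export
segmentation_f1 <- function(pred, truth, iou_threshold = 0.5) {
  m <- match_labels(pred, truth, iou_threshold)
  tp <- nrow(m)
  np <- attr(m, "n_pred"); nt <- attr(m, "n_truth")
  precision <- if (np > 0) tp / np else 1
  recall <- if (nt > 0) tp / nt else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(tp = tp, n_pred = np, n_truth = nt,
       precision = precision, recall = recall, f1 = f1)
}

#' Score pipeline outputs against scene ground truth
#'
#' @param truth a `scene_truth`.
#' @param nucleus_mask,cell_mask predicted label masks (optional).
#' @param cell_table a [reconcile_masks()] table aligned with `cell_mask`
#'   (required for clustering/expression scoring).
#' @param cluster_labels per-cell atlas cluster labels, aligned with
#'   `cell_table` rows (optional).
#' @param features a feature table aligned with `cell_table` rows (optional;
#'   used for per-marker expression correlation on M20 cell features).
#' @param scene_id id carried by the rendered run; checked against the truth.
#' @return a `recovery_report` list: `nucleus_f1`, `cell_f1` (each as from
#'   [segmentation_f1()]), `ari`, `expression_cor` (per marker), `n_matched`.
#' @export
evaluate_recovery <- function(truth, nucleus_mask = NULL, cell_mask = NULL,
                              cell_table = NULL, cluster_labels = NULL,
                              features = NULL, scene_id = NULL) {
  stopifnot(inherits(truth, "scene_truth"))
  if (!is.null(scene_id) && !identical(scene_id, truth$scene_id)) {
    stopf("outputs come from scene '%s' but truth is scene '%s'",
          scene_id, truth$scene_id)
  }
  out <- list(nucleus_f1 = NULL, cell_f1 = NULL, ari = NA_real_,
              expression_cor = NULL, n_matched = 0L)
  if (!is.null(nucleus_mask)) {
    out$nucleus_f1 <- segmentation_f1(nucleus_mask, truth$true_nucleus_mask)
  }
  if (!is.null(cell_mask)) {
    out$cell_f1 <- segmentation_f1(cell_mask, truth$true_cell_mask)
  }
  if (!is.null(cell_table) && !is.null(cell_mask)) {
    m <- match_labels(cell_mask, truth$true_cell_mask)
    idx <- match(cell_table$cell_label, m$pred)
    matched <- !is.na(idx)
    truth_cell <- m$truth[idx[matched]]
    out$n_matched <- sum(matched)
    if (!is.null(cluster_labels)) {
      stopifnot(length(cluster_labels) == nrow(cell_table))
      out$ari <- adjusted_rand_index(cluster_labels[matched],
                                     truth$type_labels[truth_cell])
    }
    if (!is.null(features)) {
      markers <- colnames(truth$true_expression)
      cors <- setNames(rep(NA_real_, length(markers)), markers)
      for (mk in markers) {
        col <- paste0(mk, "_M20_cell")
        if (col %in% names(features)) {
          v <- features[[col]][matched]
          e <- truth$true_expression[truth_cell, mk]
          if (sd(e) > 0 && sd(v) > 0) cors[mk] <- cor(v, e)
        }
      }
      out$expression_cor <- cors
    }
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report\n")
  if (!is.null(x$nucleus_f1)) {
    cat(sprintf("  nucleus F1@0.5: %.3f (%d/%d matched)\n",
                x$nucleus_f1$f1, x$nucleus_f1$tp, x$nucleus_f1$n_truth))
  }
  if (!is.null(x$cell_f1)) {
    cat(sprintf("  cell F1@0.5:    %.3f (%d/%d matched)\n",
                x$cell_f1$f1, x$cell_f1$tp, x$cell_f1$n_truth))
  }
  if (!is.na(x$ari)) cat(sprintf("  clustering ARI: %.3f\n", x$ari))
  if (!is.null(x$expression_cor)) {
    cat(sprintf("  median marker expression r: %.3f\n",
                median(x$expression_cor, na.rm = TRUE)))
  }
  invisible(x)
}
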