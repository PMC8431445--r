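# Nucleus/cell segmentation baseline and mask reconciliation.
#
# The classical baseline (smoothing -> global threshold -> distance-transform
# watershed -> small-object removal) stands in for externally trained
# instance-segmentation models; label masks produced elsewhere can be loaded
# with read_label_mask() and used in place of either baseline.

as_label_matrix <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

remove_small_objects <- function(labels, min_size) {
  if (min_size <= 1 || max(labels) == 0) return(labels)
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes < min_size)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

#' Segment nuclei from a nuclear-stain image
#'
#' Classical baseline: Gaussian smoothing, Otsu global threshold,
#' distance-transform watershed to split touching nuclei, small-object
#' removal. Returns an integer label mask (0 = background, 8-connected
#' objects).
#'
#' @param image 2D nuclear-stain image (e.g. propidium iodide tag image).
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param min_size minimum object area in pixels.
#' @param watershed_tolerance minimum object-separating depth of the
#'   distance map passed to the watershed.
#' @return integer label matrix.
#' @export
segment_nuclei <- function(image, smooth_sigma = 2, min_size = 20,
                           watershed_tolerance = 1) {
  assert_image(image)
  rng <- range(image)
  if (diff(rng) == 0) return(matrix(0L, nrow(image), ncol(image)))
  norm <- (image - rng[1]) / diff(rng)
  sm <- EBImage::gblur(norm, sigma = smooth_sigma)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bin <- sm > thr
  if (!any(bin)) return(matrix(0L, nrow(image), ncol(image)))
  dm <- EBImage::distmap(bin)
  labels <- as_label_matrix(EBImage::watershed(dm, tolerance = watershed_tolerance))
  remove_small_objects(labels, min_size)
}

# Local standard deviation via normalized box filters (texture map).
local_sd_map <- function(image, window = 7) {
  k <- matrix(1 / window^2, window, window)
  m <- EBImage::filter2(image, k)
  m2 <- EBImage::filter2(image^2, k)
  sqrt(pmax(m2 - m^2, 0))
}

#' Segment cells from a phase-contrast image
#'
#' As [segment_nuclei()], but a local-texture (standard deviation) map
#' substitutes for intensity, since cells in phase contrast are defined by
#' texture rather than brightness. When a nucleus label mask is supplied as
#' `seeds`, objects are instead grown from the nuclei over the thresholded
#' foreground by Voronoi propagation, which also splits touching cells.
#'
#' @param image 2D phase-contrast image.
#' @param seeds optional nucleus label mask used as propagation seeds.
#' @param window texture window (pixels) for the local-sd map.
#' @param smooth_sigma Gaussian smoothing of the texture map.
#' @param erode_radius erosion radius compensating the half-window
#'   dilation of the texture map; default `(window - 1) / 2`.
#' @param min_size minimum object area in pixels.
#' @param watershed_tolerance see [segment_nuclei()].
#' @return integer label matrix.
#' @export
segment_cells <- function(image, seeds = NULL, window = 5, smooth_sigma = 2,
                          erode_radius = (window - 1) / 2, min_size = 50,
                          watershed_tolerance = 2) {
  assert_image(image)
  tex <- local_sd_map(image, window)
  rng <- range(tex)
  if (diff(rng) == 0) return(matrix(0L, nrow(image), ncol(image)))
  sm <- EBImage::gblur((tex - rng[1]) / diff(rng), sigma = smooth_sigma)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bin <- EBImage::fillHull(sm > thr)
  if (erode_radius >= 1) {
    bin <- EBImage::erode(bin, EBImage::makeBrush(2 * round(erode_radius) + 1, "disc")) > 0
  }
  if (!any(bin)) return(matrix(0L, nrow(image), ncol(image)))
  if (!is.null(seeds)) {
    assert_same_shape(image, seeds, "phase image and seed mask")
    fg <- bin | seeds > 0
    labels <- as_label_matrix(EBImage::propagate(image, seeds, mask = fg))
  } else {
    dm <- EBImage::distmap(bin)
    labels <- as_label_matrix(EBImage::watershed(dm, tolerance = watershed_tolerance))
  }
  remove_small_objects(labels, min_size)
}

label_centroids <- function(labels) {
  sel <- which(labels > 0)
  if (!length(sel)) {
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
  }
  lab <- labels[sel]
  ys <- (sel - 1) %% nrow(labels) + 1
  xs <- (sel - 1) %/% nrow(labels) + 1
  data.frame(label = as.integer(names(tapply(xs, lab, mean))),
             x = as.numeric(tapply(xs, lab, mean)),
             y = as.numeric(tapply(ys, lab, mean)))
}

#' Reconcile cell and nucleus masks into single cells
#'
#' A cell object is counted as a cell only if it is reproduced in the
#' nucleus mask: it must contain more than half of the pixels of at least
#' one nucleus object. Each kept cell is paired with its largest-overlap
#' qualifying nucleus; each nucleus is assigned to the single cell holding
#' its largest pixel share. Dropped cells and unassigned nuclei are counted
#' in the attributes `n_dropped_cells` / `n_unassigned_nuclei`.
#'
#' @param cell_mask,nucleus_mask integer label masks of the same shape.
#' @return a `cell_table` data frame with columns `cell_id`, `cell_label`,
#'   `nucleus_label`, `centroid_x`, `centroid_y`, `border_touching`.
#' @export
reconcile_masks <- function(cell_mask, nucleus_mask) {
  assert_same_shape(cell_mask, nucleus_mask, "cell and nucleus masks")
  empty <- data.frame(cell_id = integer(0), cell_label = integer(0),
                      nucleus_label = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), border_touching = logical(0))
  class(empty) <- c("cell_table", "data.frame")
  n_cells_in <- length(unique(cell_mask[cell_mask > 0]))
  if (max(nucleus_mask) == 0 || n_cells_in == 0) {
    attr(empty, "n_dropped_cells") <- n_cells_in
    attr(empty, "n_unassigned_nuclei") <- length(unique(nucleus_mask[nucleus_mask > 0]))
    return(empty)
  }
  sel <- nucleus_mask > 0
  overlap <- table(nucleus = nucleus_mask[sel], cell = cell_mask[sel])
  nuc_sizes <- rowSums(overlap)
  cell_ids_tab <- as.integer(colnames(overlap))
  # per nucleus: the cell holding its largest pixel share
  best_col <- max.col(overlap, ties.method = "first")
  best_cell <- cell_ids_tab[best_col]
  best_ov <- overlap[cbind(seq_len(nrow(overlap)), best_col)]
  containment <- best_ov / nuc_sizes
  nuc_ids <- as.integer(rownames(overlap))
  valid <- best_cell > 0 & containment > 0.5
  assign <- data.frame(nucleus = nuc_ids[valid], cell = best_cell[valid],
                       overlap = as.numeric(best_ov[valid]))
  if (!nrow(assign)) {
    attr(empty, "n_dropped_cells") <- n_cells_in
    attr(empty, "n_unassigned_nuclei") <- length(nuc_ids)
    return(empty)
  }
  # per kept cell: largest-overlap nucleus
  assign <- assign[order(assign$cell, -assign$overlap), ]
  assign <- assign[!duplicated(assign$cell), ]
  cent <- label_centroids(cell_mask)
  d <- dim(cell_mask)
  border_labels <- unique(c(cell_mask[1, ], cell_mask[d[1], ],
                            cell_mask[, 1], cell_mask[, d[2]]))
  tab <- data.frame(cell_id = seq_len(nrow(assign)),
                    cell_label = assign$cell,
                    nucleus_label = assign$nucleus,
                    centroid_x = cent$x[match(assign$cell, cent$label)],
                    centroid_y = cent$y[match(assign$cell, cent$label)],
                    border_touching = assign$cell %in% border_labels)
  class(tab) <- c("cell_table", "data.frame")
  attr(tab, "n_dropped_cells") <- n_cells_in - nrow(tab)
  attr(tab, "n_unassigned_nuclei") <- length(nuc_ids) - sum(nuc_ids %in% tab$nucleus_label)
  tab
}

point_in_polygon <- function(px, py, poly) {
  # ray casting; points exactly on an edge count as outside (strict interior)
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    if ((xi - px) * (yj - py) - (xj - px) * (yi - py) == 0 &&
        px >= min(xi, xj) && px <= max(xi, xj) &&
        py >= min(yi, yj) && py <= max(yi, yj)) {
      return(FALSE)
    }
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Remove cells inside user-defined exclusion regions
#'
#' Cells whose centroid lies in the strict interior of any polygon are
#' removed (edge points are kept). Regions come from files (e.g. a JSON list
#' of polygons) rather than interactive drawing.
#'
#' @param table a `cell_table` from [reconcile_masks()].
#' @param regions list of polygons; each a 2-column (x, y) matrix or data
#'   frame with at least 3 vertices.
#' @return filtered `cell_table`; the number of removed cells is stored in
#'   attribute `n_excluded`.
#' @export
apply_exclusions <- function(table, regions) {
  if (!length(regions)) {
    attr(table, "n_excluded") <- 0L
    return(table)
  }
  polys <- lapply(regions, function(r) {
    m <- as.matrix(as.data.frame(r))
    if (ncol(m) < 2 || nrow(m) < 3 || any(!is.finite(m))) {
      stopf("malformed exclusion polygon: need >= 3 finite (x, y) vertices")
    }
    m[, 1:2, drop = FALSE]
  })
  drop <- vapply(seq_len(nrow(table)), function(i) {
    any(vapply(polys, function(p) {
      point_in_polygon(table$centroid_x[i], table$centroid_y[i], p)
    }, logical(1)))
  }, logical(1))
  out <- table[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  attr(out, "n_dropped_cells") <- attr(table, "n_dropped_cells")
  attr(out, "n_unassigned_nuclei") <- attr(table, "n_unassigned_nuclei")
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Read exclusion regions from JSON
#'
#' @param path JSON file: a list of polygons, each a list/array of `[x, y]`
#'   vertex pairs.
#' @return list of 2-column matrices.
#' @export
read_exclusion_regions <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.data.frame(raw)) raw <- list(as.matrix(raw))
  lapply(raw, function(p) {
    m <- as.matrix(p)
    if (ncol(m) != 2) stopf("malformed exclusion polygon in %s", path)
    m
  })
}
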