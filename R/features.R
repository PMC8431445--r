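# Per-cell morphological and compartment-resolved intensity features.
#
# Schema: 6 morphological features per cell (cell size/perimeter, nucleus
# size/perimeter/roundness/solidity) plus 9 intensity features per marker —
# mean (ME), total (TO) and mean of the top 20% of pixels (M20), each in the
# nucleus, whole-cell and cytoplasm/membrane (cell minus nucleus)
# compartments. Sizes are in pixels; perimeters count unit pixel edges on
# the object/background interface, an estimator chosen for exact testability
# (its bias on curved shapes is acceptable because features are used
# comparatively).

pixelset_coords <- function(idx, dim) {
  list(y = (idx - 1) %% dim[1] + 1, x = (idx - 1) %/% dim[1] + 1)
}

# Count of unit pixel edges between the set and its complement (image
# border counts as outside).
pixelset_perimeter <- function(idx, dim) {
  co <- pixelset_coords(idx, dim)
  key <- function(x, y) (x + 1) * (dim[1] + 3) + y  # injective for x,y +- 1
  keys <- key(co$x, co$y)
  per <- 0L
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nk <- key(co$x + d[1], co$y + d[2])
    per <- per + sum(!(nk %in% keys))
  }
  per
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Area of the convex hull of the union of unit pixel squares.
pixelset_hull_area <- function(idx, dim) {
  co <- pixelset_coords(idx, dim)
  cx <- c(co$x - 0.5, co$x - 0.5, co$x + 0.5, co$x + 0.5)
  cy <- c(co$y - 0.5, co$y + 0.5, co$y - 0.5, co$y + 0.5)
  h <- chull(cx, cy)
  polygon_area(cx[h], cy[h])
}

#' Morphological features of one cell
#'
#' @param cell_pixels,nucleus_pixels linear pixel indices (1-based, column
#'   major) of the cell and nucleus pixel sets; both nonempty.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return named numeric vector: `cell_size`, `cell_perimeter`,
#'   `nucleus_size`, `nucleus_perimeter`, `nucleus_roundness`
#'   (`4*pi*A/P^2`), `nucleus_solidity` (area / convex hull area).
#' @export
compute_morphology <- function(cell_pixels, nucleus_pixels, dim) {
  if (!length(cell_pixels) || !length(nucleus_pixels)) {
    stopf("cell and nucleus pixel sets must be nonempty")
  }
  np <- pixelset_perimeter(nucleus_pixels, dim)
  ns <- length(nucleus_pixels)
  c(cell_size = length(cell_pixels),
    cell_perimeter = pixelset_perimeter(cell_pixels, dim),
    nucleus_size = ns,
    nucleus_perimeter = np,
    nucleus_roundness = 4 * pi * ns / np^2,
    nucleus_solidity = ns / pixelset_hull_area(nucleus_pixels, dim))
}

intensity_stats <- function(values) {
  n <- length(values)
  if (n == 0) return(c(ME = 0, TO = 0, M20 = 0))
  k <- max(1L, ceiling(0.2 * n))
  top <- sort(values, decreasing = TRUE)[seq_len(k)]
  c(ME = mean(values), TO = sum(values), M20 = mean(top))
}

#' Intensity features of one cell in one channel
#'
#' For each compartment (nucleus, cell, cytoplasm/membrane = cell minus
#' nucleus): mean intensity (ME), total intensity (TO) and mean of the top
#' 20% pixel intensities (M20, `k = max(1, ceiling(0.2 n))` pixels). An
#' empty cytoplasm/membrane compartment (nucleus fills the cell) yields 0
#' for its three features, with attribute `cyto_empty = TRUE`.
#'
#' @param channel numeric image matrix.
#' @param cell_pixels,nucleus_pixels linear pixel indices; the nucleus
#'   compartment is `nucleus_pixels` intersected with `cell_pixels`.
#' @return named numeric vector of 9 features in ME/TO/M20 x
#'   nucleus/cell/cyto order.
#' @export
compute_intensity <- function(channel, cell_pixels, nucleus_pixels) {
  assert_image(channel)
  nuc <- intersect(nucleus_pixels, cell_pixels)
  cyto <- setdiff(cell_pixels, nuc)
  s_nuc <- intensity_stats(channel[nuc])
  s_cell <- intensity_stats(channel[cell_pixels])
  s_cyto <- intensity_stats(channel[cyto])
  out <- c(ME_nucleus = unname(s_nuc["ME"]), ME_cell = unname(s_cell["ME"]),
           ME_cyto = unname(s_cyto["ME"]),
           TO_nucleus = unname(s_nuc["TO"]), TO_cell = unname(s_cell["TO"]),
           TO_cyto = unname(s_cyto["TO"]),
           M20_nucleus = unname(s_nuc["M20"]), M20_cell = unname(s_cell["M20"]),
           M20_cyto = unname(s_cyto["M20"]))
  attr(out, "cyto_empty") <- length(cyto) == 0
  out
}

morphology_feature_names <- function() {
  c("cell_size", "cell_perimeter", "nucleus_size", "nucleus_perimeter",
    "nucleus_roundness", "nucleus_solidity")
}

intensity_feature_names <- function(marker) {
  paste0(marker, "_", c("ME_nucleus", "ME_cell", "ME_cyto",
                        "TO_nucleus", "TO_cell", "TO_cyto",
                        "M20_nucleus", "M20_cell", "M20_cyto"))
}

#' Build the per-cell feature table
#'
#' One row per reconciled cell: metadata (`sample_id`, `fov_id`, `cell_id`,
#' `cell_label`, `nucleus_label`), 6 morphological features, then 9
#' intensity features per channel in panel order (negative-control channels
#' included for later normalization). Column order is deterministic:
#' morphology block first, then per marker ME/TO/M20 x
#' nucleus/cell/cytoplasm-membrane.
#'
#' @param run corrected `melc_run`.
#' @param cell_table a [reconcile_masks()] result.
#' @param cell_mask,nucleus_mask the label masks the table was built from.
#' @param markers channels to extract; default all cycles of the run.
#' @return a `feature_table` data frame; a logical `cyto_empty` column flags
#'   cells whose nucleus fills the whole cell footprint.
#' @export
build_feature_table <- function(run, cell_table, cell_mask, nucleus_mask,
                                markers = NULL) {
  stopifnot(inherits(run, "melc_run"))
  run_markers <- vapply(run$cycles, function(cy) cy$marker, character(1))
  if (is.null(markers)) markers <- run_markers
  missing <- setdiff(markers, run_markers)
  if (length(missing)) {
    stopf("markers missing from run: %s", paste(missing, collapse = ", "))
  }
  dim_img <- dim(cell_mask)
  cols <- c("sample_id", "fov_id", "cell_id", "cell_label", "nucleus_label",
            morphology_feature_names(),
            unlist(lapply(markers, intensity_feature_names)), "cyto_empty")
  n <- nrow(cell_table)
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$sample_id <- character(0); out$fov_id <- character(0)
    out$cyto_empty <- logical(0)
    class(out) <- c("feature_table", "data.frame")
    return(out)
  }
  cell_px <- split(which(cell_mask > 0), cell_mask[cell_mask > 0])
  nuc_px <- split(which(nucleus_mask > 0), nucleus_mask[nucleus_mask > 0])
  channels <- setNames(lapply(markers, function(m) {
    run$cycles[[match(m, run_markers)]]$tag_image
  }), markers)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- cell_px[[as.character(cell_table$cell_label[i])]]
    np <- nuc_px[[as.character(cell_table$nucleus_label[i])]]
    np <- intersect(np, cp)  # nucleus compartment = nucleus within its cell
    morph <- compute_morphology(cp, np, dim_img)
    feats <- numeric(0)
    cyto_empty <- FALSE
    for (m in markers) {
      fi <- compute_intensity(channels[[m]], cp, np)
      cyto_empty <- cyto_empty || isTRUE(attr(fi, "cyto_empty"))
      names(fi) <- intensity_feature_names(m)
      feats <- c(feats, fi)
    }
    rows[[i]] <- c(morph, feats, cyto_empty = as.numeric(cyto_empty))
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(sample_id = run$sample_id, fov_id = run$fov_id,
                    cell_id = cell_table$cell_id,
                    cell_label = cell_table$cell_label,
                    nucleus_label = cell_table$nucleus_label,
                    as.data.frame(mat), check.names = FALSE)
  out$cyto_empty <- as.logical(out$cyto_empty)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Names of the feature columns of a feature table
#'
#' @param table a `feature_table`.
#' @param markers restrict to these markers' intensity features.
#' @param intensity_only drop the morphology block.
#' @return character vector of column names present in `table`.
#' @export
feature_columns <- function(table, markers = NULL, intensity_only = FALSE) {
  meta <- c("sample_id", "fov_id", "cell_id", "cell_label", "nucleus_label",
            "cyto_empty")
  cols <- setdiff(names(table), meta)
  if (intensity_only) cols <- setdiff(cols, morphology_feature_names())
  if (!is.null(markers)) {
    keep_int <- unlist(lapply(markers, intensity_feature_names))
    cols <- cols[cols %in% c(if (!intensity_only) morphology_feature_names(),
                             keep_int)]
  }
  cols
}

#' Write / read a feature table as CSV
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}
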