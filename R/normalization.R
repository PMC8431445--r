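# Normalization: negative-control ratio and mutually-exclusive-marker
# background levels (per-image batch correction).
#
# Two steps, both per cell or per image and both monotone within an image:
# (1) for markers acquired with a negative-control secondary antibody, each
# intensity feature is divided by the same cell's corresponding NC feature,
# cancelling unspecific binding/autofluorescence; (2) for markers with a
# declared mutually exclusive counterpart, a per-image background level b
# (the threshold separating signal from background) is estimated from
# counterpart-positive cells — which should not genuinely express the
# marker — and all of the marker's intensity features are divided by b, so
# 1.0 means "at background". Because b is estimated per image, step (2) is
# also the batch correction.

#' Normalization configuration
#'
#' @param nc_pairs named character vector: marker -> negative-control
#'   channel name.
#' @param exclusive_pairs named character vector: marker -> mutually
#'   exclusive counterpart marker.
#' @param q_counterpart quantile defining counterpart-positive cells
#'   (default 0.8).
#' @param q_background quantile of the marker among counterpart-positive
#'   cells taken as the background level (default 0.95).
#' @param reference_feature statistic/compartment suffix used for
#'   thresholds (default `"M20_cyto"`, the top-20% mean in
#'   cytoplasm/membrane).
#' @param min_reference_cells minimum counterpart-positive cells per image
#'   (default 20); below it the marker passes through unnormalized with a
#'   warning.
#' @param eps denominator guard.
#' @return a `normalization_config` list.
#' @export
normalization_config <- function(nc_pairs = character(),
                                 exclusive_pairs = character(),
                                 q_counterpart = 0.8, q_background = 0.95,
                                 reference_feature = "M20_cyto",
                                 min_reference_cells = 20, eps = 1e-6) {
  stopifnot(q_counterpart > 0, q_counterpart < 1,
            q_background > 0, q_background < 1, eps > 0)
  structure(list(nc_pairs = nc_pairs, exclusive_pairs = exclusive_pairs,
                 q_counterpart = q_counterpart, q_background = q_background,
                 reference_feature = reference_feature,
                 min_reference_cells = min_reference_cells, eps = eps),
            class = "normalization_config")
}

#' Derive a normalization config from a panel
#'
#' Collects `nc_partner` and `exclusive_partner` columns of a
#' `panel_config` into a [normalization_config()].
#' @param panel a `panel_config`.
#' @param ... overrides passed to [normalization_config()].
#' @return a `normalization_config`.
#' @export
panel_normalization_config <- function(panel, ...) {
  has_nc <- !is.na(panel$nc_partner %||% rep(NA, nrow(panel)))
  has_ex <- !is.na(panel$exclusive_partner %||% rep(NA, nrow(panel)))
  normalization_config(
    nc_pairs = setNames(panel$nc_partner[has_nc], panel$marker[has_nc]),
    exclusive_pairs = setNames(panel$exclusive_partner[has_ex],
                               panel$marker[has_ex]),
    ...)
}

stat_suffixes <- function() {
  c("ME_nucleus", "ME_cell", "ME_cyto", "TO_nucleus", "TO_cell", "TO_cyto",
    "M20_nucleus", "M20_cell", "M20_cyto")
}

#' Negative-control ratio normalization
#'
#' For each marker with a declared NC pairing, every intensity feature is
#' divided by the same cell's matching NC-channel feature (plus `eps`).
#' Morphology and unpaired markers are untouched; NC columns are dropped
#' after use. Cells with an NC feature of exactly 0 are flagged in the
#' logical column `nc_zero`.
#'
#' @param table a `feature_table` containing NC channel columns.
#' @param config a [normalization_config()] with `nc_pairs`.
#' @return normalized `feature_table`.
#' @export
nc_ratio_normalize <- function(table, config) {
  pairs <- config$nc_pairs
  if (!length(pairs)) return(table)
  nc_zero <- rep(FALSE, nrow(table))
  for (marker in names(pairs)) {
    nc <- pairs[[marker]]
    for (suf in stat_suffixes()) {
      mcol <- paste0(marker, "_", suf)
      ncol_ <- paste0(nc, "_", suf)
      if (!ncol_ %in% names(table)) {
        stopf("negative-control column '%s' missing from feature table", ncol_)
      }
      if (!mcol %in% names(table)) next
      denom <- table[[ncol_]]
      nc_zero <- nc_zero | denom == 0
      table[[mcol]] <- table[[mcol]] / (denom + config$eps)
    }
  }
  drop <- unlist(lapply(unique(unname(pairs)), function(nc) {
    paste0(nc, "_", stat_suffixes())
  }))
  table <- table[, !(names(table) %in% drop), drop = FALSE]
  table$nc_zero <- nc_zero
  class(table) <- c("feature_table", "data.frame")
  table
}

image_key <- function(table) paste(table$sample_id, table$fov_id, sep = "/")

#' Estimate per-image background levels from mutually exclusive markers
#'
#' For each marker with a declared mutually exclusive counterpart and each
#' image: counterpart-positive cells are those above the `q_counterpart`
#' quantile of the counterpart's reference feature; the background level
#' `b` is the `q_background` quantile of the marker's reference feature
#' among those cells. Counterpart-positive cells should not genuinely
#' express the marker, so `b` caps the unspecific signal.
#'
#' @param table a `feature_table` (after NC normalization, typically).
#' @param config a [normalization_config()] with `exclusive_pairs`.
#' @return a `background_levels` data frame: `sample_id`, `fov_id`,
#'   `marker`, `b`, `n_reference`, `flagged`.
#' @export
estimate_background_levels <- function(table, config) {
  pairs <- config$exclusive_pairs
  ref <- config$reference_feature
  keys <- image_key(table)
  rows <- list()
  for (marker in names(pairs)) {
    counterpart <- pairs[[marker]]
    mcol <- paste0(marker, "_", ref)
    ccol <- paste0(counterpart, "_", ref)
    if (!all(c(mcol, ccol) %in% names(table))) {
      stopf("reference feature columns missing for pair %s / %s", marker, counterpart)
    }
    for (key in unique(keys)) {
      sel <- keys == key
      cvals <- table[[ccol]][sel]
      thr <- quantile(cvals, config$q_counterpart, names = FALSE)
      pos <- sel & table[[ccol]] > thr
      npos <- sum(pos)
      ids <- strsplit(key, "/", fixed = TRUE)[[1]]
      if (npos < config$min_reference_cells) {
        warnf("insufficient mutually-exclusive reference population for %s in %s (%d cells); marker passes through unnormalized",
              marker, key, npos)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = ids[1], fov_id = ids[2], marker = marker,
          b = NA_real_, n_reference = npos, flagged = TRUE)
        next
      }
      b <- quantile(table[[mcol]][pos], config$q_background, names = FALSE)
      flagged <- FALSE
      if (!is.finite(b) || b <= 0) {
        b <- config$eps
        flagged <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[1], fov_id = ids[2], marker = marker,
        b = b, n_reference = npos, flagged = flagged)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sample_id = character(0), fov_id = character(0),
               marker = character(0), b = numeric(0),
               n_reference = integer(0), flagged = logical(0))
  }
  class(out) <- c("background_levels", "data.frame")
  out
}

#' Apply background-level normalization (batch correction)
#'
#' Each marker intensity feature is divided by its image's background level
#' `b`, putting all markers in all images on a common background-relative
#' scale (1.0 = background). Markers without a level for an image (no
#' exclusive pair, or insufficient reference cells) pass through unchanged
#' with a warning.
#'
#' @param table a `feature_table`.
#' @param levels a `background_levels` table from
#'   [estimate_background_levels()].
#' @return normalized `feature_table`.
#' @export
apply_background_normalization <- function(table, levels) {
  keys <- image_key(table)
  lvl_keys <- paste(levels$sample_id, levels$fov_id, sep = "/")
  markers_in_table <- unique(sub("_(ME|TO|M20)_(nucleus|cell|cyto)$", "",
                                 grep("_(ME|TO|M20)_(nucleus|cell|cyto)$",
                                      names(table), value = TRUE)))
  covered <- unique(levels$marker[!is.na(levels$b)])
  uncovered <- setdiff(markers_in_table, covered)
  if (length(uncovered)) {
    warnf("no background level for marker(s) %s; passed through unchanged",
          paste(uncovered, collapse = ", "))
  }
  for (i in seq_len(nrow(levels))) {
    if (is.na(levels$b[i])) next
    sel <- keys == lvl_keys[i]
    if (!any(sel)) next
    for (suf in stat_suffixes()) {
      col <- paste0(levels$marker[i], "_", suf)
      if (col %in% names(table)) {
        table[[col]][sel] <- table[[col]][sel] / levels$b[i]
      }
    }
  }
  class(table) <- c("feature_table", "data.frame")
  table
}

#' Full normalization of a feature table
#'
#' NC-ratio normalization followed by background-level estimation and
#' per-image background normalization.
#' @param table a `feature_table`.
#' @param config a [normalization_config()].
#' @return list with `table` (normalized) and `levels`
#'   (`background_levels`).
#' @export
normalize_features <- function(table, config) {
  table <- nc_ratio_normalize(table, config)
  levels <- estimate_background_levels(table, config)
  if (nrow(levels)) {
    table <- suppressWarnings(apply_background_normalization(table, levels))
  }
  list(table = table, levels = levels)
}
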