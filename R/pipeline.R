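# End-to-end orchestration with config, per-stage artifacts and
# deterministic seeds.

#' Default pipeline configuration
#'
#' A nested list with one section per stage; [run_pipeline()] merges user
#' overrides into these defaults. The single global `seed` is fanned out to
#' per-stage seeds.
#' @param seed global seed.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 0) {
  list(
    seed = as.integer(seed),
    correction = list(register = TRUE, reference_cycle = 1, max_shift = 30,
                      on_fail = "error", flat_field = TRUE, bleach = TRUE,
                      vignette = "auto", min_images = 8),
    segmentation = list(nuclear_marker = "PI", smooth_sigma = 2,
                        min_nucleus_size = 20, min_cell_size = 50,
                        seed_cells_with_nuclei = TRUE),
    normalization = list(q_counterpart = 0.8, q_background = 0.95,
                         reference_feature = "M20_cyto",
                         min_reference_cells = 20),
    atlas = list(perplexity = 30, gms_bandwidth = NULL, grid_size = 128,
                 n_subclusters = 30)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full single-cell pipeline on a MELC run
#'
#' Stages in fixed order: image correction ([correct_run()]), nucleus and
#' cell segmentation with mask reconciliation, feature extraction,
#' normalization, and the atlas (embedding + Gaussian mean-shift
#' clustering). Each stage consumes only prior-stage artifacts; re-running
#' with identical inputs and seed reproduces the feature tables exactly.
#'
#' @param run a `melc_run` (e.g. from [render_run()] or [read_melc_run()]).
#' @param config overrides merged into [default_pipeline_config()].
#' @param exclusions optional list of exclusion polygons (see
#'   [apply_exclusions()]).
#' @param output_dir optional directory; when given, per-stage artifacts
#'   (shift table, gain field, masks, cell table, feature CSVs, background
#'   levels, embedding + labels, heatmap matrix, composition, log counts)
#'   are written there.
#' @return a `pipeline_result` list: `corrected`, `shifts`, `gain`,
#'   `nucleus_mask`, `cell_mask`, `cell_table`, `features` (raw),
#'   `normalized`, `background_levels`, `atlas`, `counts`, `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(run, config = list(), exclusions = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(run, "melc_run"))
  cfg <- merge_config(default_pipeline_config(), config)
  cfg_hash <- object_hash(cfg)
  seed <- cfg$seed

  run_markers <- vapply(run$cycles, function(cy) cy$marker, character(1))
  nuc_marker <- cfg$segmentation$nuclear_marker
  if (!nuc_marker %in% run_markers) {
    stopf("nuclear marker '%s' not found in run (markers: %s)",
          nuc_marker, paste(run_markers, collapse = ", "))
  }
  if (cfg$correction$flat_field && is.null(run$calibration)) {
    stopf("flat-field correction enabled but run has no calibration images")
  }

  # --- correction ---------------------------------------------------------
  corr <- correct_run(run,
                      register = cfg$correction$register,
                      reference_cycle = cfg$correction$reference_cycle,
                      max_shift = cfg$correction$max_shift,
                      on_fail = cfg$correction$on_fail,
                      flat_field = cfg$correction$flat_field,
                      bleach = cfg$correction$bleach,
                      vignette = cfg$correction$vignette,
                      min_images = cfg$correction$min_images)
  crun <- corr$run

  # --- segmentation -------------------------------------------------------
  nuc_cycle <- crun$cycles[[match(nuc_marker, run_markers)]]
  nucleus_mask <- segment_nuclei(nuc_cycle$tag_image,
                                 smooth_sigma = cfg$segmentation$smooth_sigma,
                                 min_size = cfg$segmentation$min_nucleus_size)
  seeds <- if (isTRUE(cfg$segmentation$seed_cells_with_nuclei)) nucleus_mask else NULL
  cell_mask <- segment_cells(nuc_cycle$phase_image, seeds = seeds,
                             min_size = cfg$segmentation$min_cell_size)
  cell_table <- reconcile_masks(cell_mask, nucleus_mask)
  if (!is.null(exclusions)) cell_table <- apply_exclusions(cell_table, exclusions)

  counts <- list(cells_segmented = attr(cell_table, "n_dropped_cells") %||% 0L,
                 cells_kept = nrow(cell_table),
                 dropped_by_reconciliation = attr(cell_table, "n_dropped_cells") %||% 0L,
                 unassigned_nuclei = attr(cell_table, "n_unassigned_nuclei") %||% 0L,
                 removed_by_exclusion = attr(cell_table, "n_excluded") %||% 0L)
  counts$cells_segmented <- counts$cells_kept + counts$dropped_by_reconciliation

  # --- features -----------------------------------------------------------
  features <- build_feature_table(crun, cell_table, cell_mask, nucleus_mask)

  # --- normalization ------------------------------------------------------
  panel_like <- data.frame(
    step = seq_along(crun$cycles),
    marker = vapply(crun$cycles, function(cy) cy$marker, character(1)),
    nc_partner = vapply(crun$cycles, function(cy) {
      # cycles store marker -> NC as nc_partner on the marker cycle
      cy$nc_partner %||% NA_character_
    }, character(1)),
    stringsAsFactors = FALSE)
  nc_pairs <- setNames(panel_like$nc_partner[!is.na(panel_like$nc_partner)],
                       panel_like$marker[!is.na(panel_like$nc_partner)])
  ex_pairs <- cfg$normalization$exclusive_pairs %||% character()
  ncfg <- normalization_config(
    nc_pairs = nc_pairs, exclusive_pairs = ex_pairs,
    q_counterpart = cfg$normalization$q_counterpart,
    q_background = cfg$normalization$q_background,
    reference_feature = cfg$normalization$reference_feature,
    min_reference_cells = cfg$normalization$min_reference_cells)
  norm <- normalize_features(features, ncfg)

  # --- atlas --------------------------------------------------------------
  atlas <- NULL
  n_cells <- nrow(norm$table)
  if (n_cells > max(10, cfg$atlas$perplexity)) {
    ap <- atlas_params(perplexity = cfg$atlas$perplexity,
                       gms_bandwidth = cfg$atlas$gms_bandwidth,
                       grid_size = cfg$atlas$grid_size,
                       n_subclusters = cfg$atlas$n_subclusters,
                       seed = derive_seed(seed, "atlas"))
    # exclude the nuclear-stain channel from phenotype features
    cols <- feature_columns(norm$table)
    cols <- cols[!grepl(paste0("^", nuc_marker, "_"), cols)]
    atlas <- build_atlas(norm$table, ap, columns = cols)
  }

  result <- structure(list(corrected = crun, shifts = corr$shifts,
                           gain = corr$gain, nucleus_mask = nucleus_mask,
                           cell_mask = cell_mask, cell_table = cell_table,
                           features = features, normalized = norm$table,
                           background_levels = norm$levels, atlas = atlas,
                           counts = counts, config = cfg,
                           config_hash = cfg_hash),
                      class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_artifacts(result, output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  cells kept: %d (dropped by reconciliation: %d, excluded: %d)\n",
              x$counts$cells_kept, x$counts$dropped_by_reconciliation,
              x$counts$removed_by_exclusion))
  if (!is.null(x$atlas)) {
    cat(sprintf("  atlas clusters: %d\n", length(unique(x$atlas$labels))))
  }
  cat(sprintf("  config hash: %s\n", x$config_hash))
  invisible(x)
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$shifts)) {
    write.csv(result$shifts, file.path(dir, "shifts.csv"), row.names = FALSE)
  }
  if (!is.null(result$gain)) {
    write_image_tiff(result$gain, file.path(dir, "gain_field.tif"), scale = 4)
  }
  write_label_mask(result$nucleus_mask, file.path(dir, "nucleus_mask.tif"))
  write_label_mask(result$cell_mask, file.path(dir, "cell_mask.tif"))
  write.csv(as.data.frame(result$cell_table), file.path(dir, "cell_table.csv"),
            row.names = FALSE)
  write_feature_table(result$features, file.path(dir, "features_raw.csv"))
  write_feature_table(result$normalized, file.path(dir, "features_normalized.csv"))
  write.csv(as.data.frame(result$background_levels),
            file.path(dir, "background_levels.csv"), row.names = FALSE)
  if (!is.null(result$atlas)) {
    emb <- data.frame(result$atlas$embedding, cluster = result$atlas$labels)
    write.csv(emb, file.path(dir, "atlas_embedding.csv"), row.names = FALSE)
    write.csv(as.data.frame(result$atlas$profiles),
              file.path(dir, "atlas_profiles.csv"), row.names = TRUE)
    write.csv(result$atlas$composition, file.path(dir, "atlas_composition.csv"),
              row.names = FALSE)
  }
  yaml::write_yaml(c(result$counts, list(config_hash = result$config_hash)),
                   file.path(dir, "pipeline_log.yaml"))
  invisible(dir)
}
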