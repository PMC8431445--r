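# Core containers: acquisition cycles, runs, calibration and panel configs.

#' Calibration image pair
#'
#' Brightfield and darkframe calibration images acquired once per field of
#' view; used by [flat_field_correct()].
#' @param brightfield,darkframe nonnegative numeric matrices, same shape.
#' @return a `calibration_images` list.
#' @export
calibration_images <- function(brightfield, darkframe) {
  assert_image(brightfield, "brightfield")
  assert_image(darkframe, "darkframe")
  assert_same_shape(brightfield, darkframe, "calibration images")
  if (any(brightfield < 0) || any(darkframe < 0)) {
    stopf("calibration images must be nonnegative")
  }
  structure(list(brightfield = brightfield, darkframe = darkframe),
            class = "calibration_images")
}

#' One MELC acquisition cycle
#'
#' A staining cycle contributes a fluorescence tag image, the post-bleach
#' image taken after photobleaching, and a phase-contrast image.
#' @param index 1-based cycle number, unique within a run.
#' @param marker marker (antibody/stain) name for the cycle.
#' @param is_negative_control `TRUE` for negative-control secondary-antibody
#'   acquisitions (no primary), which capture unspecific binding.
#' @param nc_partner for a marker cycle, the name of its negative-control
#'   channel, or `NULL`.
#' @param tag_image,postbleach_image,phase_image numeric matrices, same shape.
#' @return a `melc_cycle` list.
#' @export
new_melc_cycle <- function(index, marker, is_negative_control = FALSE,
                           nc_partner = NULL, tag_image, postbleach_image,
                           phase_image) {
  assert_image(tag_image, "tag_image")
  assert_same_shape(tag_image, postbleach_image, "cycle images")
  assert_same_shape(tag_image, phase_image, "cycle images")
  structure(list(index = as.integer(index), marker = as.character(marker),
                 is_negative_control = isTRUE(is_negative_control),
                 nc_partner = nc_partner,
                 tag_image = tag_image, postbleach_image = postbleach_image,
                 phase_image = phase_image),
            class = "melc_cycle")
}

#' A MELC acquisition run
#'
#' Ordered cycles plus calibration images and acquisition geometry.
#' @param cycles list of [new_melc_cycle()] objects.
#' @param calibration a [calibration_images()] pair.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param sample_id,fov_id identifiers carried into all outputs.
#' @return a `melc_run`.
#' @export
new_melc_run <- function(cycles, calibration, pixel_size,
                         sample_id = "sample", fov_id = "fov1") {
  if (length(cycles) < 1) stopf("a run needs at least one cycle")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")
  idx <- vapply(cycles, function(cy) cy$index, integer(1))
  if (anyDuplicated(idx)) stopf("cycle indices must be unique")
  structure(list(cycles = cycles[order(idx)], calibration = calibration,
                 pixel_size = pixel_size, sample_id = sample_id,
                 fov_id = fov_id),
            class = "melc_run")
}

#' @export
print.melc_run <- function(x, ...) {
  d <- dim(x$cycles[[1]]$tag_image)
  cat(sprintf("MELC run %s/%s: %d cycles, %dx%d px, %.2f um/px\n",
              x$sample_id, x$fov_id, length(x$cycles), d[1], d[2],
              x$pixel_size))
  mk <- vapply(x$cycles, function(cy) cy$marker, character(1))
  nc <- vapply(x$cycles, function(cy) cy$is_negative_control, logical(1))
  cat("  markers:", paste0(mk, ifelse(nc, " (NC)", ""), collapse = ", "), "\n")
  invisible(x)
}

markers_of <- function(run, include_nc = FALSE) {
  keep <- vapply(run$cycles, function(cy) include_nc || !cy$is_negative_control,
                 logical(1))
  vapply(run$cycles[keep], function(cy) cy$marker, character(1))
}

#' Field-of-view physical size
#'
#' Side length of the imaged field in micrometres:
#' `image_size_px * pixel_size_um`. For the standard MELC camera geometry
#' (2018 px at 0.45 um/px) this is 908.1 um.
#' @param image_size_px image side length in pixels.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @return side length in micrometres.
#' @examples
#' fov_physical_size(2018, 0.45)  # 908.1
#' @export
fov_physical_size <- function(image_size_px, pixel_size_um) {
  stopifnot(image_size_px > 0, pixel_size_um > 0)
  image_size_px * pixel_size_um
}

#' Read a panel configuration
#'
#' The panel table defines the imaging sequence: one row per staining step
#' with the marker name, conjugate/channel, whether the acquisition is a
#' negative control, and optional negative-control and mutually-exclusive
#' partner markers. A 20-plex bone-marrow panel is shipped at
#' `system.file("extdata", "panel_20plex.tsv", package = "melcpipe")`.
#'
#' @param path a TSV file with columns `step`, `marker`, `conjugate`,
#'   `is_negative_control`, `nc_partner`, `exclusive_partner` (missing
#'   optional columns are filled).
#' @return a `panel_config` data frame; step indices are validated to be
#'   contiguous 1..N.
#' @export
read_panel <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("step", "marker")
  if (!all(required %in% names(tab))) {
    stopf("panel file must have columns: %s", paste(required, collapse = ", "))
  }
  if (is.null(tab$conjugate)) tab$conjugate <- NA_character_
  if (is.null(tab$is_negative_control)) tab$is_negative_control <- FALSE
  tab$is_negative_control <- as.logical(tab$is_negative_control)
  for (col in c("nc_partner", "exclusive_partner")) {
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_
    tab[[col]][tab[[col]] %in% c("", "NA")] <- NA_character_
  }
  as_panel_config(tab)
}

#' Construct/validate a panel configuration
#'
#' @param tab data frame with at least `step` and `marker` columns.
#' @return the validated `panel_config`.
#' @export
as_panel_config <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  tab <- tab[order(tab$step), , drop = FALSE]
  if (!identical(as.integer(tab$step), seq_len(nrow(tab)))) {
    stopf("panel step indices must be contiguous 1..%d", nrow(tab))
  }
  for (col in c("nc_partner", "exclusive_partner")) {
    if (!is.null(tab[[col]])) {
      refs <- tab[[col]][!is.na(tab[[col]])]
      missing <- setdiff(refs, tab$marker)
      if (length(missing)) {
        stopf("panel column '%s' references unknown markers: %s",
              col, paste(missing, collapse = ", "))
      }
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("panel_config", "data.frame")
  tab
}
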