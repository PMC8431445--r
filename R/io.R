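# TIFF and tabular I/O for runs, masks and gain fields.
#
# Images are plain numeric matrices (rows = y, columns = x) in intensity
# counts. 16-bit grayscale TIFF is the on-disk interchange format; label
# masks are written as 16-bit TIFF with the label number as pixel value.

#' Read a grayscale image from TIFF
#'
#' @param path path to a TIFF file.
#' @param scale multiply the stored \[0, 1\] sample values by this factor;
#'   default 65535 restores 16-bit integer counts.
#' @return numeric matrix.
#' @export
read_image_tiff <- function(path, scale = 65535) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * scale
}

#' Write a grayscale image as 16-bit TIFF
#'
#' Values are clipped to `[0, scale]` and rounded to the nearest of 65535
#' levels, so a written-and-reread image is integer-valued.
#' @param img numeric matrix.
#' @param path output path.
#' @param scale intensity corresponding to the top of the 16-bit range.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, scale = 65535) {
  assert_image(img)
  x <- round(pmin(pmax(img / scale, 0), 1) * 65535) / 65535
  tiff::writeTIFF(x, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read / write integer label masks
#'
#' Label masks (0 = background) round-trip exactly through 16-bit TIFF for
#' up to 65535 objects.
#' @param path TIFF path.
#' @return integer matrix.
#' @export
read_label_mask <- function(path) {
  m <- read_image_tiff(path, scale = 65535)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_mask
#' @param mask integer matrix of labels.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535) stopf("label mask has more than 65535 labels")
  write_image_tiff(mask, path, scale = 65535)
}

melc_image_filename <- function(sample_id, fov_id, cycle, kind) {
  sprintf("%s_%s_c%02d_%s.tif", sample_id, fov_id, cycle, kind)
}

#' Write a MELC run to a directory
#'
#' One 16-bit TIFF per image, named
#' `<sample>_<fov>_c<cycle>_<tag|bleach|phase>.tif`, plus
#' `<sample>_<fov>_brightfield.tif` / `_darkframe.tif` and a `run.yaml`
#' manifest with the cycle table and pixel size.
#' @param run a `melc_run` (see [render_run()]).
#' @param dir output directory (created if missing).
#' @param scale intensity mapped to the top of the 16-bit range.
#' @return `dir`, invisibly.
#' @export
write_melc_run <- function(run, dir, scale = 65535) {
  stopifnot(inherits(run, "melc_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kinds <- c(tag = "tag", postbleach = "bleach", phase = "phase")
  cyc_rows <- list()
  for (cy in run$cycles) {
    for (field in names(kinds)) {
      fn <- melc_image_filename(run$sample_id, run$fov_id, cy$index, kinds[[field]])
      write_image_tiff(cy[[paste0(field, "_image")]], file.path(dir, fn), scale)
    }
    cyc_rows[[length(cyc_rows) + 1L]] <- data.frame(
      index = cy$index, marker = cy$marker,
      is_negative_control = cy$is_negative_control,
      nc_partner = cy$nc_partner %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  write_image_tiff(run$calibration$brightfield,
                   file.path(dir, sprintf("%s_%s_brightfield.tif", run$sample_id, run$fov_id)), scale)
  write_image_tiff(run$calibration$darkframe,
                   file.path(dir, sprintf("%s_%s_darkframe.tif", run$sample_id, run$fov_id)), scale)
  manifest <- list(sample_id = run$sample_id, fov_id = run$fov_id,
                   pixel_size = run$pixel_size, intensity_scale = scale,
                   cycles = do.call(rbind, cyc_rows))
  yaml::write_yaml(list(sample_id = manifest$sample_id, fov_id = manifest$fov_id,
                        pixel_size = manifest$pixel_size, intensity_scale = scale,
                        cycles = lapply(cyc_rows, as.list)),
                   file.path(dir, "run.yaml"))
  invisible(dir)
}

#' Read a MELC run written by [write_melc_run()]
#'
#' @param dir directory containing the TIFFs and `run.yaml`.
#' @return a `melc_run`.
#' @export
read_melc_run <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "run.yaml"))
  scale <- man$intensity_scale %||% 65535
  kinds <- c(tag = "tag", postbleach = "bleach", phase = "phase")
  cycles <- lapply(man$cycles, function(cy) {
    imgs <- lapply(kinds, function(k) {
      read_image_tiff(file.path(dir, melc_image_filename(
        man$sample_id, man$fov_id, cy$index, k)), scale)
    })
    new_melc_cycle(index = cy$index, marker = cy$marker,
                   is_negative_control = isTRUE(cy$is_negative_control),
                   nc_partner = if (is.null(cy$nc_partner) || is.na(cy$nc_partner)) NULL else cy$nc_partner,
                   tag_image = imgs$tag, postbleach_image = imgs$postbleach,
                   phase_image = imgs$phase)
  })
  calib <- calibration_images(
    brightfield = read_image_tiff(file.path(dir, sprintf("%s_%s_brightfield.tif",
                                                         man$sample_id, man$fov_id)), scale),
    darkframe = read_image_tiff(file.path(dir, sprintf("%s_%s_darkframe.tif",
                                                       man$sample_id, man$fov_id)), scale))
  new_melc_run(cycles = cycles, calibration = calib, pixel_size = man$pixel_size,
               sample_id = man$sample_id, fov_id = man$fov_id)
}
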