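#' Write / read a well image stack as multi-page TIFF
#'
#' Pages are ordered frame-major, channel-minor with channel order
#' brightfield, blue, green (channels absent from the set are skipped
#' consistently across frames). Intensities are stored as-is in `[0, 1]`.
#'
#' @param images a [well_image_set()].
#' @param path output TIFF path.
#' @return `read_well_tiff()` returns a [well_image_set()].
#' @export
write_well_tiff <- function(images, path) {
  chans <- intersect(c("bf", "blue", "green"), names(images$frames[[1]]))
  pages <- list()
  for (fr in images$frames) for (ch in chans)
    pages[[length(pages) + 1L]] <- fr[[ch]]
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_well_tiff
#' @param well_id,times_h,um_per_px metadata for the restored set (TIFF
#'   pages carry no timing/scale metadata of their own).
#' @param channels channel names present in the stack, in page order.
#' @export
read_well_tiff <- function(path, well_id, times_h, um_per_px,
                           channels = c("bf", "blue", "green")) {
  if (!file.exists(path)) stop("TIFF not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  k <- length(channels)
  if (length(pages) %% k != 0L)
    stop(sprintf("parse error in %s: %d pages not divisible by %d channels",
                 path, length(pages), k), call. = FALSE)
  n_fr <- length(pages) %/% k
  if (length(times_h) != n_fr)
    stop(sprintf("parse error in %s: %d frames on disk vs %d times given",
                 path, n_fr, length(times_h)), call. = FALSE)
  frames <- lapply(seq_len(n_fr), function(f) {
    fr <- lapply(seq_len(k), function(c_i) {
      pg <- pages[[(f - 1L) * k + c_i]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]
      pg
    })
    names(fr) <- channels
    fr
  })
  well_image_set(well_id, times_h, frames, um_per_px)
}

#' Write / read a label mask as 16-bit TIFF
#'
#' Labels are stored as intensity `label / 65535`, so up to 65535
#' objects round-trip exactly.
#'
#' @param mask a [labeled_mask()].
#' @param path TIFF path.
#' @export
write_mask_tiff <- function(mask, path) {
  labels <- mask_labels(mask)
  if (max(labels) > 65535L)
    stop("more than 65535 labels cannot be stored in 16 bits", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param frame,provenance metadata for the restored mask.
#' @export
read_mask_tiff <- function(path, frame = 0L, provenance = "truth") {
  pg <- tiff::readTIFF(path)
  if (length(dim(pg)) == 3L) pg <- pg[, , 1]
  labeled_mask(matrix(as.integer(round(pg * 65535)), nrow(pg), ncol(pg)),
               frame = frame, provenance = provenance)
}

#' Colored object overlay
#'
#' Writes a PNG in which each labeled object is drawn in a distinct
#' color over the (grayscale) brightfield image, the standard visual
#' check of segmentation accuracy.
#'
#' @param bf brightfield raster.
#' @param mask a [labeled_mask()].
#' @param path PNG path.
#' @export
write_overlay_png <- function(bf, mask, path) {
  col <- EBImage::colorLabels(EBImage::Image(mask_labels(mask)))
  base <- EBImage::rgbImage(red = bf, green = bf, blue = bf)
  out <- base * 0.6 + col * 0.4
  EBImage::writeImage(EBImage::Image(pmin(pmax(EBImage::imageData(out), 0), 1),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write / read the truth tables of a simulated plate
#'
#' `states` and `per_well` go to two CSVs, the configuration to YAML.
#'
#' @param truth a `plate_truth` from [simulate_plate()].
#' @param dir output directory (created if needed).
#' @export
write_plate_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(truth$states),
                   file.path(dir, "truth_states.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(as.data.frame(truth$per_well),
                   file.path(dir, "truth_per_well.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  write_sim_config(truth$config, file.path(dir, "sim_config.yaml"))
  write_plate_map(truth$plate_map, file.path(dir, "plate_map.csv"))
  invisible(dir)
}

#' Round-trip a simulation configuration through YAML
#'
#' @param config a [simulation_config()].
#' @param path YAML path.
#' @return `read_sim_config()` returns the validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  # named atomic vectors flatten to plain sequences in YAML; keep the map
  cfg$artifact_rates <- as.list(cfg$artifact_rates)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$image_size_px <- as.integer(cfg$image_size_px)
  cfg$artifact_rates <- unlist(cfg$artifact_rates)
  validate_sim_config(cfg)
}
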