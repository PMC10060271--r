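#' Multi-channel time-lapse image set for one well
#'
#' Container for the raw imaging data of a single well: an ordered list of
#' frames, each holding a required brightfield raster and optional blue
#' (nuclear) and green (death-marker) rasters, plus the physical pixel
#' scale. Frame times are hours from the first measurement (T0) and must
#' be strictly increasing; all channels of a frame must share dimensions.
#'
#' @param well_id plate coordinate (e.g. `"B07"`).
#' @param times_h numeric vector of frame times in hours from T0.
#' @param frames list (one element per frame) of lists with elements
#'   `bf` (required matrix) and optionally `blue`, `green`.
#' @param um_per_px physical scale in micrometres per pixel.
#' @return A `well_image_set` object.
#' @export
well_image_set <- function(well_id, times_h, frames, um_per_px) {
  if (length(times_h) != length(frames))
    stop("times_h and frames must have equal length", call. = FALSE)
  if (length(times_h) && any(diff(times_h) <= 0))
    abort_field("times_h", "frame times must be strictly increasing")
  assert_scalar_num(um_per_px, "um_per_px", lower = 0, strict_lower = TRUE)
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (is.null(fr$bf))
      abort_field("frames", sprintf("frame %d lacks the brightfield channel", f))
    assert_matrix(fr$bf, sprintf("frames[[%d]]$bf", f))
    for (ch in intersect(c("blue", "green"), names(fr))) {
      if (is.null(fr[[ch]])) next
      assert_matrix(fr[[ch]], sprintf("frames[[%d]]$%s", f, ch))
      if (!identical(dim(fr[[ch]]), dim(fr$bf)))
        abort_field("frames",
                    sprintf("frame %d: %s and bf dimensions differ", f, ch))
    }
  }
  structure(list(well_id = well_id, times_h = as.numeric(times_h),
                 frames = frames, um_per_px = um_per_px),
            class = "well_image_set")
}

#' @export
print.well_image_set <- function(x, ...) {
  chans <- if (length(x$frames))
    paste(intersect(c("bf", "blue", "green"), names(x$frames[[1]])),
          collapse = "+") else ""
  dims <- if (length(x$frames)) paste(dim(x$frames[[1]]$bf), collapse = "x")
  else "?"
  cat(sprintf("<well_image_set> %s: %d frames (%s), %s px @ %.3g um/px\n",
              x$well_id, length(x$frames), chans, dims, x$um_per_px))
  invisible(x)
}

n_frames <- function(ws) length(ws$frames)
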