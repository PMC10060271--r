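#' Segmentation parameters
#'
#' Settings of the classical brightfield segmentation chain and the shared
#' post-processing used by both the classical and the network path.
#'
#' @param min_object_area_px smallest object kept, in pixels; excludes
#'   single-pixel noise and debris specks.
#' @param background_sigma Gaussian sigma (px) of the large-scale smoothing
#'   used for background flattening.
#' @param smooth_sigma Gaussian sigma (px) smoothing the darkness response
#'   before thresholding.
#' @param min_contrast smallest peak response (after smoothing) treated
#'   as signal; below it the frame is declared empty (guards Otsu
#'   against pure noise).
#' @param closing_radius radius (px) of the disc brush used for
#'   morphological closing before hole filling.
#' @param split_touching if `TRUE`, touching objects are split with
#'   distance-transform watershed markers. Off by default: fused organoids
#'   are intentionally kept as one object.
#' @param split_tolerance watershed tolerance when splitting.
#' @return A `seg_params` list.
#' @export
seg_params <- function(min_object_area_px = 60,
                       background_sigma = 20,
                       smooth_sigma = 1.5,
                       min_contrast = 0.12,
                       closing_radius = 5,
                       split_touching = FALSE,
                       split_tolerance = 1) {
  structure(list(min_object_area_px = min_object_area_px,
                 background_sigma = background_sigma,
                 smooth_sigma = smooth_sigma, min_contrast = min_contrast,
                 closing_radius = closing_radius,
                 split_touching = isTRUE(split_touching),
                 split_tolerance = split_tolerance),
            class = "seg_params")
}

#' Classical brightfield segmentation
#'
#' Deterministic label-free segmentation of organoids in a brightfield
#' raster: background flattening (subtraction of a large-sigma Gaussian
#' blur), a darkness response (organoids image darker than the
#' background; bright artifacts such as bubble rings drop out here),
#' smoothing, Otsu thresholding, morphological closing and hole filling
#' (so cystic lumens are included in the object, matching brightfield
#' area semantics), connected components, a minimum-area filter and
#' optional marker-based splitting of touching objects.
#'
#' @param bf 2-D numeric brightfield raster in `[0, 1]`.
#' @param params a [seg_params()].
#' @param frame frame index recorded on the output mask.
#' @return A [labeled_mask()] with `provenance = "classical"`.
#' @export
segment_classical <- function(bf, params = seg_params(), frame = 0L) {
  assert_matrix(bf, "bf")
  # the Gaussian brush (2*ceiling(3*sigma)+1 wide) must fit the raster
  sigma_bg <- min(params$background_sigma, (min(dim(bf)) - 3) / 6)
  bg <- EBImage::gblur(bf, sigma = sigma_bg)
  darkness <- pmax(bg - bf, 0)
  resp <- EBImage::gblur(darkness, sigma = params$smooth_sigma)
  if (max(resp) < params$min_contrast) {
    return(labeled_mask(matrix(0L, nrow(bf), ncol(bf)), frame = frame,
                        provenance = "classical"))
  }
  resp <- resp / max(resp)
  thr <- EBImage::otsu(EBImage::Image(resp), range = c(0, 1))
  labels <- postprocess_binary(resp > thr, params)
  as_labeled <- labeled_mask(labels, frame = frame, provenance = "classical")
  as_labeled$boundary_labels <- boundary_labels(labels)
  as_labeled
}

#' Fluorescence-derived ground-truth mask
#'
#' Builds the segmentation ground truth from fluorescence channels, the
#' way the network training labels are produced: the nuclear (blue)
#' channel is auto-thresholded per frame, green-positive regions are
#' unioned in (dead nuclei remain part of the object), and rim-only
#' cystic signals are closed into filled objects via morphological
#' closing and hole filling.
#'
#' @param blue nuclear-channel raster (required).
#' @param green death-marker raster or `NULL`.
#' @param params a [seg_params()].
#' @param frame frame index recorded on the output mask.
#' @return A [labeled_mask()] with `provenance = "truth"`.
#' @export
fluorescence_ground_truth <- function(blue, green = NULL,
                                      params = seg_params(), frame = 0L) {
  if (is.null(blue)) stop("blue channel is required", call. = FALSE)
  assert_matrix(blue, "blue")
  if (max(blue) == 0) {
    warning("all-zero blue channel; returning empty mask")
    return(labeled_mask(matrix(0L, nrow(blue), ncol(blue)), frame = frame,
                        provenance = "truth"))
  }
  bin <- auto_threshold(blue, params$min_contrast)
  if (!is.null(green)) {
    assert_matrix(green, "green")
    if (!identical(dim(green), dim(blue)))
      stop("green and blue dimensions differ", call. = FALSE)
    bin <- bin | auto_threshold(green, params$min_contrast)
  }
  labels <- postprocess_binary(bin, params)
  out <- labeled_mask(labels, frame = frame, provenance = "truth")
  out$boundary_labels <- boundary_labels(labels)
  out
}

# Background-robust automatic threshold: light smoothing (suppresses
# read noise), median subtraction, normalization, Otsu; returns
# all-FALSE if the channel has no contrast beyond the noise floor.
auto_threshold <- function(x, min_contrast) {
  x <- EBImage::gblur(x, sigma = 1)
  x0 <- pmax(x - stats::median(x), 0)
  if (max(x0) < min_contrast) return(matrix(FALSE, nrow(x), ncol(x)))
  x0 <- x0 / max(x0)
  thr <- EBImage::otsu(EBImage::Image(x0), range = c(0, 1))
  x0 > thr
}

# Shared post-processing: closing -> hole fill -> components -> min-area
# filter (-> optional watershed split), then sequential relabeling.
postprocess_binary <- function(bin, params) {
  bin <- matrix(as.numeric(bin), nrow(bin), ncol(bin))
  brush_r <- max(3, 2 * floor(params$closing_radius / 2) + 1)
  bin <- EBImage::closing(bin, EBImage::makeBrush(brush_r, "disc"))
  bin <- EBImage::fillHull(bin)
  if (params$split_touching) {
    dm <- EBImage::distmap(bin)
    labels <- EBImage::watershed(dm, tolerance = params$split_tolerance)
  } else {
    labels <- EBImage::bwlabel(bin)
  }
  labels <- matrix(as.integer(round(as.numeric(labels))),
                   nrow(bin), ncol(bin))
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= params$min_object_area_px)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0] <- relabel[labels[labels > 0]]
  labels
}

boundary_labels <- function(labels) {
  edge <- c(labels[1, ], labels[nrow(labels), ], labels[, 1],
            labels[, ncol(labels)])
  sort(setdiff(unique(edge), 0L))
}

#' Overlap summary between two masks
#'
#' Compares the foregrounds of two masks of identical dimensions, in
#' physical units, the way brightfield/Hoechst and green/brightfield
#' overlaps are reported per well.
#'
#' @param a,b [labeled_mask()]s or binary/label matrices with identical
#'   dimensions.
#' @param um_per_px physical scale used to convert pixel counts to µm².
#' @return A list: `intersection_um2`, `area_a_um2`, `area_b_um2`,
#'   `fraction_a` = |A∩B|/|A| (NA when A is empty), `iou`, and
#'   `per_object` — for each object of `a`, the fraction of its pixels
#'   covered by `b`.
#' @export
mask_overlap <- function(a, b, um_per_px = 1) {
  ba <- mask_binary(a); bb <- mask_binary(b)
  if (!identical(dim(ba), dim(bb)))
    stop("mask dimensions differ: ", paste(dim(ba), collapse = "x"), " vs ",
         paste(dim(bb), collapse = "x"), call. = FALSE)
  px2 <- um_per_px^2
  inter <- sum(ba & bb)
  union <- sum(ba | bb)
  la <- mask_labels(if (inherits(a, "labeled_mask")) a else ba * 1L)
  ids <- sort(setdiff(unique(as.vector(la)), 0L))
  per_object <- tibble::tibble(
    label = as.integer(ids),
    fraction = vapply(ids, function(k) {
      sel <- la == k
      sum(sel & bb) / sum(sel)
    }, numeric(1)))
  list(intersection_um2 = inter * px2,
       area_a_um2 = sum(ba) * px2,
       area_b_um2 = sum(bb) * px2,
       fraction_a = if (sum(ba)) inter / sum(ba) else NA_real_,
       iou = if (union) inter / union else NA_real_,
       per_object = per_object)
}
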