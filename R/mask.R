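#' Labeled segmentation mask
#'
#' An integer raster in which 0 is background and each positive value
#' labels one organoid object, plus the frame index it belongs to and the
#' provenance of the segmentation (`"classical"`, `"fcn"` or `"truth"`).
#'
#' @param labels integer matrix, 0 = background.
#' @param frame 0-based timepoint index.
#' @param provenance one of `"classical"`, `"fcn"`, `"truth"`.
#' @param boundary_labels labels of objects touching the raster edge.
#' @return A `labeled_mask` object.
#' @export
labeled_mask <- function(labels, frame = 0L,
                         provenance = c("classical", "fcn", "truth"),
                         boundary_labels = integer()) {
  assert_matrix(labels, "labels")
  provenance <- match.arg(provenance)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, frame = as.integer(frame),
                 provenance = provenance,
                 boundary_labels = as.integer(boundary_labels)),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %dx%d, %d object(s), frame %d, provenance %s\n",
              nrow(x$labels), ncol(x$labels), n_objects(x), x$frame,
              x$provenance))
  invisible(x)
}

#' Object-level summaries of a labeled mask
#'
#' @param mask a [labeled_mask()] (or a bare label matrix).
#' @return `n_objects()`: the number of distinct nonzero labels.
#'   `mask_objects()`: a tibble with one row per object (`label`,
#'   `area_px`, centroid `cx_px`/`cy_px` in 0-based pixel coordinates,
#'   and `boundary` — whether the object touches the raster edge).
#' @export
n_objects <- function(mask) {
  labels <- mask_labels(mask)
  length(setdiff(unique(as.vector(labels)), 0L))
}

#' @rdname n_objects
#' @export
mask_objects <- function(mask) {
  labels <- mask_labels(mask)
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!length(ids))
    return(tibble::tibble(label = integer(), area_px = integer(),
                          cx_px = numeric(), cy_px = numeric(),
                          boundary = logical()))
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nr          # 0-based row
  cols <- (idx - 1L) %/% nr         # 0-based col
  area <- tapply(rep(1L, length(lab)), lab, sum)
  cx <- tapply(cols, lab, mean)
  cy <- tapply(rows, lab, mean)
  on_edge <- rows == 0L | rows == nr - 1L | cols == 0L | cols == nc - 1L
  bdry <- tapply(on_edge, lab, any)
  tibble::tibble(label = as.integer(names(area)),
                 area_px = as.integer(area),
                 cx_px = as.numeric(cx), cy_px = as.numeric(cy),
                 boundary = as.logical(bdry))
}

mask_labels <- function(mask) {
  if (inherits(mask, "labeled_mask")) mask$labels
  else { assert_matrix(mask, "mask"); mask }
}

# Binary foreground of a mask argument (labeled_mask, label matrix or
# logical matrix).
mask_binary <- function(mask) {
  m <- if (inherits(mask, "labeled_mask")) mask$labels else mask
  assert_matrix(m * 1, "mask")
  m > 0
}
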