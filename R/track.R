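#' Track organoid objects across frames
#'
#' Greedy overlap-based tracking (organoids are near-static, so no motion
#' model is used): each object in frame `t` is linked to the frame `t+1`
#' object sharing the most pixels with it; ties go to the larger-area
#' successor, then the lower label. An object in frame `t+1` claimed by
#' two or more predecessors generates a merge (fusion) event; objects
#' with no link generate appearance or disappearance events.
#'
#' @param masks list of per-frame [labeled_mask()]s (or label matrices)
#'   with identical dimensions, ordered by frame.
#' @return A `track_graph`: `nodes` (frame, label, area_px, centroid),
#'   `edges` (frame_from, label_from, label_to, overlap_px) and `events`
#'   (type `merge` / `appearance` / `disappearance`, frame, label,
#'   `parent_labels` for merges).
#' @export
track_objects <- function(masks) {
  labels <- lapply(masks, mask_labels)
  if (length(labels) < 1L) stop("no masks supplied", call. = FALSE)
  dims <- dim(labels[[1]])
  for (m in labels) if (!identical(dim(m), dims))
    stop("masks must share dimensions", call. = FALSE)
  nodes <- do.call(rbind, lapply(seq_along(labels), function(f) {
    obj <- mask_objects(labels[[f]])
    if (nrow(obj)) tibble::tibble(frame = f - 1L, label = obj$label,
                                  area_px = obj$area_px, cx_px = obj$cx_px,
                                  cy_px = obj$cy_px)
    else tibble::tibble(frame = integer(), label = integer(),
                        area_px = integer(), cx_px = numeric(),
                        cy_px = numeric())
  }))
  edges <- list(); events <- list()
  if (length(labels) < 2L) {
    warning("single frame: empty edge set")
  }
  for (f in seq_len(length(labels) - 1L)) {
    a <- labels[[f]]; b <- labels[[f + 1L]]
    both <- a > 0L & b > 0L
    link <- if (any(both)) {
      ov <- as.data.frame(table(from = a[both], to = b[both]),
                          stringsAsFactors = FALSE)
      ov <- ov[ov$Freq > 0, ]
      ov$from <- as.integer(ov$from); ov$to <- as.integer(ov$to)
      area_b <- tabulate(b[b > 0L])
      # per predecessor: successor with max overlap; ties -> larger
      # successor area, then lower label
      ov <- ov[order(ov$from, -ov$Freq, -area_b[ov$to], ov$to), ]
      ov[!duplicated(ov$from), ]
    } else data.frame(from = integer(), to = integer(), Freq = integer())
    if (nrow(link))
      edges[[length(edges) + 1L]] <- tibble::tibble(
        frame_from = f - 1L, label_from = link$from, label_to = link$to,
        overlap_px = as.integer(link$Freq))
    # merge events: successor claimed by >= 2 predecessors
    if (nrow(link)) {
      tab <- table(link$to)
      for (to in as.integer(names(tab)[tab >= 2])) {
        events[[length(events) + 1L]] <- tibble::tibble(
          type = "merge", frame = f, label = to,
          parent_labels = paste(sort(link$from[link$to == to]),
                                collapse = ";"))
      }
    }
    la <- setdiff(unique(as.vector(a)), 0L)
    lb <- setdiff(unique(as.vector(b)), 0L)
    for (gone in setdiff(la, link$from))
      events[[length(events) + 1L]] <- tibble::tibble(
        type = "disappearance", frame = f, label = gone, parent_labels = "")
    for (new in setdiff(lb, link$to))
      events[[length(events) + 1L]] <- tibble::tibble(
        type = "appearance", frame = f, label = new, parent_labels = "")
  }
  empty_edges <- tibble::tibble(frame_from = integer(), label_from = integer(),
                                label_to = integer(), overlap_px = integer())
  empty_events <- tibble::tibble(type = character(), frame = integer(),
                                 label = integer(), parent_labels = character())
  structure(list(
    nodes = nodes,
    edges = if (length(edges)) do.call(rbind, edges) else empty_edges,
    events = if (length(events)) do.call(rbind, events) else empty_events),
    class = "track_graph")
}

#' @export
print.track_graph <- function(x, ...) {
  cat(sprintf("<track_graph> %d nodes, %d edges, %d event(s) (%d merges)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$events),
              sum(x$events$type == "merge")))
  invisible(x)
}

#' Per-frame object counts of a track graph
#'
#' @param graph a `track_graph`.
#' @return Tibble with `frame` and `count`.
#' @export
track_counts <- function(graph) {
  frames <- sort(unique(graph$nodes$frame))
  tibble::tibble(frame = frames,
                 count = vapply(frames, function(f)
                   sum(graph$nodes$frame == f), integer(1)))
}

#' Write a track graph's events to JSON
#'
#' @param graph a `track_graph`.
#' @param path output file.
#' @export
write_track_graph <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes, edges = graph$edges, events = graph$events),
    path, dataframe = "rows", digits = NA)
  invisible(path)
}
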