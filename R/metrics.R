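#' Per-well kinetic metric table
#'
#' Reduces a well's image stack and per-frame masks to the well-level
#' kinetic metrics: object count, mean and total mask area (µm²), total
#' green (death-marker) area and intensity within the mask, the
#' intra-well normalized ratios green-area/mask-area (µm²/µm²) and
#' green-intensity/mask-area (RFU/µm²), and the viable area
#' (total mask area − total green area).
#'
#' Green intensities are background-subtracted (median of out-of-mask
#' pixels, per frame) before summation. When the set has no green
#' channel, green metrics are 0-filled and flagged via `green_available`.
#' Ratios with an empty mask are undefined: reported as `NA` with
#' `ratio_defined = FALSE`, never silently 0.
#'
#' @param images a [well_image_set()].
#' @param masks list of per-frame [labeled_mask()]s aligned to the frames.
#' @param green_threshold intensity (above background) above which a
#'   pixel counts as green-positive.
#' @return A `well_time_series` tibble with one row per frame and
#'   attributes `well_id` and `um_per_px`.
#' @export
compute_well_metrics <- function(images, masks, green_threshold = 0.25) {
  if (!inherits(images, "well_image_set"))
    stop("images must be a well_image_set", call. = FALSE)
  if (length(masks) != n_frames(images))
    stop(sprintf("frame/mask misalignment: %d frames vs %d masks",
                 n_frames(images), length(masks)), call. = FALSE)
  px2 <- images$um_per_px^2
  rows <- lapply(seq_along(masks), function(f) {
    lab <- mask_labels(masks[[f]])
    fr <- images$frames[[f]]
    if (!identical(dim(lab), dim(fr$bf)))
      stop(sprintf("frame/mask misalignment at frame %d: dimensions differ",
                   f), call. = FALSE)
    fg <- lab > 0L
    count <- length(setdiff(unique(lab[fg]), 0L))
    total_area <- sum(fg) * px2
    green_avail <- !is.null(fr$green)
    if (green_avail) {
      bgmed <- if (all(fg)) 0 else stats::median(fr$green[!fg])
      gcorr <- pmax(fr$green - bgmed, 0)
      gpos <- gcorr > green_threshold & fg
      green_area <- sum(gpos) * px2
      green_int <- sum(gcorr[fg])
    } else {
      green_area <- 0; green_int <- 0
    }
    tibble::tibble(
      well_id = images$well_id, frame = f - 1L,
      time_h = images$times_h[f], count = count,
      mean_mask_area_um2 = if (count) total_area / count else 0,
      total_mask_area_um2 = total_area,
      total_green_area_um2 = green_area,
      total_green_intensity = green_int,
      green_area_ratio = if (total_area > 0) green_area / total_area
      else NA_real_,
      green_intensity_ratio = if (total_area > 0) green_int / total_area
      else NA_real_,
      viable_area_um2 = max(total_area - green_area, 0),
      ratio_defined = total_area > 0,
      green_available = green_avail)
  })
  ts <- do.call(rbind, rows)
  attr(ts, "well_id") <- images$well_id
  attr(ts, "um_per_px") <- images$um_per_px
  class(ts) <- c("well_time_series", class(ts))
  ts
}

#' Fold change of a metric from the first measurement
#'
#' Per-well fold change: the metric at time `t` divided by its value at
#' the first measurement (T0).
#'
#' @param ts a `well_time_series` (or any data frame with `frame` and
#'   the metric column).
#' @param metric metric column name, e.g. `"viable_area_um2"`.
#' @param frame frame at which to evaluate; default the last.
#' @return A single fold change, or `NA` (with a warning) if the metric
#'   is not positive at T0.
#' @export
fold_change <- function(ts, metric = "viable_area_um2", frame = max(ts$frame)) {
  v0 <- ts[[metric]][ts$frame == min(ts$frame)]
  vt <- ts[[metric]][ts$frame == frame]
  if (!length(v0) || !is.finite(v0) || v0 <= 0) {
    warning("fold change undefined: metric not positive at T0")
    return(NA_real_)
  }
  vt / v0
}

#' Interval growth rates of a well metric
#'
#' Log2 fold change of the metric per frame interval, plus the average
#' rate over the series (per interval and per hour).
#'
#' @inheritParams fold_change
#' @return A list: `per_interval` (tibble with `frame`, `time_h`,
#'   `log2_fc`), `average_log2_per_interval`, `average_log2_per_h`, and
#'   `defined` (FALSE when the metric is not positive at T0, in which
#'   case rates are `NA`).
#' @export
growth_rate_series <- function(ts, metric = "total_mask_area_um2") {
  ord <- order(ts$frame)
  v <- ts[[metric]][ord]
  t_h <- ts$time_h[ord]
  if (!is.finite(v[1]) || v[1] <= 0) {
    warning("growth rate undefined: metric not positive at T0")
    return(list(per_interval = tibble::tibble(frame = integer(),
                                              time_h = numeric(),
                                              log2_fc = numeric()),
                average_log2_per_interval = NA_real_,
                average_log2_per_h = NA_real_, defined = FALSE))
  }
  lf <- diff(log2(v))
  dt <- diff(t_h)
  list(per_interval = tibble::tibble(frame = ts$frame[ord][-1],
                                     time_h = t_h[-1], log2_fc = lf),
       average_log2_per_interval = mean(lf),
       average_log2_per_h = mean(lf / dt),
       defined = TRUE)
}

#' Write well time series as long-format CSV
#'
#' One row per (well, frame, metric): columns `well_id`, `frame`,
#' `time_h`, `metric`, `value`.
#'
#' @param ts_list list of `well_time_series` (or a single one).
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(ts_list, path) {
  if (inherits(ts_list, "well_time_series")) ts_list <- list(ts_list)
  metrics <- c("count", "mean_mask_area_um2", "total_mask_area_um2",
               "total_green_area_um2", "total_green_intensity",
               "green_area_ratio", "green_intensity_ratio",
               "viable_area_um2")
  long <- do.call(rbind, lapply(ts_list, function(ts) {
    do.call(rbind, lapply(metrics, function(m)
      data.frame(well_id = ts$well_id, frame = ts$frame, time_h = ts$time_h,
                 metric = m, value = as.numeric(ts[[m]]))))
  }))
  long <- long[order(long$well_id, long$frame, long$metric), ]
  utils::write.csv(long, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format metrics CSV back into wide per-well tables
#'
#' @param path CSV written by [write_metrics_csv()].
#' @return Named list of per-well wide tibbles.
#' @export
read_metrics_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  wells <- unique(long$well_id)
  out <- lapply(wells, function(w) {
    sub <- long[long$well_id == w, ]
    wide <- stats::reshape(sub, idvar = c("well_id", "frame", "time_h"),
                           timevar = "metric", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    tibble::as_tibble(wide[order(wide$frame), ])
  })
  names(out) <- wells
  out
}
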