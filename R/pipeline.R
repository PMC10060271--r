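#' Pipeline run configuration
#'
#' Bundles everything one screening run needs: where images come from (a
#' simulation config, or a directory of per-well TIFF stacks), the plate
#' map, the segmentation backend, the response metric and endpoint, and
#' the output directory.
#'
#' @param plate_map a [plate_map()] or path to a plate-map CSV.
#' @param out_dir output directory.
#' @param sim a [simulation_config()] to simulate input images, or `NULL`
#'   to read them from `images_dir`.
#' @param images_dir directory with `well_<id>.tif` stacks (used when
#'   `sim` is `NULL`); requires `times_h` and `um_per_px`.
#' @param times_h,um_per_px acquisition times and pixel scale for
#'   `images_dir` input.
#' @param backend `"classical"` or `"fcn"`.
#' @param seg a [seg_params()].
#' @param model a trained `seg_model` (required for the fcn backend).
#' @param metric response metric column, default the viable area
#'   (total mask area − total green area).
#' @param endpoint_frame frame used for fold changes (default: last).
#' @param normalize_mode control normalization for the dose-response fit.
#' @param seed master seed for any stochastic stage.
#' @param write_images write simulated TIFF stacks and truth tables.
#' @param write_overlays write one overlay PNG per well (final frame).
#' @return A `run_config` list.
#' @export
run_config <- function(plate_map, out_dir, sim = NULL, images_dir = NULL,
                       times_h = NULL, um_per_px = NULL,
                       backend = c("classical", "fcn"), seg = seg_params(),
                       model = NULL, metric = "viable_area_um2",
                       endpoint_frame = NULL,
                       normalize_mode = c("vehicle", "vehicle+baseline"),
                       seed = 1L, write_images = FALSE,
                       write_overlays = FALSE) {
  backend <- match.arg(backend)
  normalize_mode <- match.arg(normalize_mode)
  if (is.character(plate_map)) plate_map <- read_plate_map(plate_map)
  if (is.null(sim) && is.null(images_dir))
    abort_field("run_config", "either sim or images_dir must be given")
  if (!is.null(images_dir)) {
    if (!dir.exists(images_dir))
      abort_field("images_dir", paste("does not exist:", images_dir))
    if (is.null(times_h) || is.null(um_per_px))
      abort_field("run_config", "images_dir input needs times_h and um_per_px")
  }
  if (backend == "fcn" && is.null(model))
    abort_field("model", "fcn backend needs a trained seg_model")
  structure(list(plate_map = plate_map, out_dir = out_dir, sim = sim,
                 images_dir = images_dir, times_h = times_h,
                 um_per_px = um_per_px, backend = backend, seg = seg,
                 model = model, metric = metric,
                 endpoint_frame = endpoint_frame,
                 normalize_mode = normalize_mode, seed = as.integer(seed),
                 write_images = isTRUE(write_images),
                 write_overlays = isTRUE(write_overlays)),
            class = "run_config")
}

#' Run the full screening pipeline
#'
#' Executes simulate (when configured) → segment → track → metrics →
#' response on every non-empty well, writing each stage's outputs under
#' `out_dir`: `metrics.csv` (long format), `tracks/<well>.json`,
#' `response.csv` (per-well GR/NDR/classification), `fits.csv` (per-drug
#' 4PL parameters), `quality.csv` (Z-factor per metric) and
#' `manifest.json` (seeds, parameters, package version). Re-running with
#' an identical configuration reproduces identical CSVs (classical
#' backend, or fcn with a fixed model).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `metrics` (per-well time series),
#'   `tracks`, `response`, `fits`, `quality` and `truth` (when
#'   simulated).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop("config must be a run_config", call. = FALSE)
  pm <- config$plate_map
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  truth <- NULL
  wells <- pm$well_id[pm$role != "empty"]
  if (!is.null(config$sim)) {
    truth <- stage("simulate", simulate_plate(config$sim, pm))
    logf("simulate", sprintf("%d wells, %d frames", length(wells),
                             config$sim$n_timepoints))
    if (config$write_images) {
      write_plate_truth(truth, file.path(config$out_dir, "truth"))
      img_dir <- file.path(config$out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
    }
    get_images <- function(w) render_well_series(truth, w)$images
  } else {
    get_images <- function(w) read_well_tiff(
      file.path(config$images_dir, sprintf("well_%s.tif", w)),
      well_id = w, times_h = config$times_h, um_per_px = config$um_per_px)
  }

  metrics <- list(); tracks <- list()
  for (w in wells) {
    images <- stage("images", get_images(w))
    if (!is.null(config$sim) && config$write_images)
      write_well_tiff(images, file.path(config$out_dir, "images",
                                        sprintf("well_%s.tif", w)))
    masks <- stage("segment", lapply(seq_len(n_frames(images)), function(f) {
      bf <- images$frames[[f]]$bf
      if (config$backend == "classical")
        segment_classical(bf, config$seg, frame = f - 1L)
      else segment_fcn(bf, config$model, params = config$seg, frame = f - 1L)
    }))
    tracks[[w]] <- stage("track", track_objects(masks))
    metrics[[w]] <- stage("metrics", compute_well_metrics(images, masks))
    if (config$write_overlays)
      write_overlay_png(images$frames[[n_frames(images)]]$bf,
                        masks[[length(masks)]],
                        file.path(config$out_dir,
                                  sprintf("overlay_%s.png", w)))
  }
  logf("segment", sprintf("%d wells segmented (%s backend)", length(wells),
                          config$backend))
  write_metrics_csv(metrics, file.path(config$out_dir, "metrics.csv"))
  trk_dir <- file.path(config$out_dir, "tracks")
  dir.create(trk_dir, showWarnings = FALSE)
  for (w in wells)
    write_track_graph(tracks[[w]], file.path(trk_dir, paste0(w, ".json")))

  result <- stage("response", {
    endpoint <- config$endpoint_frame %||%
      max(metrics[[wells[1]]]$frame)
    fc <- do.call(rbind, lapply(wells, function(w)
      data.frame(well_id = w,
                 fc = fold_change(metrics[[w]], config$metric,
                                  frame = endpoint))))
    resp <- response_table(fc, pm)
    # Z-factor on the endpoint metric of the control wells
    ctrl <- merge(fc, as.data.frame(pm), by = "well_id")
    quality <- if (sum(ctrl$role == "vehicle") >= 2 &&
                   sum(ctrl$role == "positive") >= 2) {
      tibble::tibble(metric = paste0(config$metric, "_fold_change"),
                     z_factor = z_factor(ctrl$fc[ctrl$role == "vehicle"],
                                         ctrl$fc[ctrl$role == "positive"]))
    } else tibble::tibble(metric = character(), z_factor = numeric())
    # one 4PL fit per drug with >= 5 distinct concentrations
    fits <- list()
    for (d in setdiff(unique(pm$drug[pm$role == "treated"]), NA)) {
      sub <- merge(fc, as.data.frame(pm), by = "well_id")
      sub <- sub[sub$role %in% c("vehicle", "positive", "treated") &
                   (is.na(sub$drug) | sub$drug == d), ]
      names(sub)[names(sub) == "fc"] <- "response_raw"
      norm <- normalize_viability(sub, mode = config$normalize_mode)
      tr <- norm[norm$role == "treated", ]
      if (length(unique(tr$concentration)) >= 5) {
        fit <- fit_4pl(tr$concentration, tr$response_pct)
        fits[[d]] <- tibble::tibble(
          drug = d, top = fit$top, bottom = fit$bottom, hill = fit$hill,
          log_ic50 = fit$log_ic50, ic50_M = fit$ic50, ic50_uM = fit$ic50 * 1e6,
          rss = fit$rss, df = fit$df, n_points = fit$n_points)
      }
    }
    fits <- if (length(fits)) do.call(rbind, fits)
    else tibble::tibble(drug = character())
    list(response = resp, fits = fits, quality = quality)
  })
  utils::write.csv(as.data.frame(result$response),
                   file.path(config$out_dir, "response.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(as.data.frame(result$fits),
                   file.path(config$out_dir, "fits.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(as.data.frame(result$quality),
                   file.path(config$out_dir, "quality.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  manifest <- list(
    package = as.character(utils::packageVersion("organoidscreen")),
    seed = config$seed,
    sim_seed = if (!is.null(config$sim)) config$sim$seed,
    backend = config$backend, metric = config$metric,
    normalize_mode = config$normalize_mode,
    seg_params = unclass(config$seg),
    wells = wells)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("response", "fits, response table and quality written")
  invisible(list(metrics = metrics, tracks = tracks,
                 response = result$response, fits = result$fits,
                 quality = result$quality, truth = truth))
}
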