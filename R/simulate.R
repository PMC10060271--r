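#' Simulate an organoid plate with known ground truth
#'
#' Runs the per-well organoid population model over all wells of a plate
#' map and returns the full ground truth: per-organoid states at every
#' frame and the per-(well, frame) expected metric table.
#'
#' The population model: organoid projected areas grow exponentially at
#' `growth_rate_h`, scaled by `density_slowdown_factor` while the well
#' holds more objects than `density_slowdown_threshold`; an object's
#' growth stalls once its disk spans the imaged well (space limit). Treated wells
#' apply a Hill effect `E(c) = c^h / (c^h + EC50^h)`: cytostatic drugs
#' multiply the growth rate by `1 - E(c)`; cytotoxic drugs drive the
#' viable fraction linearly toward zero at a rate proportional to `E(c)`,
#' reaching `1 - max_kill_fraction * E(c)` at the final frame (total area
#' keeps growing — dead organoids remain visible in brightfield).
#' Positive-control wells behave as a fully effective cytotoxic drug and
#' reach viable fraction 0 at the final frame. Organoids whose disks come
#' to overlap merge into a single object: areas are summed, the lower id
#' is kept, and the constituent ids are recorded in `parent_ids` at the
#' fusion frame.
#'
#' @param config a [simulation_config()].
#' @param pm a [plate_map()].
#' @return A `plate_truth` list with elements `states` (per-organoid
#'   tibble: `well_id`, `organoid_id`, `frame`, `time_h`, `cx_px`,
#'   `cy_px`, `radius_px`, `area_um2`, `morphology`, `alive_fraction`,
#'   `parent_ids`), `per_well` (per well and frame: `count`,
#'   `mean_area_um2`, `total_area_um2`, `dead_area_um2`,
#'   `viable_area_um2`), and the echoed `config` and `plate_map`.
#' @export
#' @examples
#' pm <- plate_map("A01", "vehicle")
#' cfg <- simulation_config(n_timepoints = 3, seeding_density = 4, seed = 2)
#' truth <- simulate_plate(cfg, pm)
#' truth$per_well
simulate_plate <- function(config, pm) {
  config <- validate_sim_config(config)
  pm <- validate_plate_map(pm, plate_format = config$plate_format)
  if (length(config$drug_panel)) {
    if (!any(pm$role == "vehicle"))
      abort_field("plate_map", "needs >= 1 vehicle well when drugs are screened")
    if (!any(pm$role == "positive"))
      abort_field("plate_map", "needs >= 1 positive-control well when drugs are screened")
  }
  states <- vector("list", nrow(pm))
  for (w in seq_len(nrow(pm))) {
    states[[w]] <- simulate_well(config, pm[w, ], well_index = w)
  }
  states <- do.call(rbind, states)
  truth <- list(states = states,
                per_well = aggregate_truth(states, pm, config),
                config = config, plate_map = pm)
  class(truth) <- "plate_truth"
  truth
}

# Drug context of one well: effect level E, kill ceiling m and mode.
well_drug_context <- function(config, row) {
  role <- row$role
  if (role == "vehicle" || role == "empty")
    return(list(effect = 0, max_kill = 0, mode = "none"))
  if (role == "positive")
    return(list(effect = 1, max_kill = 1, mode = "cytotoxic"))
  panel <- Filter(function(e) identical(e$drug, row$drug), config$drug_panel)
  if (!length(panel))
    abort_field("drug_panel", paste("no panel entry for drug", row$drug))
  e <- panel[[1]]
  list(effect = hill_effect(row$concentration, e$ec50_true, e$hill_true),
       max_kill = e$max_kill_fraction, mode = e$mode)
}

simulate_well <- function(config, row, well_index) {
  n_frames <- config$n_timepoints
  times <- (seq_len(n_frames) - 1) * config$dt_h
  t_end <- times[n_frames]
  n0 <- if (row$role == "empty") 0L else config$seeding_density
  if (n0 == 0L) {
    return(tibble::tibble(well_id = character(), organoid_id = integer(),
                          frame = integer(), time_h = numeric(),
                          cx_px = numeric(), cy_px = numeric(),
                          radius_px = numeric(), area_um2 = numeric(),
                          morphology = character(),
                          alive_fraction = numeric(),
                          parent_ids = character()))
  }
  set.seed(derive_seed(config$seed, well_index))
  ctx <- well_drug_context(config, row)
  org <- place_organoids(config, n0)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    t_h <- times[f]
    if (f > 1L) {
      slow <- if (nrow(org) > config$density_slowdown_threshold)
        config$density_slowdown_factor else 1
      rate <- config$growth_rate_h * slow
      if (ctx$mode == "cytostatic") rate <- rate * (1 - ctx$effect)
      new_area <- org$area_um2 * exp(rate * config$dt_h)
      new_r <- sqrt(new_area / pi) / config$um_per_px
      # growth stalls once an object spans the well (space/nutrient limit)
      r_max <- min(config$image_size_px) / 2 - 3
      grown <- new_r <= r_max | new_r <= org$radius_px
      org$area_um2[grown] <- new_area[grown]
      org$radius_px <- sqrt(org$area_um2 / pi) / config$um_per_px
    }
    alive <- if (ctx$mode == "cytotoxic")
      max(0, 1 - ctx$max_kill * ctx$effect * t_h / t_end) else 1
    org$parent_ids <- ""
    if (config$fusion_enabled && nrow(org) > 1L)
      org <- merge_touching(org, config)
    out[[f]] <- tibble::tibble(
      well_id = row$well_id, organoid_id = org$organoid_id,
      frame = f - 1L, time_h = t_h, cx_px = org$cx_px, cy_px = org$cy_px,
      radius_px = org$radius_px, area_um2 = org$area_um2,
      morphology = org$morphology, alive_fraction = alive,
      parent_ids = org$parent_ids)
  }
  do.call(rbind, out)
}

# Rejection-sampled initial placement: disks inside the raster with an
# 8-px clearance between any two rims, so freshly seeded organoids are
# resolvable as separate objects (fusion then arises from growth).
place_organoids <- function(config, n) {
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  r_px <- (config$mean_radius_um / config$um_per_px) *
    exp(stats::rnorm(n, 0, config$radius_cv))
  morph <- ifelse(stats::runif(n) < config$morphology_mix, "solid", "cystic")
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    if (2 * (r_px[i] + 3) >= min(nr, nc))
      stop(sprintf(
        "placement error: organoid radius %.0f px does not fit a %dx%d image",
        r_px[i], nr, nc), call. = FALSE)
    placed <- FALSE
    for (try in seq_len(400L)) {
      x <- stats::runif(1, r_px[i] + 1, nc - r_px[i] - 2)
      y <- stats::runif(1, r_px[i] + 1, nr - r_px[i] - 2)
      if (x <= r_px[i] || y <= r_px[i]) next
      if (i == 1L ||
          all(sqrt((cx[seq_len(i - 1)] - x)^2 + (cy[seq_len(i - 1)] - y)^2) >
              r_px[i] + r_px[seq_len(i - 1)] + 8)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf(
        "placement error: could not fit %d organoids of radius ~%.0f px into a %dx%d image",
        n, mean(r_px), nr, nc), call. = FALSE)
  }
  tibble::tibble(organoid_id = seq_len(n), cx_px = cx, cy_px = cy,
                 radius_px = r_px,
                 area_um2 = pi * (r_px * config$um_per_px)^2,
                 morphology = morph, parent_ids = "")
}

# Union-find merge of overlapping disks; merged object keeps the lowest id,
# sums areas, takes the area-weighted centroid and the largest member's
# morphology; constituent ids land in parent_ids at this frame.
merge_touching <- function(org, config) {
  n <- nrow(org)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sqrt((org$cx_px[i] - org$cx_px[j])^2 + (org$cy_px[i] - org$cy_px[j])^2)
    if (d <= org$radius_px[i] + org$radius_px[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  groups <- vapply(seq_len(n), find, integer(1))
  if (all(tabulate(groups) <= 1L)) return(org)
  merged <- lapply(unique(groups), function(g) {
    m <- org[groups == g, , drop = FALSE]
    if (nrow(m) == 1L) return(m)
    a <- sum(m$area_um2)
    tibble::tibble(
      organoid_id = min(m$organoid_id),
      cx_px = sum(m$cx_px * m$area_um2) / a,
      cy_px = sum(m$cy_px * m$area_um2) / a,
      radius_px = sqrt(a / pi) / config$um_per_px,
      area_um2 = a,
      morphology = m$morphology[which.max(m$area_um2)],
      parent_ids = paste(sort(m$organoid_id), collapse = ";"))
  })
  out <- do.call(rbind, merged)
  out[order(out$organoid_id), , drop = FALSE]
}

# Per-(well, frame) expected metrics by direct aggregation of the states.
aggregate_truth <- function(states, pm, config) {
  times <- (seq_len(config$n_timepoints) - 1) * config$dt_h
  grid <- expand.grid(well_id = pm$well_id,
                      frame = seq_len(config$n_timepoints) - 1L,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$well_id, pm$well_id), grid$frame), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- states[states$well_id == grid$well_id[i] &
                  states$frame == grid$frame[i], , drop = FALSE]
    total <- sum(s$area_um2)
    dead <- sum(s$area_um2 * (1 - s$alive_fraction))
    tibble::tibble(well_id = grid$well_id[i], frame = grid$frame[i],
                   time_h = times[grid$frame[i] + 1L],
                   count = nrow(s),
                   mean_area_um2 = if (nrow(s)) total / nrow(s) else 0,
                   total_area_um2 = total, dead_area_um2 = dead,
                   viable_area_um2 = total - dead)
  })
  do.call(rbind, rows)
}

#' @export
print.plate_truth <- function(x, ...) {
  cat(sprintf("<plate_truth> %d wells x %d frames, %d organoid-states\n",
              nrow(x$plate_map), x$config$n_timepoints, nrow(x$states)))
  invisible(x)
}
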