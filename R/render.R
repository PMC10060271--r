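#' Render one well frame to brightfield / Hoechst / death-marker rasters
#'
#' Turns the simulator's per-organoid states for a single (well, frame)
#' into the three imaging channels plus the ground-truth label mask:
#'
#' * brightfield (`bf`): dark textured disks for solid organoids, dark
#'   annuli with a bright lumen for cystic ones, on a bright background
#'   with a smooth illumination ramp;
#' * nuclear channel (`blue`): whole-object signal for solid organoids,
#'   rim-only for cystic (nuclear dyes stain only the outer edge of
#'   cystic organoids);
#' * death marker (`green`): signal over the dead fraction of each
#'   organoid, drawn as a sub-region growing from the organoid interior.
#'
#' Artifacts — bright rings emulating air bubbles and small high-contrast
#' debris specks — are added to the brightfield channel at the configured
#' rates and are excluded from the truth mask. All channels receive
#' Gaussian read noise and are clipped to `[0, 1]`.
#'
#' @param states rows of `plate_truth$states` for a single well and frame.
#' @param config the [simulation_config()] used to simulate them.
#' @return A list with matrices `bf`, `blue`, `green` in `[0, 1]` and
#'   `mask`, a [labeled_mask()] whose labels are the organoid ids.
#' @export
render_well <- function(states, config) {
  config <- validate_sim_config(config)
  if (nrow(states)) {
    if (length(unique(states$well_id)) != 1L ||
        length(unique(states$frame)) != 1L)
      stop("states must belong to a single (well, frame)", call. = FALSE)
  }
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  frame <- if (nrow(states)) states$frame[1] else 0L
  widx <- if (nrow(states)) well_index_from_id(states$well_id[1]) else 0L
  set.seed(derive_seed(config$seed, widx, frame + 1L))

  grad <- illumination_ramp(nr, nc, config$illumination_gradient)
  bf <- matrix(0.75, nr, nc) + grad
  blue <- matrix(0.03, nr, nc) + grad * 0.3
  green <- matrix(0.03, nr, nc) + grad * 0.3
  mask <- matrix(0L, nr, nc)

  if (nrow(states)) {
    ord <- order(states$organoid_id)
    for (i in ord) {
      s <- states[i, ]
      r <- s$radius_px
      # an object (e.g. a large fusion product) may be clipped at the
      # raster edge; only an unplaceable one is an error
      if (r >= min(nr, nc) ||
          s$cx_px < 0 || s$cy_px < 0 || s$cx_px > nc - 1 || s$cy_px > nr - 1)
        stop(sprintf(
          "placement error: organoid %d (r=%.0f px) does not fit the %dx%d image",
          s$organoid_id, r, nr, nc), call. = FALSE)
      box <- disk_box(nr, nc, s$cx_px, s$cy_px, r)
      inside <- box$dist <= r
      mask[box$rows, box$cols][inside & mask[box$rows, box$cols] == 0L] <-
        s$organoid_id
      if (s$morphology == "solid") {
        tex <- 0.45 + 0.05 * matrix(stats::rnorm(length(box$dist)),
                                    nrow(box$dist))
        patch <- bf[box$rows, box$cols]
        patch[inside] <- tex[inside]
        bf[box$rows, box$cols] <- patch
        bpatch <- blue[box$rows, box$cols]
        bpatch[inside] <- 0.75
        blue[box$rows, box$cols] <- bpatch
      } else {
        rim <- inside & box$dist >= 0.68 * r
        lumen <- box$dist < 0.68 * r
        patch <- bf[box$rows, box$cols]
        patch[rim] <- 0.45 + 0.05 * stats::rnorm(sum(rim))
        patch[lumen] <- 0.80
        bf[box$rows, box$cols] <- patch
        bpatch <- blue[box$rows, box$cols]
        bpatch[rim] <- 0.75
        blue[box$rows, box$cols] <- bpatch
      }
      dead <- 1 - s$alive_fraction
      if (dead > 0) {
        rd <- r * sqrt(dead)
        gpatch <- green[box$rows, box$cols]
        gpatch[box$dist <= rd] <- 0.80
        green[box$rows, box$cols] <- gpatch
      }
    }
  }

  bf <- add_artifacts(bf, config)
  bf <- clip01(bf + stats::rnorm(nr * nc, 0, config$noise_sd))
  blue <- clip01(blue + stats::rnorm(nr * nc, 0, config$noise_sd))
  green <- clip01(green + stats::rnorm(nr * nc, 0, config$noise_sd))
  list(bf = bf, blue = blue, green = green,
       mask = labeled_mask(mask, frame = frame, provenance = "truth"))
}

#' Render every frame of one well
#'
#' @param truth a `plate_truth` from [simulate_plate()].
#' @param well_id the well to render.
#' @return A list with `images` (a [well_image_set()]) and `masks`
#'   (a list of truth [labeled_mask()]s, one per frame).
#' @export
render_well_series <- function(truth, well_id) {
  config <- truth$config
  frames <- seq_len(config$n_timepoints) - 1L
  out <- lapply(frames, function(f) {
    s <- truth$states[truth$states$well_id == well_id &
                        truth$states$frame == f, , drop = FALSE]
    if (nrow(s) == 0L && !well_id %in% truth$plate_map$well_id)
      stop("unknown well: ", well_id, call. = FALSE)
    s$well_id <- well_id; s$frame <- f
    render_well(s, config)
  })
  images <- well_image_set(
    well_id = well_id,
    times_h = frames * config$dt_h,
    frames = lapply(out, function(x) x[c("bf", "blue", "green")]),
    um_per_px = config$um_per_px)
  list(images = images, masks = lapply(out, `[[`, "mask"))
}

well_index_from_id <- function(well_id) {
  match(substr(well_id, 1, 1), LETTERS) * 24L +
    as.integer(substr(well_id, 2, 3))
}

illumination_ramp <- function(nr, nc, amplitude) {
  theta <- stats::runif(1, 0, 2 * pi)
  gx <- cos(theta); gy <- sin(theta)
  cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) / max(nc - 1, 1)
  rows <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc) / max(nr - 1, 1)
  ramp <- gx * cols + gy * rows
  amplitude * (ramp - mean(ramp))
}

# Bounding-box coordinate patch around a disk; dist holds the Euclidean
# distance of each patch pixel from the (0-based) center.
disk_box <- function(nr, nc, cx, cy, r) {
  rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r + 2))
  cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r + 2))
  dc <- matrix(rep(cols - 1 - cx, each = length(rows)), length(rows))
  dr <- matrix(rep(rows - 1 - cy, times = length(cols)), length(rows))
  list(rows = rows, cols = cols, dist = sqrt(dc^2 + dr^2))
}

# Bubbles: bright rings. Debris: small dark specks (below any reasonable
# min-object-area). Neither enters the truth mask.
add_artifacts <- function(bf, config) {
  nr <- nrow(bf); nc <- ncol(bf)
  rates <- config$artifact_rates
  rate_of <- function(nm) if (nm %in% names(rates)) rates[[nm]] else 0
  n_bub <- stats::rpois(1, rate_of("bubbles"))
  for (i in seq_len(n_bub)) {
    r <- stats::runif(1, 8, 16)
    cx <- stats::runif(1, r, nc - r - 1); cy <- stats::runif(1, r, nr - r - 1)
    box <- disk_box(nr, nc, cx, cy, r)
    ring <- abs(box$dist - r) <= 1.2
    patch <- bf[box$rows, box$cols]
    patch[ring] <- 0.97
    bf[box$rows, box$cols] <- patch
  }
  n_deb <- stats::rpois(1, rate_of("debris"))
  for (i in seq_len(n_deb)) {
    r <- stats::runif(1, 1, 2.2)
    cx <- stats::runif(1, 3, nc - 4); cy <- stats::runif(1, 3, nr - 4)
    box <- disk_box(nr, nc, cx, cy, r)
    patch <- bf[box$rows, box$cols]
    patch[box$dist <= r] <- 0.30
    bf[box$rows, box$cols] <- patch
  }
  bf
}
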