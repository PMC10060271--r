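test_that("config validation errors name the offending field", {
  expect_error(simulation_config(dt_h = 0), "dt_h")
  expect_error(simulation_config(n_timepoints = 1), "n_timepoints")
  expect_error(simulation_config(um_per_px = -1), "um_per_px")
  expect_error(simulation_config(morphology_mix = 1.5), "morphology_mix")
  expect_error(simulation_config(drug_panel = list(list(drug = "x"))),
               "drug_panel")
  expect_error(
    simulation_config(drug_panel = list(list(
      drug = "x", concentrations = 1e-6, ec50_true = 1e-6, hill_true = 1,
      max_kill_fraction = 2, mode = "cytotoxic"))),
    "max_kill_fraction")
})

test_that("same seed and config give bit-identical truth and renders", {
  pm <- plate_map(c("A01", "B02"), c("vehicle", "positive"))
  cfg <- small_sim_config(artifact_rates = c(bubbles = 1, debris = 2))
  t1 <- simulate_plate(cfg, pm)
  t2 <- simulate_plate(cfg, pm)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$per_well, t2$per_well)
  r1 <- render_well_series(t1, "A01")
  r2 <- render_well_series(t2, "A01")
  expect_identical(r1$images$frames, r2$images$frames)
  expect_identical(r1$masks[[1]]$labels, r2$masks[[1]]$labels)
})

test_that("zero seeding density yields count 0 at every frame", {
  pm <- plate_map("A01", "vehicle")
  truth <- simulate_plate(small_sim_config(seeding_density = 0L), pm)
  expect_equal(truth$per_well$count, rep(0L, 3))
  expect_equal(truth$per_well$total_area_um2, rep(0, 3))
})

test_that("vehicle total area follows the closed-form exponential", {
  # doubles per 24 h over a 48 h horizon: fold change 4 exactly
  pm <- plate_map("A01", "vehicle")
  cfg <- small_sim_config(growth_rate_h = log(2) / 24, n_timepoints = 5L,
                          dt_h = 12, fusion_enabled = FALSE)
  truth <- simulate_plate(cfg, pm)
  pw <- truth$per_well
  expect_equal(pw$total_area_um2[pw$frame == 4] / pw$total_area_um2[pw$frame == 0],
               4, tolerance = 1e-10)
  expect_equal(pw$count, rep(4L, 5))
})

test_that("fusion decrements the count and conserves total area", {
  # crowded small well so growth forces contact
  pm <- plate_map("A01", "vehicle")
  cfg <- simulation_config(image_size_px = c(96L, 96L), n_timepoints = 8L,
                           seeding_density = 5L, mean_radius_um = 35,
                           seed = 7L, artifact_rates = c(bubbles = 0, debris = 0))
  truth <- simulate_plate(cfg, pm)
  pw <- truth$per_well
  merged <- truth$states[truth$states$parent_ids != "", ]
  expect_gt(nrow(merged), 0)
  # counts non-increasing after placement (fusion only, no death loss)
  expect_true(all(diff(pw$count) <= 0))
  # across every step the area ratio is exactly the growth factor:
  # merging moves area between objects but never creates or destroys it
  growth <- exp(cfg$growth_rate_h * cfg$dt_h)
  expect_equal(pw$total_area_um2[-1] / pw$total_area_um2[-nrow(pw)],
               rep(growth, nrow(pw) - 1), tolerance = 1e-10)
  # a merged object's area equals the sum of its parents' previous areas
  # times one growth step
  k <- merged$frame[1]
  parents <- as.integer(strsplit(merged$parent_ids[1], ";")[[1]])
  prev <- truth$states[truth$states$frame == k - 1 &
                         truth$states$organoid_id %in% parents, ]
  expect_equal(merged$area_um2[1], sum(prev$area_um2) * growth,
               tolerance = 1e-10)
  expect_equal(merged$organoid_id[1], min(parents))
})

test_that("plates with drugs require both control roles", {
  panel <- list(list(drug = "d", concentrations = 1e-6, ec50_true = 1e-6,
                     hill_true = 1, max_kill_fraction = 1,
                     mode = "cytotoxic"))
  cfg <- small_sim_config(drug_panel = panel)
  pm_no_pos <- plate_map(c("A01", "A02"), c("vehicle", "treated"),
                         drug = c(NA, "d"), concentration = c(NA, 1e-6))
  expect_error(simulate_plate(cfg, pm_no_pos), "positive")
})

test_that("cytotoxic viable area is non-increasing in concentration and
           cytostatic growth slows with dose", {
  conc <- 10^seq(-8, -4, length.out = 6)
  for (mode in c("cytotoxic", "cytostatic")) {
    panel <- list(list(drug = "d", concentrations = conc, ec50_true = 1e-6,
                       hill_true = 1, max_kill_fraction = 0.95, mode = mode))
    pm <- titration_plate_map("d", conc, n_vehicle = 1, n_positive = 1)
    cfg <- small_sim_config(drug_panel = panel, n_timepoints = 5L)
    truth <- simulate_plate(cfg, pm)
    pw <- truth$per_well[truth$per_well$frame == 4, ]
    treated <- merge(pw, as.data.frame(pm), by = "well_id")
    treated <- treated[treated$role == "treated", ]
    treated <- treated[order(treated$concentration), ]
    # normalize by initial area: seeds differ per well
    pw0 <- truth$per_well[truth$per_well$frame == 0, ]
    fc <- treated$viable_area_um2 /
      pw0$total_area_um2[match(treated$well_id, pw0$well_id)]
    expect_true(all(diff(fc) <= 1e-9))
  }
})

test_that("positive control reaches zero viable fraction at the last frame", {
  pm <- plate_map("A01", "positive")
  truth <- simulate_plate(small_sim_config(), pm)
  last <- truth$states[truth$states$frame == 2, ]
  expect_true(all(last$alive_fraction == 0))
})

test_that("per-well expected table equals direct aggregation of states", {
  pm <- plate_map(c("A01", "A02"), c("vehicle", "positive"))
  truth <- simulate_plate(small_sim_config(), pm)
  for (i in sample(nrow(truth$per_well), 4)) {
    row <- truth$per_well[i, ]
    s <- truth$states[truth$states$well_id == row$well_id &
                        truth$states$frame == row$frame, ]
    expect_equal(row$count, nrow(s))
    expect_equal(row$total_area_um2, sum(s$area_um2))
    expect_equal(row$dead_area_um2, sum(s$area_um2 * (1 - s$alive_fraction)))
    expect_equal(row$viable_area_um2, row$total_area_um2 - row$dead_area_um2)
  }
})

test_that("renderer channel semantics match the morphology model", {
  pm <- plate_map("A01", "vehicle")
  cfg_solid <- small_sim_config(morphology_mix = 1, seeding_density = 1L,
                                noise_sd = 0)
  truth <- simulate_plate(cfg_solid, pm)
  s <- truth$states[truth$states$frame == 0, ]
  rw <- render_well(s, cfg_solid)
  # truth mask pixel count equals the rasterized disk pixel count
  nr <- cfg_solid$image_size_px[1]; nc <- cfg_solid$image_size_px[2]
  disk <- organoidscreen:::disk_mask(nr, nc, s$cx_px, s$cy_px, s$radius_px)
  expect_equal(sum(rw$mask$labels > 0), sum(disk))
  # area in um^2 = pixel count x um_per_px^2, close to the continuous truth
  expect_equal(sum(disk) * cfg_solid$um_per_px^2, s$area_um2,
               tolerance = 0.05)
  # alive everywhere: green is background only
  expect_lt(max(rw$green), 0.2)
  # solid organoid: blue-positive pixels ~ truth mask (IoU >= 0.9)
  blue_pos <- rw$blue > 0.4
  iou <- sum(blue_pos & disk) / sum(blue_pos | disk)
  expect_gte(iou, 0.9)

  # cystic organoid: blue positives are a strict subset of the mask (rim)
  cfg_cyst <- small_sim_config(morphology_mix = 0, seeding_density = 1L,
                               noise_sd = 0)
  truth_c <- simulate_plate(cfg_cyst, pm)
  rw_c <- render_well(truth_c$states[truth_c$states$frame == 0, ], cfg_cyst)
  blue_pos <- rw_c$blue > 0.4
  in_mask <- rw_c$mask$labels > 0
  expect_true(all(in_mask[blue_pos]))
  expect_lt(sum(blue_pos), sum(in_mask))
})

test_that("green-positive truth pixels stay inside the organoid mask", {
  pm <- plate_map("A01", "positive")
  cfg <- small_sim_config(noise_sd = 0)
  truth <- simulate_plate(cfg, pm)
  rw <- render_well(truth$states[truth$states$frame == 1, ], cfg)
  green_pos <- rw$green > 0.4
  expect_true(all((rw$mask$labels > 0)[green_pos]))
})

test_that("organoids too large for the raster raise a placement error", {
  pm <- plate_map("A01", "vehicle")
  cfg <- small_sim_config(seeding_density = 1L)
  truth <- simulate_plate(cfg, pm)
  s <- truth$states[truth$states$frame == 0, ]
  s$radius_px <- 400
  expect_error(render_well(s, cfg), "placement")
  expect_error(
    simulate_plate(small_sim_config(mean_radius_um = 2000), pm),
    "placement")
})
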