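test_that("a static mask tracks to identity links with no events", {
  m <- matrix(0L, 40, 40)
  m[5:15, 5:15] <- 1L; m[25:35, 25:35] <- 2L
  g <- track_objects(list(m, m, m))
  expect_equal(nrow(g$edges), 4)
  expect_true(all(g$edges$label_from == g$edges$label_to))
  expect_equal(nrow(g$events), 0)
  expect_equal(track_counts(g)$count, c(2L, 2L, 2L))
})

test_that("simulator fusions produce exactly one merge event each", {
  pm <- plate_map("A01", "vehicle")
  cfg <- simulation_config(image_size_px = c(96L, 96L), n_timepoints = 8L,
                           seeding_density = 5L, mean_radius_um = 35,
                           seed = 7L, artifact_rates = c(bubbles = 0, debris = 0))
  truth <- simulate_plate(cfg, pm)
  rw <- render_well_series(truth, "A01")
  g <- track_objects(rw$masks)
  sched <- truth$states[truth$states$parent_ids != "", ]
  merges <- g$events[g$events$type == "merge", ]
  expect_equal(nrow(merges), nrow(sched))
  expect_setequal(merges$frame, sched$frame)
  # count series from the graph equals the truth count series
  expect_equal(track_counts(g)$count,
               truth$per_well$count[order(truth$per_well$frame)])
  # merge conservation: successor area >= 0.9 x summed predecessor areas
  for (i in seq_len(nrow(merges))) {
    f <- merges$frame[i]
    parents <- as.integer(strsplit(merges$parent_labels[i], ";")[[1]])
    pre <- g$nodes[g$nodes$frame == f - 1 & g$nodes$label %in% parents, ]
    succ <- g$nodes[g$nodes$frame == f & g$nodes$label == merges$label[i], ]
    expect_gte(succ$area_px, 0.9 * sum(pre$area_px))
  }
})

test_that("vanishing and appearing objects generate events", {
  a <- matrix(0L, 30, 30); a[5:10, 5:10] <- 1L; a[20:25, 20:25] <- 2L
  b <- matrix(0L, 30, 30); b[5:10, 5:10] <- 1L
  g <- track_objects(list(a, b))
  expect_equal(g$events$type, "disappearance")
  expect_equal(g$events$label, 2L)
  g2 <- track_objects(list(b, a))
  expect_equal(g2$events$type, "appearance")
  expect_warning(track_objects(list(a)), "single frame")
})

test_that("well metrics follow exact pixel arithmetic", {
  # one 1000-px object at 2 um/px with green over 250 px
  bf <- matrix(0.7, 50, 50)
  lab <- matrix(0L, 50, 50); lab[1:40, 1:25] <- 1L  # 1000 px
  green <- matrix(0, 50, 50); green[1:10, 1:25] <- 0.9  # 250 px inside
  imgs <- well_image_set("A01", 0, list(list(bf = bf, green = green)),
                         um_per_px = 2)
  ts <- compute_well_metrics(imgs, list(lab))
  expect_equal(ts$total_mask_area_um2, 4000)
  expect_equal(ts$total_green_area_um2, 1000)
  expect_equal(ts$green_area_ratio, 0.25)
  expect_equal(ts$viable_area_um2, 3000)
  expect_equal(ts$count, 1L)
  expect_equal(ts$total_mask_area_um2, ts$count * ts$mean_mask_area_um2)
})

test_that("empty masks flag ratios instead of zero-filling them", {
  bf <- matrix(0.7, 30, 30)
  imgs <- well_image_set("A01", 0, list(list(bf = bf)), um_per_px = 2)
  ts <- compute_well_metrics(imgs, list(matrix(0L, 30, 30)))
  expect_equal(ts$count, 0L)
  expect_equal(ts$total_mask_area_um2, 0)
  expect_true(is.na(ts$green_area_ratio))
  expect_false(ts$ratio_defined)
  expect_false(ts$green_available)
  expect_error(compute_well_metrics(imgs, list(lab = matrix(0L, 30, 30),
                                               matrix(0L, 30, 30))),
               "misalignment")
})

test_that("green ratios respond correctly to uniform intensity rescaling", {
  pm <- plate_map("A01", "positive")
  cfg <- small_sim_config(seed = 12L)
  truth <- simulate_plate(cfg, pm)
  rw <- render_well_series(truth, "A01")
  ts <- compute_well_metrics(rw$images, rw$masks)
  scaled <- rw$images
  # rescaling below the channel ceiling: double a dimmed copy
  for (f in seq_along(scaled$frames))
    scaled$frames[[f]]$green <- scaled$frames[[f]]$green * 0.5
  ts2 <- compute_well_metrics(scaled, rw$masks, green_threshold = 0.125)
  expect_equal(ts2$green_area_ratio, ts$green_area_ratio, tolerance = 1e-6)
  expect_equal(ts2$total_green_intensity, ts$total_green_intensity * 0.5,
               tolerance = 1e-6)
})

test_that("fold change is anchored at T0 and simulator-faithful", {
  pm <- plate_map("A01", "vehicle")
  cfg <- small_sim_config(n_timepoints = 9L, seeding_density = 5L,
                          seed = 31L)
  truth <- simulate_plate(cfg, pm)
  rw <- render_well_series(truth, "A01")
  ts <- compute_well_metrics(rw$images, rw$masks)
  expect_equal(fold_change(ts, "viable_area_um2", frame = 0), 1)
  fc_meas <- fold_change(ts, "viable_area_um2")
  pw <- truth$per_well
  fc_true <- pw$viable_area_um2[pw$frame == 8] / pw$viable_area_um2[pw$frame == 0]
  expect_lt(abs(fc_meas - fc_true) / fc_true, 0.15)
})

test_that("growth rates are exact on closed-form series and recovered
           from the simulator", {
  ts_const <- tibble::tibble(frame = 0:3, time_h = (0:3) * 6,
                             total_mask_area_um2 = rep(5, 4))
  gr <- growth_rate_series(ts_const)
  expect_equal(gr$average_log2_per_interval, 0)
  ts_doubling <- tibble::tibble(frame = 0:3, time_h = (0:3) * 6,
                                total_mask_area_um2 = 5 * 2^(0:3))
  gr2 <- growth_rate_series(ts_doubling)
  expect_equal(gr2$per_interval$log2_fc, rep(1, 3))
  expect_equal(gr2$average_log2_per_interval, 1)
  expect_equal(gr2$average_log2_per_h, 1 / 6)
  ts_zero <- tibble::tibble(frame = 0:2, time_h = (0:2) * 6,
                            total_mask_area_um2 = c(0, 1, 2))
  expect_warning(gr0 <- growth_rate_series(ts_zero), "undefined")
  expect_false(gr0$defined)

  pm <- plate_map("A01", "vehicle")
  cfg <- small_sim_config(n_timepoints = 9L, seeding_density = 5L,
                          seed = 31L)
  truth <- simulate_plate(cfg, pm)
  rw <- render_well_series(truth, "A01")
  ts <- compute_well_metrics(rw$images, rw$masks)
  gr_meas <- growth_rate_series(ts)$average_log2_per_h
  gr_true <- cfg$growth_rate_h / log(2)
  expect_lt(abs(gr_meas - gr_true) / gr_true, 0.10)
})

test_that("metrics round-trip through the long-format CSV", {
  pm <- plate_map("A01", "vehicle")
  cfg <- small_sim_config(seed = 13L)
  truth <- simulate_plate(cfg, pm)
  rw <- render_well_series(truth, "A01")
  ts <- compute_well_metrics(rw$images, rw$masks)
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(ts, path)
  back <- read_metrics_csv(path)[["A01"]]
  expect_equal(back$total_mask_area_um2, ts$total_mask_area_um2)
  expect_equal(back$viable_area_um2, ts$viable_area_um2)
})
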