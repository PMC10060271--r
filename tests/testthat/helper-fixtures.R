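# Shared fixture builders: every fixture is generated in code at test
# time from a fixed seed.

# A small, artifact-free plate for fast unit tests.
small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(image_size_px = c(128L, 128L), n_timepoints = 3L,
                   seeding_density = 4L, mean_radius_um = 45,
                   seed = 42L, artifact_rates = c(bubbles = 0, debris = 0))
  do.call(simulation_config, utils::modifyList(defaults, args))
}

vehicle_wells <- function(n) {
  sprintf("%s%02d", LETTERS[(seq_len(n) - 1) %/% 24 + 1],
          (seq_len(n) - 1) %% 24 + 1)
}

# (brightfield, fluorescence-truth mask) training pairs from simulated
# vehicle wells; one pair per well, taken at `frame`.
make_training_pairs <- function(n, image_px = 96L, seed = 11L,
                                frame = 2L, seeding = 3L,
                                mean_radius_um = 40) {
  cfg <- simulation_config(image_size_px = c(image_px, image_px),
                           n_timepoints = max(frame, 2L),
                           seeding_density = seeding,
                           mean_radius_um = mean_radius_um, seed = seed,
                           artifact_rates = c(bubbles = 0.2, debris = 0.5))
  pm <- plate_map(vehicle_wells(n), "vehicle")
  truth <- simulate_plate(cfg, pm)
  lapply(pm$well_id, function(w) {
    rw <- render_well_series(truth, w)
    f <- rw$images$frames[[frame]]
    list(bf = f$bf,
         mask = fluorescence_ground_truth(f$blue, f$green),
         truth_mask = rw$masks[[frame]])
  })
}
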