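#' Simulation configuration for the synthetic plate generator
#'
#' Bundles every knob of the synthetic organoid-plate simulator. Defaults
#' describe the screening setup the generator emulates: a 384-well plate
#' imaged every 6 h, organoids whose projected area doubles roughly once a
#' day, a mixed solid/cystic population, fusion of touching organoids, and
#' density-dependent growth slowdown once a well gets crowded.
#'
#' @param plate_format wells per plate (96 or 384).
#' @param image_size_px integer pair, raster size (rows, cols) of one well image.
#' @param um_per_px physical pixel scale in micrometres per pixel.
#' @param n_timepoints number of frames (>= 2).
#' @param dt_h hours between frames.
#' @param seed integer RNG seed; identical seed + config give bit-identical
#'   truth tables and rendered stacks.
#' @param seeding_density organoids placed per well at T0.
#' @param morphology_mix fraction of solid (vs cystic) organoids in `[0, 1]`.
#' @param growth_rate_h per-organoid exponential area growth rate (1/h);
#'   the default `log(2)/24` doubles the area every 24 h.
#' @param density_slowdown_threshold object count above which the growth
#'   rate is multiplied by `density_slowdown_factor`.
#' @param density_slowdown_factor multiplicative growth penalty (< 1) applied
#'   above the threshold.
#' @param drug_panel list of drug entries, each a list with fields `drug`,
#'   `concentrations` (molar vector), `ec50_true` (molar), `hill_true`,
#'   `max_kill_fraction` in `[0, 1]`, and `mode` (`"cytostatic"` or
#'   `"cytotoxic"`).
#' @param artifact_rates named numeric, expected artifacts per well:
#'   `bubbles` (bright rings) and `debris` (small high-contrast specks).
#' @param mean_radius_um mean initial organoid radius (µm).
#' @param radius_cv coefficient of variation of the initial radius.
#' @param noise_sd Gaussian read-noise standard deviation (intensity units,
#'   images live in `[0, 1]`).
#' @param illumination_gradient peak-to-peak amplitude of the smooth
#'   illumination ramp added to every channel.
#' @param fusion_enabled if `TRUE`, overlapping organoids merge into one
#'   object (areas summed, lower id kept).
#'
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(n_timepoints = 5, seeding_density = 6, seed = 7)
#' cfg$dt_h
simulation_config <- function(plate_format = 384,
                              image_size_px = c(192L, 192L),
                              um_per_px = 4,
                              n_timepoints = 9,
                              dt_h = 6,
                              seed = 1L,
                              seeding_density = 10,
                              morphology_mix = 0.7,
                              growth_rate_h = log(2) / 24,
                              density_slowdown_threshold = 25,
                              density_slowdown_factor = 0.5,
                              drug_panel = list(),
                              artifact_rates = c(bubbles = 0.3, debris = 1),
                              mean_radius_um = 55,
                              radius_cv = 0.2,
                              noise_sd = 0.02,
                              illumination_gradient = 0.05,
                              fusion_enabled = TRUE) {
  cfg <- list(plate_format = plate_format,
              image_size_px = as.integer(image_size_px),
              um_per_px = um_per_px, n_timepoints = as.integer(n_timepoints),
              dt_h = dt_h, seed = as.integer(seed),
              seeding_density = as.integer(seeding_density),
              morphology_mix = morphology_mix, growth_rate_h = growth_rate_h,
              density_slowdown_threshold = density_slowdown_threshold,
              density_slowdown_factor = density_slowdown_factor,
              drug_panel = drug_panel, artifact_rates = artifact_rates,
              mean_radius_um = mean_radius_um, radius_cv = radius_cv,
              noise_sd = noise_sd,
              illumination_gradient = illumination_gradient,
              fusion_enabled = isTRUE(fusion_enabled))
  validate_sim_config(cfg)
}

#' @rdname simulation_config
#' @param cfg a candidate configuration list.
#' @export
validate_sim_config <- function(cfg) {
  plate_dims(cfg$plate_format)
  if (length(cfg$image_size_px) != 2L || any(cfg$image_size_px < 16L))
    abort_field("image_size_px", "must be an integer pair, each >= 16")
  assert_scalar_num(cfg$um_per_px, "um_per_px", lower = 0, strict_lower = TRUE)
  if (!is.numeric(cfg$n_timepoints) || cfg$n_timepoints < 2)
    abort_field("n_timepoints", "must be >= 2")
  assert_scalar_num(cfg$dt_h, "dt_h", lower = 0, strict_lower = TRUE)
  assert_scalar_num(cfg$seed, "seed")
  assert_scalar_num(cfg$seeding_density, "seeding_density", lower = 0)
  assert_scalar_num(cfg$morphology_mix, "morphology_mix", lower = 0, upper = 1)
  assert_scalar_num(cfg$growth_rate_h, "growth_rate_h", lower = 0)
  assert_scalar_num(cfg$density_slowdown_threshold, "density_slowdown_threshold",
                    lower = 0)
  assert_scalar_num(cfg$density_slowdown_factor, "density_slowdown_factor",
                    lower = 0, upper = 1)
  assert_scalar_num(cfg$mean_radius_um, "mean_radius_um", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(cfg$noise_sd, "noise_sd", lower = 0)
  for (entry in cfg$drug_panel) {
    for (f in c("drug", "concentrations", "ec50_true", "hill_true",
                "max_kill_fraction", "mode"))
      if (is.null(entry[[f]]))
        abort_field("drug_panel", paste("entry missing field", f))
    assert_scalar_num(entry$max_kill_fraction,
                      "drug_panel$max_kill_fraction", lower = 0, upper = 1)
    assert_scalar_num(entry$ec50_true, "drug_panel$ec50_true", lower = 0,
                      strict_lower = TRUE)
    if (!entry$mode %in% c("cytostatic", "cytotoxic"))
      abort_field("drug_panel$mode", "must be 'cytostatic' or 'cytotoxic'")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("  %d-well plate, %dx%d px @ %.3g um/px",
              x$plate_format, x$image_size_px[1], x$image_size_px[2],
              x$um_per_px),
      sprintf("  %d frames every %g h; seed %d", x$n_timepoints, x$dt_h,
              x$seed),
      sprintf("  %d organoids/well (%.0f%% solid), growth %.4g /h",
              x$seeding_density, 100 * x$morphology_mix, x$growth_rate_h),
      sprintf("  drug panel: %d entr%s", length(x$drug_panel),
              if (length(x$drug_panel) == 1) "y" else "ies"),
      sep = "\n")
  invisible(x)
}

# Hill effect E(c) = c^h / (c^h + ec50^h), the fractional drug effect.
hill_effect <- function(conc, ec50, hill) {
  conc^hill / (conc^hill + ec50^hill)
}
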