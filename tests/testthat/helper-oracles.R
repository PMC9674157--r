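# Shared model and brute-force grid-scan oracles. The oracles never call the
# package's solvers: they evaluate the closed-form curve on a dense age grid
# and pick the closest grid point, so they are an independent check on the
# bisection-based inversion.

default_model <- reserve_params()

# log10 z-track on a dense grid; step 0.001 y bounds the oracle error by
# half a step.
oracle_grid <- seq(0, 60, by = 0.001)

oracle_track <- function(z, model = default_model) {
  rise <- pnorm(oracle_grid, model$center_age - model$width_1 / 2,
                model$exponent)
  fall <- 1 - pnorm(oracle_grid, model$center_age + model$width_1 / 2,
                    model$width_2)
  model$amplitude * rise * fall + z * model$sigma_log10
}

oracle_inverse_age <- function(log10_count, z = 0, model = default_model) {
  oracle_grid[which.min(abs(oracle_track(z, model) - log10_count))]
}

# POI prediction by stepping the healthy curve on the grid, no root finder.
oracle_poi_age <- function(age, dose, z = 0, model = default_model,
                           ld50 = 2) {
  track <- oracle_track(z, model)
  thr <- log10(model$poi_threshold)
  t_z <- oracle_grid[which.min(abs(track - thr))]
  pre <- track[which.min(abs(oracle_grid - age))]
  post <- pre - dose / ld50 * log10(2)
  if (post <= thr) return(age)
  eq <- oracle_grid[which.min(abs(track - post))]
  age + (t_z - eq)
}

valid_dose_records <- function() {
  data.frame(
    patient_id = "p1",
    plan_label = c("photon", "photon", "proton", "proton"),
    ovary_side = c("left", "right", "left", "right"),
    modality = c("photon", "photon", "proton", "proton"),
    dose_min_gy = c(4, 8, 0.2, 0.5),
    dose_mean_gy = c(6, 10, 0.5, 1.0),
    dose_max_gy = c(9, 14, 1.0, 2.0),
    stringsAsFactors = FALSE)
}
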