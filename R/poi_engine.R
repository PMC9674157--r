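# Counselling threshold drawn on charts and used for flagging only; it never
# alters a computed prediction.
POI_COUNSEL_AGE <- 30

#' Equivalent chronologic age after irradiation
#'
#' Radiation reduces the reserve by the surviving fraction; the equivalent age
#' is the (older) age at which a healthy subject on the same z-track holds the
#' reduced count:
#' `inverse_age(log10(ngf_count(age, z) * surviving_fraction(dose)), z)`.
#' After treatment the reserve is assumed to resume the healthy decline from
#' this equivalent age.
#'
#' @param age Chronologic age at treatment in years.
#' @param dose Total dose to the least-affected ovary in Gy (or CGE);
#'   non-negative.
#' @param z z-score of the subject's reserve (0 = population average).
#' @param model A `"reserve_model"` from [reserve_params()].
#' @param ld50_gy Median lethal dose for NGFs in Gy.
#' @return Equivalent age in years (`>= age`; equal at dose 0). If the
#'   post-dose count falls below the z-track minimum over the whole age
#'   domain, no equivalent age exists and an error condition of class
#'   `"radpoi_immediate_poi"` is signalled.
#' @examples
#' equivalent_age(5, 0)  # 5
#' equivalent_age(5, 2)  # the age at which the mean track holds half the
#'                       # age-5 reserve
#' @export
equivalent_age <- function(age, dose, z = 0, model = reserve_params(),
                           ld50_gy = 2.0) {
  .check_age(age, model)
  n <- length(age)
  stopifnot(length(dose) %in% c(1L, n), length(z) %in% c(1L, n))
  dose <- rep_len(dose, n); z <- rep_len(z, n)
  vapply(seq_len(n), function(i) {
    post <- log10(ngf_count(age[i], z[i], model) *
                    surviving_fraction(dose[i], ld50_gy))
    track_min <- .curve_log10(model$age_domain[2], model) +
      z[i] * model$sigma_log10
    if (post < track_min)
      stop(structure(
        class = c("radpoi_immediate_poi", "error", "condition"),
        list(message = sprintf(
               paste0("post-dose reserve (log10 = %.3g) is below the z-track ",
                      "minimum: immediate POI at the treatment age"), post),
             call = NULL)))
    inverse_age(post, z = z[i], model = model)
  }, numeric(1))
}

.poi_one <- function(age, dose, z, model, ld50_gy) {
  thr <- model$poi_threshold
  t_z <- age_at_threshold(z, model)
  if (age >= t_z) {
    warning(sprintf(paste0("treatment age %.3g is at or beyond the z = %g ",
                           "track menopause age %.3g: immediate POI"),
                    age, z, t_z), call. = FALSE)
    return(list(poi_age = age, immediate = TRUE, natural = t_z))
  }
  post <- ngf_count(age, z, model) * surviving_fraction(dose, ld50_gy)
  if (post <= thr)
    return(list(poi_age = age, immediate = TRUE, natural = t_z))
  eq <- equivalent_age(age, dose, z, model, ld50_gy)
  # clamp: dose can only shorten reproductive lifespan, never extend it, and
  # POI cannot precede treatment (guards the 1e-6-year solver tolerance)
  poi <- min(t_z, max(age, age + (t_z - eq)))
  list(poi_age = poi, immediate = FALSE, natural = t_z)
}

#' Predicted age at premature ovarian insufficiency
#'
#' The survivor ages forward along the healthy decline from the equivalent
#' age, reaching the POI threshold after `age_at_threshold(z) -
#' equivalent_age(age, dose, z)` further years:
#' `poi_age = age + (age_at_threshold(z) - equivalent_age(age, dose, z))`.
#' If the dose immediately reduces the reserve to or below the threshold
#' (or the treatment age is already past the z-track menopause age), POI is
#' immediate and the treatment age itself is returned.
#'
#' @inheritParams equivalent_age
#' @return Predicted age at POI in years; never less than `age`, never more
#'   than the z-track natural menopause age. Elementwise over recycled
#'   arguments.
#' @examples
#' predict_poi_age(5, 1)    # ~42: 1 Gy at age 5
#' predict_poi_age(5, 12)   # ~12: 12 Gy at age 5
#' predict_poi_age(25, 0)   # natural menopause, ~49.5
#' @export
predict_poi_age <- function(age, dose, z = 0, model = reserve_params(),
                            ld50_gy = 2.0) {
  .check_age(age, model)
  n <- max(length(age), length(dose), length(z))
  age <- rep_len(age, n); dose <- rep_len(dose, n); z <- rep_len(z, n)
  vapply(seq_len(n), function(i)
    .poi_one(age[i], dose[i], z[i], model, ld50_gy)$poi_age, numeric(1))
}

#' Reproductive lifespan lost to irradiation
#'
#' Years of reproductive life removed by the dose: the z-track natural
#' menopause age minus the predicted POI age. Zero at dose 0; equal to the
#' full remaining natural lifespan when POI is immediate.
#'
#' @inheritParams equivalent_age
#' @return Years lost (non-negative), elementwise over recycled arguments.
#' @examples
#' years_lost(5, 1)  # ~8
#' years_lost(5, 0)  # 0
#' @export
years_lost <- function(age, dose, z = 0, model = reserve_params(),
                       ld50_gy = 2.0) {
  n <- max(length(age), length(dose), length(z))
  z <- rep_len(z, n)
  poi <- predict_poi_age(age, dose, z, model, ld50_gy)
  t_z <- vapply(z, age_at_threshold, numeric(1), model = model)
  pmax(0, t_z - poi)
}

#' Exposure scenario for one ovary
#'
#' The calculator's input unit: age at treatment plus the minimum, mean and
#' maximum dose to the least-affected ovary from one treatment plan.
#'
#' @param age_at_treatment Age in years (decimal allowed).
#' @param dose_min,dose_mean,dose_max Dose triplet in Gy (or CGE for proton
#'   plans); must satisfy `0 <= dose_min <= dose_mean <= dose_max`.
#' @param modality `"photon"` or `"proton"`.
#' @return An object of class `"exposure_scenario"`.
#' @examples
#' exposure_scenario(5, 0.8, 1, 1.4)
#' @export
exposure_scenario <- function(age_at_treatment, dose_min, dose_mean, dose_max,
                              modality = c("photon", "proton")) {
  modality <- match.arg(modality)
  doses <- c(dose_min, dose_mean, dose_max)
  if (!is.numeric(age_at_treatment) || length(age_at_treatment) != 1L ||
      !is.finite(age_at_treatment) || age_at_treatment < 0)
    stop("'age_at_treatment' must be a single non-negative age in years",
         call. = FALSE)
  if (!is.numeric(doses) || length(doses) != 3L || any(!is.finite(doses)))
    stop("dose triplet must be three finite numbers (Gy)", call. = FALSE)
  if (dose_min < 0 || dose_min > dose_mean || dose_mean > dose_max)
    stop("dose triplet must satisfy 0 <= dose_min <= dose_mean <= dose_max",
         call. = FALSE)
  structure(list(age_at_treatment = age_at_treatment,
                 dose_min = dose_min, dose_mean = dose_mean,
                 dose_max = dose_max, modality = modality),
            class = "exposure_scenario")
}

#' POI prediction window over the dose triplet and z-score band
#'
#' Fills the 3 x 3 grid of predicted POI ages: minimum / mean / maximum dose
#' crossed with z-scores -1, 0, +1. The z = +/-1 span is the 68% prediction
#' window for the natural variation in reserve. Each cell carries an
#' immediate-POI flag, the years of reproductive lifespan lost, and whether
#' the predicted POI age falls before the 30-year counselling threshold
#' (annotation only).
#'
#' @param scenario An [exposure_scenario()].
#' @param model A `"reserve_model"`.
#' @param ld50_gy Median lethal dose in Gy.
#' @return An object of class `"poi_prediction"`: list with `grid` (data frame
#'   with columns `dose_label`, `dose_gy`, `z`, `poi_age`, `immediate_poi`,
#'   `years_lost`, `before_30`), `natural_menopause` (named by z), `scenario`
#'   and `ld50_gy`.
#' @examples
#' predict_window(exposure_scenario(5, 0.8, 1, 1.4))
#' @export
predict_window <- function(scenario, model = reserve_params(), ld50_gy = 2.0) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  .check_age(scenario$age_at_treatment, model, "age_at_treatment")
  zs <- c(-1, 0, 1)
  doses <- c(min = scenario$dose_min, mean = scenario$dose_mean,
             max = scenario$dose_max)
  grid <- expand.grid(dose_label = names(doses), z = zs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$dose_gy <- doses[grid$dose_label]
  cells <- lapply(seq_len(nrow(grid)), function(i)
    .poi_one(scenario$age_at_treatment, grid$dose_gy[i], grid$z[i],
             model, ld50_gy))
  grid$poi_age <- vapply(cells, `[[`, numeric(1), "poi_age")
  grid$immediate_poi <- vapply(cells, `[[`, logical(1), "immediate")
  grid$years_lost <- pmax(0, vapply(cells, `[[`, numeric(1), "natural") -
                               grid$poi_age)
  grid$before_30 <- grid$poi_age < POI_COUNSEL_AGE
  grid <- grid[, c("dose_label", "dose_gy", "z", "poi_age", "immediate_poi",
                   "years_lost", "before_30")]
  rownames(grid) <- NULL
  natural <- vapply(zs, age_at_threshold, numeric(1), model = model)
  names(natural) <- paste0("z", zs)
  structure(list(grid = grid, natural_menopause = natural,
                 scenario = scenario, ld50_gy = ld50_gy),
            class = "poi_prediction")
}

#' @export
as.data.frame.poi_prediction <- function(x, ...) x$grid

#' @export
print.poi_prediction <- function(x, digits = 1, ...) {
  s <- x$scenario
  unit <- if (s$modality == "photon") "Gy" else "CGE"
  cat(sprintf("POI prediction for treatment at age %.4g y (%s, LD50 %g Gy)\n",
              s$age_at_treatment, s$modality, x$ld50_gy))
  cat(sprintf("Dose to least-affected ovary: min %g / mean %g / max %g %s\n",
              s$dose_min, s$dose_mean, s$dose_max, unit))
  g <- x$grid
  z0 <- g[g$z == 0, ]
  mean0 <- z0[z0$dose_label == "mean", ]
  cat(sprintf("Predicted age at POI (mean dose, average reserve): %.*f y%s\n",
              digits, mean0$poi_age,
              if (mean0$immediate_poi) " [immediate POI]" else ""))
  cat(sprintf("Dose range (z = 0): %.*f - %.*f y\n",
              digits, min(z0$poi_age), digits, max(z0$poi_age)))
  cat(sprintf("68%% window (z = -1 to +1, mean dose): %.*f - %.*f y\n",
              digits, g$poi_age[g$z == -1 & g$dose_label == "mean"],
              digits, g$poi_age[g$z == 1 & g$dose_label == "mean"]))
  cat(sprintf("Years of reproductive lifespan lost (mean dose, z = 0): %.*f\n",
              digits, mean0$years_lost))
  if (any(g$before_30))
    cat("NOTE: predicted POI before age 30 in at least one cell;",
        "fertility preservation should be discussed.\n")
  cat("Caveat: concurrent chemotherapy is additive in an unquantified way;",
      "predictions are an upper limit on the fertile window.\n")
  invisible(x)
}

#' Write a POI prediction grid to JSON or CSV
#'
#' JSON carries the full object (scenario, LD50, natural menopause ages per z,
#' and the grid); CSV carries one row per grid cell.
#'
#' @param x A `"poi_prediction"` from [predict_window()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_poi_json <- function(x, path) {
  stopifnot(inherits(x, "poi_prediction"))
  out <- list(scenario = unclass(x$scenario), ld50_gy = x$ld50_gy,
              natural_menopause = as.list(x$natural_menopause),
              grid = x$grid)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_poi_json
#' @export
write_poi_csv <- function(x, path) {
  stopifnot(inherits(x, "poi_prediction"))
  utils::write.csv(x$grid, path, row.names = FALSE)
  invisible(path)
}

#' Sterilizing dose at an age and z-score
#'
#' The dose that immediately reduces the reserve to the POI threshold; any
#' larger dose causes immediate POI. Closed form from the survival law:
#' `ld50_gy * log2(ngf_count(age, z) / poi_threshold)`. Returns 0 when the
#' reserve is already at or below the threshold.
#'
#' At z = 0 this is the mean sterilizing dose (sterilizes 50% of subjects);
#' at z = +1.96 it is the effective sterilizing dose, ESD (97.5% of subjects).
#'
#' @inheritParams equivalent_age
#' @return Dose in Gy, vectorised over `age`.
#' @examples
#' sterilizing_dose(20)          # ~13.4 Gy
#' sterilizing_dose(20, 1.96)    # ESD, larger
#' @export
sterilizing_dose <- function(age, z = 0, model = reserve_params(),
                             ld50_gy = 2.0) {
  counts <- ngf_count(age, z, model)
  pmax(0, ld50_gy * log2(counts / model$poi_threshold))
}

#' Mean and effective sterilizing dose curves over an age grid
#'
#' The mean sterilizing dose (z = 0; sterilizes 50% of subjects) and the
#' effective sterilizing dose, ESD (z = +1.96; 97.5% of subjects), at each
#' age of a grid. Both decrease with age as the reserve declines, and the ESD
#' is always at least the mean dose.
#'
#' @param age_grid Ages in years within the model domain; non-empty.
#' @inheritParams equivalent_age
#' @return A data frame of class `"sterilizing_dose_curve"` with columns
#'   `age`, `mean_dose` and `esd` (Gy).
#' @examples
#' sterilizing_dose_curves(seq(0, 45, by = 5))
#' @export
sterilizing_dose_curves <- function(age_grid, model = reserve_params(),
                                    ld50_gy = 2.0) {
  if (length(age_grid) == 0L)
    stop("'age_grid' must be non-empty", call. = FALSE)
  .check_age(age_grid, model, "age_grid")
  out <- data.frame(age = age_grid,
                    mean_dose = sterilizing_dose(age_grid, 0, model, ld50_gy),
                    esd = sterilizing_dose(age_grid, 1.96, model, ld50_gy))
  class(out) <- c("sterilizing_dose_curve", "data.frame")
  out
}
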