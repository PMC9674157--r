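#' Built-in illustrative case fixtures
#'
#' Four representative paediatric cases spanning the ages and diagnoses used
#' to illustrate the predictive model: an 8-year-old with pineoblastoma, a
#' 19-year-old with high-risk medulloblastoma (both craniospinal irradiation),
#' and a 16-year-old and a 3-year-old each with a large unresectable pelvic
#' Ewing sarcoma (local radiotherapy). Each case has photon and proton plan
#' templates. Per-ovary dose triplets are deliberately NOT included: published
#' values exist only as figure panels, so doses must be supplied by the user
#' (see [fixture_dose_records()]).
#'
#' @return A data frame with columns `case`, `label`, `age_at_treatment`,
#'   `diagnosis` and `plans` (comma-separated plan template labels).
#' @examples
#' case_fixtures()
#' @export
case_fixtures <- function() {
  data.frame(
    case = 1:4,
    label = paste0("case", 1:4),
    age_at_treatment = c(8, 19, 16, 3),
    diagnosis = c("pineoblastoma",
                  "high-risk medulloblastoma",
                  "unresectable pelvic Ewing sarcoma (>8 cm)",
                  "unresectable pelvic Ewing sarcoma (>8 cm)"),
    plans = rep("photon,proton", 4),
    stringsAsFactors = FALSE)
}

#' Dose records for a case fixture from user-supplied dose triplets
#'
#' Builds a validated per-ovary dose summary for one built-in case, filling
#' the photon and proton plan templates with user-supplied (min, mean, max)
#' dose triplets for the least-affected ovary.
#'
#' @param case Case number 1-4 (see [case_fixtures()]).
#' @param photon,proton Numeric length-3 dose triplets `c(min, mean, max)` in
#'   Gy (photon) and CGE (proton).
#' @param ovary_side Side of the least-affected ovary for both plans
#'   (default `"left"`).
#' @return A dose-record data frame suitable for [compare_plans()].
#' @examples
#' fixture_dose_records(4, photon = c(8, 12, 15), proton = c(0.5, 1, 2))
#' @export
fixture_dose_records <- function(case, photon, proton, ovary_side = "left") {
  fx <- case_fixtures()
  if (!case %in% fx$case) stop("'case' must be 1, 2, 3 or 4", call. = FALSE)
  stopifnot(length(photon) == 3L, length(proton) == 3L)
  df <- data.frame(
    patient_id = fx$label[fx$case == case],
    plan_label = c("photon", "proton"),
    ovary_side = ovary_side,
    modality = c("photon", "proton"),
    dose_min_gy = c(photon[1], proton[1]),
    dose_mean_gy = c(photon[2], proton[2]),
    dose_max_gy = c(photon[3], proton[3]),
    stringsAsFactors = FALSE)
  .validate_dose_records(df, "fixture doses")
}

.save_chart <- function(p, path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    ggplot2::ggsave(path, p, device = grDevices::svg,
                    width = width, height = height)
  } else if (ext == "png") {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  } else {
    stop("chart output must end in .png or .svg: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Dose-response chart: predicted POI age by age at treatment
#'
#' One curve per dose level: predicted age at POI (z = 0) against age at
#' treatment, with the 30-year counselling threshold drawn. The zero-dose
#' curve is the natural menopause age.
#'
#' @param ages Ages at treatment (years) for the x-axis grid.
#' @param doses Dose levels in Gy, one curve each.
#' @param model A `"reserve_model"`.
#' @param ld50_gy Median lethal dose in Gy.
#' @return A ggplot object whose `data` holds columns `age`, `dose`,
#'   `poi_age`.
#' @export
plot_dose_response <- function(ages = 0:45,
                               doses = c(1, 2, 4, 6, 8, 10, 12, 14, 16),
                               model = reserve_params(), ld50_gy = 2.0) {
  .check_age(ages, model, "ages")
  df <- expand.grid(age = ages, dose = doses, KEEP.OUT.ATTRS = FALSE)
  df$poi_age <- predict_poi_age(df$age, df$dose, z = 0, model = model,
                                ld50_gy = ld50_gy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$poi_age,
                                   colour = factor(.data$dose),
                                   group = factor(.data$dose))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = POI_COUNSEL_AGE, linetype = "dashed") +
    ggplot2::labs(x = "Age at radiotherapy (years)",
                  y = "Predicted age at POI (years)",
                  colour = "Dose to ovary (Gy)",
                  title = "Predicted age at POI by age and dose",
                  subtitle = sprintf(
                    "z = 0 (average reserve); LD50 = %g Gy; dashed line: 30-year counselling threshold",
                    ld50_gy)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_dose_response
#' @param path Output chart path (`.png` or `.svg`).
#' @return `render_dose_response_chart()` writes the chart and returns `path`
#'   invisibly.
#' @export
render_dose_response_chart <- function(path, ages = 0:45,
                                       doses = c(1, 2, 4, 6, 8, 10, 12, 14, 16),
                                       model = reserve_params(),
                                       ld50_gy = 2.0) {
  .save_chart(plot_dose_response(ages, doses, model, ld50_gy), path)
}

#' Sterilizing-dose chart
#'
#' Mean sterilizing dose (z = 0; 50% of subjects) and effective sterilizing
#' dose (ESD, z = +1.96; 97.5% of subjects) against age.
#'
#' @param age_grid Ages in years; non-empty, within the model domain.
#' @inheritParams plot_dose_response
#' @return A ggplot object; its `data` has columns `age`, `series`, `dose_gy`.
#' @export
plot_esd <- function(age_grid = 0:45, model = reserve_params(),
                     ld50_gy = 2.0) {
  cv <- sterilizing_dose_curves(age_grid, model, ld50_gy)
  df <- data.frame(
    age = rep(cv$age, 2),
    series = rep(c("mean sterilizing dose (50%)", "ESD (97.5%)"),
                 each = nrow(cv)),
    dose_gy = c(cv$mean_dose, cv$esd))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$dose_gy,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = "Dose to ovary (Gy)",
                  colour = NULL,
                  title = "Mean and effective sterilizing doses",
                  subtitle = sprintf("LD50 = %g Gy", ld50_gy)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_esd
#' @param path Output chart path (`.png` or `.svg`).
#' @export
render_esd_chart <- function(path, age_grid = 0:45,
                             model = reserve_params(), ld50_gy = 2.0) {
  .save_chart(plot_esd(age_grid, model, ld50_gy), path)
}

#' Case comparison panel
#'
#' One row per treatment plan: a dot at the z = 0 mean-dose POI age, a bar
#' spanning the z = 0 min-to-max-dose predictions, a shaded band spanning the
#' z = -1 to +1 mean-dose predictions (the 68% window), and a vertical line at
#' the 30-year counselling threshold.
#'
#' @param comparison A `"plan_comparison"` from [compare_plans()].
#' @return A ggplot object; its `data` is the comparison table.
#' @export
plot_case_panel <- function(comparison) {
  stopifnot(inherits(comparison, "plan_comparison"))
  df <- as.data.frame(comparison)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$plan_label)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$poi_age_z_minus1,
                                       xend = .data$poi_age_z_plus1,
                                       yend = .data$plan_label),
                          linewidth = 6, colour = "grey80") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$poi_age_max_dose,
                                       xend = .data$poi_age_min_dose,
                                       yend = .data$plan_label),
                          linewidth = 1.5) +
    ggplot2::geom_point(ggplot2::aes(x = .data$poi_age_mean_dose), size = 3) +
    ggplot2::geom_vline(xintercept = POI_COUNSEL_AGE, linetype = "dashed") +
    ggplot2::labs(x = "Predicted age at POI (years)", y = NULL,
                  title = sprintf("Plan comparison, treatment at age %.4g",
                                  attr(comparison, "age_at_treatment")),
                  subtitle = paste("Dot: mean dose (z = 0); bar: min-max dose;",
                                   "band: 68% reserve-variation window")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_case_panel
#' @param path Output chart path (`.png` or `.svg`).
#' @export
render_case_panel <- function(comparison, path) {
  .save_chart(plot_case_panel(comparison), path, width = 7, height = 3.5)
}
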