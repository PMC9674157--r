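test_that("case fixtures carry the four illustrative ages without doses", {
  fx <- case_fixtures()
  expect_equal(fx$age_at_treatment, c(8, 19, 16, 3))
  expect_equal(nrow(fx), 4L)
  expect_false(any(grepl("dose", names(fx))))
  recs <- fixture_dose_records(4, photon = c(8, 12, 15),
                               proton = c(0.5, 1, 2))
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$modality, c("photon", "proton"))
  expect_error(fixture_dose_records(5, c(1, 2, 3), c(1, 2, 3)), "case")
  expect_error(fixture_dose_records(1, c(3, 2, 1), c(1, 2, 3)), "ordering")
})

test_that("dose-response chart reflects the engine and writes a file", {
  p <- plot_dose_response(ages = c(0, 5, 10), doses = c(1, 12))
  d <- p$data
  expect_equal(d$poi_age[d$age == 5 & d$dose == 1],
               predict_poi_age(5, 1, 0, default_model))
  expect_equal(d$poi_age[d$age == 5 & d$dose == 12],
               predict_poi_age(5, 12, 0, default_model))
  path <- withr::local_tempfile(fileext = ".png")
  render_dose_response_chart(path, ages = c(0, 5, 10), doses = c(1, 12))
  expect_true(file.exists(path) && file.size(path) > 0)
  # degenerate single-point chart still renders
  path2 <- withr::local_tempfile(fileext = ".png")
  render_dose_response_chart(path2, ages = 5, doses = 1)
  expect_true(file.exists(path2) && file.size(path2) > 0)
})

test_that("sterilizing-dose chart data are identical to the curve module", {
  grid <- seq(0, 45, by = 5)
  p <- plot_esd(grid)
  cv <- sterilizing_dose_curves(grid, default_model)
  expect_equal(p$data$dose_gy, c(cv$mean_dose, cv$esd))
  expect_error(plot_esd(numeric(0)), "non-empty")
  path <- withr::local_tempfile(fileext = ".svg")
  render_esd_chart(path, grid)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("case panel band endpoints equal the z = +/-1 grid cells", {
  recs <- fixture_dose_records(4, photon = c(8, 12, 15),
                               proton = c(0.5, 1, 2))
  cmp <- compare_plans(recs, age = 3)
  p <- plot_case_panel(cmp)
  w <- attr(cmp, "windows")
  for (plan in c("photon", "proton")) {
    g <- w[[plan]]$grid
    row <- p$data[p$data$plan_label == plan, ]
    expect_equal(row$poi_age_z_minus1,
                 g$poi_age[g$z == -1 & g$dose_label == "mean"])
    expect_equal(row$poi_age_z_plus1,
                 g$poi_age[g$z == 1 & g$dose_label == "mean"])
  }
  path <- withr::local_tempfile(fileext = ".png")
  render_case_panel(cmp, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  # re-rendering is idempotent at the data level
  expect_equal(plot_case_panel(cmp)$data, p$data)
})

test_that("cli predict reports the z = 0 POI age and validates flags", {
  out <- capture.output(
    code <- withr::with_options(list(warn = -1), suppressMessages(
      poi_cli(c("predict", "--age", "5", "--dose-min", "1",
                "--dose-mean", "1", "--dose-max", "1",
                "--format", "text")))))
  expect_equal(code, 0L)
  poi <- sprintf("%.1f", predict_poi_age(5, 1, 0, default_model))
  expect_true(any(grepl(poi, out, fixed = TRUE)))
  expect_true(any(grepl("chemotherapy", out)))

  # json output parses and matches the engine
  out <- capture.output(suppressMessages(
    poi_cli(c("predict", "--age", "5", "--dose-min", "1",
              "--dose-mean", "1", "--dose-max", "1"))))
  j <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(j$grid$poi_age[j$grid$z == 0 & j$grid$dose_label == "mean"],
               predict_poi_age(5, 1, 0, default_model))

  # missing required flag: usage error, exit code 2
  expect_equal(suppressMessages(poi_cli(c("predict", "--dose-mean", "1",
                                          "--dose-min", "1",
                                          "--dose-max", "1"))), 2L)
  expect_equal(suppressMessages(poi_cli(character(0))), 2L)
  expect_equal(suppressMessages(poi_cli(c("transmogrify"))), 2L)
})

test_that("cli esd and case-report subcommands produce their outputs", {
  path <- withr::local_tempfile(fileext = ".png")
  expect_equal(suppressMessages(poi_cli(c("esd", "--output", path))), 0L)
  expect_true(file.exists(path) && file.size(path) > 0)

  out <- capture.output(code <- suppressMessages(
    poi_cli(c("case-report", "--case", "4",
              "--photon-doses", "8,12,15", "--proton-doses", "0.5,1,2",
              "--format", "text"))))
  expect_equal(code, 0L)
  expect_true(any(grepl("proton", out)))

  # --ld50 override flows through to the prediction
  out <- capture.output(suppressMessages(
    poi_cli(c("predict", "--age", "5", "--dose-min", "2", "--dose-mean", "2",
              "--dose-max", "2", "--ld50", "1"))))
  j <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(j$ld50_gy, 1)
  expect_equal(j$grid$poi_age[j$grid$z == 0 & j$grid$dose_label == "mean"],
               predict_poi_age(5, 2, 0, default_model, ld50_gy = 1))
})
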