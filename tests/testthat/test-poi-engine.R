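test_that("equivalent age is identity at dose 0 and increases with dose", {
  m <- default_model
  expect_equal(equivalent_age(5, 0, 0, m), 5, tolerance = 1e-5)
  eq <- equivalent_age(rep(5, 5), c(0, 1, 2, 4, 8), 0, m)
  expect_true(all(diff(eq) > 0))
  expect_true(all(eq >= 5 - 1e-6))
  # at the LD50 the equivalent age holds half the pre-treatment reserve
  eq2 <- equivalent_age(5, 2, 0, m)
  expect_equal(ngf_count(eq2, 0, m), ngf_count(5, 0, m) / 2,
               tolerance = 1e-4)
  expect_lt(abs(eq2 - oracle_inverse_age(log10(ngf_count(5, 0, m) / 2))),
            0.01)
})

test_that("a reserve annihilated within the domain signals immediate POI", {
  expect_error(equivalent_age(5, 200, 0, default_model),
               class = "radpoi_immediate_poi")
})

test_that("POI predictions reproduce zero-dose and immediate-POI limits", {
  m <- default_model
  # dose 0: natural menopause for that z-track, regardless of treatment age
  for (a in c(2, 10, 30)) {
    expect_equal(predict_poi_age(a, 0, 0, m), m$menopause_age,
                 tolerance = 1e-5)
    expect_equal(predict_poi_age(a, 0, 1, m), age_at_threshold(1, m),
                 tolerance = 1e-5)
  }
  # overwhelming dose: POI at the treatment age
  expect_equal(predict_poi_age(5, 100, 0, m), 5)
  expect_equal(years_lost(5, 100, 0, m), m$menopause_age - 5,
               tolerance = 1e-5)
  # treatment after the z-track menopause age: immediate POI with a warning
  expect_warning(p <- predict_poi_age(55, 1, 0, m), "immediate POI")
  expect_equal(p, 55)
  expect_equal(years_lost(5, 0, 0, m), 0, tolerance = 1e-6)
})

test_that("POI age is monotone in dose and z and bounded by age and menopause", {
  m <- default_model
  doses <- c(0, 0.5, 1, 2, 4, 8, 16)
  for (z in c(-1, 0, 1)) {
    poi <- predict_poi_age(rep(8, length(doses)), doses, z, m)
    expect_true(all(diff(poi) <= 1e-9))
    expect_true(all(poi >= 8 - 1e-9))
    expect_true(all(poi <= age_at_threshold(z, m) + 1e-9))
  }
  for (d in c(0.5, 2, 6)) {
    poi <- predict_poi_age(8, d, c(-1, 0, 1), m)
    expect_true(all(diff(poi) > 0))
  }
})

test_that("POI solver agrees with the grid-scan oracle on random scenarios", {
  set.seed(20221118)
  n <- 50
  ages <- runif(n, 0.5, 45)
  doses <- runif(n, 0, 12)
  zs <- runif(n, -1.5, 1.5)
  for (i in seq_len(n)) {
    got <- predict_poi_age(ages[i], doses[i], zs[i], default_model)
    expect_lt(abs(got - oracle_poi_age(ages[i], doses[i], zs[i])), 0.01)
  }
})

test_that("prediction window grid has the expected structure and ordering", {
  m <- default_model
  w <- predict_window(exposure_scenario(5, 0.5, 1, 2), m)
  g <- w$grid
  expect_equal(nrow(g), 9L)
  expect_setequal(unique(g$dose_label), c("min", "mean", "max"))
  expect_setequal(unique(g$z), c(-1, 0, 1))
  # monotone in z at every dose, and in dose at every z
  for (lab in c("min", "mean", "max")) {
    sub <- g[g$dose_label == lab, ]
    expect_true(all(diff(sub$poi_age[order(sub$z)]) > 0))
  }
  for (zz in c(-1, 0, 1)) {
    sub <- g[g$z == zz, ]
    ord <- match(c("min", "mean", "max"), sub$dose_label)
    expect_true(all(diff(sub$poi_age[ord]) <= 1e-9))
  }
  # zero dose reproduces the natural menopause age of each track
  w0 <- predict_window(exposure_scenario(5, 0, 0, 0), m)
  for (zz in c(-1, 0, 1)) {
    expect_equal(unique(round(w0$grid$poi_age[w0$grid$z == zz], 6)),
                 round(age_at_threshold(zz, m), 6))
  }
  expect_false(any(w0$grid$before_30))
})

test_that("degenerate dose triplet collapses the dose axis", {
  w <- predict_window(exposure_scenario(5, 1, 1, 1), default_model)
  z0 <- w$grid[w$grid$z == 0, ]
  expect_equal(z0$poi_age,
               rep(predict_poi_age(5, 1, 0, default_model), 3))
  expect_error(exposure_scenario(5, 2, 1, 3), "dose triplet")
})

test_that("sterilizing dose closed form inverts the POI prediction", {
  m <- default_model
  for (z in c(0, 1.96)) {
    for (a in seq(1, 45, by = 4)) {
      d <- sterilizing_dose(a, z, m)
      expect_equal(predict_poi_age(a, d, z, m), a, tolerance = 0.1)
      expect_gt(sterilizing_dose(a, 1.96, m), sterilizing_dose(a, 0, m))
    }
  }
  # already below threshold: dose 0
  expect_equal(sterilizing_dose(55, 0, m), 0)
  # boundary: at the threshold crossing the dose is ~0
  expect_lt(sterilizing_dose(m$menopause_age, 0, m), 1e-4)
})

test_that("sterilizing dose curves decrease with age, ESD on top", {
  cv <- sterilizing_dose_curves(0:45, default_model)
  expect_true(all(diff(cv$mean_dose) < 0))
  expect_true(all(diff(cv$esd) < 0))
  expect_true(all(cv$esd >= cv$mean_dose))
  expect_equal(cv$mean_dose[cv$age == 20],
               sterilizing_dose(20, 0, default_model))
  expect_error(sterilizing_dose_curves(numeric(0)), "non-empty")
})

test_that("prediction grids serialize to JSON and CSV faithfully", {
  w <- predict_window(exposure_scenario(8, 4, 6, 9), default_model)
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_poi_json(w, jpath)
  write_poi_csv(w, cpath)
  j <- jsonlite::fromJSON(jpath)
  expect_equal(j$scenario$age_at_treatment, 8)
  expect_equal(j$ld50_gy, 2)
  expect_equal(j$grid$poi_age, w$grid$poi_age)
  csv <- read.csv(cpath)
  expect_equal(nrow(csv), 9L)
  expect_equal(csv$poi_age, w$grid$poi_age)
  expect_equal(csv$dose_gy, w$grid$dose_gy)
})
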