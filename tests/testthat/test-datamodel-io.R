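test_that("measurement tables parse, validate and normalize idempotently", {
  df <- tiny_measurements()
  m <- voi_measurements(df)
  expect_equal(nrow(m), 3)
  expect_equal(unique(m$region), "kidneys")
  # derived quantities: A = S*C, c = A/V
  expect_equal(voi_activity_MBq(m), m$sensitivity_MBq_per_cps * m$count_rate_cps)
  expect_true(all(voi_concentration_MBq_per_cc(m) >= 0))
  # normalization is idempotent
  expect_identical(voi_measurements(m), m)

  bad <- df; bad$volume_cc[2] <- 0
  expect_error(voi_measurements(bad), "row 2.*volume_cc",
               class = "prrtdose_parse_error")
  dup <- rbind(df, df[1, ])
  expect_error(voi_measurements(dup), "duplicate",
               class = "prrtdose_parse_error")
  expect_error(voi_measurements(df[, -3]), "missing column",
               class = "prrtdose_parse_error")
})

test_that("cycle studies enforce the imaging protocol invariants", {
  st <- cycle_study("P1", 1, 7300, "adult_male", tiny_measurements(),
                    data.frame(time_h = c(24, 168),
                               concentration_MBq_per_cc = c(0.03, 0.001)))
  expect_s3_class(st, "cycle_study")
  # cycle 1 needs >= 2 time points per region
  expect_error(
    cycle_study("P1", 1, 7300, "adult_male", tiny_measurements(times = 24,
                                                               cps = 1500)),
    ">= 2 time point")
  # later cycles accept a single point
  st2 <- cycle_study("P1", 2, 7300, "adult_male",
                     tiny_measurements(times = 24, cps = 1500))
  expect_equal(st2$cycle_index, 2L)
  expect_error(cycle_study("P1", 0, 7300, "adult_male", tiny_measurements()))
})

test_that("a CSV round trip reproduces randomly generated studies exactly", {
  spec <- cohort_spec(n_patients = 3, seed = 11)
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    p <- generate_patient(spec, i)
    for (st in p$studies) {
      meta <- write_cycle_study(st, dir)
      back <- read_cycle_study(meta)
      expect_equal(back$measurements, st$measurements, tolerance = 0)
      expect_equal(back$blood, st$blood, tolerance = 0)
      expect_identical(back$patient_id, st$patient_id)
      expect_identical(back$cycle_index, st$cycle_index)
      expect_equal(back$injected_activity_MBq, st$injected_activity_MBq)
      expect_identical(back$phantom, st$phantom)
    }
  }
})

test_that("the packaged coefficient file loads with the published values", {
  set <- read_coefficients(system.file("extdata",
                                       "mlr_coefficients_published.json",
                                       package = "prrtdose"))
  k <- get_coefficients(set, "kidneys", "t1t2t3")
  expect_equal(k$alpha0, 11.86)
  expect_equal(k$alpha1, 0.85)
  expect_equal(k$alpha2, 0.0111)
  bm <- get_coefficients(set, "bone_marrow", "t3")
  expect_equal(bm$theta_bm_bm, 1889)
  expect_equal(bm$theta_bm_rm, 315)
  expect_equal(bm$beta0, 5.03)
  expect_equal(bm$beta1, 0.82)
  expect_equal(bm$beta2, 0.0069)
  expect_error(get_coefficients(set, "kidneys", "t9"),
               class = "prrtdose_lookup_error")
})

test_that("coefficient files with missing or unknown fields fail by name", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"kidneys": {"t1": {"alpha0": 12.0, "alpha1": 0.9}}}', f)
  expect_error(read_coefficients(f), "kidneys",
               class = "prrtdose_parse_error")
  writeLines('{"kidneys": {"t7": {"alpha0": 1, "alpha1": 1, "alpha2": 1}}}', f)
  expect_error(read_coefficients(f), "t_f_label",
               class = "prrtdose_parse_error")
})

test_that("coefficient serialization changes no prediction at all", {
  rows <- exact_solid_rows(n = 20, lambda = 0.0129, seed = 3)
  rows$ln_dose <- rows$ln_dose + stats::rnorm(20, 0, 0.1)  # irrational coefs
  co <- train_mlr_solid(rows, "kidneys", "t1t2t3")
  f <- withr::local_tempfile(fileext = ".json")
  write_coefficients(structure(list(kidneys = list(t1t2t3 = co)),
                               class = "mlr_coefficient_set"), f)
  co2 <- get_coefficients(read_coefficients(f), "kidneys", "t1t2t3")
  conc <- c(0.001, 0.02, 0.3); ts <- c(24, 96, 168)
  expect_identical(predict_dose_solid(co, conc, ts),
                   predict_dose_solid(co2, conc, ts))
})

test_that("dose-factor tables round-trip and refuse missing lookups", {
  dft <- toy_dft()
  f <- withr::local_tempfile(fileext = ".json")
  write_dose_factors(dft, f)
  back <- read_dose_factors(f, "adult_male")
  expect_equal(back$entries, dft$entries)
  expect_equal(back$theta_bm_bm, dft$theta_bm_bm)
  expect_equal(df_lookup(back, "kidneys", "liver"), 0.1)
  expect_error(df_lookup(back, "kidneys", "brain"),
               class = "prrtdose_lookup_error")
  expect_error(dose_factor_table("adult_male",
                                 data.frame(source = "a", target = "b",
                                            df_mGy_per_MBq_s = -1),
                                 1, 1))
})
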