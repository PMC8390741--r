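test_that("mono-exponential fitting recovers exact and noisy kinetics", {
  # two points determine the curve exactly
  f <- fit_monoexponential(c(24, 168), 100 * exp(-0.01 * c(24, 168)))
  expect_equal(f$amplitude_at_t0, 100)
  expect_equal(f$lambda_eff_per_h, 0.01)

  # noiseless 3-point data: machine-precision recovery
  tt <- c(19, 97, 163)
  f3 <- fit_monoexponential(tt, 50 * exp(-0.0129 * tt))
  expect_equal(f3$amplitude_at_t0, 50, tolerance = 1e-12)
  expect_equal(f3$lambda_eff_per_h, 0.0129, tolerance = 1e-12)

  # Monte-Carlo: 200 replicate fits with 5% lognormal noise, mean lambda
  # estimate within 2% of truth
  set.seed(101)
  sdl <- sqrt(log(1 + 0.05^2))
  lams <- replicate(200, {
    y <- 50 * exp(-0.0129 * tt) * stats::rlnorm(3, 0, sdl)
    fit_monoexponential(tt, y)$lambda_eff_per_h
  })
  expect_lt(abs(mean(lams) / 0.0129 - 1), 0.02)

  expect_error(fit_monoexponential(c(24), 5), "at least 2")
  expect_error(fit_monoexponential(c(24, 96), c(5, 0)), "strictly positive")
  err <- tryCatch(fit_monoexponential(c(24, 96), c(5, 6)), error = identity)
  expect_s3_class(err, "prrtdose_nondecaying_error")
  expect_s3_class(err$fit, "kinetic_fit")  # the rejected fit travels along

  # nonlinear refinement agrees with log-OLS on noiseless data
  fn <- fit_monoexponential(tt, 50 * exp(-0.0129 * tt), method = "nls")
  expect_equal(fn$lambda_eff_per_h, 0.0129, tolerance = 1e-8)
})

test_that("cumulated activity matches the analytic integral and quadrature", {
  f <- kinetic_fit("kidneys", 100, 0.01, "activity", 2L)
  expect_equal(cumulated_activity_multipoint(f), 10000)
  expect_equal(cumulated_activity_multipoint(
    kinetic_fit("kidneys", 0, 0.01, "activity", 2L)), 0)

  # quadrature oracle for the clinical magnitude case
  a0 <- 7.3e3; lam <- 0.0129
  q <- stats::integrate(function(t) a0 * exp(-lam * t), 0, Inf,
                        rel.tol = 1e-12)$value
  expect_equal(cumulated_activity_multipoint(
    kinetic_fit("x", a0, lam, "activity", 3L)), q, tolerance = 1e-9)
})

test_that("single-point cumulated activity is consistent with multipoint", {
  expect_equal(cumulated_activity_single_point(50, 24, 0.01),
               50 * exp(0.24) / 0.01)
  # algebraic identity: a point on the curve back-extrapolates to A0/lambda
  set.seed(7)
  for (i in 1:25) {
    a0 <- stats::runif(1, 10, 5000)
    lam <- stats::runif(1, 0.004, 0.05)
    ts <- stats::runif(1, 5, 200)
    expect_equal(cumulated_activity_single_point(a0 * exp(-lam * ts), ts, lam),
                 a0 / lam, tolerance = 1e-12)
    # quadrature oracle: forward tail from ts plus back-extrapolated [0, ts]
    ats <- stats::runif(1, 1, 100)
    tail_int <- stats::integrate(function(t) ats * exp(-lam * (t - ts)),
                                 ts, Inf, rel.tol = 1e-11)$value
    head_int <- stats::integrate(function(t) ats * exp(lam * (ts - t)),
                                 0, ts, rel.tol = 1e-11)$value
    expect_equal(cumulated_activity_single_point(ats, ts, lam),
                 tail_int + head_int, tolerance = 1e-8)
  }
  expect_error(cumulated_activity_single_point(5, 24, -0.01), "lambda")
})

test_that("MIRD organ dose sums self and cross terms against a hand oracle", {
  dft <- toy_dft()
  # one-term sum: cumulated activity of 1 MBq s, DF = 2 -> 2 mGy
  res <- data.frame(region = "kidneys", cumulated_activity_MBq_h = 1 / 3600)
  expect_equal(organ_dose_mird(res, "kidneys", dft), 2)

  # three sources: explicit hand-summed oracle, additive and order-invariant
  set.seed(21)
  a <- stats::runif(3, 100, 5000)  # MBq h
  res3 <- data.frame(region = c("kidneys", "liver", "spleen"),
                     cumulated_activity_MBq_h = a)
  hand <- a[1] * 3600 * 2 + a[2] * 3600 * 0.1 + a[3] * 3600 * 0.2
  expect_equal(organ_dose_mird(res3, "kidneys", dft), hand)
  expect_equal(organ_dose_mird(res3[c(3, 1, 2), ], "kidneys", dft), hand)
  expect_equal(organ_dose_mird(res3[1, ], "kidneys", dft) +
                 organ_dose_mird(res3[c(1, 2), ], "kidneys", dft) -
                 organ_dose_mird(res3[1, ], "kidneys", dft) +
                 a[3] * 3600 * 0.2,
               hand)

  # a listed source with no dose factor fails loudly
  res_bad <- rbind(res3, data.frame(region = "brain",
                                    cumulated_activity_MBq_h = 1))
  expect_error(organ_dose_mird(res_bad, "kidneys", dft),
               class = "prrtdose_lookup_error")
  expect_error(organ_dose_mird(res3, "brain", dft), "no residence")
})

test_that("bone-marrow dose evaluates blood self and remainder cross terms", {
  bfit <- kinetic_fit("blood", 0.03, 0.035, "concentration", 2L)
  rfit <- kinetic_fit("remainder", 4000, 0.011, "activity", 3L)

  # theta_rm = 0: blood self-term only
  dft0 <- toy_dft(theta_bm_bm = 150, theta_bm_rm = 0)
  expect_equal(bone_marrow_dose_standard(bfit, rfit, 60, dft0),
               0.03 / 0.035 * 150)
  # zero amplitudes -> 0
  z <- kinetic_fit("blood", 0, 0.035, "concentration", 2L)
  zr <- kinetic_fit("remainder", 0, 0.011, "activity", 2L)
  expect_equal(bone_marrow_dose_standard(z, zr, 60, toy_dft()), 0)

  # random inputs against term-by-term hand evaluation
  set.seed(5)
  for (i in 1:10) {
    a <- stats::runif(1, 0.001, 0.1); lb <- stats::runif(1, 0.01, 0.06)
    A <- stats::runif(1, 500, 6000); lr <- stats::runif(1, 0.005, 0.02)
    m <- stats::runif(1, 40, 80)
    dft <- toy_dft(theta_bm_bm = stats::runif(1, 50, 300),
                   theta_bm_rm = stats::runif(1, 0.001, 0.02))
    got <- bone_marrow_dose_standard(
      kinetic_fit("blood", a, lb, "concentration", 2L),
      kinetic_fit("remainder", A, lr, "activity", 2L), m, dft)
    expect_equal(got, a / lb * dft$theta_bm_bm +
                   A / (m * lr) * dft$theta_bm_rm)
  }
})

test_that("tumor self-dose uses the sphere table with interpolation rules", {
  fit <- kinetic_fit("tumor-1", 10, 0.01, "activity", 3L)
  # flat table: D = (A0/(m lambda)) * 3600 * Theta
  expect_equal(tumor_dose_self(fit, 0.02, flat_sphere(2e-5)),
               10 / (0.02 * 0.01) * 3600 * 2e-5)
  expect_equal(tumor_dose_self(kinetic_fit("t", 0, 0.01, "activity", 2L),
                               0.02, flat_sphere()), 0)
  # a mass exactly on a grid node uses the tabulated value
  st <- data.frame(mass_kg = c(0.01, 0.05, 0.2), theta = c(1e-5, 2e-5, 3e-5))
  expect_equal(tumor_dose_self(fit, 0.05, st),
               10 / (0.05 * 0.01) * 3600 * 2e-5)
  # interpolation between nodes matches stats::approx directly
  th <- stats::approx(st$mass_kg, st$theta, xout = 0.1)$y
  expect_equal(tumor_dose_self(fit, 0.1, st), 10 / (0.1 * 0.01) * 3600 * th)
  expect_error(tumor_dose_self(fit, 0.5, st), "extrapolation")
})

test_that("doses are homogeneous of degree 1 in injected activity", {
  spec <- cohort_spec_model_matched(n_patients = 2, seed = 3)
  p <- generate_patient(spec, 1)
  std <- standard_protocol_patient(p)
  st <- p$studies[[1]]
  scaled <- st
  scaled$measurements$count_rate_cps <- 3 * scaled$measurements$count_rate_cps
  scaled$blood$concentration_MBq_per_cc <-
    3 * scaled$blood$concentration_MBq_per_cc
  res_s <- standard_cycle_doses(scaled, default_dose_factors(p$phantom),
                                default_sphere_table())
  expect_equal(res_s$record$doses_mGy,
               3 * std$records[[1]]$doses_mGy, tolerance = 1e-12)
})

test_that("standard doses close on the generator ground truth", {
  spec <- cohort_spec_model_matched(n_patients = 3, seed = 13)
  for (i in 1:3) {
    p <- generate_patient(spec, i)
    std <- standard_protocol_patient(p)
    for (cy in seq_along(std$records)) {
      truth <- p$truth[[cy]]$doses_mGy
      est <- std$records[[cy]]$doses_mGy[names(truth)]
      expect_lt(max(abs(est / truth - 1)), 1e-9)
    }
  }
  # later cycles without a cycle-1 fit for a region fail loudly
  p <- generate_patient(spec, 1)
  if (length(p$studies) > 1) {
    res1 <- standard_cycle_doses(p$studies[[1]],
                                 default_dose_factors(p$phantom),
                                 default_sphere_table())
    bad_fits <- res1$fits; bad_fits$kidneys <- NULL
    expect_error(standard_cycle_doses(p$studies[[2]],
                                      default_dose_factors(p$phantom),
                                      default_sphere_table(),
                                      prior_fits = bad_fits),
                 "absent from cycle-1")
  }
})
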