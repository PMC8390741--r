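test_that("theta estimation recovers exact and degenerate designs correctly", {
  set.seed(9)
  bt <- stats::rlnorm(12, log(0.02), 0.4)
  rt <- stats::rlnorm(12, log(0.15), 0.4)
  d <- 1889 * bt + 315 * rt
  th <- estimate_theta_bm(bt, rt, d)
  expect_equal(unname(th), c(1889, 315), tolerance = 1e-10)

  # all-zero remainder terms: singular design
  expect_error(estimate_theta_bm(bt, rep(0, 12), d),
               class = "prrtdose_singular_error")
  expect_error(estimate_theta_bm(bt, 2 * bt, d),
               class = "prrtdose_singular_error")
  expect_error(estimate_theta_bm(bt[1], rt[1], d[1]), ">= 2")

  # negative unconstrained solution is clamped to the boundary
  th2 <- estimate_theta_bm(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3) * 10 -
                             0.001 * c(3, 2, 1))
  expect_true(all(th2 >= 0))
})

test_that("theta estimation under noise stays inside the frozen tolerance", {
  # tolerance 15%: > 3 SD of the replicate distribution at n = 40, 5% noise
  set.seed(40)
  nn <- function(n, m, cv) {
    sdl <- sqrt(log(1 + cv^2)); stats::rlnorm(n, log(m) - sdl^2 / 2, sdl)
  }
  for (r in 1:5) {
    bt <- nn(40, 0.02, 0.4); rt <- nn(40, 0.15, 0.4)
    d <- (1889 * bt + 315 * rt) * nn(40, 1, 0.05)
    th <- estimate_theta_bm(bt, rt, d)
    expect_lt(abs(th[["theta_bm_bm"]] / 1889 - 1), 0.15)
    expect_lt(abs(th[["theta_bm_rm"]] / 315 - 1), 0.15)
  }
})

test_that("solid-organ training is exact on model-consistent rows", {
  rows <- exact_solid_rows(n = 12, lambda = 0.0111, K = 5e4)
  co <- train_mlr_solid(rows, "kidneys", "t1t2t3")
  expect_equal(co$alpha1, 1, tolerance = 1e-10)
  expect_equal(co$alpha2, 0.0111, tolerance = 1e-10)
  expect_equal(co$r2_train, 1, tolerance = 1e-12)

  # multiplying all doses by e shifts only the intercept, by exactly 1
  rows_e <- rows; rows_e$ln_dose <- rows_e$ln_dose + 1
  co_e <- train_mlr_solid(rows_e, "kidneys", "t1t2t3")
  expect_equal(co_e$alpha0, co$alpha0 + 1, tolerance = 1e-10)
  expect_equal(co_e$alpha1, co$alpha1, tolerance = 1e-12)
  expect_equal(co_e$alpha2, co$alpha2, tolerance = 1e-12)

  expect_error(train_mlr_solid(rows[1:3, ], "kidneys", "t1t2t3"), ">= 4")
  rows_c <- rows; rows_c$ts_h <- 24
  rows_c$ln_conc <- 0.5
  expect_error(train_mlr_solid(rows_c, "kidneys", "t1"),
               class = "prrtdose_singular_error")
})

test_that("training matches an independent normal-equations oracle", {
  set.seed(17)
  rows <- exact_solid_rows(n = 30, lambda = 0.0129, seed = 17)
  rows$ln_dose <- rows$ln_dose + stats::rnorm(30, 0, 0.2)
  co <- train_mlr_solid(rows, "kidneys", "t1t2t3")
  # oracle: explicit normal equations, no lm
  X <- cbind(1, rows$ln_conc, rows$ts_h)
  beta <- solve(t(X) %*% X, t(X) %*% rows$ln_dose)
  expect_equal(c(co$alpha0, co$alpha1, co$alpha2), drop(beta),
               tolerance = 1e-8, ignore_attr = TRUE)

  # marrow regression through the same oracle
  bm <- train_mlr_bm(rows, 1889, 315, "t1t3")
  expect_equal(c(bm$beta0, bm$beta1, bm$beta2), drop(beta),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(bm$theta_bm_bm, 1889)
})

test_that("marrow training is exact when the composite model holds", {
  # ln D = -ln(lambda_BM) + 1 * ln(composite) + lambda_BM * ts
  lam <- 0.0069
  set.seed(23)
  comp <- exp(stats::runif(10, -5, -1))
  ts <- stats::runif(10, 20, 170)
  rows <- data.frame(ln_conc = log(comp), ts_h = ts,
                     ln_dose = log(comp) + lam * ts - log(lam))
  co <- train_mlr_bm(rows, 1889, 315, "t3")
  expect_equal(co$beta1, 1, tolerance = 1e-10)
  expect_equal(co$beta2, lam, tolerance = 1e-10)
  expect_equal(co$beta0, -log(lam), tolerance = 1e-8)

  rows$ln_conc <- -2
  expect_error(train_mlr_bm(rows, 1889, 315, "t3"),
               class = "prrtdose_singular_error")
})

test_that("solid prediction reproduces the published closed form", {
  set <- read_coefficients(system.file("extdata",
                                       "mlr_coefficients_published.json",
                                       package = "prrtdose"))
  k <- get_coefficients(set, "kidneys", "t1t2t3")
  # unit concentration at injection time reduces to e^alpha0
  expect_equal(predict_dose_solid(k, 1, 0), exp(11.86))
  # 1 MBq/cc at 163 h: frozen against a 50-digit evaluation of the closed form
  expect_equal(predict_dose_solid(k, 1 / 37, 163), 40135.631075128389,
               tolerance = 1e-12)
  expect_equal(predict_dose_solid(k, 1, 163, conc_unit = "MBq/cc"),
               predict_dose_solid(k, 1 / 37, 163))
  expect_error(predict_dose_solid(k, 0, 24), "strictly positive")
  expect_error(predict_dose_solid(k, 1, -5), ">= 0")

  # monotone in concentration (alpha1 > 0) and time (alpha2 > 0)
  conc <- seq(0.001, 0.1, length.out = 20)
  expect_true(all(diff(predict_dose_solid(k, conc, 96)) > 0))
  expect_true(all(diff(predict_dose_solid(k, 0.01, seq(24, 168, 12))) > 0))
})

test_that("matched coefficients make the regression identical to the MIRD form", {
  # alpha1 = 1, alpha2 = lambda, alpha0 = ln(37 * 3600 * V * DF / lambda)
  lam <- 0.0129; V <- 310; DF <- 7.581e-5
  co <- mlr_coefficients("kidneys", "t1t2t3",
                         alpha0 = log(37 * 3600 * V * DF / lam),
                         alpha1 = 1, alpha2 = lam)
  set.seed(31)
  for (i in 1:200) {
    a0 <- stats::runif(1, 10, 800)
    ts <- stats::runif(1, 5, 200)
    conc_mbq <- a0 * exp(-lam * ts) / V
    direct <- a0 / lam * 3600 * DF            # A0/lambda in MBq s times DF
    expect_equal(predict_dose_solid(co, conc_mbq, ts, conc_unit = "MBq/cc"),
                 direct, tolerance = 1e-12)
  }
})

test_that("marrow prediction reproduces its closed form and reductions", {
  set <- read_coefficients(system.file("extdata",
                                       "mlr_coefficients_published.json",
                                       package = "prrtdose"))
  bm <- get_coefficients(set, "bone_marrow", "t3")
  # composite = 1 at injection time reduces to e^beta0
  expect_equal(predict_dose_bm(bm, 1 / 1889, 0, 0), exp(5.03))
  expect_equal(predict_dose_bm(bm, 1 / 1889, 0, 0), 152.93301269561472,
               tolerance = 1e-12)
  # beta1 = 1 reproduces the single-decay-constant form exactly
  lam <- 0.011
  co1 <- mlr_coefficients("bone_marrow", "t3", beta0 = -log(lam), beta1 = 1,
                          beta2 = lam, theta_bm_bm = 200, theta_bm_rm = 8)
  set.seed(33)
  for (i in 1:100) {
    ab <- stats::runif(1, 1e-4, 0.05); cr <- stats::runif(1, 1e-4, 0.05)
    ts <- stats::runif(1, 5, 200)
    composite <- ab * 200 + cr * 8
    expect_equal(predict_dose_bm(co1, ab, cr, ts),
                 composite * exp(lam * ts) / lam, tolerance = 1e-12)
  }
  expect_error(predict_dose_bm(bm, 0, 0, 24), "strictly positive")
})

test_that("cohort training recovers the generating decay constant", {
  # pooled-time training on 40 noisy patients: alpha2 estimates lambda and
  # must fall inside the generator's between-patient 95% interval
  spec <- cohort_spec(n_patients = 40, seed = 77)
  cohort <- generate_cohort(spec, n_train = 39)
  train <- c(cohort$train, cohort$test)
  std <- lapply(train, standard_protocol_patient)
  std1 <- lapply(std, function(s) list(record = s$records[[1]],
                                       fits = s$fits_cycle1))
  set <- train_mlr_from_cohort(lapply(train, function(p) p$studies[[1]]),
                               std1, "t1t2t3")
  sdl <- sqrt(log(1 + spec$lambda_cv^2))
  for (reg in c("kidneys", "liver", "spleen")) {
    mu <- spec$regions$lambda_per_h[spec$regions$region == reg]
    lo <- stats::qlnorm(0.025, log(mu) - sdl^2 / 2, sdl)
    hi <- stats::qlnorm(0.975, log(mu) - sdl^2 / 2, sdl)
    a2 <- set[[reg]][[1]]$alpha2
    expect_gt(a2, lo)
    expect_lt(a2, hi)
  }
  # training r2 is high but not exact: the between-patient lambda spread
  # leaves irreducible residual in the pooled-time fit
  expect_gt(set$kidneys[[1]]$r2_train, 0.6)
  expect_lt(set$kidneys[[1]]$r2_train, 1)
})

test_that("train-then-predict is the identity on model-consistent cohorts", {
  spec <- cohort_spec_model_matched(n_patients = 10, seed = 5)
  cohort <- generate_cohort(spec, n_train = 6)
  std_train <- lapply(cohort$train, standard_protocol_patient)
  std1 <- lapply(std_train, function(s) list(record = s$records[[1]],
                                             fits = s$fits_cycle1))
  set <- train_mlr_from_cohort(lapply(cohort$train, function(p) p$studies[[1]]),
                               std1, "t1t2t3")
  expect_equal(set$kidneys[[1]]$alpha1, 1, tolerance = 1e-9)
  expect_equal(set$kidneys[[1]]$alpha2, 0.0129, tolerance = 1e-9)
  expect_equal(set$kidneys[[1]]$r2_train, 1, tolerance = 1e-12)
  # predictions on held-out patients equal the generating doses
  for (p in cohort$test) {
    std <- standard_protocol_patient(p)
    rec <- mlr_cycle_doses(p$studies[[1]], set, "t3",
                           fits_cycle1 = std$fits_cycle1)
    truth <- p$truth[[1]]$doses_mGy
    common <- intersect(names(rec$doses_mGy), names(truth))
    expect_lt(max(abs(rec$doses_mGy[common] / truth[common] - 1)), 1e-6)
  }
})
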