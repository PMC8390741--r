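# Synthetic patient-cohort generator with analytic ground truth. Emulates
# the clinical study population: mono-exponential organ/blood kinetics with
# patient-specific amplitudes and effective decay constants, multiplicative
# lognormal measurement noise, imaging nominally at 24/96/168 h after
# cycle 1 and at 24 h after later cycles, blood samples at the first and
# last imaging times of cycle 1 and at 24 h thereafter.

#' Packaged synthetic dose-factor table
#' @param phantom `"adult_male"` or `"adult_female"`
#' @return a [dose_factor_table()]
#' @export
default_dose_factors <- function(phantom = "adult_male") {
  read_dose_factors(system.file("extdata", "dose_factors_synthetic.json",
                                package = "prrtdose"), phantom)
}

#' Packaged synthetic tumor sphere-model table
#' @return data.frame `mass_kg`, `theta`
#' @export
default_sphere_table <- function() {
  read_sphere_table(system.file("extdata", "sphere_theta_synthetic.json",
                                package = "prrtdose"))
}

default_region_params <- function() {
  data.frame(
    region = c("kidneys", "liver", "spleen", "tumor-1", "remainder"),
    uptake_fraction = c(0.025, 0.045, 0.012, 0.012, 0.55),
    volume_cc = c(310, 1800, 180, 40, 60000),
    lambda_per_h = c(0.0129, 0.0098, 0.0095, 0.0082, 0.011))
}

#' Specification of a synthetic cohort
#'
#' Population defaults reflect the clinical study conditions: per-region
#' mean effective decay constants 0.0129 (kidneys), 0.0098 (liver), 0.0095
#' (spleen) and 0.0082 1/h (tumors) with 20% between-patient lognormal CV;
#' injected activity 7300 +/- 500 MBq per cycle; imaging at 24 +/- 2,
#' 96 +/- 8 and 168 +/- 12 h (jitter per patient); 5% multiplicative
#' lognormal measurement noise, unbiased in log space; cycles per patient
#' drawn from the reported completion pattern (4/32 one cycle, 2/32 two,
#' 9/32 three, 17/32 four). Uptake-fraction and VOI-volume variability are
#' not reported clinically; 40% and 20% lognormal CVs are used so per-cycle
#' kidney doses span the clinically observed range.
#'
#' @param n_patients cohort size (default 72: 40 train + 32 test).
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @param regions data.frame with columns `region`, `uptake_fraction`,
#'   `volume_cc`, `lambda_per_h` (population means).
#' @param uptake_cv,volume_cv,lambda_cv between-patient lognormal CVs.
#' @param lambda_cycle_jitter_cv per-cycle lognormal jitter on the decay
#'   constant (default 0: the unchanged-effective-half-life assumption
#'   holds exactly; raise it to violate the assumption deliberately).
#' @param noise_cv multiplicative measurement-noise CV per measurement.
#' @param blood_fraction,blood_volume_cc,blood_lambda_per_h blood kinetics:
#'   initial blood activity fraction of injected activity, blood pool
#'   volume, clearance constant.
#' @param schedule_mean_h,schedule_sd_h nominal imaging times and their
#'   per-patient jitter SDs.
#' @param injected_mean_MBq,injected_sd_MBq injected activity distribution.
#' @param cycle_count_probs probability of 1, 2, 3, 4 completed cycles.
#' @param sensitivity_MBq_per_cps camera calibration factor.
#' @param density_g_per_cc tissue density for VOI mass.
#' @param phantom_male_prob probability a patient uses the adult-male
#'   phantom.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 72L, seed,
                        regions = default_region_params(),
                        uptake_cv = 0.40, volume_cv = 0.20, lambda_cv = 0.20,
                        lambda_cycle_jitter_cv = 0,
                        noise_cv = 0.05,
                        blood_fraction = 0.02, blood_volume_cc = 5000,
                        blood_lambda_per_h = 0.035,
                        schedule_mean_h = c(24, 96, 168),
                        schedule_sd_h = c(2, 8, 12),
                        injected_mean_MBq = 7300, injected_sd_MBq = 500,
                        cycle_count_probs = c(4, 2, 9, 17) / 32,
                        sensitivity_MBq_per_cps = 0.1,
                        density_g_per_cc = 1.0,
                        phantom_male_prob = 40 / 72) {
  if (missing(seed) || !is.finite(seed))
    stop_domain("cohort_spec requires an explicit integer seed")
  stopifnot(n_patients >= 1,
            all(regions$uptake_fraction > 0 & regions$uptake_fraction < 1),
            all(regions$volume_cc > 0), all(regions$lambda_per_h > 0),
            uptake_cv >= 0, volume_cv >= 0, lambda_cv >= 0, noise_cv >= 0,
            blood_fraction > 0, blood_fraction < 1,
            blood_lambda_per_h > 0,
            length(schedule_mean_h) == length(schedule_sd_h),
            all(schedule_mean_h > 0), all(schedule_sd_h >= 0),
            injected_mean_MBq > 0, injected_sd_MBq >= 0,
            abs(sum(cycle_count_probs) - 1) < 1e-9,
            sensitivity_MBq_per_cps > 0, density_g_per_cc > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Model-matched cohort specification
#'
#' A [cohort_spec()] in which the single-time-point log-log model family is
#' exact: zero measurement noise, zero between-patient spread on decay
#' constants and volumes, and one common decay constant for blood and the
#' remainder of the body (so the composite marrow model holds with a single
#' total decay constant). Uptake fractions still vary, so doses span a
#' realistic range. Used for closure and concordance properties.
#'
#' @param n_patients,seed,... passed to [cohort_spec()]
#' @param marrow_lambda_per_h common blood/remainder decay constant
#' @export
cohort_spec_model_matched <- function(n_patients = 72L, seed,
                                      marrow_lambda_per_h = 0.011, ...) {
  regions <- default_region_params()
  regions$lambda_per_h[regions$region == "remainder"] <- marrow_lambda_per_h
  # one phantom only: with mixed phantoms the dose-factor table (hence the
  # model intercept) differs between patients and the family is not exact
  cohort_spec(n_patients = n_patients, seed = seed, regions = regions,
              volume_cv = 0, lambda_cv = 0, noise_cv = 0,
              blood_lambda_per_h = marrow_lambda_per_h,
              phantom_male_prob = 1, ...)
}

# lognormal sampler: `cv = 0` degenerates to the mean; `log_unbiased`
# noise has meanlog 0 (mean of log ratios -> 0), population samplers keep
# the arithmetic mean at `mean`.
rlnorm_cv <- function(n, mean, cv, log_unbiased = FALSE) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- if (log_unbiased) log(mean) else log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

patient_seed <- function(seed, index) {
  (as.integer(seed) + 747563L * as.integer(index)) %% 2147483647L
}

#' Generate one synthetic patient
#'
#' Samples patient-level kinetics once (uptake fractions, volumes, decay
#' constants, imaging-time jitter, number of cycles), then builds one
#' [cycle_study()] per cycle: three imaging times and two blood samples for
#' cycle 1, one each for later cycles. Measurements are the true
#' exponentials times lognormal noise. The returned ground truth carries
#' the true amplitudes, decay constants and closed-form absorbed doses per
#' cycle (organ/tumor self-dose and blood-plus-remainder marrow dose), so
#' every downstream module can be checked against an analytic answer.
#'
#' Randomness is drawn from a substream derived deterministically from
#' `(spec$seed, index)`; the same pair always yields a bit-identical
#' patient.
#'
#' @param spec a [cohort_spec()]
#' @param index 1-based patient index
#' @param dft,sphere_table dose tables used for ground-truth doses
#'   (defaults: the packaged synthetic tables for the sampled phantom)
#' @return list with `patient_id`, `phantom`, `studies` (list of
#'   [cycle_study()]), and `truth` (per-cycle amplitudes, decay constants
#'   and `doses_mGy`)
#' @export
generate_patient <- function(spec, index, dft = NULL, sphere_table = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(patient_seed(spec$seed, index))
  pid <- sprintf("P%03d", index)
  phantom <- if (stats::runif(1) < spec$phantom_male_prob) "adult_male"
  else "adult_female"
  if (is.null(dft)) dft <- default_dose_factors(phantom)
  if (is.null(sphere_table)) sphere_table <- default_sphere_table()

  rp <- spec$regions
  nr <- nrow(rp)
  uptake <- rlnorm_cv(nr, rp$uptake_fraction, spec$uptake_cv)
  volume <- rlnorm_cv(nr, rp$volume_cc, spec$volume_cv)
  lambda <- rlnorm_cv(nr, rp$lambda_per_h, spec$lambda_cv)
  blood_lambda <- rlnorm_cv(1, spec$blood_lambda_per_h, spec$lambda_cv)
  blood_frac <- rlnorm_cv(1, spec$blood_fraction, spec$uptake_cv)
  times <- pmax(1, stats::rnorm(length(spec$schedule_mean_h),
                                spec$schedule_mean_h, spec$schedule_sd_h))
  times <- sort(times)
  n_cycles <- sample(seq_along(spec$cycle_count_probs), 1,
                     prob = spec$cycle_count_probs)

  S <- spec$sensitivity_MBq_per_cps
  rho <- spec$density_g_per_cc
  studies <- vector("list", n_cycles)
  truth <- vector("list", n_cycles)
  for (cy in seq_len(n_cycles)) {
    inj <- max(1, stats::rnorm(1, spec$injected_mean_MBq, spec$injected_sd_MBq))
    lam_cy <- lambda * if (spec$lambda_cycle_jitter_cv > 0)
      rlnorm_cv(nr, 1, spec$lambda_cycle_jitter_cv, log_unbiased = TRUE)
    else 1
    blam_cy <- blood_lambda * if (spec$lambda_cycle_jitter_cv > 0)
      rlnorm_cv(1, 1, spec$lambda_cycle_jitter_cv, log_unbiased = TRUE)
    else 1
    A0 <- uptake * inj
    a0_blood <- blood_frac * inj / spec$blood_volume_cc
    tt <- if (cy == 1L) times else times[1]
    meas <- list()
    for (j in seq_len(nr)) {
      true_act <- A0[j] * exp(-lam_cy[j] * tt)
      noise <- rlnorm_cv(length(tt), 1, spec$noise_cv, log_unbiased = TRUE)
      meas[[j]] <- data.frame(
        region = rp$region[j], time_h = tt,
        cps = true_act * noise / S,
        volume_cc = volume[j], sensitivity = S)
    }
    meas <- do.call(rbind, meas)
    names(meas) <- c("region", "time_h", "count_rate_cps", "volume_cc",
                     "sensitivity_MBq_per_cps")
    bt <- if (cy == 1L) times[c(1, length(times))] else times[1]
    bnoise <- rlnorm_cv(length(bt), 1, spec$noise_cv, log_unbiased = TRUE)
    blood <- data.frame(time_h = bt,
                        concentration_MBq_per_cc =
                          a0_blood * exp(-blam_cy * bt) * bnoise)
    studies[[cy]] <- cycle_study(pid, cy, inj, phantom, meas, blood)

    # closed-form true doses on the noiseless kinetics
    doses <- c()
    for (j in seq_len(nr)) {
      reg <- rp$region[j]
      if (reg == "remainder") next
      a_tilde_s <- A0[j] / lam_cy[j] * SECONDS_PER_HOUR
      mass <- volume[j] * rho / 1000
      doses[reg] <- if (is_tumor_region(reg))
        a_tilde_s / mass * sphere_theta(sphere_table, mass)
      else a_tilde_s * df_lookup(dft, reg, reg)
    }
    jrm <- which(rp$region == "remainder")
    m_rm <- volume[jrm] * rho / 1000
    doses["bone_marrow"] <- (a0_blood / blam_cy) * dft$theta_bm_bm +
      A0[jrm] / (m_rm * lam_cy[jrm]) * dft$theta_bm_rm
    truth[[cy]] <- list(injected_activity_MBq = inj,
                        A0_MBq = stats::setNames(A0, rp$region),
                        lambda_per_h = stats::setNames(lam_cy, rp$region),
                        blood_a0_MBq_per_cc = a0_blood,
                        blood_lambda_per_h = blam_cy,
                        volume_cc = stats::setNames(volume, rp$region),
                        doses_mGy = doses)
  }
  list(patient_id = pid, phantom = phantom, studies = studies, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a cohort split into training and test bundles
#'
#' The first `n_train` patients form the training set (their cycle-1
#' studies carry the full multi-time-point protocol), the rest the test
#' set, mirroring the 40/32 clinical design at the default sizes.
#'
#' @param spec a [cohort_spec()]
#' @param n_train number of training patients (default 40, capped at
#'   `n_patients - 1`)
#' @param sphere_table tumor sphere table for ground truth
#' @return list with `train` and `test`, each a list of patients as
#'   returned by [generate_patient()], plus the `spec`
#' @export
generate_cohort <- function(spec, n_train = 40L,
                            sphere_table = default_sphere_table()) {
  if (spec$n_patients < 2)
    stop_domain("a train/test split needs at least 2 patients")
  n_train <- min(as.integer(n_train), spec$n_patients - 1L)
  patients <- lapply(seq_len(spec$n_patients), function(i)
    generate_patient(spec, i, dft = NULL, sphere_table = sphere_table))
  list(train = patients[seq_len(n_train)],
       test = patients[(n_train + 1L):spec$n_patients],
       spec = spec)
}

#' Write a cohort's studies as CSV fixture bundles
#' @param cohort as returned by [generate_cohort()]
#' @param dir output directory
#' @return character vector of metadata-file paths, invisibly
#' @export
write_cohort_fixtures <- function(cohort, dir) {
  paths <- character(0)
  for (p in c(cohort$train, cohort$test))
    for (st in p$studies)
      paths <- c(paths, write_cycle_study(st, dir))
  invisible(paths)
}
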