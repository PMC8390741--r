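# Standard-protocol dosimetry: mono-exponential time-activity fitting,
# cumulated activity, MIRD organ/tumor dose and blood-based bone-marrow
# dose. All times h, activities MBq, volumes cc, doses mGy; dose factors
# mGy/(MBq s), hence the 3600 s/h factor where cumulated activity meets a
# dose factor.

SECONDS_PER_HOUR <- 3600

#' Fit a mono-exponential time-activity curve
#'
#' Fits \eqn{A(t) = A_0 e^{-\lambda t}} by unweighted ordinary least squares
#' on \eqn{\ln A} versus \eqn{t} (the default), or by nonlinear least squares
#' on the original scale (`method = "nls"`, seeded from the log-linear fit).
#' With exactly two points both methods interpolate exactly.
#'
#' @param times_h sample times, strictly increasing, > 0.
#' @param values activities (MBq) or concentrations (MBq/cc); strictly
#'   positive — zeros cannot be log-transformed and are rejected.
#' @param region_id label stored in the fit.
#' @param fit_kind `"activity"` or `"concentration"`.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return a [kinetic_fit()]. A fitted \eqn{\lambda \le 0} raises a
#'   `prrtdose_nondecaying_error` carrying the offending fit in its `fit`
#'   field.
#' @export
fit_monoexponential <- function(times_h, values, region_id = "region",
                                fit_kind = c("activity", "concentration"),
                                method = c("loglinear", "nls")) {
  fit_kind <- match.arg(fit_kind)
  method <- match.arg(method)
  if (length(times_h) != length(values))
    stop_domain("times and values must have equal length")
  if (length(values) < 2)
    stop_domain("mono-exponential fit needs at least 2 samples, got %d",
                length(values))
  if (any(!is.finite(times_h)) || any(diff(times_h) <= 0))
    stop_domain("sample times must be finite and strictly increasing")
  if (any(!is.finite(values) | values <= 0))
    stop_domain("all sampled values must be strictly positive for region %s",
                region_id)
  co <- stats::lm.fit(cbind(1, times_h), log(values))$coefficients
  a0 <- exp(co[[1]])
  lam <- -co[[2]]
  if (method == "nls" && length(values) > 2) {
    df <- data.frame(t = times_h, y = values)
    # zero-residual data makes nls report non-convergence; the log-OLS
    # start is already exact there, so keep it on failure
    nfit <- tryCatch(
      stats::nls(y ~ A0 * exp(-lam * t), data = df,
                 start = list(A0 = a0, lam = max(lam, 1e-6))),
      error = function(e) NULL)
    if (!is.null(nfit)) {
      p <- stats::coef(nfit)
      a0 <- p[["A0"]]
      lam <- p[["lam"]]
    }
  }
  kinetic_fit(region_id = region_id, amplitude_at_t0 = a0,
              lambda_eff_per_h = lam, fit_kind = fit_kind,
              n_points = length(values))
}

#' Cumulated activity from a multi-point fit
#'
#' For mono-exponential kinetics the time integral of activity from
#' injection to infinity is \eqn{\tilde A = A_0 / \lambda}.
#'
#' @param fit a [kinetic_fit()]
#' @return cumulated activity in MBq h (or MBq h/cc for concentration fits)
#' @export
cumulated_activity_multipoint <- function(fit) {
  if (fit$lambda_eff_per_h <= 0)
    stop_domain("non-decaying kinetics: lambda must be > 0")
  fit$amplitude_at_t0 / fit$lambda_eff_per_h
}

#' Cumulated activity from a single time point and a decay-constant prior
#'
#' Back-extrapolates the single measurement with an effective decay constant
#' taken from the same patient's first-cycle fit (the protocol's
#' unchanged-effective-half-life assumption):
#' \eqn{\tilde A = A(t_s) e^{\lambda t_s} / \lambda}. The integral runs from
#' injection (t = 0) to infinity on the same exponential.
#'
#' @param activity_at_ts measured activity at `ts_h` (MBq).
#' @param ts_h measurement time, h (> 0).
#' @param lambda_prior_per_h effective decay constant, 1/h (> 0).
#' @return cumulated activity, MBq h.
#' @export
cumulated_activity_single_point <- function(activity_at_ts, ts_h,
                                            lambda_prior_per_h) {
  if (!is.finite(lambda_prior_per_h) || lambda_prior_per_h <= 0)
    stop_domain("non-decaying kinetics: lambda must be > 0")
  if (!is.finite(ts_h) || ts_h <= 0)
    stop_domain("ts_h must be > 0")
  if (!is.finite(activity_at_ts) || activity_at_ts < 0)
    stop_domain("activity must be >= 0")
  activity_at_ts * exp(lambda_prior_per_h * ts_h) / lambda_prior_per_h
}

#' MIRD absorbed dose to a target organ
#'
#' \deqn{D(r_k) = \tilde A_k DF(r_k \leftarrow r_k) +
#'   \sum_{s \ne k} \tilde A_s DF(r_k \leftarrow r_s)}
#' Cumulated activities are given in MBq h and converted to MBq s against
#' dose factors in mGy/(MBq s). Every region listed in `residences` must
#' resolve to a dose factor — a missing pair is an error, never a silent 0.
#'
#' @param residences data.frame with columns `region`,
#'   `cumulated_activity_MBq_h` and (unused here but carried for provenance)
#'   optionally `mass_kg`.
#' @param target region label; must appear in `residences`.
#' @param dft a [dose_factor_table()].
#' @return absorbed dose in mGy.
#' @export
organ_dose_mird <- function(residences, target, dft) {
  if (!"region" %in% names(residences) ||
      !"cumulated_activity_MBq_h" %in% names(residences))
    stop_domain("residences needs columns region, cumulated_activity_MBq_h")
  if (any(!is.finite(residences$cumulated_activity_MBq_h) |
          residences$cumulated_activity_MBq_h < 0))
    stop_domain("cumulated activities must be finite and >= 0")
  if (!target %in% residences$region)
    stop_domain("target %s has no residence entry", target)
  dose <- 0
  for (i in seq_len(nrow(residences))) {
    src <- residences$region[i]
    a_tilde_s <- residences$cumulated_activity_MBq_h[i] * SECONDS_PER_HOUR
    dose <- dose + a_tilde_s * df_lookup(dft, target, src)
  }
  dose
}

#' Blood-based bone-marrow absorbed dose (standard protocol)
#'
#' Marrow dose is modeled as blood self-dose plus remainder-of-body
#' cross-dose:
#' \deqn{D(BM) = \frac{a_{blood}(0)}{\lambda_{blood}} \Theta_{BM,BM} +
#'   \frac{A_{RM}(0)}{m_{RM} \lambda_{RM}} \Theta_{BM,RM}}
#' evaluated with the fitted amplitudes (equivalent to back-extrapolating
#' any single time point on the fitted exponential). The Theta coupling
#' constants come from the dose-factor table; any marrow-to-blood
#' concentration ratio is folded into `theta_bm_bm`.
#'
#' @param blood_fit [kinetic_fit()] of blood concentration (MBq/cc).
#' @param remainder_fit [kinetic_fit()] of remainder-of-body activity (MBq).
#' @param remainder_mass_kg mass of the remainder of the body, kg.
#' @param dft a [dose_factor_table()] carrying `theta_bm_bm`, `theta_bm_rm`.
#' @return absorbed dose in mGy.
#' @export
bone_marrow_dose_standard <- function(blood_fit, remainder_fit,
                                      remainder_mass_kg, dft) {
  if (blood_fit$lambda_eff_per_h <= 0 || remainder_fit$lambda_eff_per_h <= 0)
    stop_domain("non-decaying kinetics: lambda must be > 0")
  if (!is.finite(remainder_mass_kg) || remainder_mass_kg <= 0)
    stop_domain("remainder mass must be > 0")
  if (is.null(dft$theta_bm_bm) || is.null(dft$theta_bm_rm))
    stop_domain("dose-factor table lacks marrow Theta constants",
                class = "prrtdose_lookup_error")
  blood_term <- blood_fit$amplitude_at_t0 / blood_fit$lambda_eff_per_h
  rm_term <- remainder_fit$amplitude_at_t0 /
    (remainder_mass_kg * remainder_fit$lambda_eff_per_h)
  blood_term * dft$theta_bm_bm + rm_term * dft$theta_bm_rm
}

#' Interpolate the sphere-model coupling constant at a given mass
#'
#' Piecewise-linear interpolation in mass on the supplied table;
#' extrapolation outside the tabulated mass range is an error.
#'
#' @param sphere_table data.frame with columns `mass_kg`, `theta` (sorted or
#'   not); see [read_sphere_table()].
#' @param mass_kg query mass.
#' @return Theta(m) in kg mGy/(MBq s).
#' @export
sphere_theta <- function(sphere_table, mass_kg) {
  st <- sphere_table[order(sphere_table$mass_kg), , drop = FALSE]
  if (!is.finite(mass_kg) || mass_kg <= 0)
    stop_domain("mass must be > 0")
  if (mass_kg < min(st$mass_kg) || mass_kg > max(st$mass_kg))
    stop_domain("mass %.4g kg outside sphere table range [%.4g, %.4g]; extrapolation refused",
                mass_kg, min(st$mass_kg), max(st$mass_kg))
  stats::approx(st$mass_kg, st$theta, xout = mass_kg, method = "linear")$y
}

#' Tumor absorbed dose from self-dose only
#'
#' Tumor dose is essentially self-dose (cross-dose negligible):
#' \deqn{D = \frac{A_0}{m \lambda} \Theta(m)} with \eqn{\Theta(m)} taken
#' from a sphere-model table interpolated at the tumor mass.
#'
#' @param fit tumor activity [kinetic_fit()].
#' @param mass_kg tumor mass, kg (VOI volume x density).
#' @param sphere_table as for [sphere_theta()].
#' @return absorbed dose in mGy.
#' @export
tumor_dose_self <- function(fit, mass_kg, sphere_table) {
  if (!is.finite(mass_kg) || mass_kg <= 0) stop_domain("mass must be > 0")
  theta <- sphere_theta(sphere_table, mass_kg)
  a_tilde_s <- cumulated_activity_multipoint(fit) * SECONDS_PER_HOUR
  a_tilde_s / mass_kg * theta
}

is_tumor_region <- function(region) {
  !(region %in% RESERVED_REGIONS)
}

#' Standard-protocol absorbed doses for one therapy cycle
#'
#' Runs the full standard workflow on one [cycle_study()]: for cycle 1
#' (multi-time-point), mono-exponential fits per region and for blood; for
#' later cycles, single-point back-extrapolation with the same patient's
#' cycle-1 decay constants (`prior_fits`), per the unchanged-effective-
#' half-life assumption — a region absent from the priors fails loudly.
#' Solid organs and tumors receive self-dose (cross-dose negligible at
#' therapy geometry); bone marrow receives blood self-dose plus remainder
#' cross-dose when blood samples are present.
#'
#' @param study a [cycle_study()].
#' @param dft a [dose_factor_table()] matching the study phantom.
#' @param sphere_table tumor sphere-model table, see [sphere_theta()].
#' @param prior_fits named list of cycle-1 [kinetic_fit()]s (including
#'   `blood`), required for `cycle_index > 1`.
#' @param density_g_per_cc tissue density converting VOI volume to mass
#'   (default 1.0).
#' @return list with `record` (a [cycle_dose_record()]) and `fits` (named
#'   list of kinetic fits, including `blood` when fitted).
#' @export
standard_cycle_doses <- function(study, dft, sphere_table,
                                 prior_fits = NULL, density_g_per_cc = 1.0) {
  m <- study$measurements
  regions <- unique(m$region)
  multipoint <- study$cycle_index == 1L
  if (!multipoint && is.null(prior_fits))
    stop_domain("cycle %d needs cycle-1 prior fits", study$cycle_index)
  fits <- list()
  doses <- c()
  for (reg in setdiff(regions, "blood")) {
    rows <- m[m$region == reg, , drop = FALSE]
    act <- voi_activity_MBq(rows)
    mass_kg <- rows$volume_cc[1] * density_g_per_cc / 1000
    if (multipoint) {
      fit <- fit_monoexponential(rows$time_h, act, region_id = reg)
    } else {
      prior <- prior_fits[[reg]]
      if (is.null(prior))
        stop_domain("region %s absent from cycle-1 fits; cannot borrow a population decay constant",
                    reg)
      a_tilde <- cumulated_activity_single_point(act[1], rows$time_h[1],
                                                 prior$lambda_eff_per_h)
      # equivalent amplitude at t=0 on the prior exponential
      fit <- kinetic_fit(reg, a_tilde * prior$lambda_eff_per_h,
                         prior$lambda_eff_per_h, "activity", 1L)
    }
    fits[[reg]] <- fit
    if (reg == "remainder") next  # remainder feeds marrow, not its own record
    if (is_tumor_region(reg)) {
      doses[reg] <- tumor_dose_self(fit, mass_kg, sphere_table)
    } else {
      res <- data.frame(region = reg,
                        cumulated_activity_MBq_h =
                          cumulated_activity_multipoint(fit))
      doses[reg] <- organ_dose_mird(res, reg, dft)
    }
  }
  if (!is.null(study$blood) && "remainder" %in% names(fits)) {
    b <- study$blood
    if (multipoint) {
      bfit <- fit_monoexponential(b$time_h, b$concentration_MBq_per_cc,
                                  region_id = "blood",
                                  fit_kind = "concentration")
    } else {
      prior <- prior_fits[["blood"]]
      if (is.null(prior))
        stop_domain("blood absent from cycle-1 fits")
      lam <- prior$lambda_eff_per_h
      a0 <- b$concentration_MBq_per_cc[1] * exp(lam * b$time_h[1])
      bfit <- kinetic_fit("blood", a0, lam, "concentration", 1L)
    }
    fits[["blood"]] <- bfit
    rm_rows <- m[m$region == "remainder", , drop = FALSE]
    rm_mass <- rm_rows$volume_cc[1] * density_g_per_cc / 1000
    doses["bone_marrow"] <- bone_marrow_dose_standard(
      bfit, fits[["remainder"]], rm_mass, dft)
  }
  protocol <- if (multipoint) "standard_multipoint" else "standard_single_point"
  list(record = cycle_dose_record(study$patient_id, study$cycle_index,
                                  doses, protocol),
       fits = fits)
}
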