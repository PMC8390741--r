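#' prrtdose: internal dosimetry for Lu-177 peptide receptor radionuclide therapy
#'
#' Tools for absorbed-dose calculation after [177Lu]-DOTA-TATE therapy:
#' the standard multi-time-point MIRD protocol, a trained log-log multiple
#' linear regression (MLR) model that predicts organ, tumor and bone-marrow
#' dose from a single SPECT/CT study, cumulative-dose treatment management,
#' a synthetic cohort generator with analytic ground truth, and agreement
#' statistics.
#'
#' Canonical internal units are MBq (activity), cc (volume), h (time) and
#' mGy (dose). Dose factors are stored in mGy/(MBq s). The MLR model is
#' trained and evaluated with concentrations in mCi/cc; the MBq -> mCi
#' conversion (division by 37) happens exactly once, at the MLR boundary.
#'
#' @name prrtdose-package
#' @keywords internal
"_PACKAGE"

# Reserved region vocabulary. Tumor labels are free-form (e.g. "tumor-1").
RESERVED_REGIONS <- c("kidneys", "liver", "spleen", "remainder", "blood",
                      "bone_marrow")

#' Conversion constant: 1 mCi = 37 MBq
#' @noRd
MBQ_PER_MCI <- 37

stop_parse <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c("prrtdose_parse_error", "prrtdose_error")))
}

stop_domain <- function(fmt, ..., class = "prrtdose_domain_error", extra = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- errorCondition(msg, class = c(class, "prrtdose_error"))
  if (!is.null(extra)) {
    for (nm in names(extra)) cond[[nm]] <- extra[[nm]]
  }
  stop(cond)
}

#' Validate a table of VOI measurements
#'
#' A VOI (volume-of-interest) measurement is one SPECT observation of one
#' region at one time post-injection: the count rate in the VOI, the VOI
#' volume and the camera sensitivity \eqn{S} in MBq/cps. The measured
#' activity is \eqn{A = S \cdot C} and the activity concentration
#' \eqn{A / V} in MBq/cc.
#'
#' @param df data.frame with columns `region`, `time_h`, `count_rate_cps`,
#'   `volume_cc`, `sensitivity_MBq_per_cps`.
#' @return the validated data.frame (invisibly the same columns, ordered by
#'   region then time).
#' @export
voi_measurements <- function(df) {
  req <- c("region", "time_h", "count_rate_cps", "volume_cc",
           "sensitivity_MBq_per_cps")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_parse("measurement table missing column(s): %s",
               paste(miss, collapse = ", "))
  df <- df[req]
  df$region <- as.character(df$region)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!is.finite(r$time_h) || r$time_h <= 0)
      stop_parse("row %d (region %s): time_h must be > 0, got %s",
                 i, r$region, format(r$time_h))
    if (!is.finite(r$count_rate_cps) || r$count_rate_cps < 0)
      stop_parse("row %d (region %s): count_rate_cps must be >= 0", i, r$region)
    if (!is.finite(r$volume_cc) || r$volume_cc <= 0)
      stop_parse("row %d (region %s): volume_cc must be > 0", i, r$region)
    if (!is.finite(r$sensitivity_MBq_per_cps) || r$sensitivity_MBq_per_cps <= 0)
      stop_parse("row %d (region %s): sensitivity_MBq_per_cps must be > 0",
                 i, r$region)
  }
  key <- paste(df$region, df$time_h)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop_parse("row %d: duplicate (region, time) pair (%s, %s h)",
               d, df$region[d], format(df$time_h[d]))
  }
  df <- df[order(df$region, df$time_h), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Measured activity (MBq) of VOI measurement rows
#' @param m data.frame as validated by [voi_measurements()]
#' @return numeric vector, `sensitivity * count_rate` per row
#' @export
voi_activity_MBq <- function(m) m$sensitivity_MBq_per_cps * m$count_rate_cps

#' Measured activity concentration (MBq/cc) of VOI measurement rows
#' @inheritParams voi_activity_MBq
#' @export
voi_concentration_MBq_per_cc <- function(m) voi_activity_MBq(m) / m$volume_cc

#' Validate a table of blood samples
#'
#' @param df data.frame with columns `time_h`, `concentration_MBq_per_cc`.
#' @return validated data.frame ordered by time.
#' @export
blood_samples <- function(df) {
  req <- c("time_h", "concentration_MBq_per_cc")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_parse("blood table missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[req]
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$time_h[i]) || df$time_h[i] <= 0)
      stop_parse("blood row %d: time_h must be > 0", i)
    if (!is.finite(df$concentration_MBq_per_cc[i]) ||
        df$concentration_MBq_per_cc[i] < 0)
      stop_parse("blood row %d: concentration must be >= 0", i)
  }
  if (anyDuplicated(df$time_h))
    stop_parse("blood table has duplicate sample times")
  df <- df[order(df$time_h), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' One therapy cycle of one patient
#'
#' Bundles the injected activity, the per-region VOI measurements and the
#' blood samples of a single PRRT cycle. The standard protocol images three
#' times after cycle 1 (nominally 24, 96 and 168 h post-injection) and once
#' after later cycles, so cycle 1 must carry at least two time points per
#' region and later cycles at least one.
#'
#' @param patient_id character scalar.
#' @param cycle_index 1-based cycle number.
#' @param injected_activity_MBq administered activity, MBq.
#' @param phantom `"adult_male"` or `"adult_female"`; selects the dose-factor
#'   table.
#' @param measurements data.frame accepted by [voi_measurements()].
#' @param blood data.frame accepted by [blood_samples()], or NULL.
#' @return object of class `cycle_study`.
#' @export
cycle_study <- function(patient_id, cycle_index, injected_activity_MBq,
                        phantom = c("adult_male", "adult_female"),
                        measurements, blood = NULL) {
  phantom <- match.arg(phantom)
  cycle_index <- as.integer(cycle_index)
  if (is.na(cycle_index) || cycle_index < 1L)
    stop_domain("cycle_index must be a positive integer")
  if (!is.finite(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop_domain("injected_activity_MBq must be > 0")
  measurements <- voi_measurements(measurements)
  if (!is.null(blood)) blood <- blood_samples(blood)
  min_pts <- if (cycle_index == 1L) 2L else 1L
  cnt <- table(measurements$region)
  short <- names(cnt)[cnt < min_pts]
  if (length(short) > 0)
    stop_domain("cycle %d requires >= %d time point(s) per region; region(s) %s have fewer",
                cycle_index, min_pts, paste(short, collapse = ", "))
  structure(
    list(patient_id = as.character(patient_id),
         cycle_index = cycle_index,
         injected_activity_MBq = injected_activity_MBq,
         phantom = phantom,
         measurements = measurements,
         blood = blood),
    class = "cycle_study")
}

#' @export
print.cycle_study <- function(x, ...) {
  cat(sprintf("<cycle_study> patient %s, cycle %d, %.0f MBq injected (%s)\n",
              x$patient_id, x$cycle_index, x$injected_activity_MBq, x$phantom))
  cat(sprintf("  regions: %s\n",
              paste(unique(x$measurements$region), collapse = ", ")))
  cat(sprintf("  imaging times (h): %s\n",
              paste(sort(unique(round(x$measurements$time_h, 1))), collapse = ", ")))
  if (!is.null(x$blood))
    cat(sprintf("  blood samples: %d\n", nrow(x$blood)))
  invisible(x)
}

#' Fitted mono-exponential kinetics for one region
#'
#' Represents \eqn{A(t) = A_0 e^{-\lambda t}} (or the concentration
#' analogue). Non-decaying fits (\eqn{\lambda \le 0}) are rejected: the
#' time-integral to infinity would diverge.
#'
#' @param region_id region label.
#' @param amplitude_at_t0 value at injection time: MBq for `fit_kind =
#'   "activity"`, MBq/cc for `"concentration"`.
#' @param lambda_eff_per_h effective decay constant, 1/h; must be > 0.
#' @param fit_kind `"activity"` or `"concentration"`.
#' @param n_points number of samples behind the fit.
#' @return object of class `kinetic_fit`.
#' @export
kinetic_fit <- function(region_id, amplitude_at_t0, lambda_eff_per_h,
                        fit_kind = c("activity", "concentration"),
                        n_points = NA_integer_) {
  fit_kind <- match.arg(fit_kind)
  if (!is.finite(amplitude_at_t0) || amplitude_at_t0 < 0)
    stop_domain("amplitude_at_t0 must be finite and >= 0")
  fit <- structure(
    list(region_id = as.character(region_id),
         amplitude_at_t0 = amplitude_at_t0,
         lambda_eff_per_h = lambda_eff_per_h,
         fit_kind = fit_kind,
         n_points = as.integer(n_points)),
    class = "kinetic_fit")
  if (!is.finite(lambda_eff_per_h) || lambda_eff_per_h <= 0)
    stop_domain("non-decaying kinetics for region %s: fitted lambda = %s 1/h (must be > 0)",
                region_id, format(lambda_eff_per_h),
                class = "prrtdose_nondecaying_error", extra = list(fit = fit))
  fit
}

#' @export
print.kinetic_fit <- function(x, ...) {
  unit <- if (x$fit_kind == "activity") "MBq" else "MBq/cc"
  cat(sprintf("<kinetic_fit> %s: A0 = %.4g %s, lambda = %.4g 1/h (T1/2eff = %.1f h), n = %d\n",
              x$region_id, x$amplitude_at_t0, unit, x$lambda_eff_per_h,
              log(2) / x$lambda_eff_per_h, x$n_points))
  invisible(x)
}

#' Evaluate a kinetic fit at time t
#' @param fit a [kinetic_fit()]
#' @param time_h hours post-injection
#' @return activity (MBq) or concentration (MBq/cc) at `time_h`
#' @export
kinetic_value_at <- function(fit, time_h) {
  fit$amplitude_at_t0 * exp(-fit$lambda_eff_per_h * time_h)
}

#' Source-to-target dose-factor table
#'
#' Dose factors DF(target <- source) in mGy/(MBq s) for one phantom, plus the
#' two bone-marrow coupling constants: `theta_bm_bm` scales the blood
#' self-dose term (units mGy per MBq h/cc of integrated blood concentration)
#' and `theta_bm_rm` the remainder-of-body cross-dose term (mGy per MBq h/kg).
#' The equilibrium dose constants and absorbed fractions that compose a dose
#' factor are not carried individually; DF and Theta are opaque constants.
#'
#' @param phantom `"adult_male"` or `"adult_female"`.
#' @param entries data.frame with columns `source`, `target`, `df_mGy_per_MBq_s`.
#' @param theta_bm_bm,theta_bm_rm marrow coupling constants (>= 0).
#' @return object of class `dose_factor_table`.
#' @export
dose_factor_table <- function(phantom = c("adult_male", "adult_female"),
                              entries, theta_bm_bm, theta_bm_rm) {
  phantom <- match.arg(phantom)
  req <- c("source", "target", "df_mGy_per_MBq_s")
  miss <- setdiff(req, names(entries))
  if (length(miss) > 0)
    stop_parse("dose-factor table missing column(s): %s",
               paste(miss, collapse = ", "))
  entries <- entries[req]
  entries$source <- as.character(entries$source)
  entries$target <- as.character(entries$target)
  if (any(!is.finite(entries$df_mGy_per_MBq_s) | entries$df_mGy_per_MBq_s < 0))
    stop_domain("all dose factors must be finite and >= 0")
  if (anyDuplicated(paste(entries$source, entries$target)))
    stop_parse("duplicate (source, target) pair in dose-factor table")
  if (!is.finite(theta_bm_bm) || theta_bm_bm < 0 ||
      !is.finite(theta_bm_rm) || theta_bm_rm < 0)
    stop_domain("theta_bm_bm and theta_bm_rm must be finite and >= 0")
  structure(
    list(phantom = phantom, entries = entries,
         theta_bm_bm = theta_bm_bm, theta_bm_rm = theta_bm_rm),
    class = "dose_factor_table")
}

#' Look up a dose factor
#'
#' Missing pairs fail explicitly rather than returning 0: a source the
#' caller listed must never contribute silently nothing.
#'
#' @param dft a [dose_factor_table()]
#' @param target,source region labels
#' @return DF(target <- source) in mGy/(MBq s)
#' @export
df_lookup <- function(dft, target, source) {
  hit <- dft$entries$source == source & dft$entries$target == target
  if (!any(hit))
    stop_domain("no dose factor for target <- source pair (%s <- %s) in %s table",
                target, source, dft$phantom,
                class = "prrtdose_lookup_error")
  dft$entries$df_mGy_per_MBq_s[which(hit)[1]]
}

#' Per-cycle absorbed-dose record
#'
#' @param patient_id,cycle_index identifiers.
#' @param doses_mGy named numeric vector, region -> absorbed dose in mGy.
#'   Regions without a dose are simply absent (never recorded as 0).
#' @param protocol provenance: `"standard_multipoint"`,
#'   `"standard_single_point"` or `"mlr_single_point"`.
#' @return object of class `cycle_dose_record`.
#' @export
cycle_dose_record <- function(patient_id, cycle_index, doses_mGy,
                              protocol = c("standard_multipoint",
                                           "standard_single_point",
                                           "mlr_single_point")) {
  protocol <- match.arg(protocol)
  if (is.null(names(doses_mGy)) || any(names(doses_mGy) == ""))
    stop_domain("doses_mGy must be a fully named numeric vector")
  if (any(!is.finite(doses_mGy) | doses_mGy < 0))
    stop_domain("absorbed doses must be finite and >= 0")
  structure(
    list(patient_id = as.character(patient_id),
         cycle_index = as.integer(cycle_index),
         doses_mGy = doses_mGy,
         protocol = protocol),
    class = "cycle_dose_record")
}

#' @export
print.cycle_dose_record <- function(x, ...) {
  cat(sprintf("<cycle_dose_record> patient %s cycle %d (%s)\n",
              x$patient_id, x$cycle_index, x$protocol))
  print(round(x$doses_mGy, 1))
  invisible(x)
}

#' MLR coefficient set for one target region
#'
#' For solid organs and tumors the model is
#' \deqn{\ln D = \alpha_0 + \alpha_1 \ln c(t_s) + \alpha_2 t_s}
#' with \eqn{c} the activity concentration in mCi/cc and \eqn{t_s} the
#' imaging time in h; for bone marrow
#' \deqn{\ln D = \beta_0 + \beta_1 \ln[a_{blood}\Theta_{BM,BM} +
#'   c_{RM}\Theta_{BM,RM}] + \beta_2 t_s}
#' where the Theta pair estimated before training is embedded in the
#' coefficient object and reused verbatim at prediction time.
#'
#' @param target region label, or `"bone_marrow"`.
#' @param t_f_label which imaging times trained the model: one of `"t1"`,
#'   `"t2"`, `"t3"`, `"t1t2t3"`, `"t1t3"`.
#' @param alpha0,alpha1,alpha2 solid-organ/tumor coefficients.
#' @param beta0,beta1,beta2 marrow coefficients.
#' @param theta_bm_bm,theta_bm_rm marrow coupling constants used to build the
#'   composite regressor (marrow targets only).
#' @param r2_train,n_train training diagnostics (optional).
#' @return object of class `mlr_coefficients`. The unit contract is fixed:
#'   concentrations in mCi/cc, times in h, doses in mGy.
#' @export
mlr_coefficients <- function(target, t_f_label,
                             alpha0 = NULL, alpha1 = NULL, alpha2 = NULL,
                             beta0 = NULL, beta1 = NULL, beta2 = NULL,
                             theta_bm_bm = NULL, theta_bm_rm = NULL,
                             r2_train = NA_real_, n_train = NA_integer_) {
  t_f_label <- as.character(t_f_label)
  if (!t_f_label %in% c("t1", "t2", "t3", "t1t2t3", "t1t3"))
    stop_parse("unknown t_f_label '%s' for target %s", t_f_label, target)
  marrow <- identical(as.character(target), "bone_marrow")
  if (marrow) {
    co <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2,
            theta_bm_bm = theta_bm_bm, theta_bm_rm = theta_bm_rm)
  } else {
    co <- c(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2)
  }
  expected <- if (marrow) 5L else 3L
  if (length(co) != expected || any(!is.finite(co)))
    stop_parse("target %s@%s: missing or non-finite coefficient(s) [have: %s]",
               target, t_f_label, paste(names(co), collapse = ", "))
  structure(
    c(list(target = as.character(target), t_f_label = t_f_label),
      as.list(co),
      list(r2_train = r2_train, n_train = as.integer(n_train),
           unit_contract = list(concentration = "mCi/cc", time = "h",
                                dose = "mGy"))),
    class = "mlr_coefficients")
}

#' @export
print.mlr_coefficients <- function(x, ...) {
  if (x$target == "bone_marrow") {
    cat(sprintf("<mlr_coefficients> bone_marrow @ %s: Theta = (%.4g, %.4g), beta = (%.4g, %.4g, %.4g)",
                x$t_f_label, x$theta_bm_bm, x$theta_bm_rm,
                x$beta0, x$beta1, x$beta2))
  } else {
    cat(sprintf("<mlr_coefficients> %s @ %s: alpha = (%.4g, %.4g, %.4g)",
                x$target, x$t_f_label, x$alpha0, x$alpha1, x$alpha2))
  }
  if (is.finite(x$r2_train)) cat(sprintf(", r2_train = %.3g", x$r2_train))
  cat("\n")
  invisible(x)
}

#' Patient dose history with safety thresholds
#'
#' Accumulates per-cycle dose records of one patient (all under the same
#' protocol) and carries the management thresholds: further PRRT is withheld
#' when the cumulative kidney or bone-marrow dose is expected to exceed
#' 25 Gy or 2 Gy, respectively.
#'
#' @param patient_id identifier.
#' @param records list of [cycle_dose_record()]s, cycles contiguous from 1.
#' @param kidney_Gy,marrow_Gy safety thresholds in Gy.
#' @param planned_cycles intended number of cycles (default 4).
#' @return object of class `dose_history`.
#' @export
dose_history <- function(patient_id, records, kidney_Gy = 25, marrow_Gy = 2,
                         planned_cycles = 4L) {
  if (length(records) == 0)
    stop_domain("dose history needs at least one cycle record")
  idx <- vapply(records, function(r) r$cycle_index, integer(1))
  records <- records[order(idx)]
  idx <- sort(idx)
  if (!identical(idx, seq_along(idx)))
    stop_domain("cycle records must be contiguous from 1; got cycles %s",
                paste(idx, collapse = ", "))
  if (!all(vapply(records, function(r) r$patient_id, character(1)) == patient_id))
    stop_domain("all records must belong to patient %s", patient_id)
  if (kidney_Gy <= 0 || marrow_Gy <= 0)
    stop_domain("thresholds must be > 0")
  structure(
    list(patient_id = as.character(patient_id),
         records = records,
         thresholds = c(kidneys = kidney_Gy, bone_marrow = marrow_Gy),
         planned_cycles = as.integer(planned_cycles)),
    class = "dose_history")
}

#' Per-cycle doses of one region across a history
#' @param history a [dose_history()]
#' @param region region label
#' @return numeric vector of per-cycle doses in Gy (cycles where the region
#'   is absent are dropped)
#' @export
region_cycle_doses_Gy <- function(history, region) {
  d <- vapply(history$records, function(r) {
    if (region %in% names(r$doses_mGy)) r$doses_mGy[[region]] / 1000 else NA_real_
  }, numeric(1))
  d[!is.na(d)]
}
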