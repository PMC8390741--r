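# Agreement statistics and study orchestration: run the standard and
# MLR-based protocols over a synthetic cohort, compare doses and
# management decisions, and summarize agreement the way method-comparison
# studies do (relative differences, Bland-Altman limits, Pearson r and the
# angular coefficient of the correlation plot).

#' Relative differences between two dose sets
#'
#' Per item, `100 * (model / reference - 1)` percent — the model-versus-
#' standard deviation with the standard protocol as denominator.
#'
#' @param model,reference equal-length numeric vectors; `reference` must be
#'   strictly positive.
#' @return list with `per_item` (%), `mean`, `sd`, `n`.
#' @export
relative_difference <- function(model, reference) {
  if (length(model) != length(reference))
    stop_domain("model and reference must have equal length")
  if (any(!is.finite(reference) | reference <= 0))
    stop_domain("reference doses must be strictly positive")
  d <- 100 * (model / reference - 1)
  list(per_item = d, mean = mean(d),
       sd = if (length(d) > 1) stats::sd(d) else NA_real_,
       n = length(d))
}

#' Bland-Altman agreement limits
#'
#' Differences `model - reference`; 95% limits of agreement are the mean
#' difference plus/minus 1.96 times the SD of the differences (n-1
#' denominator).
#'
#' @param model,reference equal-length numeric vectors, n >= 2.
#' @return list `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(model, reference) {
  n <- length(model)
  if (length(reference) != n || n < 2)
    stop_domain("Bland-Altman needs two equal-length vectors with n >= 2")
  d <- model - reference
  s <- stats::sd(d)
  list(mean_diff = mean(d),
       loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s,
       sd_diff = s, n = n)
}

#' Pearson correlation and angular coefficient
#'
#' The angular coefficient `a` is the slope of the ordinary least-squares
#' fit of model on reference (with intercept, reported alongside); `r2` is
#' the squared Pearson correlation between the two dose sets.
#'
#' @param model,reference equal-length numeric vectors, n >= 2, each with
#'   nonzero variance.
#' @return list `r`, `a`, `intercept`, `r2`, `n`.
#' @export
pearson_and_slope <- function(model, reference) {
  n <- length(model)
  if (length(reference) != n || n < 2)
    stop_domain("correlation needs two equal-length vectors with n >= 2")
  if (stats::sd(model) == 0 || stats::sd(reference) == 0)
    stop_domain("zero variance: correlation undefined")
  r <- stats::cor(model, reference)
  co <- stats::coef(stats::lm(model ~ reference))
  list(r = r, a = unname(co[2]), intercept = unname(co[1]), r2 = r^2, n = n)
}

#' Power of the one-sided binomial discordance test
#'
#' Null hypothesis: the two protocols never disagree (discordance
#' probability 0), so at any significance level below 1 the test rejects as
#' soon as one discordant pair is observed. Against a true discordance
#' probability `p_alt` the power is \eqn{1 - (1 - p_{alt})^n}. With n = 32
#' and a true difference of at least 10% this is 96.6%.
#'
#' @param n number of paired management decisions.
#' @param p_alt true discordance probability under the alternative.
#' @param alpha significance level (any value in (0, 1) gives the same
#'   rejection region under the zero null; kept for the call signature).
#' @return power in percent.
#' @export
binomial_power <- function(n, p_alt, alpha = 0.05) {
  if (!is.finite(n) || n < 1) stop_domain("n must be >= 1")
  if (!is.finite(p_alt) || p_alt <= 0 || p_alt >= 1)
    stop_domain("p_alt must lie strictly between 0 and 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_domain("alpha must lie strictly between 0 and 1")
  100 * (1 - (1 - p_alt)^n)
}

#' Full agreement summary for one region
#' @inheritParams relative_difference
#' @return list bundling [relative_difference()], [bland_altman()] and
#'   [pearson_and_slope()]
#' @export
agreement_report <- function(model, reference) {
  list(relative = relative_difference(model, reference),
       bland_altman = bland_altman(model, reference),
       correlation = pearson_and_slope(model, reference))
}

#' Bland-Altman plot
#'
#' Simple base-graphics render: differences against means with the mean
#' difference and 95% limits of agreement as horizontal lines.
#'
#' @inheritParams bland_altman
#' @param xlab,ylab,main usual plot annotations
#' @return the [bland_altman()] statistics, invisibly
#' @export
plot_bland_altman <- function(model, reference,
                              xlab = "Mean of protocols (Gy)",
                              ylab = "Difference MLR - standard (Gy)",
                              main = "") {
  ba <- bland_altman(model, reference)
  graphics::plot((model + reference) / 2, model - reference,
                 xlab = xlab, ylab = ylab, main = main, pch = 19)
  graphics::abline(h = c(ba$mean_diff, ba$loa_low, ba$loa_high),
                   lty = c(1, 2, 2))
  invisible(ba)
}

# --- protocol orchestration -------------------------------------------------

#' Standard-protocol dosimetry for all cycles of one patient
#' @param patient as returned by [generate_patient()]
#' @param sphere_table tumor sphere table
#' @param density_g_per_cc tissue density
#' @return list `records` (per-cycle [cycle_dose_record()]s) and
#'   `fits_cycle1`
#' @export
standard_protocol_patient <- function(patient,
                                      sphere_table = default_sphere_table(),
                                      density_g_per_cc = 1.0) {
  dft <- default_dose_factors(patient$phantom)
  res1 <- standard_cycle_doses(patient$studies[[1]], dft, sphere_table,
                               density_g_per_cc = density_g_per_cc)
  records <- list(res1$record)
  if (length(patient$studies) > 1) {
    for (cy in 2:length(patient$studies)) {
      res <- standard_cycle_doses(patient$studies[[cy]], dft, sphere_table,
                                  prior_fits = res1$fits,
                                  density_g_per_cc = density_g_per_cc)
      records[[cy]] <- res$record
    }
  }
  list(records = records, fits_cycle1 = res1$fits)
}

single_label_rank <- function(t_s_label) {
  r <- tf_label_to_ranks(t_s_label)
  if (length(r) != 1)
    stop_domain("a single-time-point prediction needs a single time label, got %s",
                t_s_label)
  r
}

first_coef <- function(set, target) {
  if (is.null(set[[target]]) || length(set[[target]]) == 0)
    stop_domain("no trained coefficients for target %s", target,
                class = "prrtdose_lookup_error")
  set[[target]][[1]]
}

#' MLR single-time-point doses for one cycle
#'
#' Predicts every solid-organ/tumor dose from the measurement at the
#' requested ranked time point (tumor regions use the pooled `"tumor"`
#' coefficients) and the marrow dose from the nearest blood sample plus the
#' remainder VOI. For cycles imaged only at 24 h, requesting a later
#' nominal time builds hypothetic activities by decaying the 24-h
#' measurement with the patient's cycle-1 decay constants
#' ([hypothetic_activity()]).
#'
#' @param study a [cycle_study()]
#' @param coef_set `mlr_coefficient_set` (one t_f label per target)
#' @param t_s_label `"t1"`, `"t2"` or `"t3"`: which ranked acquisition to
#'   use
#' @param fits_cycle1 cycle-1 [kinetic_fit()]s, needed when the requested
#'   time is not available in `study`
#' @param nominal_times_h nominal schedule used for hypothetic times
#' @return a [cycle_dose_record()] with protocol `"mlr_single_point"`
#' @export
mlr_cycle_doses <- function(study, coef_set, t_s_label,
                            fits_cycle1 = NULL,
                            nominal_times_h = c(24, 96, 168)) {
  rank <- single_label_rank(t_s_label)
  m <- study$measurements
  doses <- c()
  solid_regions <- setdiff(unique(m$region), c("remainder", "blood"))
  for (reg in solid_regions) {
    rows <- m[m$region == reg, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    if (rank <= nrow(rows)) {
      ts <- rows$time_h[rank]
      conc <- voi_concentration_MBq_per_cc(rows[rank, , drop = FALSE])
    } else {
      if (is.null(fits_cycle1) || is.null(fits_cycle1[[reg]]))
        stop_domain("time point %s unavailable for region %s and no cycle-1 fit to extrapolate from",
                    t_s_label, reg)
      ts <- nominal_times_h[rank]
      act <- hypothetic_activity(
        voi_activity_MBq(rows[1, , drop = FALSE]), rows$time_h[1],
        fits_cycle1[[reg]]$lambda_eff_per_h, ts)
      conc <- act / rows$volume_cc[1]
    }
    target <- if (is_tumor_region(reg)) "tumor" else reg
    doses[reg] <- predict_dose_solid(first_coef(coef_set, target),
                                     conc, ts, conc_unit = "MBq/cc")
  }
  if (!is.null(study$blood) && "remainder" %in% m$region &&
      !is.null(coef_set[["bone_marrow"]])) {
    rows <- m[m$region == "remainder", , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    if (rank <= nrow(rows)) {
      ts <- rows$time_h[rank]
      c_rm <- voi_concentration_MBq_per_cc(rows[rank, , drop = FALSE])
      bi <- which.min(abs(study$blood$time_h - ts))
      a_blood <- study$blood$concentration_MBq_per_cc[bi]
      # blood sampled only near the first/last imaging: decay the nearest
      # sample onto the imaging time on the cycle-1 blood kinetics if off
      dt <- ts - study$blood$time_h[bi]
      if (abs(dt) > 1 && !is.null(fits_cycle1$blood))
        a_blood <- a_blood * exp(-fits_cycle1$blood$lambda_eff_per_h * dt)
    } else {
      if (is.null(fits_cycle1))
        stop_domain("time point %s unavailable for marrow and no cycle-1 fits",
                    t_s_label)
      ts <- nominal_times_h[rank]
      act <- hypothetic_activity(
        voi_activity_MBq(rows[1, , drop = FALSE]), rows$time_h[1],
        fits_cycle1[["remainder"]]$lambda_eff_per_h, ts)
      c_rm <- act / rows$volume_cc[1]
      a_blood <- hypothetic_activity(
        study$blood$concentration_MBq_per_cc[1], study$blood$time_h[1],
        fits_cycle1[["blood"]]$lambda_eff_per_h, ts)
    }
    doses["bone_marrow"] <- predict_dose_bm(
      first_coef(coef_set, "bone_marrow"), a_blood, c_rm, ts,
      conc_unit = "MBq/cc")
  }
  cycle_dose_record(study$patient_id, study$cycle_index, doses,
                    "mlr_single_point")
}

#' MLR-based protocol for all cycles of one patient
#'
#' Cycle 1 is predicted with `coef_set_cycle1` at `t_s_cycle1`; later
#' cycles with `coef_set_later` at `t_s_later` (hypothetic activities when
#' the requested time was not imaged). Cycle-1 kinetic fits come from the
#' standard protocol run.
#'
#' @param patient as returned by [generate_patient()]
#' @param std result of [standard_protocol_patient()] for this patient
#' @param coef_set_cycle1,coef_set_later trained `mlr_coefficient_set`s
#' @param t_s_cycle1,t_s_later single-time labels
#' @return list of per-cycle [cycle_dose_record()]s
#' @export
mlr_protocol_patient <- function(patient, std, coef_set_cycle1,
                                 coef_set_later,
                                 t_s_cycle1 = "t3", t_s_later = "t1") {
  records <- list(mlr_cycle_doses(patient$studies[[1]], coef_set_cycle1,
                                  t_s_cycle1, fits_cycle1 = std$fits_cycle1))
  if (length(patient$studies) > 1) {
    for (cy in 2:length(patient$studies))
      records[[cy]] <- mlr_cycle_doses(patient$studies[[cy]], coef_set_later,
                                       t_s_later,
                                       fits_cycle1 = std$fits_cycle1)
  }
  records
}

#' Decision concordance between two protocols
#'
#' Runs [decide_continuation()] after each successive cycle under both
#' protocols and counts agreements over all (patient, cycle) decision
#' points.
#'
#' @param histories_a,histories_b parallel lists of [dose_history()]s
#' @return list `percent`, `n_decisions`, `n_agree`, `disagreements`
#'   (data.frame patient/cycle/decision_a/decision_b)
#' @export
decision_concordance <- function(histories_a, histories_b) {
  stopifnot(length(histories_a) == length(histories_b))
  n <- 0L; agree <- 0L
  dis <- list()
  for (i in seq_along(histories_a)) {
    ha <- histories_a[[i]]; hb <- histories_b[[i]]
    k <- min(length(ha$records), length(hb$records))
    for (cy in seq_len(k)) {
      da <- decide_continuation(
        dose_history(ha$patient_id, ha$records[seq_len(cy)],
                     ha$thresholds[["kidneys"]], ha$thresholds[["bone_marrow"]],
                     ha$planned_cycles))$decision
      db <- decide_continuation(
        dose_history(hb$patient_id, hb$records[seq_len(cy)],
                     hb$thresholds[["kidneys"]], hb$thresholds[["bone_marrow"]],
                     hb$planned_cycles))$decision
      n <- n + 1L
      if (identical(da, db)) agree <- agree + 1L
      else dis[[length(dis) + 1]] <- data.frame(
        patient_id = ha$patient_id, cycle = cy,
        decision_a = da, decision_b = db)
    }
  }
  list(percent = 100 * agree / n, n_decisions = n, n_agree = agree,
       disagreements = if (length(dis)) do.call(rbind, dis) else NULL)
}

#' Run a full synthetic protocol-comparison study
#'
#' Orchestrates the pipeline: simulate a cohort, run the standard protocol
#' on everyone, train the MLR model on the training set, predict the test
#' set with a single time point per cycle, run management under both
#' protocols, and summarize agreement.
#'
#' @param config list; recognized fields (with defaults): `n_patients`
#'   (72), `n_train` (40), `seed` (required), `t_f` ("t1t2t3") and
#'   `t_s_cycle1` ("t3") for cycle 1, `t_f_later`/`t_s_later` ("t1") for
#'   later cycles, `model_matched` (FALSE: use the realistic generator;
#'   TRUE: the exactly model-consistent generator of
#'   [cohort_spec_model_matched()]), `kidney_Gy` (25), `marrow_Gy` (2),
#'   plus any [cohort_spec()] override (e.g. `noise_cv`, `lambda_cv`).
#' @return list with the trained `coefficients`, per-region `agreement`
#'   (cumulative test doses, MLR vs standard), `concordance` of management
#'   decisions, per-patient `decisions`, and the generating `spec`.
#' @export
run_study <- function(config) {
  defaults <- list(n_patients = 72L, n_train = 40L, t_f = "t1t2t3",
                   t_s_cycle1 = "t3", t_f_later = "t1", t_s_later = "t1",
                   model_matched = FALSE, kidney_Gy = 25, marrow_Gy = 2)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$seed)) stop_domain("run_study config requires a seed")
  spec_args <- config[intersect(names(config), names(formals(cohort_spec)))]
  spec <- if (isTRUE(config$model_matched)) {
    do.call(cohort_spec_model_matched,
            spec_args[setdiff(names(spec_args),
                              c("regions", "volume_cv", "lambda_cv",
                                "noise_cv", "blood_lambda_per_h"))])
  } else do.call(cohort_spec, spec_args)

  cohort <- generate_cohort(spec, n_train = config$n_train)
  std_train <- lapply(cohort$train, standard_protocol_patient,
                      density_g_per_cc = spec$density_g_per_cc)
  std_test <- lapply(cohort$test, standard_protocol_patient,
                     density_g_per_cc = spec$density_g_per_cc)

  train_studies <- lapply(cohort$train, function(p) p$studies[[1]])
  train_std1 <- lapply(std_train, function(s)
    list(record = s$records[[1]], fits = s$fits_cycle1))
  coef1 <- train_mlr_from_cohort(train_studies, train_std1, config$t_f,
                                 density_g_per_cc = spec$density_g_per_cc)
  coef_later <- if (identical(config$t_f_later, config$t_f)) coef1
  else train_mlr_from_cohort(train_studies, train_std1, config$t_f_later,
                             density_g_per_cc = spec$density_g_per_cc)

  mlr_test <- mapply(function(p, s)
    mlr_protocol_patient(p, s, coef1, coef_later,
                         config$t_s_cycle1, config$t_s_later),
    cohort$test, std_test, SIMPLIFY = FALSE)

  hist_std <- lapply(std_test, function(s)
    dose_history(s$records[[1]]$patient_id, s$records,
                 config$kidney_Gy, config$marrow_Gy))
  hist_mlr <- lapply(mlr_test, function(recs)
    dose_history(recs[[1]]$patient_id, recs,
                 config$kidney_Gy, config$marrow_Gy))
  concordance <- decision_concordance(hist_std, hist_mlr)

  # cumulative test-set doses per region, MLR vs standard
  regions <- unique(unlist(lapply(std_test, function(s)
    names(s$records[[1]]$doses_mGy))))
  agreement <- list()
  cumulative <- list()
  for (reg in regions) {
    std_cum <- vapply(hist_std, function(h)
      sum(region_cycle_doses_Gy(h, reg)), numeric(1))
    mlr_cum <- vapply(hist_mlr, function(h)
      sum(region_cycle_doses_Gy(h, reg)), numeric(1))
    ok <- std_cum > 0 & mlr_cum > 0
    if (sum(ok) >= 2) {
      agreement[[reg]] <- agreement_report(mlr_cum[ok], std_cum[ok])
      cumulative[[reg]] <- data.frame(standard_Gy = std_cum[ok],
                                      mlr_Gy = mlr_cum[ok])
    }
  }
  decisions <- lapply(seq_along(hist_std), function(i)
    list(patient_id = hist_std[[i]]$patient_id,
         standard = decide_continuation(hist_std[[i]])$decision,
         mlr = decide_continuation(hist_mlr[[i]])$decision,
         classification_standard =
           classify_predicted_management(hist_std[[i]])$category,
         classification_mlr =
           classify_predicted_management(hist_mlr[[i]])$category))

  list(config = config, spec = spec, coefficients = coef1,
       coefficients_later = coef_later,
       agreement = agreement, cumulative = cumulative,
       concordance = concordance, decisions = decisions,
       histories = list(standard = hist_std, mlr = hist_mlr))
}

#' Concordance over a grid of training and prediction times
#'
#' Generates one cohort, then evaluates management concordance for every
#' combination of training label, cycle-1 prediction time and later-cycle
#' prediction time — the synthetic analogue of scanning all protocol
#' variants for the one that preserves management.
#'
#' @param config as for [run_study()] (seed required)
#' @param t_f_options,t_s_cycle1_options,t_s_later_options grid axes
#' @return data.frame `t_f`, `t_s_cycle1`, `t_s_later`,
#'   `concordance_percent`, `n_decisions`
#' @export
concordance_sweep <- function(config,
                              t_f_options = c("t1", "t2", "t3", "t1t2t3"),
                              t_s_cycle1_options = c("t1", "t2", "t3"),
                              t_s_later_options = c("t1", "t2", "t3")) {
  grid <- expand.grid(t_f = t_f_options, t_s_cycle1 = t_s_cycle1_options,
                      t_s_later = t_s_later_options,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- utils::modifyList(config, as.list(grid[i, ]))
    cfg$t_f_later <- "t1"
    res <- run_study(cfg)
    out[[i]] <- cbind(grid[i, ],
                      concordance_percent = res$concordance$percent,
                      n_decisions = res$concordance$n_decisions)
  }
  ret <- do.call(rbind, out)
  rownames(ret) <- NULL
  ret
}
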