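# Single-time-point MLR dose model: Theta_BM estimation, log-log training
# for solid organs/tumors and bone marrow, and closed-form prediction.
#
# Unit contract at this boundary: concentrations in mCi/cc, times in h,
# doses in mGy. Internal MBq/cc concentrations are divided by 37 exactly
# once, here.

#' Convert MBq to mCi (or MBq/cc to mCi/cc)
#' @param x numeric
#' @export
mbq_to_mci <- function(x) x / MBQ_PER_MCI

#' Estimate the bone-marrow coupling constants
#'
#' Non-negative least squares through the origin of the standard-protocol
#' marrow dose on its two kinetic terms,
#' \eqn{x_1 = a_{blood}(0)/\lambda_{blood}} (MBq h/cc) and
#' \eqn{x_2 = A_{RM}(0)/(m_{RM}\lambda_{RM})} (MBq h/kg):
#' \eqn{D(BM) \approx \Theta_{BM,BM} x_1 + \Theta_{BM,RM} x_2}.
#' No intercept is included and coefficients are constrained non-negative
#' (a negative energy coupling is unphysical); with two regressors the
#' active-set solution is enumerated exactly.
#'
#' @param blood_terms,remainder_terms,doses_mGy equal-length numeric vectors
#'   (>= 2 records).
#' @return named numeric vector `c(theta_bm_bm =, theta_bm_rm =)`.
#' @export
estimate_theta_bm <- function(blood_terms, remainder_terms, doses_mGy) {
  n <- length(doses_mGy)
  if (length(blood_terms) != n || length(remainder_terms) != n)
    stop_domain("theta estimation needs equal-length term and dose vectors")
  if (n < 2)
    stop_domain("theta estimation needs >= 2 records, got %d", n)
  X <- cbind(blood = blood_terms, remainder = remainder_terms)
  if (any(!is.finite(X)) || any(!is.finite(doses_mGy)))
    stop_domain("non-finite values in theta estimation inputs")
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12)
    stop_domain("singular design in theta estimation (collinear or constant-zero term columns)",
                class = "prrtdose_singular_error")
  xty <- crossprod(X, doses_mGy)
  cand <- list()
  beta <- drop(solve(xtx, xty))
  if (all(beta >= 0)) cand <- c(cand, list(beta))
  for (j in 1:2) {                      # clamp one coefficient at zero
    b <- c(0, 0)
    b[j] <- max(0, xty[j] / xtx[j, j])
    cand <- c(cand, list(b))
  }
  rss <- vapply(cand, function(b) sum((doses_mGy - drop(X %*% b))^2),
                numeric(1))
  best <- unname(cand[[which.min(rss)]])
  c(theta_bm_bm = best[1], theta_bm_rm = best[2])
}

check_training_rows <- function(rows, n_min = 4L) {
  req <- c("ln_conc", "ts_h", "ln_dose")
  miss <- setdiff(req, names(rows))
  if (length(miss) > 0)
    stop_domain("training rows need columns %s; missing %s",
                paste(req, collapse = ", "), paste(miss, collapse = ", "))
  if (nrow(rows) < n_min)
    stop_domain("MLR training needs >= %d rows, got %d", n_min, nrow(rows))
  if (any(!is.finite(rows$ln_conc)) || any(!is.finite(rows$ts_h)) ||
      any(!is.finite(rows$ln_dose)))
    stop_domain("training rows contain non-finite values (zero-activity VOIs must be excluded before log transform)")
  rows
}

fit_loglog <- function(rows) {
  fit <- stats::lm(ln_dose ~ ln_conc + ts_h, data = rows)
  co <- stats::coef(fit)
  if (any(is.na(co)))
    stop_domain("rank-deficient MLR design (constant regressor column?)",
                class = "prrtdose_singular_error")
  # r^2 computed directly so exact fits do not trip summary.lm warnings
  tss <- sum((rows$ln_dose - mean(rows$ln_dose))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(coef = co, r2 = r2, n = nrow(rows))
}

#' Train the solid-organ/tumor MLR model
#'
#' Ordinary least squares of log dose on log concentration and imaging time:
#' \deqn{\ln D = \alpha_0 + \alpha_1 \ln c(t_s) + \alpha_2 t_s}
#' The time regressor is each study's actual acquisition time, which varies
#' patient to patient even within a nominal time point; this is what keeps
#' the time column non-degenerate in single-time-point training sets.
#'
#' @param rows data.frame with columns `ln_conc` (ln of concentration in
#'   mCi/cc), `ts_h`, `ln_dose` (ln of the standard-protocol dose in mGy);
#'   >= 4 rows.
#' @param target region label stored in the result.
#' @param t_f_label training-time tag (`"t1"`, `"t2"`, `"t3"`, `"t1t2t3"`,
#'   `"t1t3"`).
#' @return an [mlr_coefficients()] with `r2_train`, `n_train` filled in.
#' @export
train_mlr_solid <- function(rows, target, t_f_label) {
  rows <- check_training_rows(rows)
  f <- fit_loglog(rows)
  mlr_coefficients(target = target, t_f_label = t_f_label,
                   alpha0 = unname(f$coef[1]), alpha1 = unname(f$coef[2]),
                   alpha2 = unname(f$coef[3]),
                   r2_train = f$r2, n_train = f$n)
}

#' Train the bone-marrow MLR model
#'
#' Same regression as [train_mlr_solid()], but the concentration regressor
#' is the log of the composite marrow term
#' \eqn{a_{blood}(t_s)\Theta_{BM,BM} + c_{RM}(t_s)\Theta_{BM,RM}}
#' built with the previously estimated Theta pair; that same pair is
#' embedded in the returned coefficients and reused verbatim at prediction
#' time.
#'
#' @inheritParams train_mlr_solid
#' @param rows data.frame as in [train_mlr_solid()], `ln_conc` holding the
#'   log composite term.
#' @param theta_bm_bm,theta_bm_rm the coupling pair used to build `ln_conc`,
#'   in the form that multiplies mCi/cc concentrations.
#' @return an [mlr_coefficients()] for target `"bone_marrow"`.
#' @export
train_mlr_bm <- function(rows, theta_bm_bm, theta_bm_rm, t_f_label) {
  rows <- check_training_rows(rows)
  f <- fit_loglog(rows)
  mlr_coefficients(target = "bone_marrow", t_f_label = t_f_label,
                   beta0 = unname(f$coef[1]), beta1 = unname(f$coef[2]),
                   beta2 = unname(f$coef[3]),
                   theta_bm_bm = theta_bm_bm, theta_bm_rm = theta_bm_rm,
                   r2_train = f$r2, n_train = f$n)
}

check_conc_unit <- function(conc, conc_unit) {
  conc_unit <- match.arg(conc_unit, c("mCi/cc", "MBq/cc"))
  if (conc_unit == "MBq/cc") conc <- mbq_to_mci(conc)
  conc
}

#' Predict solid-organ/tumor dose from a single SPECT/CT study
#'
#' Closed form of the trained log-log model:
#' \deqn{D = c(t_s)^{\alpha_1} e^{\alpha_2 t_s + \alpha_0}}
#' The unit contract is concentration in mCi/cc; pass `conc_unit =
#' "MBq/cc"` to convert on entry. Silently mismatched units are the one
#' failure mode this interface refuses to allow.
#'
#' @param coef an [mlr_coefficients()] for a solid organ or tumor.
#' @param conc activity concentration(s) at the imaging time, > 0.
#' @param ts_h imaging time(s) post-injection, h (>= 0).
#' @param conc_unit `"mCi/cc"` (contract default) or `"MBq/cc"`.
#' @return predicted absorbed dose(s) in mGy.
#' @export
predict_dose_solid <- function(coef, conc, ts_h, conc_unit = "mCi/cc") {
  if (is.null(coef$alpha0))
    stop_domain("coefficient set for %s is not a solid-organ/tumor model",
                coef$target)
  conc <- check_conc_unit(conc, conc_unit)
  if (any(!is.finite(conc) | conc <= 0))
    stop_domain("concentration must be strictly positive (log-scale model)")
  if (any(!is.finite(ts_h) | ts_h < 0))
    stop_domain("imaging time must be >= 0")
  conc^coef$alpha1 * exp(coef$alpha2 * ts_h + coef$alpha0)
}

#' Predict bone-marrow dose from a single SPECT/CT study and blood sample
#'
#' \deqn{D(BM) = [a_{blood}(t_s)\Theta_{BM,BM} +
#'   c_{RM}(t_s)\Theta_{BM,RM}]^{\beta_1} e^{\beta_2 t_s + \beta_0}}
#' with the Theta pair stored in the coefficient object.
#'
#' @param coef an [mlr_coefficients()] for `"bone_marrow"`.
#' @param blood_conc blood activity concentration at `ts_h`.
#' @param remainder_conc remainder-of-body concentration
#'   \eqn{S C_{RM}/V_{RM}} at `ts_h`.
#' @param ts_h imaging time, h (>= 0).
#' @param conc_unit `"mCi/cc"` (contract default) or `"MBq/cc"`, applied to
#'   both concentrations.
#' @return predicted absorbed dose(s) in mGy.
#' @export
predict_dose_bm <- function(coef, blood_conc, remainder_conc, ts_h,
                            conc_unit = "mCi/cc") {
  if (is.null(coef$beta0))
    stop_domain("coefficient set for %s is not a bone-marrow model",
                coef$target)
  blood_conc <- check_conc_unit(blood_conc, conc_unit)
  remainder_conc <- check_conc_unit(remainder_conc, conc_unit)
  composite <- blood_conc * coef$theta_bm_bm +
    remainder_conc * coef$theta_bm_rm
  if (any(!is.finite(composite) | composite <= 0))
    stop_domain("composite marrow term must be strictly positive")
  if (any(!is.finite(ts_h) | ts_h < 0))
    stop_domain("imaging time must be >= 0")
  composite^coef$beta1 * exp(coef$beta2 * ts_h + coef$beta0)
}

# --- cohort-level training orchestration -----------------------------------

tf_label_to_ranks <- function(t_f_label) {
  switch(t_f_label,
         t1 = 1L, t2 = 2L, t3 = 3L,
         t1t2t3 = 1:3, t1t3 = c(1L, 3L),
         stop_parse("unknown t_f_label '%s'", t_f_label))
}

#' Build solid-organ/tumor training rows from a cohort
#'
#' One row per (patient, included time point): the log concentration
#' measured at that time (converted to mCi/cc), the actual acquisition
#' time, and the log of that patient's standard multi-time-point dose.
#' Zero-count VOI rows cannot be log-transformed; they are excluded with a
#' warning.
#'
#' @param studies list of cycle-1 [cycle_study()]s.
#' @param standard list parallel to `studies`, each element the result of
#'   [standard_cycle_doses()] on that study.
#' @param target region label.
#' @param t_f_label which ranked time points enter training.
#' @return data.frame `ln_conc`, `ts_h`, `ln_dose`.
#' @export
mlr_training_rows_solid <- function(studies, standard, target, t_f_label) {
  ranks <- tf_label_to_ranks(t_f_label)
  rows <- list()
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    rec <- standard[[i]]$record
    # the pooled label "tumor" collects every free-form tumor region
    regs <- if (identical(target, "tumor"))
      Filter(is_tumor_region, names(rec$doses_mGy))
    else intersect(target, names(rec$doses_mGy))
    for (reg in regs) {
      m <- st$measurements[st$measurements$region == reg, , drop = FALSE]
      m <- m[order(m$time_h), , drop = FALSE]
      use <- ranks[ranks <= nrow(m)]
      for (r in use) {
        conc <- mbq_to_mci(voi_concentration_MBq_per_cc(m[r, , drop = FALSE]))
        if (conc <= 0) {
          warning(sprintf("patient %s, %s at %.1f h: zero-activity VOI excluded from training",
                          st$patient_id, reg, m$time_h[r]))
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          ln_conc = log(conc), ts_h = m$time_h[r],
          ln_dose = log(rec$doses_mGy[[reg]]))
      }
    }
  }
  if (length(rows) == 0)
    stop_domain("no usable training rows for target %s", target)
  do.call(rbind, rows)
}

#' Build bone-marrow training rows from a cohort
#'
#' For each included time point, the blood sample closest to the imaging
#' time supplies \eqn{a_{blood}(t_s)} and the remainder VOI supplies
#' \eqn{c_{RM}(t_s)}; both are converted to mCi/cc before entering the
#' composite term with the supplied Theta pair.
#'
#' @inheritParams mlr_training_rows_solid
#' @param theta_bm_bm,theta_bm_rm coupling pair in mCi/cc-applied form.
#' @return data.frame `ln_conc` (log composite), `ts_h`, `ln_dose`.
#' @export
mlr_training_rows_bm <- function(studies, standard, theta_bm_bm, theta_bm_rm,
                                 t_f_label) {
  ranks <- tf_label_to_ranks(t_f_label)
  rows <- list()
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    rec <- standard[[i]]$record
    if (!"bone_marrow" %in% names(rec$doses_mGy) || is.null(st$blood)) next
    m <- st$measurements[st$measurements$region == "remainder", , drop = FALSE]
    m <- m[order(m$time_h), , drop = FALSE]
    use <- ranks[ranks <= nrow(m)]
    for (r in use) {
      ts <- m$time_h[r]
      bi <- which.min(abs(st$blood$time_h - ts))
      a_blood <- mbq_to_mci(st$blood$concentration_MBq_per_cc[bi])
      c_rm <- mbq_to_mci(voi_concentration_MBq_per_cc(m[r, , drop = FALSE]))
      composite <- a_blood * theta_bm_bm + c_rm * theta_bm_rm
      if (composite <= 0) {
        warning(sprintf("patient %s marrow term at %.1f h non-positive; excluded",
                        st$patient_id, ts))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        ln_conc = log(composite), ts_h = ts,
        ln_dose = log(rec$doses_mGy[["bone_marrow"]]))
    }
  }
  if (length(rows) == 0)
    stop_domain("no usable marrow training rows")
  do.call(rbind, rows)
}

#' Train the full MLR model family on a cohort
#'
#' Estimates the marrow Theta pair from the cohort's standard-protocol
#' kinetics, then fits the log-log regression for every requested target.
#' Marrow training uses only time points with a matching blood sample
#' (ranked times 1 and 3 under the standard schedule), so marrow models are
#' fitted for `t_f_label` in `t1`, `t3`, `t1t3`; requesting `t2`/`t1t2t3`
#' for marrow maps to the nearest supported label `t1t3`.
#'
#' @param studies list of cycle-1 [cycle_study()]s (training set).
#' @param standard parallel list of [standard_cycle_doses()] results.
#' @param t_f_label training-time tag for solid targets.
#' @param targets solid-organ/tumor labels to fit (default: all regions with
#'   standard doses, tumors pooled under label `"tumor"`).
#' @param density_g_per_cc density used for remainder mass.
#' @return an `mlr_coefficient_set`: `set[[target]][[t_f_label]]`.
#' @export
train_mlr_from_cohort <- function(studies, standard, t_f_label,
                                  targets = NULL, density_g_per_cc = 1.0) {
  if (is.null(targets)) {
    present <- unique(unlist(lapply(standard, function(s)
      names(s$record$doses_mGy))))
    targets <- intersect(c("kidneys", "liver", "spleen"), present)
    if (any(vapply(present, is_tumor_region, logical(1))))
      targets <- c(targets, "tumor")
  }
  set <- list()
  for (tg in targets) {
    rows <- mlr_training_rows_solid(studies, standard, tg, t_f_label)
    set[[tg]] <- stats::setNames(
      list(train_mlr_solid(rows, tg, t_f_label)), t_f_label)
  }
  # marrow: Theta first, from Eq.(5)-style integral terms of the standard fits
  has_bm <- vapply(standard, function(s)
    "bone_marrow" %in% names(s$record$doses_mGy), logical(1))
  if (any(has_bm)) {
    bt <- rt <- dd <- numeric(0)
    for (i in which(has_bm)) {
      fits <- standard[[i]]$fits
      st <- studies[[i]]
      rm_rows <- st$measurements[st$measurements$region == "remainder", ,
                                 drop = FALSE]
      m_rm <- rm_rows$volume_cc[1] * density_g_per_cc / 1000
      bt <- c(bt, fits$blood$amplitude_at_t0 / fits$blood$lambda_eff_per_h)
      rt <- c(rt, fits$remainder$amplitude_at_t0 /
                (m_rm * fits$remainder$lambda_eff_per_h))
      dd <- c(dd, standard[[i]]$record$doses_mGy[["bone_marrow"]])
    }
    theta <- estimate_theta_bm(bt, rt, dd)
    # convert to the form that multiplies mCi/cc concentrations: the blood
    # term is already per cc; the remainder term in Eq.(5) is per kg, and
    # concentration per cc = (mass/volume) x per kg = density/1000 x per kg
    th_bb <- unname(theta["theta_bm_bm"])
    th_rm <- unname(theta["theta_bm_rm"]) * 1000 / density_g_per_cc
    bm_label <- if (t_f_label %in% c("t1", "t3", "t1t3")) t_f_label else "t1t3"
    rows <- mlr_training_rows_bm(studies, standard, th_bb, th_rm, bm_label)
    set[["bone_marrow"]] <- stats::setNames(
      list(train_mlr_bm(rows, th_bb, th_rm, bm_label)), bm_label)
  }
  structure(set, class = "mlr_coefficient_set")
}
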