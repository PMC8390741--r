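# Treatment-continuation logic: cumulative dose tracking against the
# 25 Gy (kidneys) / 2 Gy (bone marrow) safety thresholds, the
# expected-next-cycle rule, hypothetic later-time activities, and the
# early "predicted total" classification. Decisions are advisory; the
# multi-disciplinary override stays with the clinic.

#' Expected cumulative dose after one further cycle
#'
#' The expected total is the cumulative dose so far plus the arithmetic
#' mean of the completed per-cycle doses — the minimal faithful estimator
#' of "estimated from the absorbed doses during previous treatments"; it
#' is isolated here so a clinic can substitute its own.
#'
#' @param history a [dose_history()]
#' @param region region label
#' @return expected cumulative dose in Gy
#' @export
expected_next_cycle_dose <- function(history, region) {
  d <- region_cycle_doses_Gy(history, region)
  if (length(d) == 0)
    stop_domain("region %s absent from all cycles of patient %s",
                region, history$patient_id)
  sum(d) + mean(d)
}

#' Continue-or-stop decision after the latest cycle
#'
#' Stops further PRRT when the expected cumulative dose after one more
#' cycle strictly exceeds the kidney (default 25 Gy) or bone-marrow
#' (default 2 Gy) threshold; a predicted total of exactly the threshold
#' continues ("exceed" read strictly).
#'
#' @param history a [dose_history()] containing kidney and marrow doses.
#' @return list with `decision` (`"continue"`, `"stop_kidney"`,
#'   `"stop_marrow"` or `"stop_both"`), the expected doses and the
#'   thresholds, for audit.
#' @export
decide_continuation <- function(history) {
  exp_k <- expected_next_cycle_dose(history, "kidneys")
  exp_m <- expected_next_cycle_dose(history, "bone_marrow")
  thr <- history$thresholds
  over_k <- exp_k > thr[["kidneys"]]
  over_m <- exp_m > thr[["bone_marrow"]]
  decision <- if (over_k && over_m) "stop_both"
  else if (over_k) "stop_kidney"
  else if (over_m) "stop_marrow"
  else "continue"
  list(patient_id = history$patient_id,
       decision = decision,
       expected_Gy = c(kidneys = exp_k, bone_marrow = exp_m),
       thresholds_Gy = thr,
       completed_cycles = length(history$records))
}

#' Hypothetic activity at a later time from first-cycle kinetics
#'
#' Decays a measured activity forward on the exponential defined by the
#' effective half-life obtained after the first cycle:
#' \eqn{A(t) = A(t_1) e^{-\lambda (t - t_1)}}. Used to evaluate the MLR
#' model at the late nominal times (96 h, 168 h) for cycles imaged only at
#' 24 h.
#'
#' @param measured_MBq activity measured at `t1_h`.
#' @param t1_h measurement time, h.
#' @param lambda_cycle1_per_h first-cycle effective decay constant, 1/h.
#' @param target_time_h requested time, must be strictly later than `t1_h`.
#' @return activity in MBq at `target_time_h`.
#' @export
hypothetic_activity <- function(measured_MBq, t1_h, lambda_cycle1_per_h,
                                target_time_h) {
  if (!is.finite(lambda_cycle1_per_h) || lambda_cycle1_per_h <= 0)
    stop_domain("lambda must be > 0")
  if (!is.finite(target_time_h) || target_time_h <= t1_h)
    stop_domain("target time (%.4g h) must be strictly later than the measurement time (%.4g h)",
                target_time_h, t1_h)
  measured_MBq * exp(-lambda_cycle1_per_h * (target_time_h - t1_h))
}

#' Early classification of the whole treatment course
#'
#' Projects the cumulative dose through the planned number of cycles using
#' the mean completed-cycle dose, and maps it against the threshold into
#' the management categories used for early treatment planning. With
#' \eqn{P(k)} the predicted cumulative dose through \eqn{k} cycles:
#' `stop_now` if the cumulative dose already exceeds the threshold (or no
#' further cycle fits); `4_cycles_safe` if \eqn{P(4) \le T};
#' `3_cycles_safe` when only three cycles fit and the patient still has
#' cycles to go; `consider_4th` when three cycles fit and the fourth is
#' the immediate question (>= 3 cycles completed); `consider_3rd` when
#' only two fit. This mapping reconstructs the published decision chart
#' and is an approximation of the clinic's algorithm.
#'
#' @param history a [dose_history()]
#' @param region organ driving the classification (default `"kidneys"`)
#' @return list with `category`, the predicted totals per horizon, and
#'   `n_scans` (completed cycles with imaging behind the estimate).
#' @export
classify_predicted_management <- function(history, region = "kidneys") {
  d <- region_cycle_doses_Gy(history, region)
  if (length(d) == 0)
    stop_domain("region %s absent from history", region)
  thr <- if (region == "bone_marrow") history$thresholds[["bone_marrow"]]
  else history$thresholds[["kidneys"]]
  n_done <- length(d)
  planned <- history$planned_cycles
  cum <- sum(d)
  pred <- function(k) cum + max(0, k - n_done) * mean(d)
  category <-
    if (cum > thr) "stop_now"
    else if (pred(planned) <= thr) "4_cycles_safe"
    else if (pred(planned - 1) <= thr) {
      if (n_done >= planned - 1) "consider_4th" else "3_cycles_safe"
    }
    else if (pred(planned - 2) <= thr) "consider_3rd"
    else "stop_now"
  list(patient_id = history$patient_id,
       region = region,
       category = category,
       predicted_Gy = stats::setNames(
         vapply(seq_len(planned), pred, numeric(1)),
         paste0("through_cycle_", seq_len(planned))),
       threshold_Gy = thr,
       n_scans = n_done)
}

#' Decision report for one patient under one protocol
#'
#' Runs [decide_continuation()] after each successive cycle of a history
#' and [classify_predicted_management()] on the full history; suitable for
#' JSON serialization.
#'
#' @param history a [dose_history()]
#' @return list of per-cycle decisions plus the final classification
#' @export
management_report <- function(history) {
  per_cycle <- lapply(seq_along(history$records), function(k) {
    h <- dose_history(history$patient_id, history$records[seq_len(k)],
                      kidney_Gy = history$thresholds[["kidneys"]],
                      marrow_Gy = history$thresholds[["bone_marrow"]],
                      planned_cycles = history$planned_cycles)
    decide_continuation(h)
  })
  list(patient_id = history$patient_id,
       per_cycle = per_cycle,
       final_decision = per_cycle[[length(per_cycle)]]$decision,
       classification = classify_predicted_management(history))
}
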