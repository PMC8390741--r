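# Shared fixture builders for the suite. Everything is generated in code;
# no stored data.

# minimal kidney-only measurement table at the protocol-like times
tiny_measurements <- function(times = c(19, 97, 163),
                              cps = c(1500, 700, 350),
                              region = "kidneys") {
  data.frame(region = region, time_h = times, count_rate_cps = cps,
             volume_cc = 310, sensitivity_MBq_per_cps = 0.1)
}

# dose-factor table with convenient round numbers for hand checks
toy_dft <- function(theta_bm_bm = 150, theta_bm_rm = 0.008) {
  dose_factor_table(
    phantom = "adult_male",
    entries = data.frame(
      source = c("kidneys", "liver", "spleen", "remainder",
                 "liver", "spleen"),
      target = c("kidneys", "liver", "spleen", "remainder",
                 "kidneys", "kidneys"),
      df_mGy_per_MBq_s = c(2, 1, 3, 0.5, 0.1, 0.2)),
    theta_bm_bm = theta_bm_bm, theta_bm_rm = theta_bm_rm)
}

# flat sphere table: Theta constant so tumor dose checks are closed-form
flat_sphere <- function(theta = 2e-5) {
  data.frame(mass_kg = c(0.001, 10), theta = c(theta, theta))
}

# exact log-log training rows: ln D = ln(K) + 1 * ln c + lambda * t
exact_solid_rows <- function(n = 12, lambda = 0.0111, K = 5e4, seed = 1) {
  set.seed(seed)
  conc <- exp(stats::runif(n, -8, -2))
  ts <- stats::runif(n, 20, 170)
  data.frame(ln_conc = log(conc), ts_h = ts,
             ln_dose = log(K) + log(conc) + lambda * ts)
}

# a dose history from per-cycle kidney/marrow doses in Gy
history_from_doses <- function(kidney_Gy, marrow_Gy = rep(0.2, length(kidney_Gy)),
                               patient = "T01", kidney_thr = 25, marrow_thr = 2,
                               planned = 4L) {
  recs <- lapply(seq_along(kidney_Gy), function(k)
    cycle_dose_record(patient, k,
                      c(kidneys = kidney_Gy[k] * 1000,
                        bone_marrow = marrow_Gy[k] * 1000),
                      "standard_multipoint"))
  dose_history(patient, recs, kidney_Gy = kidney_thr, marrow_Gy = marrow_thr,
               planned_cycles = planned)
}
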