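# Readers/writers for measurement tables, coefficient files, dose-factor
# tables and reports. Dialect: comma-separated, '.' decimal, UTF-8, header
# row mandatory. JSON via jsonlite; .yaml/.yml accepted where the yaml
# package is available.

DEFAULT_MEASUREMENT_SCHEMA <- c(region = "region", time_h = "time_h",
                                count_rate_cps = "cps",
                                volume_cc = "volume_cc",
                                sensitivity_MBq_per_cps = "sensitivity")
DEFAULT_BLOOD_SCHEMA <- c(time_h = "time_h",
                          concentration_MBq_per_cc = "conc")

read_structured <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_parse("reading %s requires the yaml package", path)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

write_structured <- function(x, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_parse("writing %s requires the yaml package", path)
    yaml::write_yaml(x, path)
  } else {
    # I(17) significant digits: doubles survive the round trip bit-exactly
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

rename_by_schema <- function(df, schema, what, path) {
  miss <- setdiff(unname(schema), names(df))
  if (length(miss) > 0)
    stop_parse("%s table %s missing column(s): %s", what, path,
               paste(miss, collapse = ", "))
  out <- df[unname(schema)]
  names(out) <- names(schema)
  out
}

#' Read one therapy cycle from delimited text
#'
#' Either point `path` at a bundle metadata JSON written by
#' [write_cycle_study()] (which names the CSV files and carries patient id,
#' cycle index, injected activity and phantom), or at a measurement CSV
#' directly, supplying the metadata as arguments.
#'
#' @param path bundle `.json` or measurement `.csv` file.
#' @param blood_path optional blood-sample CSV (ignored for bundles).
#' @param patient_id,cycle_index,injected_activity_MBq,phantom metadata,
#'   required when `path` is a CSV.
#' @param schema,blood_schema named character vectors mapping internal field
#'   names to CSV header names; defaults
#'   `region,time_h,cps,volume_cc,sensitivity` and `time_h,conc`.
#' @return a validated [cycle_study()].
#' @export
read_cycle_study <- function(path, blood_path = NULL,
                             patient_id = NULL, cycle_index = NULL,
                             injected_activity_MBq = NULL,
                             phantom = "adult_male",
                             schema = DEFAULT_MEASUREMENT_SCHEMA,
                             blood_schema = DEFAULT_BLOOD_SCHEMA) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    meta <- read_structured(path)
    dir <- dirname(path)
    mpath <- file.path(dir, meta$measurements_file)
    bpath <- if (!is.null(meta$blood_file)) file.path(dir, meta$blood_file)
    return(read_cycle_study(mpath, blood_path = bpath,
                            patient_id = meta$patient_id,
                            cycle_index = meta$cycle_index,
                            injected_activity_MBq = meta$injected_activity_MBq,
                            phantom = meta$phantom,
                            schema = schema, blood_schema = blood_schema))
  }
  if (is.null(patient_id) || is.null(cycle_index) ||
      is.null(injected_activity_MBq))
    stop_parse("reading a bare CSV requires patient_id, cycle_index and injected_activity_MBq")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  meas <- rename_by_schema(raw, schema, "measurement", path)
  blood <- NULL
  if (!is.null(blood_path)) {
    braw <- utils::read.csv(blood_path, stringsAsFactors = FALSE,
                            encoding = "UTF-8")
    blood <- rename_by_schema(braw, blood_schema, "blood", blood_path)
  }
  cycle_study(patient_id = patient_id, cycle_index = cycle_index,
              injected_activity_MBq = injected_activity_MBq,
              phantom = phantom, measurements = meas, blood = blood)
}

#' Write one therapy cycle as a CSV bundle
#'
#' Emits `<patient>_cycle<k>_measurements.csv`, optionally
#' `<patient>_cycle<k>_blood.csv`, and a `<patient>_cycle<k>.json` metadata
#' file tying them together. [read_cycle_study()] on the metadata file is the
#' exact inverse.
#'
#' @param study a [cycle_study()]
#' @param dir output directory (created if absent)
#' @return path of the metadata file, invisibly
#' @export
write_cycle_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_cycle%d", study$patient_id, study$cycle_index)
  mfile <- paste0(stem, "_measurements.csv")
  m <- study$measurements
  # %.17g keeps the CSV round trip bit-exact
  num <- function(x) sprintf("%.17g", x)
  out <- data.frame(region = m$region, time_h = num(m$time_h),
                    cps = num(m$count_rate_cps),
                    volume_cc = num(m$volume_cc),
                    sensitivity = num(m$sensitivity_MBq_per_cps))
  utils::write.csv(out, file.path(dir, mfile), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  bfile <- NULL
  if (!is.null(study$blood)) {
    bfile <- paste0(stem, "_blood.csv")
    b <- data.frame(time_h = num(study$blood$time_h),
                    conc = num(study$blood$concentration_MBq_per_cc))
    utils::write.csv(b, file.path(dir, bfile), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  meta <- list(patient_id = study$patient_id,
               cycle_index = study$cycle_index,
               injected_activity_MBq = study$injected_activity_MBq,
               phantom = study$phantom,
               measurements_file = mfile,
               blood_file = bfile)
  mpath <- file.path(dir, paste0(stem, ".json"))
  write_structured(meta, mpath)
  invisible(mpath)
}

coef_fields <- function(co) {
  keep <- intersect(c("alpha0", "alpha1", "alpha2", "beta0", "beta1", "beta2",
                      "theta_bm_bm", "theta_bm_rm", "r2_train", "n_train"),
                    names(co))
  co[keep]
}

#' Read MLR coefficient sets from a structured config file
#'
#' The file is nested target -> training-time label -> coefficients. The
#' package ships `inst/extdata/mlr_coefficients_published.json`, a verbatim
#' transcription of the published training summary for kidneys, tumors,
#' liver, spleen (alpha coefficients at t1, t2, t3 and pooled t1t2t3) and
#' bone marrow (Theta pair plus beta coefficients at t1, t3, t1t3).
#'
#' @param path JSON or YAML file.
#' @return nested named list `set[[target]][[t_f_label]]`, each element an
#'   [mlr_coefficients()] object; class `mlr_coefficient_set`.
#' @export
read_coefficients <- function(path) {
  raw <- read_structured(path)
  set <- lapply(names(raw), function(target) {
    per_t <- raw[[target]]
    out <- lapply(names(per_t), function(tf) {
      co <- per_t[[tf]]
      do.call(mlr_coefficients,
              c(list(target = target, t_f_label = tf), co))
    })
    names(out) <- names(per_t)
    out
  })
  names(set) <- names(raw)
  structure(set, class = "mlr_coefficient_set")
}

#' Write MLR coefficient sets
#' @param set an `mlr_coefficient_set` (or plain nested list of
#'   [mlr_coefficients()])
#' @param path JSON or YAML output file
#' @export
write_coefficients <- function(set, path) {
  raw <- lapply(set, function(per_t) lapply(per_t, coef_fields))
  write_structured(raw, path)
}

#' Fetch one coefficient set
#' @param set as returned by [read_coefficients()]
#' @param target region label or `"bone_marrow"`
#' @param t_f_label training-time label
#' @export
get_coefficients <- function(set, target, t_f_label) {
  if (is.null(set[[target]]))
    stop_domain("no coefficients for target %s", target,
                class = "prrtdose_lookup_error")
  co <- set[[target]][[t_f_label]]
  if (is.null(co))
    stop_domain("no coefficients for target %s at t_f = %s", target, t_f_label,
                class = "prrtdose_lookup_error")
  co
}

#' Read a dose-factor table
#'
#' File layout: top-level keys are phantom names; each phantom holds
#' `entries` (list of `{source, target, df_mGy_per_MBq_s}`), `theta_bm_bm`
#' and `theta_bm_rm`. The shipped
#' `inst/extdata/dose_factors_synthetic.json` is a physically plausible
#' synthetic stand-in (published phantom dose-factor compilations are
#' consumed as inputs, not redistributed here).
#'
#' @param path JSON or YAML file
#' @param phantom which phantom to load
#' @return a [dose_factor_table()]
#' @export
read_dose_factors <- function(path, phantom = "adult_male") {
  raw <- read_structured(path)
  if (is.null(raw[[phantom]]))
    stop_parse("phantom %s not present in %s", phantom, path)
  p <- raw[[phantom]]
  entries <- do.call(rbind, lapply(p$entries, function(e)
    data.frame(source = e$source, target = e$target,
               df_mGy_per_MBq_s = e$df_mGy_per_MBq_s)))
  dose_factor_table(phantom = phantom, entries = entries,
                    theta_bm_bm = p$theta_bm_bm, theta_bm_rm = p$theta_bm_rm)
}

#' Write dose-factor tables (one or more phantoms)
#' @param dfts list of [dose_factor_table()]s
#' @param path output file
#' @export
write_dose_factors <- function(dfts, path) {
  if (inherits(dfts, "dose_factor_table")) dfts <- list(dfts)
  raw <- list()
  for (dft in dfts) {
    raw[[dft$phantom]] <- list(
      entries = lapply(seq_len(nrow(dft$entries)), function(i)
        as.list(dft$entries[i, ])),
      theta_bm_bm = dft$theta_bm_bm,
      theta_bm_rm = dft$theta_bm_rm)
  }
  write_structured(raw, path)
}

#' Read a tumor sphere-model coupling table
#'
#' Maps sphere mass (kg) to the self-dose coupling constant Theta(m) in
#' kg mGy/(MBq s); tumor self-dose uses piecewise-linear interpolation in
#' mass. The shipped `sphere_theta_synthetic.json` is an illustrative
#' synthetic table.
#'
#' @param path JSON/YAML file with fields `mass_kg`, `theta`
#' @return data.frame with columns `mass_kg`, `theta`, sorted by mass
#' @export
read_sphere_table <- function(path) {
  raw <- read_structured(path)
  df <- data.frame(mass_kg = unlist(raw$mass_kg), theta = unlist(raw$theta))
  if (nrow(df) < 1 || any(!is.finite(df$mass_kg)) || any(df$mass_kg <= 0) ||
      any(!is.finite(df$theta)) || any(df$theta < 0))
    stop_parse("invalid sphere table %s", path)
  df[order(df$mass_kg), , drop = FALSE]
}

#' Write a list of dose records as a JSON report
#' @param records list of [cycle_dose_record()]s
#' @param path output JSON file
#' @export
write_dose_records <- function(records, path) {
  raw <- lapply(records, function(r)
    list(patient_id = r$patient_id, cycle_index = r$cycle_index,
         protocol = r$protocol, doses_mGy = as.list(r$doses_mGy)))
  write_structured(raw, path)
}
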