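#' Estimated glomerular filtration rate (4-variable MDRD)
#'
#' IDMS-standardized 4-variable MDRD study equation:
#' `175 * scr^-1.154 * age^-0.203 * 0.742[if female] * 1.212[if black]`.
#'
#' @param scr serum creatinine, mg/dL (> 0).
#' @param age_years age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param black logical; African-ancestry coefficient.
#' @return eGFR in ml/min/1.73m^2. Vectorized over all arguments.
#' @export
egfr_mdrd <- function(scr, age_years, sex, black) {
  if (any(scr <= 0, na.rm = TRUE)) stop2("scr must be > 0")
  if (any(age_years <= 0, na.rm = TRUE)) stop2("age_years must be > 0")
  175 * scr^(-1.154) * age_years^(-0.203) *
    ifelse(sex == "female", 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Exclusion-rule configuration
#'
#' Thresholds and temporal windows for the chronic-kidney-disease,
#' systolic-heart-failure, and diagnosis-code exclusions, plus the ICD-9-CM
#' code prefixes that disqualify a patient outright (pathologic adrenergic
#' states such as pheochromocytoma, and secondary hypertension).
#'
#' @param excluded_code_prefixes character vector of ICD-9-CM prefixes;
#'   matching is a plain string-prefix test on the verbatim code.
#' @param ckd_egfr_threshold eGFR at or below which CKD is present (ml/min).
#' @param ckd_window_days_after_index CKD labs count at/before the index date
#'   and up to this many days after it.
#' @param hf_ef_threshold ejection fraction (%) at or below which systolic
#'   heart failure is present.
#' @param hf_window_days for cases, EF evidence counts within this many days
#'   before or after the index date; for controls it counts at any time.
#' @return An object of class `exclusion_config`.
#' @export
exclusion_config <- function(excluded_code_prefixes = c("194.0", "227.0", "255.6", "405"),
                             ckd_egfr_threshold = 30,
                             ckd_window_days_after_index = 183,
                             hf_ef_threshold = 35,
                             hf_window_days = 365) {
  stopifnot(ckd_egfr_threshold > 0, ckd_window_days_after_index > 0,
            hf_ef_threshold > 0, hf_window_days > 0)
  structure(list(excluded_code_prefixes = as.character(excluded_code_prefixes),
                 ckd_egfr_threshold = ckd_egfr_threshold,
                 ckd_window_days_after_index = ckd_window_days_after_index,
                 hf_ef_threshold = hf_ef_threshold,
                 hf_window_days = hf_window_days),
            class = "exclusion_config")
}

#' Read an exclusion configuration from JSON
#'
#' @param path JSON file with any subset of the [exclusion_config()] fields;
#'   missing fields take the defaults.
#' @return An [exclusion_config()].
#' @export
read_exclusion_config <- function(path) {
  if (!file.exists(path)) stop2("exclusion config not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(exclusion_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop2(path, ": unknown field(s): ", paste(bad, collapse = ", "))
  do.call(exclusion_config, vals)
}

#' @rdname read_exclusion_config
#' @export
default_exclusion_config <- function() {
  read_exclusion_config(system.file("extdata", "exclusions.json",
                                    package = "rhtn", mustWork = TRUE))
}

# age at a date from the birth decade's midpoint (exact birth dates are not
# part of the data model)
age_at_date <- function(demographics, date) {
  pmax(year_of(date) - (demographics$birth_decade + 5), 1)
}

#' Chronic-kidney-disease exclusion
#'
#' Fires when any serum-creatinine measurement taken at or before the index
#' date, or within `ckd_window_days_after_index` days after it, yields an
#' MDRD eGFR at or below the threshold. Age at the lab date is derived from
#' the birth decade's midpoint.
#'
#' @param record a [patient_record()].
#' @param index_date the date the phenotype definition was met.
#' @param cfg an [exclusion_config()].
#' @return List with `excluded` (logical) and `reason` (string or `NULL`).
#' @export
ckd_excluded <- function(record, index_date, cfg) {
  labs <- record$labs
  labs <- labs[labs$analyte == "serum_creatinine" &
                 labs$date <= index_date + cfg$ckd_window_days_after_index, ,
               drop = FALSE]
  if (nrow(labs) == 0L) return(list(excluded = FALSE, reason = NULL))
  d <- record$demographics
  egfr <- egfr_mdrd(labs$value, age_at_date(d, labs$date), d$sex,
                    d$race_ethnicity == "african_american")
  hit <- which(egfr <= cfg$ckd_egfr_threshold)
  if (length(hit) == 0L) return(list(excluded = FALSE, reason = NULL))
  list(excluded = TRUE,
       reason = sprintf("ckd: eGFR %.1f <= %g on %s", egfr[hit[1L]],
                        cfg$ckd_egfr_threshold, labs$date[hit[1L]]))
}

#' Systolic-heart-failure exclusion
#'
#' An ejection fraction at or below the threshold excludes a patient: for
#' cases when dated within `hf_window_days` of the index date, for controls
#' at any time.
#'
#' @inheritParams ckd_excluded
#' @param role `"case"` or `"control"` (selects the temporal window rule).
#' @return List with `excluded` and `reason`.
#' @export
hf_excluded <- function(record, index_date, cfg, role = c("case", "control")) {
  role <- match.arg(role)
  efs <- record$efs
  if (role == "case")
    efs <- efs[abs(as.numeric(efs$date - index_date)) <= cfg$hf_window_days, ,
               drop = FALSE]
  hit <- which(efs$ef_percent <= cfg$hf_ef_threshold)
  if (length(hit) == 0L) return(list(excluded = FALSE, reason = NULL))
  list(excluded = TRUE,
       reason = sprintf("hf: EF %.0f%% <= %g%% on %s", efs$ef_percent[hit[1L]],
                        cfg$hf_ef_threshold, efs$date[hit[1L]]))
}

#' Diagnosis-code exclusion
#'
#' String-prefix match of every diagnosis code against the configured
#' excluded prefixes (codes are stored verbatim; `"4051"` matches prefix
#' `"405"` just as `"405.91"` does).
#'
#' @inheritParams ckd_excluded
#' @return List with `excluded` and `reason`.
#' @export
code_excluded <- function(record, cfg) {
  codes <- record$codes$code
  for (pfx in cfg$excluded_code_prefixes) {
    hit <- which(startsWith(codes, pfx))
    if (length(hit)) {
      return(list(excluded = TRUE,
                  reason = sprintf("code: %s matches excluded prefix %s on %s",
                                   codes[hit[1L]], pfx,
                                   record$codes$date[hit[1L]])))
    }
  }
  list(excluded = FALSE, reason = NULL)
}

run_exclusions <- function(record, index_date, cfg, role) {
  reasons <- character()
  for (res in list(code_excluded(record, cfg),
                   ckd_excluded(record, index_date, cfg),
                   hf_excluded(record, index_date, cfg, role))) {
    if (res$excluded) reasons <- c(reasons, res$reason)
  }
  list(excluded = length(reasons) > 0L, reasons = reasons)
}

#' Phenotyping options
#'
#' @param mention_window_days assumed coverage window of non-refill
#'   medication evidence (days); see [exposure_intervals()].
#' @param collapse_diuretics count the three diuretic subtypes as one class.
#' @param uncontrolled_bp_lag_days the elevated blood pressure that defines an
#'   uncontrolled case must be measured at least this many days after the
#'   medication criteria are first met.
#' @param control_bp_lag_days blood-pressure control for the control
#'   definition is assessed on measurements at least this many days after the
#'   first antihypertensive prescription.
#' @return A plain list of options.
#' @export
phenotype_options <- function(mention_window_days = 90,
                              collapse_diuretics = FALSE,
                              uncontrolled_bp_lag_days = 30,
                              control_bp_lag_days = 30) {
  list(mention_window_days = mention_window_days,
       collapse_diuretics = collapse_diuretics,
       uncontrolled_bp_lag_days = uncontrolled_bp_lag_days,
       control_bp_lag_days = control_bp_lag_days)
}

#' Controlled-case algorithm: four concurrent medication classes
#'
#' The first resistant-hypertension case definition: blood pressure
#' controlled, but only on at least four concurrent antihypertensive
#' medication classes. Exclusions are evaluated by [classify()], not here.
#'
#' @param record a [patient_record()].
#' @param dict a [med_dictionary()].
#' @param opts a [phenotype_options()] list.
#' @return List with `met` (logical), `index_date`, and `trace` strings.
#' @export
classify_case_controlled <- function(record, dict, opts = phenotype_options()) {
  d4 <- first_date_with_k_classes(record, dict, 4L, opts$mention_window_days,
                                  opts$collapse_diuretics)
  if (is.na(d4))
    return(list(met = FALSE, index_date = as.Date(NA),
                trace = "alg1: never >=4 concurrent classes"))
  list(met = TRUE, index_date = d4,
       trace = sprintf("alg1: >=4 concurrent classes from %s", d4))
}

#' Uncontrolled-case algorithm: three classes plus persistent elevation
#'
#' The second case definition: at least three concurrent antihypertensive
#' classes, and a systolic pressure >140 or diastolic >90 mm Hg measured at
#' least one month (`uncontrolled_bp_lag_days`) after the medication criteria
#' were met, while at least three classes remain concurrent on the
#' measurement date. The index date is the qualifying measurement's date.
#'
#' @inheritParams classify_case_controlled
#' @return List with `met`, `index_date`, `trace`.
#' @export
classify_case_uncontrolled <- function(record, dict, opts = phenotype_options()) {
  d3 <- first_date_with_k_classes(record, dict, 3L, opts$mention_window_days,
                                  opts$collapse_diuretics)
  if (is.na(d3))
    return(list(met = FALSE, index_date = as.Date(NA),
                trace = "alg2: never >=3 concurrent classes"))
  iv <- exposure_intervals(record, dict, opts$mention_window_days,
                           opts$collapse_diuretics)
  bps <- record$bps
  cand <- which(bps$date >= d3 + opts$uncontrolled_bp_lag_days &
                  (bps$sbp > 140 | bps$dbp > 90))
  for (i in cand) {
    if (concurrency_at(record, dict, iv, bps$date[i],
                       opts$collapse_diuretics) >= 3L) {
      return(list(met = TRUE, index_date = bps$date[i],
                  trace = sprintf(
                    "alg2: >=3 classes from %s; BP %g/%g on %s while >=3 classes concurrent",
                    d3, bps$sbp[i], bps$dbp[i], bps$date[i])))
    }
  }
  list(met = FALSE, index_date = as.Date(NA),
       trace = sprintf(
         "alg2: >=3 classes from %s but no qualifying elevated BP >=%d days later",
         d3, opts$uncontrolled_bp_lag_days))
}

#' Controlled-hypertensive (control) definition
#'
#' A control must show hypertension (an untreated measurement >140 systolic
#' or >90 diastolic before the first antihypertensive, or a 401.* diagnosis
#' code at any time), be treated with exactly one medication class at a time
#' (the class may change but classes never overlap), and have every blood
#' pressure from one month after the first prescription onward below 135
#' systolic and 90 diastolic, with at least one such measurement. The index
#' date is the first antihypertensive date. Exclusions are evaluated by
#' [classify()].
#'
#' @inheritParams classify_case_controlled
#' @return List with `met`, `index_date`, `trace`.
#' @export
classify_control <- function(record, dict, opts = phenotype_options()) {
  meds <- record$meds
  cls <- classify_drug(meds$drug_name, dict, opts$collapse_diuretics)
  ok <- valid_mention(meds) & !is.na(cls)
  if (!any(ok))
    return(list(met = FALSE, index_date = as.Date(NA),
                trace = "control: no classifiable antihypertensive event"))
  p_date <- min(meds$date[ok])
  trace <- sprintf("control: first antihypertensive on %s", p_date)

  bps <- record$bps
  pre_elev <- any(bps$date < p_date & (bps$sbp > 140 | bps$dbp > 90))
  htn_code <- any(startsWith(record$codes$code, "401"))
  if (!pre_elev && !htn_code)
    return(list(met = FALSE, index_date = as.Date(NA),
                trace = c(trace, "control: no pre-treatment hypertension evidence (BP or 401.*)")))
  ev <- c(if (pre_elev) "pre-treatment BP", if (htn_code) "401.* code")
  trace <- c(trace, sprintf("control: hypertension evidence (%s)",
                            paste(ev, collapse = " + ")))

  mx <- max_concurrent_classes(record, dict, opts$mention_window_days,
                               opts$collapse_diuretics)
  if (mx > 1L)
    return(list(met = FALSE, index_date = as.Date(NA),
                trace = c(trace, sprintf("control: %d simultaneous classes observed (>1)", mx))))
  trace <- c(trace, "control: never >1 simultaneous class")

  post <- bps[bps$date >= p_date + opts$control_bp_lag_days, , drop = FALSE]
  if (nrow(post) == 0L)
    return(list(met = FALSE, index_date = as.Date(NA),
                trace = c(trace, "control: no BP measurement >=1 month after first prescription")))
  bad <- which(!(post$sbp < 135 & post$dbp < 90))
  if (length(bad))
    return(list(met = FALSE, index_date = as.Date(NA),
                trace = c(trace, sprintf("control: BP %g/%g on %s not <135/<90",
                                         post$sbp[bad[1L]], post$dbp[bad[1L]],
                                         post$date[bad[1L]]))))
  list(met = TRUE, index_date = p_date,
       trace = c(trace, sprintf("control: all %d BPs >=1 month post-treatment <135/<90",
                                nrow(post))))
}

#' Classify one patient record
#'
#' Applies the definitions in order of precedence: the controlled-case
#' algorithm (four classes), then the uncontrolled-case algorithm (three
#' classes plus persistent elevation), then the control definition. The
#' exclusion rules (diagnosis codes, CKD, systolic heart failure) are
#' evaluated at the index date of the first definition whose criteria are
#' met; if any fires, the patient is `EXCLUDED`. A record meeting no
#' definition is `UNCLASSIFIED`.
#'
#' @param record a [patient_record()].
#' @param dict a [med_dictionary()].
#' @param cfg an [exclusion_config()].
#' @param opts a [phenotype_options()] list.
#' @return An object of class `phenotype_call`: `patient_id`, `status` (one
#'   of [PHENOTYPE_STATUSES]), `index_date`, `algorithm` (`"controlled"`,
#'   `"uncontrolled"`, or `NA`), and `reasons` (the ordered rule trace).
#' @export
classify <- function(record, dict, cfg = exclusion_config(),
                     opts = phenotype_options()) {
  trace <- character()
  call_out <- function(status, index_date = as.Date(NA), algorithm = NA_character_) {
    structure(list(patient_id = record$demographics$patient_id,
                   status = status, index_date = index_date,
                   algorithm = algorithm, reasons = trace),
              class = "phenotype_call")
  }
  finish <- function(res, role, status, algorithm) {
    excl <- run_exclusions(record, res$index_date, cfg, role)
    if (excl$excluded) {
      trace <<- c(trace, excl$reasons)
      return(call_out("EXCLUDED", as.Date(NA), algorithm))
    }
    trace <<- c(trace, "exclusions: none")
    call_out(status, res$index_date, algorithm)
  }

  a1 <- classify_case_controlled(record, dict, opts)
  trace <- c(trace, a1$trace)
  if (a1$met) return(finish(a1, "case", "CASE_CONTROLLED", "controlled"))

  a2 <- classify_case_uncontrolled(record, dict, opts)
  trace <- c(trace, a2$trace)
  if (a2$met) return(finish(a2, "case", "CASE_UNCONTROLLED", "uncontrolled"))

  ctl <- classify_control(record, dict, opts)
  trace <- c(trace, ctl$trace)
  if (ctl$met) return(finish(ctl, "control", "CONTROL", NA_character_))

  call_out("UNCLASSIFIED")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("<phenotype_call> %s: %s%s\n", x$patient_id, x$status,
              if (!is.na(x$index_date)) paste0(" (index ", x$index_date, ")") else ""))
  cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

#' Phenotype an entire cohort
#'
#' @param cohort a [study_cohort()].
#' @param dict a [med_dictionary()]; defaults to the bundled dictionary.
#' @param cfg an [exclusion_config()].
#' @param opts a [phenotype_options()] list.
#' @return List with `calls` (data.frame: `patient_id`, `status`,
#'   `index_date`, `algorithm`, `reasons` collapsed with `" | "`) and
#'   `summary` (class `phenotype_summary`: counts by status, by case
#'   algorithm, and by site).
#' @export
phenotype_cohort <- function(cohort, dict = default_med_dictionary(),
                             cfg = exclusion_config(),
                             opts = phenotype_options()) {
  ids <- cohort$demographics$patient_id
  calls <- lapply(ids, function(id)
    classify(patient_record(cohort, id), dict, cfg, opts))
  df <- data.frame(
    patient_id = ids,
    status = vapply(calls, `[[`, character(1), "status"),
    index_date = as.Date(vapply(calls, function(x)
      as.numeric(x$index_date), numeric(1)), origin = "1970-01-01"),
    algorithm = vapply(calls, `[[`, character(1), "algorithm"),
    reasons = vapply(calls, function(x) paste(x$reasons, collapse = " | "),
                     character(1)),
    stringsAsFactors = FALSE)
  by_status <- vapply(PHENOTYPE_STATUSES, function(s) sum(df$status == s),
                      integer(1))
  by_alg <- c(controlled = sum(df$algorithm %in% "controlled" &
                                 df$status == "CASE_CONTROLLED"),
              uncontrolled = sum(df$algorithm %in% "uncontrolled" &
                                   df$status == "CASE_UNCONTROLLED"))
  by_site <- table(site = cohort$demographics$site, status = df$status)
  summary <- structure(list(n = length(ids), by_status = by_status,
                            by_algorithm = by_alg, by_site = by_site),
                       class = "phenotype_summary")
  list(calls = df, summary = summary)
}

#' @export
print.phenotype_summary <- function(x, ...) {
  cat(sprintf("<phenotype_summary> %d patients\n", x$n))
  for (s in names(x$by_status))
    cat(sprintf("  %-17s %6d\n", s, x$by_status[[s]]))
  cat(sprintf("  case algorithms: controlled %d, uncontrolled %d\n",
              x$by_algorithm[["controlled"]], x$by_algorithm[["uncontrolled"]]))
  invisible(x)
}
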