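#' Cohort archetypes emitted by the simulator
#'
#' Each archetype instantiates exactly one branch of the phenotyping logic:
#' `case_controlled` (four concurrent classes, BP controlled),
#' `case_uncontrolled` (three classes, persistent elevation after one month),
#' `control` (one class at a time, controlled thereafter),
#' `near_miss_pseudoresistant` (three classes but elevation only before the
#' one-month lag, so no definition is met), `excluded_ckd` and `excluded_hf`
#' (case criteria met but an exclusion fires), and `unclassified`
#' (normotensive, untreated).
#'
#' @export
ARCHETYPES <- c("case_controlled", "case_uncontrolled", "control",
                "near_miss_pseudoresistant", "excluded_ckd", "excluded_hf",
                "unclassified")

ARCHETYPE_STATUS <- c(case_controlled = "CASE_CONTROLLED",
                      case_uncontrolled = "CASE_UNCONTROLLED",
                      control = "CONTROL",
                      near_miss_pseudoresistant = "UNCLASSIFIED",
                      excluded_ckd = "EXCLUDED",
                      excluded_hf = "EXCLUDED",
                      unclassified = "UNCLASSIFIED")

#' Specification for cohort simulation
#'
#' @param n_per_archetype named integer vector with one count per
#'   [ARCHETYPES] entry (missing names default to 0).
#' @param seed integer RNG seed; a fixed seed reproduces the cohort
#'   bit-for-bit.
#' @param date_start,date_end bounds of the simulated study era.
#' @param bp_noise_sd standard deviation (mm Hg) of the Gaussian noise added
#'   to blood-pressure templates. Noise is truncated at 2.5 SD so that, with
#'   the templates' guard margins, it can never flip a planted label.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_per_archetype = stats::setNames(rep(100L, 7L), ARCHETYPES),
                            seed = 1L,
                            date_start = "2000-01-01", date_end = "2007-12-31",
                            bp_noise_sd = 4) {
  full <- stats::setNames(rep(0L, length(ARCHETYPES)), ARCHETYPES)
  bad <- setdiff(names(n_per_archetype), ARCHETYPES)
  if (length(bad)) stop2("unknown archetype(s): ", paste(bad, collapse = ", "))
  full[names(n_per_archetype)] <- as.integer(n_per_archetype)
  if (any(full < 0L)) stop2("archetype counts must be >= 0")
  date_start <- as.Date(date_start); date_end <- as.Date(date_end)
  if (as.numeric(date_end - date_start) < 900)
    stop2("date span must cover at least 900 days")
  stopifnot(bp_noise_sd >= 0)
  structure(list(n_per_archetype = full, seed = as.integer(seed),
                 date_start = date_start, date_end = date_end,
                 bp_noise_sd = bp_noise_sd),
            class = "cohort_sim_spec")
}

# one builder per event kind; builders append rows to environment `acc`
acc_add <- function(acc, table, row) {
  acc[[table]][[length(acc[[table]]) + 1L]] <- row
  invisible(NULL)
}

sim_bp <- function(acc, id, dates, sbp, dbp, sd) {
  n <- length(dates)
  acc_add(acc, "bp", data.frame(
    patient_id = id, date = dates,
    sbp = round(sbp + tnorm(n, sd), 1), dbp = round(dbp + tnorm(n, sd), 1),
    stringsAsFactors = FALSE))
}

# refills every 90 days covering [from, from+360), one drug per class
sim_refills <- function(acc, id, from, classes, class_drugs) {
  for (cl in classes) {
    drug <- sample(class_drugs[[cl]], 1L)
    acc_add(acc, "meds", data.frame(
      patient_id = id, date = from + c(0, 90, 180, 270), drug_name = drug,
      source = "refill", document_id = "", days_supply = 90L,
      has_sig_attribute = NA, stringsAsFactors = FALSE))
  }
}

sim_med_list <- function(acc, id, date, classes, class_drugs, doc) {
  for (cl in classes) {
    acc_add(acc, "meds", data.frame(
      patient_id = id, date = date, drug_name = sample(class_drugs[[cl]], 1L),
      source = "list_mention", document_id = doc, days_supply = NA_integer_,
      has_sig_attribute = TRUE, stringsAsFactors = FALSE))
  }
}

#' Simulate a study cohort with planted phenotype labels
#'
#' Generates one patient per archetype count, each constructed so that it
#' satisfies exactly its archetype's defining rules (blood-pressure
#' trajectories before/after treatment, overlapping medication refills,
#' exclusion-triggering labs or ejection fractions) and unambiguously
#' violates all others. The truth table records the planted archetype, the
#' phenotype status the classifier must assign, and a two-subpopulation
#' ancestry assignment used downstream by the genotype simulator.
#'
#' @param spec a [cohort_sim_spec()].
#' @param dict a [med_dictionary()] supplying drug names per class.
#' @return List with `cohort` (a [study_cohort()]) and `truth` (data.frame:
#'   `patient_id`, `archetype`, `expected_status`, `subpop`).
#' @export
simulate_cohort <- function(spec, dict = default_med_dictionary()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  class_drugs <- split(names(dict$mapping), dict$mapping)
  if (!all(MED_CLASSES %in% names(class_drugs)))
    stop2("dictionary must name at least one drug in every class")
  acc <- new.env(parent = emptyenv())
  for (tb in names(COHORT_SCHEMA)) acc[[tb]] <- list()
  truth <- list()
  sd <- spec$bp_noise_sd
  span <- as.numeric(spec$date_end - spec$date_start)
  idx <- 0L

  for (arch in ARCHETYPES) {
    for (i in seq_len(spec$n_per_archetype[[arch]])) {
      idx <- idx + 1L
      id <- sprintf("P%05d", idx)
      race <- sample(c("european_american", "african_american"), 1L,
                     prob = c(0.7, 0.3))
      acc_add(acc, "demographics", data.frame(
        patient_id = id, sex = sample(SEXES, 1L),
        birth_decade = sample(c(1930L, 1940L, 1950L), 1L),
        race_ethnicity = race, site = sample(c("VU", "MFC"), 1L),
        platform = if (race == "european_american") "illumina_660" else "illumina_1m",
        stringsAsFactors = FALSE))
      truth[[idx]] <- data.frame(
        patient_id = id, archetype = arch,
        expected_status = ARCHETYPE_STATUS[[arch]],
        subpop = if (race == "european_american") 1L else 2L,
        stringsAsFactors = FALSE)
      t0 <- spec$date_start + sample.int(span - 800L, 1L) + 200L
      acc_add(acc, "bmi", data.frame(
        patient_id = id, date = t0 + c(-30, 30),
        bmi = round(29 + tnorm(2, 2), 1), stringsAsFactors = FALSE))

      hypertensive <- arch != "unclassified"
      if (hypertensive) {
        sim_bp(acc, id, t0 - c(60, 30), 158, 98, sd)   # untreated, elevated
        acc_add(acc, "dx", data.frame(patient_id = id, date = t0 - 30,
                                      code = "401.1", stringsAsFactors = FALSE))
        acc_add(acc, "labs", data.frame(patient_id = id, date = t0 - 10,
                                        analyte = "serum_creatinine",
                                        value = round(0.9 + tnorm(1, 0.05), 2),
                                        stringsAsFactors = FALSE))
      }

      if (arch %in% c("case_controlled", "excluded_ckd", "excluded_hf")) {
        classes <- sample(MED_CLASSES, 4L)
        sim_refills(acc, id, t0, classes, class_drugs)
        sim_med_list(acc, id, t0, classes, class_drugs, paste0("doc-", id))
        sim_bp(acc, id, t0 + c(60, 150), 120, 76, sd)  # controlled on therapy
        if (arch == "excluded_ckd")
          acc_add(acc, "labs", data.frame(patient_id = id, date = t0 + 60,
                                          analyte = "serum_creatinine",
                                          value = 3.5, stringsAsFactors = FALSE))
        if (arch == "excluded_hf")
          acc_add(acc, "ef", data.frame(patient_id = id, date = t0 + 40,
                                        ef_percent = 28, stringsAsFactors = FALSE))
        else if (arch == "case_controlled")
          acc_add(acc, "ef", data.frame(patient_id = id, date = t0 + 20,
                                        ef_percent = 60, stringsAsFactors = FALSE))
      } else if (arch == "case_uncontrolled") {
        classes <- sample(MED_CLASSES, 3L)
        sim_refills(acc, id, t0, classes, class_drugs)
        sim_bp(acc, id, t0 + c(45, 120), 158, 98, sd)  # still elevated on therapy
      } else if (arch == "near_miss_pseudoresistant") {
        classes <- sample(MED_CLASSES, 3L)
        sim_refills(acc, id, t0, classes, class_drugs)
        sim_bp(acc, id, t0 + 10, 158, 98, sd)          # elevated only inside the lag
        sim_bp(acc, id, t0 + c(60, 150), 120, 76, sd)
      } else if (arch == "control") {
        cl <- sample(MED_CLASSES, 1L)
        sim_refills(acc, id, t0, cl, class_drugs)
        sim_bp(acc, id, t0 + c(45, 150), 120, 76, sd)
      } else if (arch == "unclassified") {
        sim_bp(acc, id, t0 + c(-30, 30), 118, 74, sd)
      }
    }
  }

  tabs <- lapply(stats::setNames(names(COHORT_SCHEMA), names(COHORT_SCHEMA)),
                 function(tb) {
                   rows <- acc[[tb]]
                   if (length(rows) == 0L) empty_cohort_table(tb)
                   else do.call(rbind, rows)
                 })
  # meds table needs all schema columns in order
  cohort <- study_cohort(tabs$demographics, tabs$bp, tabs$meds, tabs$labs,
                         tabs$dx, tabs$ef, tabs$bmi)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(patient_id = character(), archetype = character(),
               expected_status = character(), subpop = integer(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(cohort = cohort, truth = truth)
}
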