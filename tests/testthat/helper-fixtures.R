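# shared fixtures: a small dictionary, a patient-record builder with
# day-offset dates, and independent oracles used across test files

ORIGIN <- as.Date("2003-01-01")

tiny_dict <- function() {
  med_dictionary(c(drugA = "ACEI_ARB", drugB = "BETA_BLOCKER",
                   drugC = "LOOP_DIURETIC", drugD = "DHP_CCB",
                   drugE = "CENTRAL_ALPHA_AGONIST",
                   hydralazine = "HYDRALAZINE",
                   hctz = "THIAZIDE_DIURETIC"),
                 excluded = c("phentolamine", "phenoxybenzamine"))
}

# builders take day offsets from ORIGIN; NULL tables stay empty
bp_rows <- function(day, sbp, dbp)
  data.frame(patient_id = "p1", date = ORIGIN + day, sbp = sbp, dbp = dbp)

refill_rows <- function(day, drug, days_supply = 90L)
  data.frame(patient_id = "p1", date = ORIGIN + day, drug_name = drug,
             source = "refill", document_id = "", days_supply = as.integer(days_supply),
             has_sig_attribute = NA)

mention_rows <- function(day, drug, doc = "doc1", sig = TRUE)
  data.frame(patient_id = "p1", date = ORIGIN + day, drug_name = drug,
             source = "list_mention", document_id = doc,
             days_supply = NA_integer_, has_sig_attribute = sig)

rx_rows <- function(day, drug)
  data.frame(patient_id = "p1", date = ORIGIN + day, drug_name = drug,
             source = "structured_rx", document_id = "",
             days_supply = NA_integer_, has_sig_attribute = NA)

lab_rows <- function(day, value, analyte = "serum_creatinine")
  data.frame(patient_id = "p1", date = ORIGIN + day, analyte = analyte,
             value = value)

dx_rows <- function(day, code)
  data.frame(patient_id = "p1", date = ORIGIN + day, code = code)

ef_rows <- function(day, ef)
  data.frame(patient_id = "p1", date = ORIGIN + day, ef_percent = ef)

bmi_rows <- function(day, bmi)
  data.frame(patient_id = "p1", date = ORIGIN + day, bmi = bmi)

make_record <- function(bps = NULL, meds = NULL, labs = NULL, dx = NULL,
                        ef = NULL, bmi = NULL, sex = "male",
                        birth_decade = 1940L, race = "european_american") {
  demo <- data.frame(patient_id = "p1", sex = sex, birth_decade = birth_decade,
                     race_ethnicity = race, site = "VU",
                     platform = "illumina_660")
  cohort <- study_cohort(demo, bp = bps, meds = meds, labs = labs, dx = dx,
                         ef = ef, bmi = bmi)
  patient_record(cohort, "p1")
}

# --- independent oracles ---------------------------------------------------

# per-day brute-force concurrency: count distinct classes covering each day
oracle_daily_counts <- function(meds, dict, mention_window_days, days) {
  cls <- classify_drug(meds$drug_name, dict)
  ok <- valid_mention(meds) & !is.na(cls)
  meds <- meds[ok, , drop = FALSE]; cls <- cls[ok]
  dur <- ifelse(meds$source == "refill", meds$days_supply, mention_window_days)
  vapply(as.list(days), function(d) {
    covered <- meds$date <= d & d < meds$date + dur
    length(unique(cls[covered]))
  }, integer(1))
}

# Wigginton-style recurrence for the exact HWE het distribution
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n - nA
  hets <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  probs <- numeric(length(hets))
  mid <- length(hets) %/% 2 + 1L
  probs[mid] <- 1
  if (mid < length(hets)) for (i in mid:(length(hets) - 1L)) {
    h <- hets[i]
    probs[i + 1L] <- probs[i] * 4 * ((nA - h) / 2) * ((na - h) / 2) /
      ((h + 2) * (h + 1))
  }
  if (mid > 1L) for (i in mid:2L) {
    h <- hets[i]
    probs[i - 1L] <- probs[i] * h * (h - 1) /
      (4 * ((nA - h) / 2 + 1) * ((na - h) / 2 + 1))
  }
  probs <- probs / sum(probs)
  obs <- match(n_Aa, hets)
  sum(probs[probs <= probs[obs] * (1 + 1e-9)])
}

# closed-form 2x2 odds ratio and Wald CI for a binary exposure
oracle_2x2 <- function(a, b, c, d) {
  # a = exposed cases, b = unexposed cases, c = exposed controls, d = unexposed
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- abs(log(or)) / se
  list(or = or, ci = exp(log(or) + c(-1, 1) * qnorm(0.975) * se),
       p = 2 * pnorm(-z), beta = log(or), se = se)
}
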