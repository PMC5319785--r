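#' Enumerations used by the cohort data model
#'
#' `SEXES`, `RACE_ETHNICITIES`, `MED_SOURCES` and `PHENOTYPE_STATUSES` are the
#' closed vocabularies accepted by the cohort tables and produced by the
#' phenotyper.
#'
#' @name enumerations
#' @keywords datasets
NULL

#' @rdname enumerations
#' @export
SEXES <- c("male", "female")

#' @rdname enumerations
#' @export
RACE_ETHNICITIES <- c("european_american", "african_american", "hispanic", "other")

#' @rdname enumerations
#' @export
MED_SOURCES <- c("structured_rx", "list_mention", "refill")

#' @rdname enumerations
#' @export
PHENOTYPE_STATUSES <- c("CASE_CONTROLLED", "CASE_UNCONTROLLED", "CONTROL",
                        "EXCLUDED", "UNCLASSIFIED")

# table name -> (column -> type). Types: chr, date, num, int, lgl.
COHORT_SCHEMA <- list(
  demographics = c(patient_id = "chr", sex = "chr", birth_decade = "int",
                   race_ethnicity = "chr", site = "chr", platform = "chr"),
  bp   = c(patient_id = "chr", date = "date", sbp = "num", dbp = "num"),
  meds = c(patient_id = "chr", date = "date", drug_name = "chr", source = "chr",
           document_id = "chr", days_supply = "int", has_sig_attribute = "lgl"),
  labs = c(patient_id = "chr", date = "date", analyte = "chr", value = "num"),
  dx   = c(patient_id = "chr", date = "date", code = "chr"),
  ef   = c(patient_id = "chr", date = "date", ef_percent = "num"),
  bmi  = c(patient_id = "chr", date = "date", bmi = "num")
)

empty_cohort_table <- function(name) {
  spec <- COHORT_SCHEMA[[name]]
  cols <- lapply(spec, function(t) switch(t,
    chr = character(), date = as.Date(character()), num = numeric(),
    int = integer(), lgl = logical()))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

coerce_cohort_table <- function(df, name, file = NULL) {
  spec <- COHORT_SCHEMA[[name]]
  where <- if (is.null(file)) name else file
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols))
    stop2(sprintf("%s: missing required column(s): %s", where,
                  paste(missing_cols, collapse = ", ")))
  df <- df[names(spec)]
  for (col in names(spec)) {
    x <- df[[col]]
    df[[col]] <- switch(spec[[col]],
      chr  = { x <- as.character(x); x[is.na(x)] <- ""; trimws(x) },
      date = as_date_strict(x, what = paste0(col, " value"), file = file),
      num  = {
        if (is.character(x)) x[!nzchar(trimws(x))] <- NA
        y <- suppressWarnings(as.numeric(x))
        bad <- which(!is.na(x) & nzchar(trimws(as.character(x))) & is.na(y))
        if (length(bad))
          stop2(sprintf("%s line %d: unparseable number %s in column %s",
                        where, bad[1L] + 1L, dQuote(as.character(x)[bad[1L]]), col))
        y
      },
      int  = {
        if (is.character(x)) x[!nzchar(trimws(x))] <- NA
        y <- suppressWarnings(as.integer(x))
        bad <- which(!is.na(x) & nzchar(trimws(as.character(x))) & is.na(y))
        if (length(bad))
          stop2(sprintf("%s line %d: unparseable integer %s in column %s",
                        where, bad[1L] + 1L, dQuote(as.character(x)[bad[1L]]), col))
        y
      },
      lgl  = {
        if (is.logical(x)) x else {
          x <- tolower(trimws(as.character(x)))
          y <- rep(NA, length(x))
          y[x %in% c("true", "t", "1")] <- TRUE
          y[x %in% c("false", "f", "0")] <- FALSE
          bad <- which(nzchar(x) & is.na(y))
          if (length(bad))
            stop2(sprintf("%s line %d: unparseable boolean %s in column %s",
                          where, bad[1L] + 1L, dQuote(x[bad[1L]]), col))
          y
        }
      })
  }
  df
}

validate_cohort_table <- function(df, name, file = NULL) {
  where <- if (is.null(file)) name else file
  fail <- function(rows, msg) {
    if (any(rows, na.rm = TRUE))
      stop2(sprintf("%s line %d: %s", where, which(rows)[1L] + 1L, msg))
  }
  if (name == "demographics") {
    fail(!df$sex %in% SEXES, "sex must be one of: male, female")
    fail(!df$race_ethnicity %in% RACE_ETHNICITIES,
         paste("race_ethnicity must be one of:", paste(RACE_ETHNICITIES, collapse = ", ")))
    fail(is.na(df$birth_decade) | df$birth_decade %% 10L != 0L,
         "birth_decade must be a year divisible by 10")
    fail(!nzchar(df$patient_id), "patient_id must be non-empty")
    if (anyDuplicated(df$patient_id))
      stop2(sprintf("%s: duplicate patient_id %s", where,
                    dQuote(df$patient_id[duplicated(df$patient_id)][1L])))
  } else {
    fail(is.na(df$date), "missing date")
  }
  if (name == "bp") {
    fail(!(df$sbp > df$dbp & df$dbp > 0), "requires sbp > dbp > 0")
  }
  if (name == "meds") {
    fail(!df$source %in% MED_SOURCES,
         paste("source must be one of:", paste(MED_SOURCES, collapse = ", ")))
    fail(df$source == "refill" & (is.na(df$days_supply) | df$days_supply < 1L),
         "refill events require days_supply >= 1")
    fail(df$source == "list_mention" & !nzchar(df$document_id),
         "list_mention events require a document_id")
    fail(!nzchar(df$drug_name), "drug_name must be non-empty")
  }
  if (name == "labs") fail(!(df$value > 0), "lab value must be > 0")
  if (name == "dx") fail(!nzchar(df$code), "code must be non-empty")
  if (name == "ef") fail(!(df$ef_percent > 0 & df$ef_percent <= 100),
                         "ef_percent must be in (0, 100]")
  if (name == "bmi") fail(!(df$bmi > 0), "bmi must be > 0")
  invisible(df)
}

#' Construct a study cohort from its component tables
#'
#' A `study_cohort` bundles the demographics table with the six longitudinal
#' event tables (blood pressure, medications, labs, diagnosis codes, ejection
#' fraction, BMI). All invariants of the data model are established here:
#' column types are coerced, enumerated fields checked, event rows with a
#' `patient_id` absent from `demographics` rejected, and every event table is
#' sorted by (`patient_id`, `date`).
#'
#' @param demographics data.frame with columns
#'   `patient_id,sex,birth_decade,race_ethnicity,site,platform`.
#' @param bp,meds,labs,dx,ef,bmi event tables; see `COHORT_SCHEMA` for the
#'   required columns. Missing tables default to empty.
#' @param files optional named character vector of source file names, used only
#'   to produce `file:line` error messages.
#' @return An object of class `study_cohort`: a named list of validated
#'   data.frames.
#' @seealso [read_cohort()], [write_cohort()], [patient_record()]
#' @export
study_cohort <- function(demographics, bp = NULL, meds = NULL, labs = NULL,
                         dx = NULL, ef = NULL, bmi = NULL, files = NULL) {
  tabs <- list(demographics = demographics, bp = bp, meds = meds, labs = labs,
               dx = dx, ef = ef, bmi = bmi)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) tabs[[nm]] <- empty_cohort_table(nm)
    file <- if (!is.null(files) && nm %in% names(files)) files[[nm]] else NULL
    tabs[[nm]] <- coerce_cohort_table(tabs[[nm]], nm, file)
    validate_cohort_table(tabs[[nm]], nm, file)
  }
  ids <- tabs$demographics$patient_id
  for (nm in setdiff(names(tabs), "demographics")) {
    orphan <- !tabs[[nm]]$patient_id %in% ids
    if (any(orphan)) {
      file <- if (!is.null(files) && nm %in% names(files)) files[[nm]] else nm
      stop2(sprintf("%s line %d: patient_id %s has no demographics row",
                    file, which(orphan)[1L] + 1L,
                    dQuote(tabs[[nm]]$patient_id[orphan][1L])))
    }
    ord <- order(tabs[[nm]]$patient_id, tabs[[nm]]$date)
    tabs[[nm]] <- tabs[[nm]][ord, , drop = FALSE]
    rownames(tabs[[nm]]) <- NULL
  }
  rownames(tabs$demographics) <- NULL
  structure(tabs, class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("<study_cohort> %d patients\n", nrow(x$demographics)))
  for (nm in setdiff(names(COHORT_SCHEMA), "demographics"))
    cat(sprintf("  %-5s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' @export
format.study_cohort <- function(x, ...) {
  sprintf("<study_cohort> %d patients", nrow(x$demographics))
}

cohort_file_names <- function(dir) {
  stats::setNames(file.path(dir, paste0(names(COHORT_SCHEMA), ".csv")),
                  names(COHORT_SCHEMA))
}

#' Read a study cohort from a directory of delimited tables
#'
#' Expects `demographics.csv`, `bp.csv`, `meds.csv`, `labs.csv`, `dx.csv`,
#' `ef.csv` and `bmi.csv` (UTF-8, comma-delimited, one header line; empty
#' fields blank, booleans `true`/`false`, dates ISO-8601). Lines starting with
#' `#` are treated as comments. Errors name the offending file and line.
#'
#' @param dir directory containing the seven tables.
#' @return A validated [study_cohort()].
#' @export
read_cohort <- function(dir) {
  paths <- cohort_file_names(dir)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop2("missing cohort file(s): ", paste(missing, collapse = ", "))
  raw <- lapply(paths, function(p)
    utils::read.csv(p, colClasses = "character", comment.char = "#",
                    na.strings = NULL, check.names = TRUE))
  do.call(study_cohort, c(unname(raw[names(COHORT_SCHEMA)]),
                          list(files = stats::setNames(basename(paths),
                                                       names(paths)))))
}

format_cohort_col <- function(x) {
  if (inherits(x, "Date")) return(ifelse(is.na(x), "", format(x, "%Y-%m-%d")))
  if (is.logical(x)) return(ifelse(is.na(x), "", ifelse(x, "true", "false")))
  ifelse(is.na(x), "", as.character(x))
}

#' Write a study cohort to a directory of delimited tables
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, d))` reproduces
#' `x` exactly.
#'
#' @param cohort a [study_cohort()].
#' @param dir output directory (created if needed).
#' @param comment optional single string written as a leading `# ...` line in
#'   every file (used by the pipeline to stamp the run's config hash).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, comment = NULL) {
  stopifnot(inherits(cohort, "study_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop2("cannot create directory ", dir)
  paths <- cohort_file_names(dir)
  for (nm in names(COHORT_SCHEMA)) {
    df <- cohort[[nm]]
    out <- as.data.frame(lapply(df, format_cohort_col), stringsAsFactors = FALSE,
                         check.names = FALSE, optional = TRUE)
    if (ncol(out) == 0L) out <- df
    con <- file(paths[[nm]], "w")
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE,
                       col.names = TRUE)
    close(con)
  }
  invisible(dir)
}

#' Extract one patient's longitudinal record
#'
#' @param cohort a [study_cohort()].
#' @param patient_id a patient identifier present in the cohort.
#' @return An object of class `patient_record`: demographics as a one-row
#'   list plus the patient's slices of the six event tables (`bps`, `meds`,
#'   `labs`, `codes`, `efs`, `bmis`), each sorted by date.
#' @export
patient_record <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "study_cohort"), is_string(patient_id))
  i <- match(patient_id, cohort$demographics$patient_id)
  if (is.na(i)) stop2("unknown patient_id ", dQuote(patient_id))
  slice <- function(nm) {
    df <- cohort[[nm]]
    df[df$patient_id == patient_id, , drop = FALSE]
  }
  structure(list(
    demographics = as.list(cohort$demographics[i, , drop = FALSE]),
    bps = slice("bp"), meds = slice("meds"), labs = slice("labs"),
    codes = slice("dx"), efs = slice("ef"), bmis = slice("bmi")
  ), class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (%s, born %ds, %s)\n",
              x$demographics$patient_id, x$demographics$sex,
              x$demographics$birth_decade, x$demographics$race_ethnicity))
  cat(sprintf("  bp: %d  meds: %d  labs: %d  codes: %d  ef: %d  bmi: %d\n",
              nrow(x$bps), nrow(x$meds), nrow(x$labs), nrow(x$codes),
              nrow(x$efs), nrow(x$bmis)))
  invisible(x)
}

#' Median BMI of a patient record
#'
#' The covariate used for confounder adjustment in the association model.
#' Invariant to the ordering of the measurements.
#'
#' @param record a [patient_record()].
#' @return The median of all BMI values (kg/m^2), or `NA_real_` when the
#'   record has no BMI measurements.
#' @export
median_bmi <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  if (nrow(record$bmis) == 0L) return(NA_real_)
  stats::median(record$bmis$bmi)
}
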