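#' Antihypertensive medication classes
#'
#' The 13 medication classes the phenotyping algorithm counts when assessing
#' concurrent antihypertensive therapy: ACE inhibitors / angiotensin receptor
#' blockers (one class), beta blockers, the two calcium-channel-blocker
#' subtypes, hydralazine, minoxidil, central alpha agonists, direct renin
#' antagonists, aldosterone antagonists, alpha antagonists, and the three
#' diuretic subtypes. Direct alpha antagonists (phentolamine,
#' phenoxybenzamine) are deliberately not a class: they mark pathologic
#' adrenergic states which are excluded from the study.
#'
#' @export
MED_CLASSES <- c("ACEI_ARB", "BETA_BLOCKER", "NONDHP_CCB", "DHP_CCB",
                 "HYDRALAZINE", "MINOXIDIL", "CENTRAL_ALPHA_AGONIST",
                 "DIRECT_RENIN_ANTAGONIST", "ALDOSTERONE_ANTAGONIST",
                 "ALPHA_ANTAGONIST", "THIAZIDE_DIURETIC",
                 "K_SPARING_DIURETIC", "LOOP_DIURETIC")

DIURETIC_CLASSES <- c("THIAZIDE_DIURETIC", "K_SPARING_DIURETIC", "LOOP_DIURETIC")

#' Build a drug-name to medication-class dictionary
#'
#' @param mapping named character vector: names are drug names (matched
#'   case-insensitively after trimming), values are elements of
#'   [MED_CLASSES].
#' @param excluded character vector of drug names that must never classify
#'   (direct alpha antagonists).
#' @return An object of class `med_dictionary`.
#' @export
med_dictionary <- function(mapping, excluded = character()) {
  nm <- tolower(trimws(names(mapping)))
  mapping <- stats::setNames(as.character(mapping), nm)
  excluded <- tolower(trimws(excluded))
  if (any(!nzchar(nm))) stop2("empty drug name in dictionary")
  dup <- unique(nm[duplicated(nm)])
  for (d in dup)
    if (length(unique(mapping[names(mapping) == d])) > 1L)
      stop2("drug ", dQuote(d), " maps to more than one class")
  mapping <- mapping[!duplicated(names(mapping))]
  bad <- setdiff(unique(mapping), MED_CLASSES)
  if (length(bad)) stop2("unknown medication class(es): ", paste(bad, collapse = ", "))
  clash <- intersect(names(mapping), excluded)
  if (length(clash))
    stop2("drug(s) both mapped and excluded: ", paste(clash, collapse = ", "))
  structure(list(mapping = mapping, excluded = unique(excluded)),
            class = "med_dictionary")
}

#' @export
print.med_dictionary <- function(x, ...) {
  cat(sprintf("<med_dictionary> %d drugs in %d classes, %d excluded names\n",
              length(x$mapping), length(unique(x$mapping)), length(x$excluded)))
  invisible(x)
}

#' Read a medication-class dictionary from a delimited file
#'
#' The file has columns `drug_name,med_class`; rows whose `med_class` is the
#' literal `EXCLUDED` populate the excluded-name set.
#'
#' @param path CSV file path.
#' @return A [med_dictionary()].
#' @export
read_med_dictionary <- function(path) {
  if (!file.exists(path)) stop2("medication dictionary not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#")
  for (col in c("drug_name", "med_class"))
    if (!col %in% names(df)) stop2(path, ": missing required column ", col)
  excl <- df$drug_name[df$med_class == "EXCLUDED"]
  df <- df[df$med_class != "EXCLUDED", , drop = FALSE]
  med_dictionary(stats::setNames(df$med_class, df$drug_name), excl)
}

#' The bundled starter dictionary of common antihypertensive agents
#'
#' A generic-name dictionary covering widely prescribed agents in each of the
#' 13 classes, shipped as editable CSV in `extdata/med_classes.csv`. Real
#' deployments should extend it with local formulary names.
#'
#' @return A [med_dictionary()].
#' @export
default_med_dictionary <- function() {
  read_med_dictionary(system.file("extdata", "med_classes.csv",
                                  package = "rhtn", mustWork = TRUE))
}

#' Map drug names to antihypertensive medication classes
#'
#' Case-insensitive exact-name lookup. Unknown names and names on the
#' dictionary's excluded list yield `NA` (the event does not count toward any
#' class).
#'
#' @param name character vector of drug names.
#' @param dict a [med_dictionary()].
#' @param collapse_diuretics if `TRUE`, the three diuretic subtypes are
#'   reported as a single `"DIURETIC"` class (AHA-style counting); by default
#'   they count as three distinct classes, as the algorithm enumerates them.
#' @return Character vector of class labels, `NA` where unclassifiable.
#' @export
classify_drug <- function(name, dict, collapse_diuretics = FALSE) {
  stopifnot(inherits(dict, "med_dictionary"))
  key <- tolower(trimws(name))
  out <- unname(dict$mapping[key])
  out[key %in% dict$excluded] <- NA_character_
  if (collapse_diuretics) out[out %in% DIURETIC_CLASSES] <- "DIURETIC"
  out
}

#' Is a medication event a valid prescribed-medication mention?
#'
#' Medication-list mentions extracted from free text only count when a sig
#' attribute (dose, strength, route, or frequency) accompanies the name;
#' structured prescriptions and refills always count.
#'
#' @param meds a `meds` event table (or a patient record's `$meds`).
#' @return Logical vector, one element per event.
#' @export
valid_mention <- function(meds) {
  meds$source != "list_mention" | (!is.na(meds$has_sig_attribute) & meds$has_sig_attribute)
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  outs <- out_e <- vector("list", length(start))
  k <- 0L
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      k <- k + 1L; outs[[k]] <- ms; out_e[[k]] <- me
      ms <- start[i]; me <- end[i]
    }
  }
  k <- k + 1L; outs[[k]] <- ms; out_e[[k]] <- me
  list(start = do.call(c, outs[seq_len(k)]), end = do.call(c, out_e[seq_len(k)]))
}

#' Medication-class exposure intervals for one patient
#'
#' Each valid, classifiable medication event contributes a half-open coverage
#' interval `[start, end)`: refills cover `days_supply` days from their date;
#' structured prescriptions and sig-validated list mentions cover
#' `mention_window_days` days (a default duration, since non-refill evidence
#' carries none). Overlapping intervals of the same class are merged.
#'
#' @param record a [patient_record()].
#' @param dict a [med_dictionary()].
#' @param mention_window_days assumed coverage of non-refill evidence (days).
#' @param collapse_diuretics see [classify_drug()].
#' @return data.frame with columns `med_class`, `start`, `end` (Dates;
#'   end-exclusive).
#' @export
exposure_intervals <- function(record, dict, mention_window_days = 90,
                               collapse_diuretics = FALSE) {
  stopifnot(mention_window_days >= 1)
  meds <- record$meds
  if (nrow(meds) == 0L)
    return(data.frame(med_class = character(), start = as.Date(character()),
                      end = as.Date(character()), stringsAsFactors = FALSE))
  cls <- classify_drug(meds$drug_name, dict, collapse_diuretics)
  keep <- valid_mention(meds) & !is.na(cls)
  meds <- meds[keep, , drop = FALSE]; cls <- cls[keep]
  if (nrow(meds) == 0L)
    return(data.frame(med_class = character(), start = as.Date(character()),
                      end = as.Date(character()), stringsAsFactors = FALSE))
  dur <- ifelse(meds$source == "refill", meds$days_supply, mention_window_days)
  start <- meds$date
  end <- meds$date + dur
  res <- lapply(split(seq_along(cls), cls), function(idx) {
    m <- merge_intervals(start[idx], end[idx])
    data.frame(med_class = cls[idx[1L]], start = m$start, end = m$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start, out$med_class), , drop = FALSE]
}

#' Count medication classes concurrently active on a date
#'
#' @param intervals output of [exposure_intervals()].
#' @param date a Date.
#' @return List with `count` (number of distinct classes whose interval
#'   covers `date`) and `classes` (their labels).
#' @export
concurrent_class_count <- function(intervals, date) {
  hit <- intervals$start <= date & date < intervals$end
  cls <- unique(intervals$med_class[hit])
  list(count = length(cls), classes = sort(cls))
}

#' Medication classes co-mentioned in medication lists on a date
#'
#' Co-mention of several classes in a single medication list (problem list,
#' clinic note, discharge summary) establishes same-day concurrency without
#' reference to coverage windows. Only sig-validated list mentions count; the
#' result is the union over all documents dated `date`.
#'
#' @inheritParams exposure_intervals
#' @param date a Date.
#' @return Character vector of class labels (possibly empty).
#' @export
same_list_concurrency <- function(record, dict, date, collapse_diuretics = FALSE) {
  meds <- record$meds
  sel <- meds$source == "list_mention" & meds$date == date & valid_mention(meds)
  cls <- classify_drug(meds$drug_name[sel], dict, collapse_diuretics)
  sort(unique(cls[!is.na(cls)]))
}

concurrency_candidate_dates <- function(record, intervals) {
  meds <- record$meds
  lm_dates <- meds$date[meds$source == "list_mention"]
  sort(unique(c(intervals$start, lm_dates)))
}

concurrency_at <- function(record, dict, intervals, date,
                           collapse_diuretics = FALSE) {
  max(concurrent_class_count(intervals, date)$count,
      length(same_list_concurrency(record, dict, date, collapse_diuretics)))
}

#' First date a patient is concurrently on at least k medication classes
#'
#' Concurrency is reached through either evidence route: `k` distinct classes
#' with overlapping coverage intervals, or `k` distinct classes co-mentioned
#' in medication lists on one date. Because concurrency only changes at
#' interval starts or list dates, those are the only dates examined.
#'
#' @inheritParams exposure_intervals
#' @param k required number of distinct classes (>= 1).
#' @return The earliest qualifying Date, or `NA` if concurrency never
#'   reaches `k`.
#' @export
first_date_with_k_classes <- function(record, dict, k, mention_window_days = 90,
                                      collapse_diuretics = FALSE) {
  stopifnot(k >= 1)
  iv <- exposure_intervals(record, dict, mention_window_days, collapse_diuretics)
  for (d in as.list(concurrency_candidate_dates(record, iv))) {
    if (concurrency_at(record, dict, iv, d, collapse_diuretics) >= k) return(d)
  }
  as.Date(NA)
}

#' Maximum concurrent medication-class count over a record's span
#'
#' Used by the control definition, which requires that a patient never has
#' more than one simultaneous medication class.
#'
#' @inheritParams first_date_with_k_classes
#' @return Integer: the maximum concurrency over all candidate dates (0 for
#'   a record with no classifiable events).
#' @export
max_concurrent_classes <- function(record, dict, mention_window_days = 90,
                                   collapse_diuretics = FALSE) {
  iv <- exposure_intervals(record, dict, mention_window_days, collapse_diuretics)
  dates <- concurrency_candidate_dates(record, iv)
  if (length(dates) == 0L) return(0L)
  max(vapply(as.list(dates), function(d)
    as.integer(concurrency_at(record, dict, iv, d, collapse_diuretics)),
    integer(1)))
}
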