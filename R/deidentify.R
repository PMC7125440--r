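#' Deidentification configuration
#'
#' Bundles the per-table column allow-lists, the key deny-list, and the age
#' cap that drive [deidentify_omop()], [deidentify_registry()] and
#' [phi_scan()]. The defaults follow a strict Safe Harbor reading: every
#' calendar date is replaced by an age in days since birth, direct
#' identifiers are dropped by key, and person-level ages above
#' `age_cap_years` are reported as the cap (ages over 89 are aggregated
#' under Safe Harbor; event-level day intervals are never capped, only the
#' single person-level age).
#'
#' @param age_cap_years Cap applied to person-level age in years (default 89).
#' @param cap_ages Whether the cap is applied at all (default `TRUE`).
#' @param deny_keys Character vector of forbidden manifest/document keys.
#' @return An object of class `deid_config`.
#' @export
deid_config <- function(age_cap_years = 89, cap_ages = TRUE,
                        deny_keys = default_deny_keys()) {
  allow <- omop_allowed_columns()
  overlap <- intersect(unlist(allow, use.names = FALSE), deny_keys)
  if (length(overlap)) {
    stop(errorCondition(paste0("allow-list and deny-list overlap: ",
                               paste(overlap, collapse = ", ")),
                        class = c("genetrust_config_error", "genetrust_error")))
  }
  structure(list(age_cap_years = as.integer(age_cap_years),
                 cap_ages = isTRUE(cap_ages),
                 deny_keys = tolower(deny_keys),
                 allow_omop = allow,
                 allow_registry = registry_allowed_columns()),
            class = "deid_config")
}

default_deny_keys <- function() {
  c("mrn", "medical_record_number", "name", "first_name", "last_name",
    "middle_name", "patient_name", "full_name", "maiden_name",
    "address", "street_address", "street", "city", "zip", "zip_code",
    "dob", "date_of_birth", "birth_date", "birth_datetime",
    "phone", "phone_number", "telephone", "fax",
    "email", "email_address", "ssn", "social_security_number",
    "contact", "contact_info", "next_of_kin")
}

# Output (deidentified) column allow-list per OMOP table; raw date columns are
# admitted implicitly through omop_date_columns() and leave as *_age_days.
omop_allowed_columns <- function() {
  list(
    person = c("person_id", "gender_concept_id", "ethnicity_concept_id",
               "race_concept_id", "age_years"),
    condition_occurrence = c("condition_occurrence_id", "person_id",
                             "condition_concept_id",
                             "condition_start_age_days"),
    procedure_occurrence = c("procedure_occurrence_id", "person_id",
                             "procedure_concept_id", "procedure_age_days"),
    drug_exposure = c("drug_exposure_id", "person_id", "drug_concept_id",
                      "drug_exposure_start_age_days",
                      "drug_exposure_end_age_days"),
    measurement = c("measurement_id", "person_id", "measurement_concept_id",
                    "measurement_age_days", "value_as_number")
  )
}

# raw date column -> deidentified age-days column, per table
omop_date_columns <- function() {
  list(
    condition_occurrence = c(condition_start_date = "condition_start_age_days"),
    procedure_occurrence = c(procedure_date = "procedure_age_days"),
    drug_exposure = c(drug_exposure_start_date = "drug_exposure_start_age_days",
                      drug_exposure_end_date = "drug_exposure_end_age_days"),
    measurement = c(measurement_date = "measurement_age_days")
  )
}

registry_allowed_columns <- function() {
  c("patient_id", "age_years", "sex", "spanish_origin", "race",
    "first_contact_age_days", "diagnosis_age_days",
    "dx_confirmation", "dx_staging_proc",
    "cancer_site_icdo3", "seer_site_group", "cancer_histology_icdo3",
    "chemo_text", "chemo_code",
    "chemo_start_age_days", "chemo_end_age_days", "completeness_state")
}

registry_date_columns <- function() {
  c(date_of_first_contact = "first_contact_age_days",
    date_of_diagnosis = "diagnosis_age_days",
    chemo_start_date = "chemo_start_age_days",
    chemo_end_date = "chemo_end_age_days")
}

#' Convert an event date to age in days since birth
#'
#' The whole-calendar-day difference between `event_date` and the date of
#' birth; an event on the birth date is day 0. The transform preserves
#' intervals exactly: two events d days apart map to ages d apart.
#'
#' @param event_date Date(s), as `Date` or `YYYY-MM-DD` text; vectorized.
#'   `NA`/empty entries pass through as `NA`.
#' @param birth Date of birth (scalar `Date` or `YYYY-MM-DD` text).
#' @return Integer vector of non-negative day counts.
#' @export
date_to_age_days <- function(event_date, birth) {
  birth <- parse_one_date(birth, "birth date")
  ev <- as.character(event_date)
  out <- rep(NA_integer_, length(ev))
  present <- !is.na(ev) & nzchar(ev)
  if (!any(present)) return(out)
  parsed <- as.Date(ev[present], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    stop(errorCondition(
      paste0("unparseable date: ", ev[present][is.na(parsed)][1L]),
      class = c("genetrust_date_error", "genetrust_error")))
  }
  days <- as.integer(parsed - birth)
  if (any(days < 0)) {
    stop(errorCondition("event date precedes date of birth",
                        class = c("genetrust_date_error", "genetrust_error")))
  }
  out[present] <- days
  out
}

parse_one_date <- function(x, what) {
  if (inherits(x, "Date")) {
    if (length(x) != 1L || is.na(x)) {
      stop(errorCondition(paste0("invalid ", what),
                          class = c("genetrust_date_error", "genetrust_error")))
    }
    return(x)
  }
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (length(d) != 1L || is.na(d)) {
    stop(errorCondition(paste0("invalid ", what, ": ", x),
                        class = c("genetrust_date_error", "genetrust_error")))
  }
  d
}

#' Deidentify an OMOP extract
#'
#' Replaces every date-typed column with an age-in-days integer column
#' (renamed `*_age_days`), drops any column outside the per-table allow-list,
#' and reduces the person record to concept identifiers plus a single
#' (optionally capped) age in years at extraction. The operation is
#' idempotent: applying it to an already-deidentified extract is the
#' identity.
#'
#' @param extract An [omop_extract()].
#' @param birth Patient date of birth; may be `NULL` when `extract` is
#'   already deidentified (no raw date columns remain).
#' @param config A [deid_config()].
#' @param extraction_date Reference date for the person-level age; defaults
#'   to the latest event date found in the extract.
#' @return A deidentified `omop_extract`.
#' @export
deidentify_omop <- function(extract, birth = NULL, config = deid_config(),
                            extraction_date = NULL) {
  stopifnot(inherits(extract, "omop_extract"))
  datecols <- omop_date_columns()
  allow <- config$allow_omop
  raw_dates <- character(0)
  for (tab in names(extract$tables)) {
    dc <- datecols[[tab]]
    have <- intersect(names(dc), names(extract$tables[[tab]]))
    raw_dates <- c(raw_dates, unlist(extract$tables[[tab]][have],
                                     use.names = FALSE))
  }
  raw_dates <- raw_dates[!is.na(raw_dates) & nzchar(raw_dates)]
  needs_dates <- length(raw_dates) > 0L
  if (needs_dates && is.null(birth)) {
    stop(errorCondition("date of birth required to convert date columns",
                        class = c("genetrust_date_error", "genetrust_error")))
  }

  out <- extract$tables
  for (tab in names(out)) {
    df <- out[[tab]]
    dc <- datecols[[tab]]
    for (raw_name in intersect(names(dc), names(df))) {
      df[[dc[[raw_name]]]] <- date_to_age_days(df[[raw_name]], birth)
      df[[raw_name]] <- NULL
    }
    if (tab == "person") {
      df <- deidentify_person(df, birth, config, extraction_date, raw_dates)
    }
    keep <- intersect(allow[[tab]] %||% character(0), names(df))
    out[[tab]] <- tibble::as_tibble(df[keep])
  }
  omop_extract(out, deidentified = TRUE)
}

deidentify_person <- function(df, birth, config, extraction_date, raw_dates) {
  if (!"age_years" %in% names(df)) {
    if (is.null(birth)) {
      stop(errorCondition("date of birth required to derive person age",
                          class = c("genetrust_date_error", "genetrust_error")))
    }
    ref <- if (!is.null(extraction_date)) {
      parse_one_date(extraction_date, "extraction date")
    } else if (length(raw_dates)) {
      max(as.Date(raw_dates, format = "%Y-%m-%d"), na.rm = TRUE)
    } else {
      stop(errorCondition(
        "no extraction_date given and no event dates to infer one from",
        class = c("genetrust_date_error", "genetrust_error")))
    }
    birth_d <- parse_one_date(birth, "birth date")
    df$age_years <- age_in_years(birth_d, ref)
  }
  if (config$cap_ages) {
    df$age_years <- pmin(df$age_years, config$age_cap_years)
  }
  df
}

# completed years between two calendar dates (birthday counting, not /365.25)
age_in_years <- function(birth, ref) {
  yb <- as.integer(format(birth, "%Y"))
  yr <- as.integer(format(ref, "%Y"))
  before_birthday <- format(ref, "%m%d") < format(birth, "%m%d")
  as.integer(yr - yb - before_birthday)
}

#' Deidentify a cancer-registry record set
#'
#' Converts the diagnosis, first-contact and treatment date fields to
#' age-in-days integers, drops every identifying column (name, MRN, date of
#' birth, contact fields), caps the person-level age, and keeps only the
#' registry allow-list columns. Idempotent.
#'
#' @param records Tibble of registry rows as returned by
#'   [read_registry_export()] (one row per patient), or an
#'   already-deidentified result.
#' @param birth Date of birth; may also be taken from a `date_of_birth`
#'   column in `records` when present. Required only if raw dates remain.
#' @param config A [deid_config()].
#' @return Tibble of deidentified registry rows.
#' @export
deidentify_registry <- function(records, birth = NULL, config = deid_config()) {
  records <- tibble::as_tibble(records)
  dc <- registry_date_columns()
  out_rows <- lapply(seq_len(nrow(records)), function(i) {
    row <- records[i, ]
    b <- birth
    if (is.null(b) && "date_of_birth" %in% names(row)) b <- row$date_of_birth
    for (raw_name in intersect(names(dc), names(row))) {
      row[[dc[[raw_name]]]] <- date_to_age_days(row[[raw_name]], b)
      row[[raw_name]] <- NULL
    }
    if (!"age_years" %in% names(row)) {
      if ("age" %in% names(row)) {
        row$age_years <- as.integer(row$age)
      } else if (!is.null(b) && "first_contact_age_days" %in% names(row) &&
                 !is.na(row$first_contact_age_days)) {
        row$age_years <- as.integer(floor(row$first_contact_age_days / 365.25))
      }
    }
    if (config$cap_ages && "age_years" %in% names(row)) {
      row$age_years <- pmin(row$age_years, config$age_cap_years)
    }
    row[intersect(config$allow_registry, names(row))]
  })
  do.call(rbind, out_rows)
}

#' Keep only somatic variants
#'
#' Germline variants are removed before sharing; variants of unknown origin
#' are dropped as well (the privacy-conservative default). Input order is
#' preserved.
#'
#' @param variants Tibble of variant calls with an `origin` column taking
#'   values in `somatic`, `germline`, `unknown-origin`.
#' @return The somatic subset, same columns, original order.
#' @export
filter_somatic <- function(variants) {
  variants <- tibble::as_tibble(variants)
  if (!"origin" %in% names(variants)) {
    stop(errorCondition("variants must carry an 'origin' column",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  bad <- setdiff(unique(variants$origin),
                 c("somatic", "germline", "unknown-origin"))
  if (length(bad)) {
    stop(errorCondition(paste0("unknown variant origin: ",
                               paste(bad, collapse = ", ")),
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  variants[variants$origin == "somatic", , drop = FALSE]
}
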