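#' OMOP extract container
#'
#' Holds per-patient row sets for the five OMOP CDM v5 tables of interest
#' (`person`, `condition_occurrence`, `procedure_occurrence`,
#' `drug_exposure`, `measurement`). Identified extracts carry real calendar
#' dates; deidentified ones carry `*_age_days` integer columns instead.
#'
#' @param tables Named list of tibbles, names drawn from the five tables.
#' @param deidentified Logical flag recorded on the object.
#' @return Object of class `omop_extract`.
#' @export
omop_extract <- function(tables, deidentified = FALSE) {
  unknown <- setdiff(names(tables), omop_table_names())
  if (length(unknown)) {
    stop(schema_error(paste0("unknown OMOP table: ",
                             paste(unknown, collapse = ", "))))
  }
  tables <- lapply(tables, tibble::as_tibble)
  tables <- tables[intersect(omop_table_names(), names(tables))]
  structure(list(tables = tables, deidentified = isTRUE(deidentified)),
            class = "omop_extract")
}

#' @export
print.omop_extract <- function(x, ...) {
  cat("<omop_extract>", if (x$deidentified) "(deidentified)" else "(identified)",
      "\n")
  for (tab in names(x$tables)) {
    cat("  ", tab, ": ", nrow(x$tables[[tab]]), " rows\n", sep = "")
  }
  invisible(x)
}

omop_table_names <- function() {
  c("person", "condition_occurrence", "procedure_occurrence",
    "drug_exposure", "measurement")
}

# recognized columns per table (identified and deidentified forms)
omop_known_columns <- function() {
  list(
    person = c("person_id", "gender_concept_id", "ethnicity_concept_id",
               "race_concept_id", "year_of_birth", "birth_datetime",
               "age_years"),
    condition_occurrence = c("condition_occurrence_id", "person_id",
                             "condition_concept_id", "condition_start_date",
                             "condition_start_age_days"),
    procedure_occurrence = c("procedure_occurrence_id", "person_id",
                             "procedure_concept_id", "procedure_date",
                             "procedure_age_days"),
    drug_exposure = c("drug_exposure_id", "person_id", "drug_concept_id",
                      "drug_exposure_start_date", "drug_exposure_end_date",
                      "drug_exposure_start_age_days",
                      "drug_exposure_end_age_days"),
    measurement = c("measurement_id", "person_id", "measurement_concept_id",
                    "measurement_date", "measurement_age_days",
                    "value_as_number")
  )
}

omop_required_columns <- function() {
  list(
    person = c("person_id", "gender_concept_id", "ethnicity_concept_id",
               "race_concept_id"),
    condition_occurrence = c("person_id", "condition_concept_id"),
    procedure_occurrence = c("person_id", "procedure_concept_id"),
    drug_exposure = c("person_id", "drug_concept_id"),
    measurement = c("person_id", "measurement_concept_id")
  )
}

omop_integer_columns <- function() {
  c("person_id", "gender_concept_id", "ethnicity_concept_id",
    "race_concept_id", "year_of_birth", "age_years",
    "condition_occurrence_id", "condition_concept_id",
    "condition_start_age_days",
    "procedure_occurrence_id", "procedure_concept_id", "procedure_age_days",
    "drug_exposure_id", "drug_concept_id", "drug_exposure_start_age_days",
    "drug_exposure_end_age_days",
    "measurement_id", "measurement_concept_id", "measurement_age_days")
}

#' Read an OMOP table-per-file extract
#'
#' Reads UTF-8, header-bearing, tab-delimited files (empty string = missing).
#' Unknown extra columns are dropped with a warning; a missing required
#' column raises a schema error naming the table and column; identifier and
#' concept columns that fail to parse as integers raise an error with the
#' offending line number.
#'
#' @param table_files Either a named character vector mapping table names to
#'   file paths, or a single directory containing `<table>.tsv` files.
#' @return An [omop_extract()].
#' @export
read_omop_extract <- function(table_files) {
  if (length(table_files) == 1L && is.null(names(table_files)) &&
      dir.exists(table_files)) {
    found <- file.path(table_files, paste0(omop_table_names(), ".tsv"))
    names(found) <- omop_table_names()
    table_files <- found[file.exists(found)]
  }
  if (is.null(names(table_files)) || any(!nzchar(names(table_files)))) {
    stop(schema_error("table_files must be named by OMOP table"))
  }
  tables <- list()
  for (tab in names(table_files)) {
    tables[[tab]] <- read_omop_table(tab, table_files[[tab]])
  }
  deid <- !any(vapply(names(tables), function(tab) {
    any(names(omop_date_columns()[[tab]]) %in% names(tables[[tab]])) ||
      any(c("birth_datetime", "year_of_birth") %in% names(tables[[tab]]))
  }, logical(1)))
  omop_extract(tables, deidentified = deid)
}

read_omop_table <- function(tab, path) {
  if (!tab %in% omop_table_names()) {
    stop(schema_error(paste0("unknown OMOP table: ", tab)))
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  missing_req <- setdiff(omop_required_columns()[[tab]], names(df))
  if (length(missing_req)) {
    stop(schema_error(paste0("table ", tab, " is missing required column ",
                             missing_req[1L])))
  }
  known <- omop_known_columns()[[tab]]
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("dropping unrecognized column(s) in ", tab, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
    df <- df[intersect(names(df), known)]
  }
  type_omop_columns(df, tab, path)
}

type_omop_columns <- function(df, tab, path) {
  int_cols <- intersect(names(df), omop_integer_columns())
  for (col in int_cols) {
    vals <- df[[col]]
    blank <- is.na(vals) | !nzchar(vals)
    parsed <- suppressWarnings(as.integer(vals))
    bad <- which(!blank & is.na(parsed))
    if (length(bad)) {
      stop(schema_error(paste0("table ", tab, " line ", bad[1L] + 1L,
                               ": cannot parse '", vals[bad[1L]],
                               "' in column ", col)))
    }
    if (any(parsed < 0, na.rm = TRUE)) {
      stop(schema_error(paste0("table ", tab, ": negative identifier in ",
                               col)))
    }
    df[[col]] <- parsed
  }
  if ("value_as_number" %in% names(df)) {
    df$value_as_number <- suppressWarnings(as.numeric(df$value_as_number))
  }
  for (col in setdiff(names(df), c(int_cols, "value_as_number"))) {
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  }
  tibble::as_tibble(df)
}

#' Write an OMOP extract as one TSV per table
#'
#' @param extract An [omop_extract()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named by table).
#' @export
write_omop_extract <- function(extract, dir) {
  stopifnot(inherits(extract, "omop_extract"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tab in names(extract$tables)) {
    p <- file.path(dir, paste0(tab, ".tsv"))
    df <- as.data.frame(extract$tables[[tab]])
    df[] <- lapply(df, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- ""
      if (any(grepl("[\t\n]", x))) {
        stop(schema_error("embedded tab/newline in field value"))
      }
      x
    })
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    paths[tab] <- p
  }
  invisible(paths)
}

#' Read a cancer-registry export
#'
#' Accepts a CSV or TSV export with one row per patient (the delimiter is
#' sniffed from the header line unless given). Adds a `completeness_state`
#' column: `complete` when both the basis-of-diagnosis and therapeutic-agent
#' fields are populated, otherwise `suspense` (the registry's minimum
#' "suspense" abstraction holds only age, gender, date of first contact,
#' primary site and histology).
#'
#' @param path Path to the export file.
#' @param sep Field delimiter; `NULL` to sniff `,` vs tab.
#' @return Tibble of registry rows with `completeness_state` appended.
#' @export
read_registry_export <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    return(tibble::as_tibble(df))
  }
  if (!"patient_id" %in% names(df)) {
    stop(schema_error("registry export is missing a patient_id column"))
  }
  if (anyDuplicated(df$patient_id)) {
    stop(schema_error(paste0("duplicate patient rows for ",
                             df$patient_id[duplicated(df$patient_id)][1L])))
  }
  df[] <- lapply(df, function(x) {
    x[!nzchar(x)] <- NA_character_
    x
  })
  has <- function(col) {
    col %in% names(df) & !is.na(df[[col]] %||% NA)
  }
  basis <- has("dx_confirmation")
  agent <- has("chemo_text") | has("chemo_code")
  df$completeness_state <- ifelse(basis & agent, "complete", "suspense")
  if ("age" %in% names(df)) df$age <- suppressWarnings(as.integer(df$age))
  if ("age_years" %in% names(df)) {
    df$age_years <- suppressWarnings(as.integer(df$age_years))
  }
  for (col in intersect(unname(registry_date_columns()), names(df))) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  tibble::as_tibble(df)
}

schema_error <- function(msg) {
  errorCondition(paste0("schema error: ", msg),
                 class = c("genetrust_schema_error", "genetrust_error"))
}
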