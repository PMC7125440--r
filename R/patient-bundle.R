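#' Per-patient shared bundle
#'
#' The unit of sharing: one deidentified document per patient holding any of
#' the four modalities (registry record, OMOP extract, somatic variant list,
#' content-addressed image references), keyed by the patient's public
#' UUID-4. At least one modality must be present.
#'
#' @param patient_id UUID-4 text.
#' @param omop Optional deidentified [omop_extract()].
#' @param registry Optional one-row tibble from [deidentify_registry()].
#' @param variants Optional tibble of somatic variant calls.
#' @param image_refs Character vector of content addresses.
#' @return Object of class `patient_bundle`.
#' @export
patient_bundle <- function(patient_id, omop = NULL, registry = NULL,
                           variants = NULL, image_refs = character(0)) {
  if (!is_uuid4(patient_id)) {
    stop(errorCondition(paste0("not a UUID-4 patient id: ", patient_id),
                        class = c("genetrust_id_error", "genetrust_error")))
  }
  if (is.null(omop) && is.null(registry) && is.null(variants) &&
      length(image_refs) == 0L) {
    stop(errorCondition("bundle must contain at least one modality",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  if (!is.null(registry)) registry <- tibble::as_tibble(registry)
  if (!is.null(variants)) variants <- tibble::as_tibble(variants)
  structure(list(patient_id = patient_id, omop = omop, registry = registry,
                 variants = variants, image_refs = as.character(image_refs)),
            class = "patient_bundle")
}

#' @rdname patient_bundle
#' @param x Object to test.
#' @export
is_uuid4 <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$",
          x)
}

#' Modalities present in a bundle
#' @param bundle A [patient_bundle()].
#' @return Character subset of
#'   `c("clinical-registry", "clinical-omop", "genomic", "imaging")`.
#' @export
bundle_modalities <- function(bundle) {
  tags <- character(0)
  if (!is.null(bundle$registry)) tags <- c(tags, "clinical-registry")
  if (!is.null(bundle$omop)) tags <- c(tags, "clinical-omop")
  if (!is.null(bundle$variants)) tags <- c(tags, "genomic")
  if (length(bundle$image_refs)) tags <- c(tags, "imaging")
  tags
}

variant_columns <- function() {
  c("gene", "protein_change", "status", "effect", "origin",
    "patient_id", "tissue_of_origin", "primary_disease")
}

#' Serialize a patient bundle to canonical JSON
#'
#' Writing is refused when [phi_scan()] reports any finding, so no document
#' with a residual date literal or identifier-shaped value can reach the
#' store. Two writes of equal bundles are byte-identical (canonical dialect:
#' sorted keys, UTF-8, no whitespace).
#'
#' @param bundle A [patient_bundle()].
#' @param config A [deid_config()] for the PHI gate.
#' @return Raw vector of canonical JSON bytes.
#' @export
write_patient_json <- function(bundle, config = deid_config()) {
  doc <- bundle_to_document(bundle)
  findings <- phi_scan(doc, config)
  if (nrow(findings)) {
    stop(errorCondition(
      paste0("refusing to serialize bundle with PHI findings: ",
             paste(findings$category, "at", findings$location,
                   collapse = "; ")),
      class = c("genetrust_phi_error", "genetrust_error")))
  }
  canonicalize(doc)
}

#' @rdname write_patient_json
#' @param bytes Raw vector or JSON text.
#' @export
read_patient_json <- function(bytes) {
  document_to_bundle(parse_canonical(bytes))
}

bundle_to_document <- function(bundle) {
  doc <- list(patient_id = bundle$patient_id)
  if (!is.null(bundle$omop)) {
    doc$omop <- lapply(bundle$omop$tables, table_to_document)
  }
  if (!is.null(bundle$registry)) {
    doc$registry <- table_to_document(bundle$registry)
  }
  if (!is.null(bundle$variants)) {
    doc$variants <- table_to_document(bundle$variants)
  }
  doc$image_refs <- as.list(bundle$image_refs)
  doc
}

# A table travels as {"columns": [...], "rows": [{...}, ...]} so that empty
# tables and all-missing columns survive the round trip with their schema.
table_to_document <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    row <- row[!vapply(row, function(v) length(v) != 1L || is.na(v),
                       logical(1))]
    if (length(row) == 0L) return(structure(list(), names = character(0)))
    row
  })
  list(columns = as.list(names(df)), rows = rows)
}

document_to_bundle <- function(doc) {
  omop <- NULL
  if (!is.null(doc$omop)) {
    tables <- lapply(doc$omop, document_to_table)
    omop <- omop_extract(tables, deidentified = TRUE)
  }
  registry <- NULL
  if (!is.null(doc$registry)) {
    registry <- document_to_table(doc$registry)
  }
  variants <- NULL
  if (!is.null(doc$variants)) {
    variants <- document_to_table(doc$variants)
  }
  patient_bundle(doc$patient_id, omop = omop, registry = registry,
                 variants = variants,
                 image_refs = unlist(doc$image_refs) %||% character(0))
}

registry_integer_columns <- function() {
  c("age", "age_years", unname(registry_date_columns()))
}

document_to_table <- function(tab_doc) {
  cols_wanted <- unlist(tab_doc$columns) %||% character(0)
  rows <- tab_doc$rows
  integer_cols <- c(omop_integer_columns(), registry_integer_columns())
  double_cols <- "value_as_number"
  cols <- lapply(cols_wanted, function(col) {
    vals <- lapply(rows, function(r) r[[col]])
    if (col %in% integer_cols) {
      vapply(vals, function(v) if (is.null(v)) NA_integer_
             else as.integer(v), integer(1))
    } else if (col %in% double_cols ||
               (length(vals) > 0L &&
                all(vapply(vals, function(v) is.null(v) || is.numeric(v),
                           logical(1))) &&
                any(!vapply(vals, is.null, logical(1))))) {
      vapply(vals, function(v) if (is.null(v)) NA_real_
             else as.numeric(v), numeric(1))
    } else {
      vapply(vals, function(v) if (is.null(v)) NA_character_
             else as.character(v), character(1))
    }
  })
  names(cols) <- cols_wanted
  tibble::as_tibble(cols, .rows = length(rows))
}

#' Per-modality row counts for a bundle
#'
#' The per-patient accounting used in the data-availability table: how many
#' condition, procedure and drug rows a bundle carries, plus which
#' modalities are present.
#'
#' @param bundle A [patient_bundle()].
#' @return One-row tibble with `patient_id`, modality flags and row counts.
#' @export
summarize_bundle <- function(bundle) {
  count <- function(tab) {
    if (is.null(bundle$omop) || is.null(bundle$omop$tables[[tab]])) {
      NA_integer_
    } else {
      nrow(bundle$omop$tables[[tab]])
    }
  }
  tibble::tibble(
    patient_id = bundle$patient_id,
    registry = !is.null(bundle$registry),
    omop = !is.null(bundle$omop),
    genomic = !is.null(bundle$variants),
    imaging = length(bundle$image_refs) > 0L,
    conditions = count("condition_occurrence"),
    procedures = count("procedure_occurrence"),
    drugs = count("drug_exposure")
  )
}
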