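#' Ingest one patient's raw files into a deidentified bundle
#'
#' Reads whatever raw inputs are present in a per-patient directory (a
#' `registry.csv` export, an `omop/` directory of table TSVs, a
#' `variants.xml` or `variants.vcf` report, `image_*.bin` blobs), applies
#' the deidentification transforms (dates to age-in-days, allow/deny-list
#' filtering, germline removal) and assembles a [patient_bundle()]. The
#' date of birth is taken from the raw registry export (or passed
#' explicitly); it is used transiently and never serialized.
#'
#' @param raw_dir Per-patient raw directory.
#' @param config A [deid_config()].
#' @param store Optional [content_store()]; when given, image blobs are
#'   stored and referenced by content address.
#' @param birth Date of birth override (`YYYY-MM-DD`).
#' @return A deidentified [patient_bundle()].
#' @export
ingest_patient <- function(raw_dir, config = deid_config(), store = NULL,
                           birth = NULL) {
  reg_path <- file.path(raw_dir, "registry.csv")
  registry <- NULL
  if (file.exists(reg_path)) {
    raw_reg <- read_registry_export(reg_path)
    if (is.null(birth) && "date_of_birth" %in% names(raw_reg)) {
      birth <- raw_reg$date_of_birth[1L]
    }
    registry <- deidentify_registry(raw_reg, birth = birth, config = config)
    registry <- scrub_text_columns(registry)
  }
  omop <- NULL
  omop_dir <- file.path(raw_dir, "omop")
  if (dir.exists(omop_dir)) {
    raw_omop <- read_omop_extract(omop_dir)
    omop <- deidentify_omop(raw_omop, birth = birth, config = config)
  }
  variants <- NULL
  xml_path <- file.path(raw_dir, "variants.xml")
  vcf_path <- file.path(raw_dir, "variants.vcf")
  if (file.exists(xml_path)) {
    variants <- filter_somatic(parse_variant_xml(xml_path))
  } else if (file.exists(vcf_path)) {
    variants <- filter_somatic(parse_somatic_vcf(vcf_path))
  }
  image_refs <- character(0)
  if (!is.null(store)) {
    for (img in sort(list.files(raw_dir, pattern = "^image_.*\\.bin$",
                                full.names = TRUE))) {
      image_refs <- c(image_refs,
                      store_put(store, readBin(img, "raw",
                                               n = file.size(img)),
                                media_hint = "image"))
    }
  }
  pid <- patient_id_for(raw_dir, registry, variants)
  patient_bundle(pid, omop = omop, registry = registry, variants = variants,
                 image_refs = image_refs)
}

patient_id_for <- function(raw_dir, registry, variants) {
  if (!is.null(registry) && "patient_id" %in% names(registry) &&
      is_uuid4(registry$patient_id[1L])) {
    return(registry$patient_id[1L])
  }
  if (!is.null(variants) && nrow(variants) &&
      is_uuid4(variants$patient_id[1L])) {
    return(variants$patient_id[1L])
  }
  base <- basename(normalizePath(raw_dir))
  if (is_uuid4(base)) return(base)
  stop(errorCondition("cannot determine a UUID-4 patient id",
                      class = c("genetrust_id_error", "genetrust_error")))
}

# defense in depth: redact any value-level PHI pattern surviving in retained
# free-text registry fields
scrub_text_columns <- function(df) {
  for (col in names(df)) {
    if (is.character(df[[col]])) {
      for (pat in phi_value_patterns) {
        df[[col]] <- gsub(pat, "[redacted]", df[[col]], perl = TRUE)
      }
    }
  }
  df
}

#' Submit a deidentified bundle to a steward's ledger
#'
#' Serializes the bundle to canonical JSON (PHI-gated), stores it, and
#' submits a manifest whose `bundle` file reference is the bundle's content
#' address, tagged with the modalities present.
#'
#' @param ledger A [cgt_ledger()].
#' @param steward Registered steward identifier.
#' @param bundle A [patient_bundle()].
#' @param config A [deid_config()].
#' @return The receipt from [submit()].
#' @export
submit_bundle <- function(ledger, steward, bundle, config = deid_config()) {
  bytes <- write_patient_json(bundle, config)
  addr <- store_put(ledger$store, bytes, media_hint = "patient-bundle")
  files <- c(list(bundle = addr),
             stats::setNames(as.list(bundle$image_refs),
                             sprintf("image_%d",
                                     seq_along(bundle$image_refs))))
  counts <- summarize_bundle(bundle)
  fields <- list(n_conditions = counts$conditions,
                 n_procedures = counts$procedures,
                 n_drugs = counts$drugs)
  fields <- fields[!vapply(fields, is.na, logical(1))]
  sub <- submission(bundle$patient_id, fields = fields, files = files,
                    tags = bundle_modalities(bundle))
  submit(ledger, steward, sub, config)
}

#' Run the full sharing pipeline over a generated cohort
#'
#' generate -> ingest -> deidentify -> submit for every patient directory
#' under `<cohort_dir>/raw`, against a fresh or existing ledger.
#'
#' @param cohort_dir Directory produced by [generate_cohort()].
#' @param ledger A [cgt_ledger()].
#' @param steward Steward identifier (registered if new).
#' @param config A [deid_config()].
#' @return Tibble of per-patient receipts (patient_id, address, sequence).
#' @export
run_pipeline <- function(cohort_dir, ledger, steward = "demo-hospital",
                         config = deid_config()) {
  if (is.null(read_stewards(ledger)[[steward]])) {
    register_steward(ledger, steward)
  }
  raw_dirs <- sort(list.dirs(file.path(cohort_dir, "raw"), recursive = FALSE))
  receipts <- list()
  for (rd in raw_dirs) {
    bundle <- ingest_patient(rd, config = config, store = ledger$store)
    rec <- submit_bundle(ledger, steward, bundle, config)
    receipts[[length(receipts) + 1L]] <-
      tibble::tibble(patient_id = bundle$patient_id, address = rec$address,
                     sequence = rec$sequence)
  }
  do.call(rbind, receipts)
}
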