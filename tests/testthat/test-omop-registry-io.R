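write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("row counts are preserved and schema violations are named", {
  dir <- withr::local_tempdir()
  write_tsv(data.frame(condition_occurrence_id = 1:3, person_id = 1L,
                       condition_concept_id = c(100L, 200L, 300L),
                       condition_start_date = "2018-01-01"),
            file.path(dir, "condition_occurrence.tsv"))
  write_tsv(data.frame(drug_exposure_id = 1:2, person_id = 1L,
                       drug_concept_id = 5L,
                       drug_exposure_start_date = "2018-02-01",
                       drug_exposure_end_date = "2018-03-01"),
            file.path(dir, "drug_exposure.tsv"))
  ext <- read_omop_extract(dir)
  expect_identical(nrow(ext$tables$condition_occurrence), 3L)
  expect_identical(nrow(ext$tables$drug_exposure), 2L)

  bad_dir <- withr::local_tempdir()
  write_tsv(data.frame(condition_occurrence_id = 1L, person_id = 1L,
                       condition_start_date = "2018-01-01"),
            file.path(bad_dir, "condition_occurrence.tsv"))
  err <- tryCatch(read_omop_extract(bad_dir), error = identity)
  expect_s3_class(err, "genetrust_schema_error")
  expect_match(conditionMessage(err), "condition_concept_id")
  expect_match(conditionMessage(err), "condition_occurrence")
})

test_that("unknown columns are dropped with a warning, bad integers error with line", {
  dir <- withr::local_tempdir()
  write_tsv(data.frame(person_id = 1L, gender_concept_id = 8507L,
                       ethnicity_concept_id = 0L, race_concept_id = 0L,
                       favorite_color = "blue"),
            file.path(dir, "person.tsv"))
  expect_warning(ext <- read_omop_extract(dir), "favorite_color")
  expect_false("favorite_color" %in% names(ext$tables$person))

  dir2 <- withr::local_tempdir()
  write_tsv(data.frame(person_id = c("1", "oops"), gender_concept_id = 8507L,
                       ethnicity_concept_id = 0L, race_concept_id = 0L),
            file.path(dir2, "person.tsv"))
  err <- tryCatch(read_omop_extract(dir2), error = identity)
  expect_s3_class(err, "genetrust_schema_error")
  expect_match(conditionMessage(err), "line 3")
})

test_that("OMOP write/read round-trips generator output", {
  res <- local_cohort(n = 4L, seed = 77L)
  pid <- res$patients$patient_id[res$patients$has_ehr][1L]
  ext <- read_omop_extract(file.path(res$dir, "raw", pid, "omop"))
  dir <- withr::local_tempdir()
  write_omop_extract(ext, dir)
  again <- read_omop_extract(dir)
  expect_identical(again$tables, ext$tables)
})

test_that("registry completeness states follow the suspense definition", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "reg.csv")
  df <- data.frame(
    patient_id = c(fresh_uuid(1), fresh_uuid(2)),
    age = c(60L, 70L), sex = c("Female", "Male"),
    date_of_first_contact = "2018-01-01",
    cancer_site_icdo3 = "C25.0", cancer_histology_icdo3 = "8140/3",
    dx_confirmation = c("pathology", ""),
    chemo_text = c("gemcitabine", ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, p, sep = ",", quote = TRUE, row.names = FALSE)
  recs <- read_registry_export(p)
  expect_identical(recs$completeness_state, c("complete", "suspense"))

  # duplicate patient rows are rejected
  df2 <- rbind(df, df[1, ])
  utils::write.table(df2, p, sep = ",", quote = TRUE, row.names = FALSE)
  expect_error_class(read_registry_export(p), "genetrust_schema_error")

  # empty export reads as an empty record set
  writeLines("patient_id,age,sex", p)
  expect_identical(nrow(read_registry_export(p)), 0L)
})

test_that("patient JSON round-trips and is byte-deterministic", {
  res <- local_cohort(n = 4L, seed = 101L)
  pid <- res$patients$patient_id[res$patients$has_ehr][1L]
  bundle <- ingest_patient(file.path(res$dir, "raw", pid))
  bytes1 <- write_patient_json(bundle)
  bytes2 <- write_patient_json(bundle)
  expect_identical(bytes1, bytes2)
  back <- read_patient_json(bytes1)
  expect_identical(back$patient_id, bundle$patient_id)
  expect_identical(back$omop$tables, bundle$omop$tables)
  expect_identical(back$registry, bundle$registry)
  expect_identical(back$variants, bundle$variants)
  expect_identical(write_patient_json(back), bytes1)
})

test_that("a minimal bundle with empty tables parses back equal", {
  empty <- omop_extract(list(
    condition_occurrence = tibble::tibble(
      condition_occurrence_id = integer(0), person_id = integer(0),
      condition_concept_id = integer(0),
      condition_start_age_days = integer(0))), deidentified = TRUE)
  b <- patient_bundle(fresh_uuid(3), omop = empty)
  back <- read_patient_json(write_patient_json(b))
  expect_identical(back$omop$tables, empty$tables)
})

test_that("bundles echo large per-modality row counts faithfully", {
  n_cond <- 1597L
  big <- omop_extract(list(
    condition_occurrence = tibble::tibble(
      condition_occurrence_id = seq_len(n_cond), person_id = 1L,
      condition_concept_id = 7000000L + seq_len(n_cond),
      condition_start_age_days = 20000L + seq_len(n_cond))),
    deidentified = TRUE)
  b <- patient_bundle(fresh_uuid(4), omop = big)
  doc <- parse_canonical(write_patient_json(b))
  expect_length(doc$omop$condition_occurrence$rows, n_cond)
  expect_identical(summarize_bundle(b)$conditions, n_cond)
})

test_that("bundle summaries equal direct row counts", {
  res <- local_cohort(n = 5L, seed = 55L)
  for (pid in res$patients$patient_id[res$patients$has_ehr]) {
    bundle <- ingest_patient(file.path(res$dir, "raw", pid))
    s <- summarize_bundle(bundle)
    expect_identical(s$conditions,
                     nrow(bundle$omop$tables$condition_occurrence))
    expect_identical(s$procedures,
                     nrow(bundle$omop$tables$procedure_occurrence))
    expect_identical(s$drugs, nrow(bundle$omop$tables$drug_exposure))
  }
})

test_that("writing a PHI-laden bundle is refused", {
  reg <- tibble::tibble(patient_id = fresh_uuid(6),
                        chemo_text = "started 03/15/2019")
  b <- patient_bundle(reg$patient_id, registry = reg)
  expect_error_class(write_patient_json(b), "genetrust_phi_error")
})
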