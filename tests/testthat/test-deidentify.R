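test_that("age in days matches a brute-force calendar walk", {
  expect_identical(date_to_age_days("1957-03-12", "1957-03-12"), 0L)
  # 41 days apart stays 41 days apart after the transform
  a <- date_to_age_days("2018-02-01", "1946-01-15")
  b <- date_to_age_days("2018-03-14", "1946-01-15")
  expect_identical(b - a, 41L)
  # iterative day-count oracle across random pairs (incl. leap years)
  withr::with_seed(5, {
    for (k in 1:25) {
      birth <- as.Date("1940-01-01") + sample.int(20000L, 1L)
      event <- birth + sample.int(25000L, 1L)
      walked <- 0L
      d <- birth
      while (d < event) {
        d <- d + 1L
        walked <- walked + 1L
      }
      expect_identical(date_to_age_days(format(event), format(birth)), walked)
    }
  })
  expect_error_class(date_to_age_days("1950-01-01", "1960-01-01"),
                     "genetrust_date_error")
  expect_error_class(date_to_age_days("not-a-date", "1960-01-01"),
                     "genetrust_date_error")
})

make_raw_extract <- function() {
  omop_extract(list(
    person = tibble::tibble(person_id = 1L, gender_concept_id = 8532L,
                            ethnicity_concept_id = 38003564L,
                            race_concept_id = 8527L, year_of_birth = 1950L,
                            birth_datetime = "1950-06-01"),
    condition_occurrence = tibble::tibble(
      condition_occurrence_id = 1:2, person_id = 1L,
      condition_concept_id = c(4000001L, 7000001L),
      condition_start_date = c("1950-07-01", "2018-05-01")),
    drug_exposure = tibble::tibble(
      drug_exposure_id = 1L, person_id = 1L, drug_concept_id = 19010001L,
      drug_exposure_start_date = "2018-06-01",
      drug_exposure_end_date = "2018-09-01")
  ))
}

test_that("OMOP deidentification converts dates and applies the allow-list", {
  ext <- make_raw_extract()
  deid <- deidentify_omop(ext, birth = "1950-06-01")
  cond <- deid$tables$condition_occurrence
  expect_identical(cond$condition_start_age_days[1L], 30L)
  expect_false("condition_start_date" %in% names(cond))
  expect_false(any(c("birth_datetime", "year_of_birth") %in%
                     names(deid$tables$person)))
  # serialized output contains no date-literal substring
  json <- rawToChar(canonicalize(list(
    p = lapply(deid$tables, function(t) lapply(seq_len(nrow(t)),
                                               function(i) as.list(t[i, ]))))))
  expect_false(grepl("[0-9]{4}-[0-9]{2}-[0-9]{2}", json))
  expect_identical(nrow(phi_scan(deid$tables)), 0L)
})

test_that("a column outside the allow-list is dropped", {
  ext <- make_raw_extract()
  ext$tables$person$provider_name <- "Dr Someone"
  deid <- deidentify_omop(ext, birth = "1950-06-01")
  expect_false("provider_name" %in% names(deid$tables$person))
})

test_that("person age is derived at extraction and capped", {
  ext <- make_raw_extract()
  deid <- deidentify_omop(ext, birth = "1950-06-01",
                          extraction_date = "2019-06-01")
  expect_identical(deid$tables$person$age_years, 69L)
  old <- deidentify_omop(ext, birth = "1920-06-01",
                         extraction_date = "2019-06-01")
  expect_identical(old$tables$person$age_years, 89L)
  uncapped <- deidentify_omop(ext, birth = "1920-06-01",
                              extraction_date = "2019-06-01",
                              config = deid_config(cap_ages = FALSE))
  expect_identical(uncapped$tables$person$age_years, 99L)
})

test_that("both deidentify operations are idempotent", {
  ext <- make_raw_extract()
  d1 <- deidentify_omop(ext, birth = "1950-06-01")
  d2 <- deidentify_omop(d1)
  expect_identical(d1$tables, d2$tables)

  reg <- tibble::tibble(
    patient_id = fresh_uuid(2), name = "Pat Example", mrn = "1234567",
    date_of_birth = "1950-06-01", age = 68L,
    date_of_first_contact = "2018-04-01", sex = "Female",
    spanish_origin = "Non-Hispanic", race = "White",
    date_of_diagnosis = "2018-05-01", dx_confirmation = "pathology",
    dx_staging_proc = "biopsy", cancer_site_icdo3 = "C25.0",
    seer_site_group = "Pancreas", cancer_histology_icdo3 = "8140/3",
    chemo_text = "gemcitabine", chemo_code = "RX101",
    chemo_start_date = "2018-06-01", chemo_end_date = "2018-09-01",
    completeness_state = "complete")
  r1 <- deidentify_registry(reg)
  r2 <- deidentify_registry(r1)
  expect_identical(r1, r2)
  expect_false(any(c("name", "mrn", "date_of_birth") %in% names(r1)))
  expect_identical(nrow(phi_scan(r1)), 0L)
  expect_identical(r1$diagnosis_age_days,
                   date_to_age_days("2018-05-01", "1950-06-01"))
})

test_that("somatic filtering equals the brute-force predicate", {
  mixed <- variant_calls(
    gene = paste0("G", 1:8),
    origin = c("somatic", "germline", "somatic", "unknown-origin", "somatic",
               "germline", "somatic", "somatic"))
  kept <- filter_somatic(mixed)
  expect_identical(kept$gene, mixed$gene[mixed$origin == "somatic"])
  expect_identical(nrow(filter_somatic(
    variant_calls(gene = c("A", "B"), origin = "germline"))), 0L)
  withr::with_seed(9, {
    for (k in 1:20) {
      n <- sample.int(15L, 1L)
      v <- variant_calls(gene = paste0("G", seq_len(n)),
                         origin = sample(c("somatic", "germline",
                                           "unknown-origin"), n,
                                         replace = TRUE))
      expect_identical(filter_somatic(v)$gene, v$gene[v$origin == "somatic"])
    }
  })
  expect_error_class(filter_somatic(tibble::tibble(gene = "A")),
                     "genetrust_type_error")
})

test_that("phi_scan flags each leak category where it is injected", {
  expect_identical(phi_scan(list(note = "seen 2017-03-04"))$category,
                   "date-literal")
  expect_identical(nrow(phi_scan(list(age_days = 26346L,
                                      site = "C25.0", hist = "8140/3"))), 0L)
  injectors <- list(
    "date-literal" = function() list(note = sample(
      c("follow-up 03/15/2019", "seen 2018-11-02", "visit on March 3, 2018",
        "12 Jan 2017 admission"), 1L)),
    "ssn-like" = function() list(note = "ssn 123-45-6789"),
    "phone-like" = function() list(note = sample(
      c("call (415) 555-0134", "tel 415-555-0134"), 1L)),
    "email-like" = function() list(note = "mail me at pt1@example.org"),
    "mrn-like" = function() list(record_number = sprintf(
      "%07d", sample.int(8999999L, 1L) + 1000000L)),
    "denied-key" = function() stats::setNames(
      list("x"), sample(c("mrn", "date_of_birth", "address", "contact"), 1L)),
    "name-field" = function() list(provider_name = "Dr Someone")
  )
  withr::with_seed(13, {
    for (trial in 1:200) {
      cat_want <- sample(names(injectors), 1L)
      doc <- list(patient = list(age_days = 100L),
                  extra = injectors[[cat_want]]())
      findings <- phi_scan(doc)
      expect_true(cat_want %in% findings$category,
                  label = paste("category", cat_want, "found"))
    }
  })
})

test_that("findings carry a reproducible location path", {
  f <- phi_scan(list(registry = list(chemo_text = "started 03/15/2019")))
  expect_identical(f$location, "registry.chemo_text")
  expect_identical(f$excerpt, "03/15/2019")
})
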