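test_that("generation is byte-identical under one seed", {
  cfg <- cohort_config(n_patients = 4L, seed = 99L, n_no_ehr = 1L,
                       n_fmi = 2L, n_ucsf500 = 1L, n_imaging = 1L)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(sha256_hex(readBin(file.path(d1, f), "raw",
                                        n = file.size(file.path(d1, f)))),
                     sha256_hex(readBin(file.path(d2, f), "raw",
                                        n = file.size(file.path(d2, f)))),
                     label = paste("digest of", f))
  }
})

test_that("different seeds give different cohorts", {
  r1 <- local_cohort(n = 3L, seed = 1L)
  r2 <- local_cohort(n = 3L, seed = 2L)
  expect_false(identical(r1$patients$patient_id, r2$patients$patient_id))
})

test_that("full capture probabilities give expected element scores of 5", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(
    n_patients = 3L, seed = 7L, n_no_ehr = 0L, n_fmi = 2L, n_ucsf500 = 1L,
    n_imaging = 0L,
    capture = list(registry_p = 1, p_suspense = 0,
                   omop_p = stats::setNames(rep(1, 10), gold_elements()),
                   omop_sitegroup_p = 1))
  res <- generate_cohort(cfg, dir)
  for (t in res$truth$patients) {
    expect_true(all(unlist(t$expected_scores$registry) == 5L))
    expect_true(all(unlist(t$expected_scores$omop) == 5L))
    expect_identical(t$expected_scores$total_registry, 50L)
    expect_identical(t$expected_scores$total_omop, 50L)
  }
})

test_that("invalid configurations are rejected", {
  expect_error_class(cohort_config(sex_p = c(male = 0.7, female = 0.7)),
                     "genetrust_config_error")
  expect_error_class(cohort_config(variants = list(range = c(5, 200))),
                     "genetrust_config_error")
  expect_error_class(cohort_config(phi_injection_rate = 1.5),
                     "genetrust_config_error")
  expect_error_class(cohort_config(n_patients = 3, n_fmi = 3, n_ucsf500 = 1),
                     "genetrust_config_error")
})

test_that("an exact cohort variant total is honored", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 13L, seed = 5L, n_no_ehr = 0L,
                       n_fmi = 13L, n_ucsf500 = 0L, n_imaging = 0L,
                       variants = list(total = 139L))
  res <- generate_cohort(cfg, dir)
  expect_identical(sum(res$patients$n_somatic), 139L)
  expect_true(all(res$patients$n_somatic >= 3L &
                    res$patients$n_somatic <= 21L))
})

test_that("burden statistics track configured targets over repeated seeds", {
  # Monte-Carlo check on the clipped negative-binomial burden model:
  # the configured mean (10.69) should be recovered within 3 standard
  # errors of the mean over pooled seeds, and the clip range respected.
  counts <- integer(0)
  for (seed in 1:10) {
    dir <- withr::local_tempdir()
    cfg <- cohort_config(n_patients = 6L, seed = seed, n_no_ehr = 0L,
                         n_fmi = 6L, n_ucsf500 = 0L, n_imaging = 0L)
    res <- generate_cohort(cfg, dir)
    counts <- c(counts, res$patients$n_somatic)
  }
  expect_true(all(counts >= 3L & counts <= 21L))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 10.69), 3 * se + 1e-9)
})

test_that("expected scores are recoverable from the pipeline exactly", {
  res <- local_cohort(n = 5L, seed = 23L)
  truth <- res$truth$patients
  for (pid in res$patients$patient_id[res$patients$has_ehr]) {
    bundle <- ingest_patient(file.path(res$dir, "raw", pid))
    gold <- lapply(truth[[pid]]$gold, function(x) unlist(x))
    sc <- score_patient(gold, registry_facts(bundle$registry),
                        omop_facts(bundle$omop))
    expect_identical(unname(sc$totals["registry"]),
                     truth[[pid]]$expected_scores$total_registry)
    expect_identical(unname(sc$totals["omop"]),
                     truth[[pid]]$expected_scores$total_omop)
    expect_identical(as.list(stats::setNames(sc$elements$registry,
                                             sc$elements$element)),
                     truth[[pid]]$expected_scores$registry)
  }
})

test_that("raw inputs leak PHI and the truth sidecar never ships", {
  res <- local_cohort(n = 4L, seed = 63L, phi_injection_rate = 1)
  truth <- res$truth$patients
  for (pid in res$patients$patient_id[res$patients$has_ehr]) {
    raw_reg <- read_registry_export(file.path(res$dir, "raw", pid,
                                              "registry.csv"))
    findings <- phi_scan(raw_reg)
    expect_gt(nrow(findings), 0L)
    inj <- truth[[pid]]$injected_phi
    if (length(inj)) {
      expect_true(inj[[1L]]$category %in% findings$category)
    }
  }
  expect_true(file.exists(file.path(res$dir, "TRUTH_do_not_submit.json")))
})

test_that("the packaged totals fixture carries the printed score table", {
  m <- load_table4_fixture()
  expect_identical(nrow(m$totals), 17L)
  first <- m$totals[m$totals$patient_id ==
                      "f9b6a782-bbf5-4be8-bf7e-d1a9586d9552", ]
  expect_identical(c(first$registry, first$omop), c(39L, 28L))
  expect_identical(sum(m$totals$registry), 642L)
  expect_identical(sum(m$totals$omop), 560L)
})
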