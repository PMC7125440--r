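#' Configuration for the synthetic oncology cohort generator
#'
#' Defaults emulate a small late-stage gastrointestinal oncology pilot
#' cohort: 18 patients with the pilot's demographic mix (one third male;
#' white/asian/unknown race 11:5:2; 2 of 18 Hispanic/Latino; age mean 59.3,
#' SD 13.3 years), 13 patients on a commercial sequencing panel and 4 on an
#' in-house panel, a clipped negative-binomial somatic variant burden
#' (mean 10.69, range 3-21) with a predominantly-unknown knowledge-status
#' mix (unknown:known:likely weights 8.07:2.18:1.43) and 83.5% missense
#' calls, and a completeness model in which the registry abstracts well but
#' is sometimes caught in a minimum "suspense" state while the OMOP extract
#' captures steadily but misses site grouping and histology detail.
#'
#' @param n_patients Cohort size.
#' @param seed Master seed; every patient draws from a derived substream so
#'   cohorts are extensible without reshuffling.
#' @param n_no_ehr Patients with no clinical (registry/OMOP) data.
#' @param n_fmi,n_ucsf500 Patients sequenced on the XML-report panel and on
#'   the VCF panel respectively (the rest are unsequenced).
#' @param n_imaging Patients with image blobs attached.
#' @param sex_p,race_p,eth_p Named probability vectors (must sum to 1).
#' @param age_mean,age_sd Age distribution (years).
#' @param variants List: `mean`, `dispersion`, `range` (length-2 clip),
#'   `total` (exact somatic total across sequenced patients, or `NULL`),
#'   `status_w` (named weights), `effect_w` (named probabilities),
#'   `germline_mean` (mean germline calls mixed into raw files).
#' @param capture List: `registry_p` (per-token capture probability in a
#'   non-suspense registry abstract), `p_suspense` (probability a registry
#'   record is still in suspense: therapeutic and basis elements
#'   unabstracted), `omop_p` (named per-element capture probabilities),
#'   `omop_sitegroup_p` (capture of the SEER site group in OMOP; defaults
#'   to 0 because the group has no standard OMOP home).
#' @param phi_injection_rate Fraction of patients receiving one extra
#'   injected PHI item in their raw registry export.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 18L,
                          seed = 20200320L,
                          n_no_ehr = 1L,
                          n_fmi = 13L,
                          n_ucsf500 = 4L,
                          n_imaging = 3L,
                          sex_p = c(male = 6 / 18, female = 12 / 18),
                          race_p = c(white = 11 / 18, asian = 5 / 18,
                                     unknown = 2 / 18),
                          eth_p = c(hispanic = 2 / 18,
                                    `non-hispanic` = 16 / 18),
                          age_mean = 59.3, age_sd = 13.3,
                          variants = list(),
                          capture = list(),
                          phi_injection_rate = 0.5) {
  variants <- utils::modifyList(list(
    mean = 10.69, dispersion = 6.4, range = c(3L, 21L), total = NULL,
    status_w = c(unknown = 8.07, known = 2.18, likely = 1.43),
    effect_w = c(missense = 0.835, nonsense = 0.05, frameshift = 0.04,
                 splice = 0.03, indel = 0.03, other = 0.015),
    germline_mean = 2), variants)
  capture <- utils::modifyList(list(
    registry_p = 0.85, p_suspense = 0.25,
    omop_p = c(Gender = 0.9, Ethnicity = 0.9, Race = 0.9,
               `Date of Diagnosis` = 0.7, `Basis of Diagnosis` = 0.6,
               `Cancer Site` = 0.7, `Cancer Histology` = 0.15,
               `Therapeutic Agent` = 0.7, `Treatment Start Date` = 0.7,
               `Treatment End Date` = 0.6),
    omop_sitegroup_p = 0), capture)
  cfg <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    n_no_ehr = as.integer(n_no_ehr), n_fmi = as.integer(n_fmi),
    n_ucsf500 = as.integer(n_ucsf500), n_imaging = as.integer(n_imaging),
    sex_p = sex_p, race_p = race_p, eth_p = eth_p,
    age_mean = age_mean, age_sd = age_sd,
    variants = variants, capture = capture,
    phi_injection_rate = phi_injection_rate), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  bad <- function(msg) stop(errorCondition(
    paste0("invalid cohort config: ", msg),
    class = c("genetrust_config_error", "genetrust_error")))
  if (cfg$n_patients < 1L) bad("n_patients must be positive")
  for (p in list(cfg$sex_p, cfg$race_p, cfg$eth_p)) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      bad("category proportions must be non-negative and sum to 1")
    }
  }
  v <- cfg$variants
  if (length(v$range) != 2L || v$range[1] > v$range[2] ||
      v$range[1] < 0 || v$range[2] > 100) {
    bad("variant count range must lie within [0, 100]")
  }
  if (abs(sum(v$effect_w) - 1) > 1e-8) bad("effect mix must sum to 1")
  probs <- c(cfg$capture$registry_p, cfg$capture$p_suspense,
             cfg$capture$omop_p, cfg$capture$omop_sitegroup_p,
             cfg$phi_injection_rate)
  if (any(probs < 0 | probs > 1)) bad("probabilities must lie in [0, 1]")
  if (cfg$n_fmi + cfg$n_ucsf500 > cfg$n_patients) {
    bad("more sequenced patients than patients")
  }
  if (!all(gold_elements() %in% names(cfg$capture$omop_p))) {
    bad("omop_p must name all ten gold elements")
  }
  invisible(cfg)
}

synthetic_first_names <- c(
  "Alex", "Morgan", "Jordan", "Casey", "Riley", "Quinn", "Avery", "Drew",
  "Jamie", "Reese", "Skyler", "Parker", "Rowan", "Emerson", "Sage", "Blake")
synthetic_last_names <- c(
  "Hillcrest", "Marlowe", "Ashford", "Winslow", "Calloway", "Thorne",
  "Fairbank", "Mercer", "Langley", "Holloway", "Prescott", "Whitfield")
synthetic_tissues <- c("liver", "pancreas", "omentum", "lymph node", "colon",
                       "stomach", "skin", "peritoneum")
synthetic_gene_pool <- c(
  "KRAS", "TP53", "ARID1A", "MLL2", "SMAD4", "CDKN2A", "PIK3CA", "BRCA2",
  "ATM", "RNF43", "GNAS", "TGFBR2", "APC", "EGFR", "ERBB2", "MYC", "RB1",
  "PTEN", "FBXW7", "CTNNB1", "NOTCH1", "KDM6A", "BAP1", "IDH1", "PBRM1",
  "STK11", "KEAP1", "NF1", "NF2", "BRAF", "MET", "ALK", "ROS1", "RET",
  "KIT", "PDGFRA", "FGFR1", "FGFR2", "FGFR3", "CCND1", "CCNE1", "MDM2",
  "MDM4", "AKT1", "AKT2", "MTOR", "TSC1", "TSC2", "VHL", "SETD2", "ARID2",
  "SMARCA4", "SMARCB1", "ATRX", "DAXX", "MEN1", "RICTOR", "RPTOR", "ERBB3",
  "ERBB4", "JAK1", "JAK2", "STAT3", "GATA3", "FOXA1", "ESR1", "AR", "CDK4",
  "CDK6", "CDK12", "CHEK1", "CHEK2", "PALB2", "RAD51", "MSH2", "MSH6",
  "MLH1", "PMS2", "POLE", "POLD1", "AXIN1", "AXIN2", "TERT", "NRAS",
  "HRAS", "MAP2K1", "MAP2K4", "MAPK1", "SRC", "ABL1", "NTRK1", "NTRK2",
  "NTRK3", "DDR2", "FLT3", "NPM1", "WT1", "SPEN", "CREBBP", "EP300",
  "KMT2C", "KMT2D", "SETBP1", "ASXL1", "BCOR", "ZRSR2", "U2AF1", "SF3B1",
  "SRSF2", "TET2", "DNMT3A", "IDH2", "RUNX1", "GATA2", "PHF6", "PTPN11",
  "RIT1", "SOS1", "CBL", "CRKL", "CARD11")

#' Generate a synthetic identified cohort with ground truth
#'
#' Writes, per patient, the raw identified inputs each pipeline stage
#' consumes -- a registry CSV export (with real dates, names, MRNs and,
#' for a configurable fraction of patients, one extra injected PHI item), a
#' directory of OMOP table TSVs with real dates, a variant report (XML for
#' commercial-panel patients, VCF for in-house-panel patients) with
#' germline calls mixed in, and opaque image blobs -- plus a cohort-level
#' ground-truth sidecar (`TRUTH_do_not_submit.json`) recording dates of
#' birth, gold and captured fact tokens, expected completeness scores, the
#' true somatic variant list and the injected PHI inventory. Output is a
#' deterministic function of the seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `dir`, `patients` (tibble of per-patient
#'   metadata) and `truth` (the sidecar as an R list).
#' @export
generate_cohort <- function(config = cohort_config(), out_dir) {
  validate_cohort_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  voc <- fact_vocabulary()

  set.seed(config$seed)
  n <- config$n_patients
  uuids <- ruuid4(n)
  # cohort-level assignments
  sexes <- sample(names(config$sex_p), n, replace = TRUE, prob = config$sex_p)
  races <- sample(names(config$race_p), n, replace = TRUE,
                  prob = config$race_p)
  eths <- sample(names(config$eth_p), n, replace = TRUE, prob = config$eth_p)
  platform <- rep("none", n)
  seq_idx <- sample.int(n, config$n_fmi + config$n_ucsf500)
  platform[seq_idx[seq_len(config$n_fmi)]] <- "fmi"
  if (config$n_ucsf500 > 0L) {
    platform[seq_idx[config$n_fmi + seq_len(config$n_ucsf500)]] <- "ucsf500"
  }
  no_ehr <- sample.int(n, config$n_no_ehr)
  imaging <- sample(setdiff(seq_len(n), no_ehr),
                    min(config$n_imaging, n - config$n_no_ehr))
  injected <- runif(n) < config$phi_injection_rate

  counts <- draw_variant_counts(config, sum(platform != "none"))

  truth <- list()
  patients <- list()
  k <- 0L
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i))
    sequenced <- platform[i] != "none"
    n_som <- if (sequenced) { k <- k + 1L; counts[k] } else 0L
    p <- generate_patient(
      config, voc, uuid = uuids[i], sex = sexes[i], race = races[i],
      eth = eths[i], platform = platform[i], n_somatic = n_som,
      has_ehr = !(i %in% no_ehr), has_imaging = i %in% imaging,
      inject_phi = injected[i], out_dir = out_dir)
    truth[[uuids[i]]] <- p$truth
    patients[[i]] <- p$meta
  }
  sidecar <- list(seed = config$seed, patients = truth)
  writeLines(rawToChar(canonicalize(sidecar)),
             file.path(out_dir, "TRUTH_do_not_submit.json"))
  invisible(list(dir = out_dir, patients = do.call(rbind, patients),
                 truth = sidecar))
}

# per-patient somatic counts: clipped negative binomial, optionally adjusted
# to an exact cohort total
draw_variant_counts <- function(config, n_seq) {
  v <- config$variants
  if (n_seq == 0L) return(integer(0))
  counts <- stats::rnbinom(n_seq, mu = v$mean, size = v$dispersion)
  counts <- pmin(pmax(counts, v$range[1]), v$range[2])
  if (!is.null(v$total)) {
    guard <- 0L
    while (sum(counts) != v$total && guard < 10000L) {
      j <- sample.int(n_seq, 1L)
      if (sum(counts) < v$total && counts[j] < v$range[2]) {
        counts[j] <- counts[j] + 1L
      } else if (sum(counts) > v$total && counts[j] > v$range[1]) {
        counts[j] <- counts[j] - 1L
      }
      guard <- guard + 1L
    }
    if (sum(counts) != v$total) {
      stop(errorCondition("variant total unreachable within count range",
                          class = c("genetrust_config_error",
                                    "genetrust_error")))
    }
  }
  as.integer(counts)
}

generate_patient <- function(config, voc, uuid, sex, race, eth, platform,
                             n_somatic, has_ehr, has_imaging, inject_phi,
                             out_dir) {
  pdir <- file.path(out_dir, "raw", uuid)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)

  age_years <- max(21, min(95, round(stats::rnorm(1, config$age_mean,
                                                  config$age_sd))))
  dob <- as.Date("2019-06-01") - round(age_years * 365.25) -
    sample.int(300L, 1L)
  first_contact <- as.Date("2018-01-01") + sample.int(365L, 1L)
  dx_date <- first_contact + sample.int(60L, 1L)
  rx_start <- dx_date + sample.int(45L, 1L)
  rx_end <- rx_start + sample.int(180L, 1L)
  extraction <- as.Date("2019-06-01")

  disease_row <- voc$disease[sample.int(nrow(voc$disease), 1L,
                                        prob = c(7, 4, 1, 1, 1, 1, 1, 2)), ]
  tissue <- sample(synthetic_tissues, 1L,
                   prob = c(5, 3, 1, 1, 2, 2, 1, 1))
  drugs <- sample(voc$drugs$drug, sample.int(3L, 1L))

  gold <- build_gold_facts(voc, sex, race, eth, disease_row, drugs,
                           dob, dx_date, rx_start, rx_end)
  suspense <- stats::runif(1) < config$capture$p_suspense
  captured <- draw_captured(config, gold, suspense)

  mrn <- sprintf("%07d", sample.int(9000000L, 1L) + 999999L)
  full_name <- paste(sample(synthetic_first_names, 1L),
                     sample(synthetic_last_names, 1L))

  injected_phi <- list()
  if (has_ehr) {
    inj <- if (inject_phi) draw_phi_injection() else NULL
    write_raw_registry(pdir, uuid, full_name, mrn, dob, age_years,
                       first_contact, dx_date, rx_start, rx_end,
                       sex, race, eth, disease_row, drugs, voc,
                       captured$registry, suspense, inj)
    if (!is.null(inj)) injected_phi <- list(inj)
    write_raw_omop(pdir, voc, dob, dx_date, rx_start, rx_end, extraction,
                   disease_row, drugs, captured$omop)
  }

  somatic <- NULL
  if (platform != "none") {
    somatic <- draw_variants(config, uuid, tissue, disease_row$disease,
                             n_somatic)
    germ <- draw_germline(config, uuid, tissue, disease_row$disease)
    raw_calls <- rbind(somatic, germ)
    raw_calls <- raw_calls[sample.int(nrow(raw_calls)), , drop = FALSE]
    if (platform == "fmi") {
      write_variant_xml(raw_calls, file.path(pdir, "variants.xml"))
    } else {
      write_somatic_vcf(raw_calls, file.path(pdir, "variants.vcf"))
    }
  }

  if (has_imaging) {
    writeBin(as.raw(sample.int(256L, 4096L, replace = TRUE) - 1L),
             file.path(pdir, "image_0.bin"))
  }

  if (length(list.files(pdir, recursive = TRUE)) == 0L) {
    unlink(pdir, recursive = TRUE)  # nothing shareable for this patient
  }

  expected <- score_patient(
    gold,
    registry_facts = if (has_ehr) captured$registry else NULL,
    omop_facts = if (has_ehr) captured$omop else NULL)

  truth <- list(
    patient_id = uuid, date_of_birth = format(dob), sex = sex, race = race,
    ethnicity = eth, age_years = age_years, platform = platform,
    disease = disease_row$disease, tissue_of_origin = tissue,
    has_ehr = has_ehr, suspense = suspense,
    dates = list(first_contact = format(first_contact),
                 diagnosis = format(dx_date), rx_start = format(rx_start),
                 rx_end = format(rx_end), extraction = format(extraction)),
    gold = lapply(gold, as.list),
    captured = list(registry = lapply(captured$registry, as.list),
                    omop = lapply(captured$omop, as.list)),
    expected_scores = list(
      registry = as.list(stats::setNames(expected$elements$registry,
                                         expected$elements$element)),
      omop = as.list(stats::setNames(expected$elements$omop,
                                     expected$elements$element)),
      total_registry = unname(expected$totals["registry"]),
      total_omop = unname(expected$totals["omop"])),
    somatic_variants = if (is.null(somatic)) list()
                       else table_to_document(somatic)$rows,
    n_somatic = if (is.null(somatic)) 0L else nrow(somatic),
    injected_phi = injected_phi)

  meta <- tibble::tibble(patient_id = uuid, sex = sex, race = race,
                         ethnicity = eth, age_years = age_years,
                         platform = platform, disease = disease_row$disease,
                         tissue_of_origin = tissue, has_ehr = has_ehr,
                         suspense = suspense,
                         n_somatic = if (is.null(somatic)) 0L
                                     else nrow(somatic),
                         expected_registry = unname(expected$totals["registry"]),
                         expected_omop = unname(expected$totals["omop"]))
  list(truth = truth, meta = meta)
}

build_gold_facts <- function(voc, sex, race, eth, disease_row, drugs,
                             dob, dx_date, rx_start, rx_end) {
  list(
    "Gender" = paste0("sex:", sex),
    "Ethnicity" = paste0("eth:", eth),
    "Race" = paste0("race:", race),
    "Date of Diagnosis" = paste0("dxdate:",
                                 date_to_age_days(format(dx_date), dob)),
    "Basis of Diagnosis" = c(sample(voc$basis$token, 1L),
                             sample(voc$basisproc$token, 1L)),
    "Cancer Site" = c(paste0("site:", disease_row$topo),
                      paste0("sitegroup:", disease_row$seer_group)),
    "Cancer Histology" = paste0("hist:", disease_row$morph),
    "Therapeutic Agent" = paste0("drug:", drugs),
    "Treatment Start Date" = paste0("rxstart:",
                                    date_to_age_days(format(rx_start), dob)),
    "Treatment End Date" = paste0("rxend:",
                                  date_to_age_days(format(rx_end), dob))
  )
}

# suspense registry records leave basis and therapy elements unabstracted
suspense_blocked_elements <- c("Basis of Diagnosis", "Therapeutic Agent",
                               "Treatment Start Date", "Treatment End Date")

draw_captured <- function(config, gold, suspense) {
  reg <- lapply(gold_elements(), function(el) {
    if (suspense && el %in% suspense_blocked_elements) return(character(0))
    toks <- gold[[el]]
    toks[stats::runif(length(toks)) < config$capture$registry_p]
  })
  names(reg) <- gold_elements()
  om <- lapply(gold_elements(), function(el) {
    toks <- gold[[el]]
    p <- rep(config$capture$omop_p[[el]], length(toks))
    p[startsWith(toks, "sitegroup:")] <- config$capture$omop_sitegroup_p
    toks[stats::runif(length(toks)) < p]
  })
  names(om) <- gold_elements()
  list(registry = reg, omop = om)
}

draw_phi_injection <- function() {
  category <- sample(c("date-literal", "ssn-like", "phone-like",
                       "email-like", "mrn-like", "denied-key"), 1L)
  switch(category,
    "date-literal" = list(category = category, key = "abstract_notes",
                          value = paste0("follow-up on ",
                                         sample(1:12, 1), "/",
                                         sample(1:28, 1), "/",
                                         sample(2015:2019, 1))),
    "ssn-like" = list(category = category, key = "abstract_notes",
                      value = sprintf("ssn on file %03d-%02d-%04d",
                                      sample(100:899, 1), sample(10:99, 1),
                                      sample(1000:9999, 1))),
    "phone-like" = list(category = category, key = "abstract_notes",
                        value = sprintf("call back %03d-555-%04d",
                                        sample(200:989, 1),
                                        sample(1000:9999, 1))),
    "email-like" = list(category = category, key = "abstract_notes",
                        value = paste0("reach at patient",
                                       sample.int(999L, 1L),
                                       "@example.org")),
    "mrn-like" = list(category = category, key = "record_number",
                      value = sprintf("%07d",
                                      sample.int(9000000L, 1L) + 999999L)),
    "denied-key" = list(category = category, key = "contact",
                        value = paste(sample(synthetic_first_names, 1L),
                                      sample(synthetic_last_names, 1L)))
  )
}

write_raw_registry <- function(pdir, uuid, full_name, mrn, dob, age_years,
                               first_contact, dx_date, rx_start, rx_end,
                               sex, race, eth, disease_row, drugs, voc,
                               captured, suspense, inj) {
  tok_val <- function(el, prefix) {
    toks <- captured[[el]]
    hit <- toks[startsWith(toks, prefix)]
    if (length(hit)) sub(paste0("^", prefix), "", hit[1L]) else ""
  }
  reg_label <- function(tab, el, prefix) {
    toks <- captured[[el]]
    hit <- toks[startsWith(toks, prefix)]
    if (!length(hit)) return("")
    tab$registry_value[match(hit[1L], tab$token)]
  }
  captured_drugs <- sub("^drug:", "",
                        captured[["Therapeutic Agent"]])
  basis_val <- {
    toks <- captured[["Basis of Diagnosis"]]
    hit <- toks[startsWith(toks, "basis:")]
    if (length(hit)) voc$basis$value[match(hit[1L], voc$basis$token)] else ""
  }
  basisproc_val <- {
    toks <- captured[["Basis of Diagnosis"]]
    hit <- toks[startsWith(toks, "basisproc:")]
    if (length(hit)) voc$basisproc$value[match(hit[1L], voc$basisproc$token)]
    else ""
  }
  row <- list(
    patient_id = uuid,
    name = full_name,
    mrn = mrn,
    date_of_birth = format(dob),
    age = age_years,
    date_of_first_contact = format(first_contact),
    sex = reg_label(voc$sex, "Gender", "sex:"),
    spanish_origin = reg_label(voc$ethnicity, "Ethnicity", "eth:"),
    race = reg_label(voc$race, "Race", "race:"),
    date_of_diagnosis = if (nzchar(tok_val("Date of Diagnosis", "dxdate:")))
      format(dx_date) else "",
    dx_confirmation = basis_val,
    dx_staging_proc = basisproc_val,
    cancer_site_icdo3 = tok_val("Cancer Site", "site:"),
    seer_site_group = tok_val("Cancer Site", "sitegroup:"),
    cancer_histology_icdo3 = tok_val("Cancer Histology", "hist:"),
    chemo_text = paste(captured_drugs, collapse = ";"),
    chemo_code = paste(voc$drugs$code[match(captured_drugs, voc$drugs$drug)],
                       collapse = ";"),
    chemo_start_date = if (nzchar(tok_val("Treatment Start Date", "rxstart:")))
      format(rx_start) else "",
    chemo_end_date = if (nzchar(tok_val("Treatment End Date", "rxend:")))
      format(rx_end) else "",
    abstract_notes = "reviewed by registrar"
  )
  if (!is.null(inj)) row[[inj$key]] <- paste(row[[inj$key]] %||% "",
                                             inj$value)
  df <- as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(pdir, "registry.csv"), sep = ",",
                     quote = TRUE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

write_raw_omop <- function(pdir, voc, dob, dx_date, rx_start, rx_end,
                           extraction, disease_row, drugs, captured) {
  odir <- file.path(pdir, "omop")
  dir.create(odir, showWarnings = FALSE)
  has <- function(el, prefix) any(startsWith(captured[[el]], prefix))
  concept_of <- function(tab, key_col, key) {
    tab$concept_id[match(key, tab[[key_col]])]
  }
  person <- tibble::tibble(
    person_id = 1L,
    gender_concept_id = if (has("Gender", "sex:"))
      concept_of(voc$sex, "token", captured[["Gender"]][1L]) else 0L,
    ethnicity_concept_id = if (has("Ethnicity", "eth:"))
      concept_of(voc$ethnicity, "token", captured[["Ethnicity"]][1L]) else 0L,
    race_concept_id = if (has("Race", "race:"))
      concept_of(voc$race, "token", captured[["Race"]][1L]) else 0L,
    year_of_birth = as.integer(format(dob, "%Y")),
    birth_datetime = format(dob))

  cond <- tibble::tibble(condition_occurrence_id = integer(0),
                         person_id = integer(0),
                         condition_concept_id = integer(0),
                         condition_start_date = character(0))
  cid <- 1L
  if (has("Cancer Site", "site:") || has("Date of Diagnosis", "dxdate:")) {
    cond <- rbind(cond, tibble::tibble(
      condition_occurrence_id = cid, person_id = 1L,
      condition_concept_id = if (has("Cancer Site", "site:"))
        concept_of(voc$site_concepts, "topo", disease_row$topo) else 0L,
      condition_start_date = if (has("Date of Diagnosis", "dxdate:"))
        format(dx_date) else ""))
    cid <- cid + 1L
  }
  if (has("Cancer Site", "sitegroup:")) {
    cond <- rbind(cond, tibble::tibble(
      condition_occurrence_id = cid, person_id = 1L,
      condition_concept_id = concept_of(voc$sitegroup_concepts, "seer_group",
                                        disease_row$seer_group),
      condition_start_date = ""))
    cid <- cid + 1L
  }
  if (has("Cancer Histology", "hist:")) {
    cond <- rbind(cond, tibble::tibble(
      condition_occurrence_id = cid, person_id = 1L,
      condition_concept_id = concept_of(voc$hist_concepts, "morph",
                                        disease_row$morph),
      condition_start_date = ""))
    cid <- cid + 1L
  }
  # background (non-scored) conditions with real dates
  n_bg <- sample.int(4L, 1L)
  for (b in seq_len(n_bg)) {
    cond <- rbind(cond, tibble::tibble(
      condition_occurrence_id = cid, person_id = 1L,
      condition_concept_id = 7000000L + sample.int(500L, 1L),
      condition_start_date = format(dx_date + sample.int(120L, 1L))))
    cid <- cid + 1L
  }

  proc <- tibble::tibble(procedure_occurrence_id = integer(0),
                         person_id = integer(0),
                         procedure_concept_id = integer(0),
                         procedure_date = character(0))
  pid_no <- 1L
  for (tok in captured[["Basis of Diagnosis"]]) {
    cidp <- c(voc$basis$concept_id[match(tok, voc$basis$token)],
              voc$basisproc$concept_id[match(tok, voc$basisproc$token)])
    cidp <- cidp[!is.na(cidp)][1L]
    proc <- rbind(proc, tibble::tibble(
      procedure_occurrence_id = pid_no, person_id = 1L,
      procedure_concept_id = cidp, procedure_date = format(dx_date)))
    pid_no <- pid_no + 1L
  }

  captured_drugs <- sub("^drug:", "", captured[["Therapeutic Agent"]])
  start_s <- if (has("Treatment Start Date", "rxstart:"))
    format(rx_start) else ""
  end_s <- if (has("Treatment End Date", "rxend:")) format(rx_end) else ""
  drug_tab <- tibble::tibble(drug_exposure_id = integer(0),
                             person_id = integer(0),
                             drug_concept_id = integer(0),
                             drug_exposure_start_date = character(0),
                             drug_exposure_end_date = character(0))
  drug_rows <- captured_drugs
  if (!length(drug_rows) && (nzchar(start_s) || nzchar(end_s))) {
    drug_rows <- NA_character_  # dates captured without an identified agent
  }
  for (j in seq_along(drug_rows)) {
    drug_tab <- rbind(drug_tab, tibble::tibble(
      drug_exposure_id = j, person_id = 1L,
      drug_concept_id = if (is.na(drug_rows[j])) 0L else
        concept_of(voc$drugs, "drug", drug_rows[j]),
      drug_exposure_start_date = start_s,
      drug_exposure_end_date = end_s))
  }

  n_meas <- sample.int(3L, 1L)
  meas <- tibble::tibble(
    measurement_id = seq_len(n_meas), person_id = 1L,
    measurement_concept_id = 3000000L + sample.int(100L, n_meas),
    measurement_date = format(dx_date + sample.int(90L, n_meas,
                                                   replace = TRUE)),
    value_as_number = round(stats::runif(n_meas, 0.5, 300), 1))

  ext <- omop_extract(list(person = person, condition_occurrence = cond,
                           procedure_occurrence = proc,
                           drug_exposure = drug_tab, measurement = meas))
  write_omop_extract(ext, odir)
  invisible(NULL)
}

draw_variants <- function(config, uuid, tissue, disease, n_somatic) {
  v <- config$variants
  w <- rep(1, length(synthetic_gene_pool))
  w[1:4] <- c(8, 8, 5, 6)  # recurrent drivers
  genes <- sample(synthetic_gene_pool, n_somatic, replace = TRUE, prob = w)
  statuses <- sample(names(v$status_w), n_somatic, replace = TRUE,
                     prob = v$status_w / sum(v$status_w))
  effects <- sample(names(v$effect_w), n_somatic, replace = TRUE,
                    prob = v$effect_w)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  pchange <- paste0(sample(aa, n_somatic, replace = TRUE),
                    sample.int(900L, n_somatic, replace = TRUE),
                    sample(aa, n_somatic, replace = TRUE))
  variant_calls(gene = genes, protein_change = pchange, status = statuses,
                effect = effects, origin = "somatic", patient_id = uuid,
                tissue_of_origin = tissue, primary_disease = disease)
}

draw_germline <- function(config, uuid, tissue, disease) {
  n_germ <- stats::rpois(1, config$variants$germline_mean)
  if (n_germ == 0L) return(variant_calls(character(0)))
  genes <- sample(synthetic_gene_pool, n_germ, replace = TRUE)
  variant_calls(gene = genes,
                protein_change = paste0("G", sample.int(500L, n_germ,
                                                        replace = TRUE), "S"),
                status = "unknown", effect = "missense", origin = "germline",
                patient_id = uuid, tissue_of_origin = tissue,
                primary_disease = disease)
}

#' Load the packaged registry-vs-OMOP totals fixture
#'
#' The packaged 17-patient score table of per-patient completeness totals
#' (registry and OMOP, each out of 50) used throughout the tests and the
#' reproduction scripts.
#'
#' @return A `cgt_score_matrix` (totals only; 17 patients).
#' @export
load_table4_fixture <- function() {
  path <- system.file("extdata", "table4_scores.tsv", package = "genetrust",
                      mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", colClasses = c("character",
                                                           "integer",
                                                           "integer"))
  score_matrix_from_totals(tibble::as_tibble(df))
}
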