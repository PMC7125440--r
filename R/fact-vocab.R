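#' Fact-token vocabulary for completeness scoring
#'
#' The scoring rubric compares sets of atomic fact tokens. How a clinical
#' document maps to tokens is configuration, not biology: this package
#' ships one artifact-defined tokenization shared by the synthetic-cohort
#' generator and the fact extractors, so expected scores are exactly
#' recoverable from what the generator chose to capture. Tokens are
#' prefixed strings, e.g. `sex:female`, `site:C25.0`, `dxdate:21550`,
#' `drug:gemcitabine`.
#'
#' @return Named list of vocabulary tables (tibbles).
#' @export
fact_vocabulary <- function() {
  list(
    sex = tibble::tibble(
      token = c("sex:male", "sex:female"),
      registry_value = c("Male", "Female"),
      concept_id = c(8507L, 8532L)),
    ethnicity = tibble::tibble(
      token = c("eth:hispanic", "eth:non-hispanic"),
      registry_value = c("Hispanic/Latino", "Non-Hispanic"),
      concept_id = c(38003563L, 38003564L)),
    race = tibble::tibble(
      token = c("race:white", "race:asian", "race:unknown"),
      registry_value = c("White", "Asian", "Unknown"),
      concept_id = c(8527L, 8515L, 8552L)),
    disease = tibble::tibble(
      disease = c("pancreatic adenocarcinoma", "cholangiocarcinoma",
                  "anal squamous carcinoma", "gastric cancer", "colon cancer",
                  "gastrointestinal stromal tumor", "cecal cancer",
                  "cancer of unknown primary"),
      topo = c("C25.0", "C22.1", "C21.0", "C16.9", "C18.9", "C26.9",
               "C18.0", "C80.9"),
      seer_group = c("Pancreas", "Liver and Intrahepatic Bile Duct", "Anus",
                     "Stomach", "Colon excluding Rectum", "Miscellaneous",
                     "Colon excluding Rectum", "Miscellaneous"),
      morph = c("8140/3", "8160/3", "8070/3", "8140/3", "8140/3", "8936/3",
                "8140/3", "8000/3")),
    site_concepts = tibble::tibble(
      topo = c("C25.0", "C22.1", "C21.0", "C16.9", "C18.9", "C26.9",
               "C18.0", "C80.9"),
      concept_id = 4000001L + 0:7),
    sitegroup_concepts = tibble::tibble(
      seer_group = c("Pancreas", "Liver and Intrahepatic Bile Duct", "Anus",
                     "Stomach", "Colon excluding Rectum", "Miscellaneous"),
      concept_id = 4100001L + 0:5),
    hist_concepts = tibble::tibble(
      morph = c("8140/3", "8160/3", "8070/3", "8936/3", "8000/3"),
      concept_id = 4200001L + 0:4),
    basis = tibble::tibble(
      token = c("basis:pathology", "basis:cytology", "basis:imaging"),
      value = c("pathology", "cytology", "imaging"),
      concept_id = 4500001L + 0:2),
    basisproc = tibble::tibble(
      token = c("basisproc:biopsy", "basisproc:resection", "basisproc:fna"),
      value = c("biopsy", "resection", "fna"),
      concept_id = 4600001L + 0:2),
    drugs = tibble::tibble(
      drug = c("gemcitabine", "cisplatin", "oxaliplatin", "fluorouracil",
               "capecitabine", "irinotecan", "paclitaxel", "trastuzumab"),
      code = paste0("RX", 101:108),
      concept_id = 19010001L + 0:7)
  )
}

#' Extract scoring fact tokens from a deidentified registry row
#'
#' Inverts the shipped tokenization: each populated registry field yields
#' the corresponding fact tokens, keyed by gold element.
#'
#' @param row One-row tibble from [deidentify_registry()].
#' @return Named list (one entry per [gold_elements()] name) of token sets.
#' @export
registry_facts <- function(row) {
  row <- tibble::as_tibble(row)
  stopifnot(nrow(row) == 1L)
  voc <- fact_vocabulary()
  val <- function(col) {
    v <- row[[col]] %||% NA_character_
    if (length(v) != 1L || is.na(v) || (is.character(v) && !nzchar(v))) NULL
    else v
  }
  lookup <- function(tab, value_col, v) {
    hit <- tab$token[tab[[value_col]] == v]
    if (length(hit)) hit else character(0)
  }
  facts <- list()
  facts[["Gender"]] <- if (!is.null(v <- val("sex")))
    lookup(voc$sex, "registry_value", v) else character(0)
  facts[["Ethnicity"]] <- if (!is.null(v <- val("spanish_origin")))
    lookup(voc$ethnicity, "registry_value", v) else character(0)
  facts[["Race"]] <- if (!is.null(v <- val("race")))
    lookup(voc$race, "registry_value", v) else character(0)
  facts[["Date of Diagnosis"]] <- if (!is.null(v <- val("diagnosis_age_days")))
    paste0("dxdate:", v) else character(0)
  facts[["Basis of Diagnosis"]] <- c(
    if (!is.null(v <- val("dx_confirmation")))
      lookup(voc$basis, "value", v) else character(0),
    if (!is.null(v <- val("dx_staging_proc")))
      lookup(voc$basisproc, "value", v) else character(0))
  facts[["Cancer Site"]] <- c(
    if (!is.null(v <- val("cancer_site_icdo3")))
      paste0("site:", v) else character(0),
    if (!is.null(v <- val("seer_site_group")))
      paste0("sitegroup:", v) else character(0))
  facts[["Cancer Histology"]] <- if (!is.null(v <- val("cancer_histology_icdo3")))
    paste0("hist:", v) else character(0)
  facts[["Therapeutic Agent"]] <- if (!is.null(v <- val("chemo_text")))
    paste0("drug:", trimws(strsplit(v, ";")[[1L]])) else character(0)
  facts[["Treatment Start Date"]] <- if (!is.null(v <- val("chemo_start_age_days")))
    paste0("rxstart:", v) else character(0)
  facts[["Treatment End Date"]] <- if (!is.null(v <- val("chemo_end_age_days")))
    paste0("rxend:", v) else character(0)
  facts
}

#' Extract scoring fact tokens from a deidentified OMOP extract
#'
#' Person-level concepts map to demographic tokens; condition rows map to
#' cancer-site, site-group, histology and diagnosis-date tokens via the
#' shipped concept tables; procedure rows to basis-of-diagnosis tokens; and
#' drug-exposure rows to therapeutic-agent and treatment-date tokens.
#' Concepts outside the vocabulary contribute nothing.
#'
#' @param extract A deidentified [omop_extract()] for one patient.
#' @return Named list (one entry per [gold_elements()] name) of token sets.
#' @export
omop_facts <- function(extract) {
  stopifnot(inherits(extract, "omop_extract"))
  voc <- fact_vocabulary()
  tabs <- extract$tables
  facts <- stats::setNames(rep(list(character(0)), length(gold_elements())),
                           gold_elements())
  person <- tabs$person
  if (!is.null(person) && nrow(person)) {
    concept_token <- function(tab, id) {
      if (is.na(id) || id == 0L) character(0)
      else tab$token[match(id, tab$concept_id)] %||% character(0)
    }
    facts[["Gender"]] <- stats::na.omit(
      concept_token(voc$sex, person$gender_concept_id[1L]))
    facts[["Ethnicity"]] <- stats::na.omit(
      concept_token(voc$ethnicity, person$ethnicity_concept_id[1L]))
    facts[["Race"]] <- stats::na.omit(
      concept_token(voc$race, person$race_concept_id[1L]))
  }
  cond <- tabs$condition_occurrence
  if (!is.null(cond) && nrow(cond)) {
    for (i in seq_len(nrow(cond))) {
      cid <- cond$condition_concept_id[i]
      hit_site <- voc$site_concepts$topo[match(cid, voc$site_concepts$concept_id)]
      hit_grp <- voc$sitegroup_concepts$seer_group[
        match(cid, voc$sitegroup_concepts$concept_id)]
      hit_hist <- voc$hist_concepts$morph[match(cid, voc$hist_concepts$concept_id)]
      if (!is.na(hit_site)) {
        facts[["Cancer Site"]] <- c(facts[["Cancer Site"]],
                                    paste0("site:", hit_site))
      }
      if (!is.na(hit_grp)) {
        facts[["Cancer Site"]] <- c(facts[["Cancer Site"]],
                                    paste0("sitegroup:", hit_grp))
      }
      if (!is.na(hit_hist)) {
        facts[["Cancer Histology"]] <- c(facts[["Cancer Histology"]],
                                         paste0("hist:", hit_hist))
      }
      age <- cond$condition_start_age_days[i]
      if (!is.null(age) && !is.na(age) && is.na(hit_hist)) {
        facts[["Date of Diagnosis"]] <- c(facts[["Date of Diagnosis"]],
                                          paste0("dxdate:", age))
      }
    }
  }
  proc <- tabs$procedure_occurrence
  if (!is.null(proc) && nrow(proc)) {
    for (cid in proc$procedure_concept_id) {
      tok <- c(voc$basis$token[match(cid, voc$basis$concept_id)],
               voc$basisproc$token[match(cid, voc$basisproc$concept_id)])
      facts[["Basis of Diagnosis"]] <- c(facts[["Basis of Diagnosis"]],
                                         tok[!is.na(tok)])
    }
  }
  drug <- tabs$drug_exposure
  if (!is.null(drug) && nrow(drug)) {
    for (i in seq_len(nrow(drug))) {
      cid <- drug$drug_concept_id[i]
      nm <- voc$drugs$drug[match(cid, voc$drugs$concept_id)]
      if (!is.na(nm)) {
        facts[["Therapeutic Agent"]] <- c(facts[["Therapeutic Agent"]],
                                          paste0("drug:", nm))
      }
      s <- drug$drug_exposure_start_age_days[i]
      e <- drug$drug_exposure_end_age_days[i]
      if (!is.null(s) && !is.na(s)) {
        facts[["Treatment Start Date"]] <- c(facts[["Treatment Start Date"]],
                                             paste0("rxstart:", s))
      }
      if (!is.null(e) && !is.na(e)) {
        facts[["Treatment End Date"]] <- c(facts[["Treatment End Date"]],
                                           paste0("rxend:", e))
      }
    }
  }
  lapply(facts, function(x) unique(as.character(x)))
}
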