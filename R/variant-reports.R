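#' Variant call tibble
#'
#' One row per reported variant: HGNC-style `gene` symbol
#' (uppercase-normalized), optional `protein_change`, knowledge `status`
#' (`known` / `likely` / `unknown` pathogenicity), functional `effect`
#' (`missense`, `nonsense`, `frameshift`, `splice`, `indel`, `other`),
#' `origin` (`somatic` / `germline` / `unknown-origin`), plus the carrying
#' patient's UUID, tissue of origin and primary disease.
#'
#' @param gene,protein_change,status,effect,origin,patient_id,tissue_of_origin,primary_disease
#'   Column vectors, recycled to a common length.
#' @return Tibble with the [variant_columns()] layout.
#' @export
variant_calls <- function(gene, protein_change = NA_character_,
                          status = "unknown", effect = "other",
                          origin = "somatic", patient_id = NA_character_,
                          tissue_of_origin = NA_character_,
                          primary_disease = NA_character_) {
  tibble::tibble(gene = toupper(as.character(gene)),
                 protein_change = as.character(protein_change),
                 status = map_status(status), effect = map_effect(effect),
                 origin = as.character(origin),
                 patient_id = as.character(patient_id),
                 tissue_of_origin = as.character(tissue_of_origin),
                 primary_disease = as.character(primary_disease))
}

map_status <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("known", "known pathogenic", "pathogenic")] <- "known"
  out[x %in% c("likely", "likely pathogenic")] <- "likely"
  out[x %in% c("unknown", "unknown significance", "uncertain significance",
               "variant of unknown significance", "vus",
               "unknown consequence")] <- "unknown"
  unmapped <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(unmapped)) {
    warning("unmappable knowledge status treated as unknown: ",
            paste(unique(x[unmapped]), collapse = ", "), call. = FALSE)
  }
  out[is.na(out)] <- "unknown"
  out
}

map_effect <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("missense", "missense_variant")] <- "missense"
  out[x %in% c("nonsense", "stop-gain", "stopgain", "stop gained",
               "stop_gained")] <- "nonsense"
  out[grepl("^frame[-_ ]?shift", x) | x == "frameshift"] <- "frameshift"
  out[x %in% c("splice", "splice-site", "splice site", "splicing",
               "splice_region_variant")] <- "splice"
  out[x %in% c("indel", "inframe-indel", "in-frame indel", "insertion",
               "deletion", "duplication", "inframe_insertion",
               "inframe_deletion")] <- "indel"
  unmapped <- is.na(out) & !is.na(x) & nzchar(x) & x != "other"
  if (any(unmapped)) {
    warning("unmappable functional effect treated as other: ",
            paste(unique(x[unmapped]), collapse = ", "), call. = FALSE)
  }
  out[is.na(out)] <- "other"
  out
}

#' Parse a variant-report XML document
#'
#' Reads the package's documented report schema (modelled on the content of
#' commercial panel reports: one `short-variant` element per call carrying
#' `gene`, `protein-effect`, `functional-effect`, `status` and `origin`
#' attributes under `variant-report/short-variants`; patient identifier,
#' tissue of origin and primary disease are attributes of the root).
#' Parsing real vendor reports is an adapter concern; this schema carries
#' the same fields.
#'
#' @param x Path to an XML file, raw bytes, or XML text.
#' @return Tibble of variant calls.
#' @export
parse_variant_xml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e) {
    stop(errorCondition(paste0("malformed variant XML: ",
                               conditionMessage(e)),
                        class = c("genetrust_parse_error", "genetrust_error")))
  })
  root <- xml2::xml_find_first(doc, "/variant-report")
  if (inherits(root, "xml_missing")) {
    stop(errorCondition("not a variant-report document",
                        class = c("genetrust_parse_error", "genetrust_error")))
  }
  pid <- xml2::xml_attr(root, "patient-id")
  tissue <- xml2::xml_attr(root, "tissue-of-origin")
  disease <- xml2::xml_attr(root, "primary-disease")
  nodes <- xml2::xml_find_all(doc, "//short-variants/short-variant")
  if (length(nodes) == 0L) {
    return(variant_calls(character(0)))
  }
  genes <- xml2::xml_attr(nodes, "gene")
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop(errorCondition(
      paste0("short-variant element ",
             which(is.na(genes) | !nzchar(genes))[1L],
             " is missing its gene attribute"),
      class = c("genetrust_parse_error", "genetrust_error")))
  }
  variant_calls(
    gene = genes,
    protein_change = xml2::xml_attr(nodes, "protein-effect"),
    status = xml2::xml_attr(nodes, "status", default = "unknown"),
    effect = xml2::xml_attr(nodes, "functional-effect", default = "other"),
    origin = ifelse(is.na(xml2::xml_attr(nodes, "origin")), "somatic",
                    xml2::xml_attr(nodes, "origin")),
    patient_id = pid, tissue_of_origin = tissue, primary_disease = disease)
}

#' Write variant calls in the report XML schema
#'
#' @param calls Tibble of variant calls (one patient).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variant_xml <- function(calls, path) {
  root <- xml2::xml_new_root("variant-report")
  if (nrow(calls)) {
    xml2::xml_set_attr(root, "patient-id", calls$patient_id[1L])
    xml2::xml_set_attr(root, "tissue-of-origin", calls$tissue_of_origin[1L])
    xml2::xml_set_attr(root, "primary-disease", calls$primary_disease[1L])
  }
  sv <- xml2::xml_add_child(root, "short-variants")
  for (i in seq_len(nrow(calls))) {
    node <- xml2::xml_add_child(sv, "short-variant")
    xml2::xml_set_attr(node, "gene", calls$gene[i])
    if (!is.na(calls$protein_change[i])) {
      xml2::xml_set_attr(node, "protein-effect", calls$protein_change[i])
    }
    xml2::xml_set_attr(node, "status", calls$status[i])
    xml2::xml_set_attr(node, "functional-effect", calls$effect[i])
    xml2::xml_set_attr(node, "origin", calls$origin[i])
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Parse a somatic VCF into variant calls
#'
#' Accepts VCF 4.x with per-record annotations in INFO under the keys
#' `GENE=`, `PCHANGE=`, `EFFECT=`, `STATUS=` and `ORIGIN=`. Only records
#' with `FILTER == PASS` are kept; a record lacking `STATUS` defaults to
#' unknown significance, and a record lacking `ORIGIN` is taken as somatic
#' (the file contract is a somatic VCF). Patient metadata may be carried in
#' `##patient_id=`, `##tissue_of_origin=` and `##primary_disease=` header
#' lines.
#'
#' @param x Path to a VCF file, or raw bytes.
#' @return Tibble of variant calls.
#' @export
parse_somatic_vcf <- function(x) {
  path <- x
  if (is.raw(x)) {
    path <- tempfile(fileext = ".vcf")
    on.exit(unlink(path))
    writeBin(x, path)
  }
  first <- readLines(path, n = 1L)
  if (!length(first) || !grepl("^##fileformat=VCF", first)) {
    stop(errorCondition("missing VCF header (##fileformat)",
                        class = c("genetrust_parse_error", "genetrust_error")))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  meta_val <- function(key) {
    hit <- grep(paste0("^##", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^##", key, "="), "", hit[1L])
    else NA_character_
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(variant_calls(character(0)))
  keep <- !is.na(fix$FILTER) & fix$FILTER == "PASS"
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) return(variant_calls(character(0)))
  info <- fix$INFO
  genes <- vapply(info, function(s) info_field(s, "GENE"), character(1),
                  USE.NAMES = FALSE)
  variant_calls(
    gene = genes,
    protein_change = vapply(info, function(s) info_field(s, "PCHANGE"),
                            character(1), USE.NAMES = FALSE),
    status = ifelse(is.na(v <- vapply(info, function(s)
      info_field(s, "STATUS"), character(1), USE.NAMES = FALSE)),
      "unknown", v),
    effect = ifelse(is.na(v2 <- vapply(info, function(s)
      info_field(s, "EFFECT"), character(1), USE.NAMES = FALSE)),
      "other", v2),
    origin = ifelse(is.na(v3 <- vapply(info, function(s)
      info_field(s, "ORIGIN"), character(1), USE.NAMES = FALSE)),
      "somatic", v3),
    patient_id = meta_val("patient_id"),
    tissue_of_origin = meta_val("tissue_of_origin"),
    primary_disease = meta_val("primary_disease"))
}

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  if (length(m) && nzchar(m)) sub(paste0("^;?", key, "="), "", m)
  else NA_character_
}

#' Write variant calls as a minimal somatic VCF
#'
#' @param calls Tibble of variant calls for one patient.
#' @param path Output file.
#' @param filter Per-record FILTER values (default all PASS).
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(calls, path, filter = rep("PASS", nrow(calls))) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Functional effect\">",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Knowledge status\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"somatic or germline\">",
    if (nrow(calls) && !is.na(calls$patient_id[1L]))
      paste0("##patient_id=", calls$patient_id[1L]),
    if (nrow(calls) && !is.na(calls$tissue_of_origin[1L]))
      paste0("##tissue_of_origin=", calls$tissue_of_origin[1L]),
    if (nrow(calls) && !is.na(calls$primary_disease[1L]))
      paste0("##primary_disease=", calls$primary_disease[1L]),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(calls))) {
    info <- paste0("GENE=", calls$gene[i],
                   if (!is.na(calls$protein_change[i]))
                     paste0(";PCHANGE=", calls$protein_change[i]),
                   ";EFFECT=", calls$effect[i],
                   ";STATUS=", calls$status[i],
                   ";ORIGIN=", calls$origin[i])
    writeLines(paste("1", 10000 + i, ".", "A", "T", ".", filter[i], info,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Summarize a somatic variant cohort
#'
#' Cohort-level aggregation of per-patient variant calls: per-patient totals
#' split by knowledge status, functional-effect counts, per-gene variant and
#' carrier counts, and the recurrently mutated genes. Unique variants are
#' keyed by `(gene, protein_change)`: the same protein change seen in two
#' patients is two call instances but one unique variant of its gene.
#' Recurrent genes are those with more than one carrier, ordered by unique
#' variant count, then carrier count, then symbol. Means and standard
#' deviations of per-patient burden use the sample (n-1) denominator.
#'
#' @param calls Non-empty tibble of somatic variant calls with `patient_id`.
#' @return Object of class `cohort_summary`: a list with `n_patients`,
#'   `n_variants`, `n_genes`, `per_patient`, `effect_counts`, `per_gene`,
#'   `recurrent_genes`, `mean_per_patient`, `sd_per_patient`.
#' @export
summarize_cohort <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0L) {
    stop(errorCondition("cannot summarize an empty call set",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  if (anyNA(calls$patient_id)) {
    stop(errorCondition("every call must carry a patient_id",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  patients <- unique(calls$patient_id)
  per_patient <- do.call(rbind, lapply(patients, function(p) {
    sub <- calls[calls$patient_id == p, ]
    tibble::tibble(patient_id = p, total = nrow(sub),
                   known = sum(sub$status == "known"),
                   likely = sum(sub$status == "likely"),
                   unknown = sum(sub$status == "unknown"))
  }))
  effect_levels <- c("missense", "nonsense", "frameshift", "splice", "indel",
                     "other")
  effect_counts <- tibble::tibble(
    effect = effect_levels,
    n = unname(vapply(effect_levels, function(e) sum(calls$effect == e),
                      integer(1))))
  genes <- sort(unique(calls$gene))
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    sub <- calls[calls$gene == g, ]
    tibble::tibble(
      gene = g,
      n_calls = nrow(sub),
      n_unique = nrow(unique(sub[, c("gene", "protein_change")])),
      carriers = length(unique(sub$patient_id)),
      statuses = paste(sort(unique(sub$status)), collapse = "+"))
  }))
  rec <- per_gene[per_gene$carriers > 1L, , drop = FALSE]
  rec <- rec[order(-rec$n_unique, -rec$carriers, rec$gene), , drop = FALSE]
  structure(list(
    n_patients = length(patients),
    n_variants = nrow(calls),
    n_genes = nrow(per_gene),
    per_patient = per_patient,
    effect_counts = effect_counts,
    per_gene = per_gene,
    recurrent_genes = rec$gene,
    mean_per_patient = mean(per_patient$total),
    sd_per_patient = stats::sd(per_patient$total)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n_variants, " variants in ", x$n_genes,
      " genes across ", x$n_patients, " patients\n",
      "  per-patient burden: mean ", round(x$mean_per_patient, 2),
      " (SD ", round(x$sd_per_patient, 2), ")\n",
      "  recurrent genes: ",
      paste(utils::head(x$recurrent_genes, 8), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
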