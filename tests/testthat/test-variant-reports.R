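sample_xml <- function(path) {
  writeLines(c(
    '<variant-report patient-id="00000000-0000-4000-8000-000000000000"',
    ' tissue-of-origin="liver" primary-disease="cholangiocarcinoma">',
    '  <short-variants>',
    '    <short-variant gene="KRAS" protein-effect="G12D"',
    '      functional-effect="missense" status="known" origin="somatic"/>',
    '    <short-variant gene="tp53" protein-effect="R175H"',
    '      functional-effect="missense" status="likely" origin="somatic"/>',
    '    <short-variant gene="MLL2" protein-effect="Q123*"',
    '      functional-effect="nonsense" status="unknown significance"',
    '      origin="germline"/>',
    '  </short-variants>',
    '</variant-report>'), path)
  path
}

test_that("variant XML parses with vocabulary mapping", {
  path <- sample_xml(withr::local_tempfile(fileext = ".xml"))
  calls <- parse_variant_xml(path)
  expect_identical(nrow(calls), 3L)
  expect_identical(calls$gene, c("KRAS", "TP53", "MLL2"))  # uppercased
  expect_identical(calls$status, c("known", "likely", "unknown"))
  expect_identical(calls$effect, c("missense", "missense", "nonsense"))
  expect_identical(calls$origin, c("somatic", "somatic", "germline"))
  expect_identical(unique(calls$tissue_of_origin), "liver")
})

test_that("malformed XML and missing gene attributes error", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<variant-report><short-variants><oops>", bad)
  expect_error_class(parse_variant_xml(bad), "genetrust_parse_error")
  nogene <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0('<variant-report><short-variants>',
                    '<short-variant status="known"/>',
                    '</short-variants></variant-report>'), nogene)
  expect_error_class(parse_variant_xml(nogene), "genetrust_parse_error")
})

test_that("VCF parsing keeps PASS records and applies defaults", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##patient_id=00000000-0000-4000-8000-000000000001",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tA\tT\t.\tPASS\tGENE=KRAS;PCHANGE=G12D;EFFECT=missense;STATUS=known;ORIGIN=somatic",
    "1\t200\t.\tC\tG\t.\tq10\tGENE=TP53;EFFECT=missense;STATUS=known;ORIGIN=somatic",
    "1\t300\t.\tG\tA\t.\tPASS\tGENE=APC;EFFECT=nonsense;ORIGIN=somatic",
    "1\t400\t.\tT\tC\t.\tPASS\tGENE=ATM;EFFECT=missense;STATUS=likely;ORIGIN=germline"),
    path)
  calls <- parse_somatic_vcf(path)
  expect_identical(nrow(calls), 3L)  # one record filtered out
  expect_identical(calls$gene, c("KRAS", "APC", "ATM"))
  expect_identical(calls$status[2L], "unknown")  # STATUS missing
  expect_identical(unique(calls$patient_id),
                   "00000000-0000-4000-8000-000000000001")
  expect_identical(nrow(filter_somatic(calls)), 2L)
})

test_that("a VCF without a header is rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines("1\t100\t.\tA\tT\t.\tPASS\tGENE=KRAS", path)
  expect_error_class(parse_somatic_vcf(path), "genetrust_parse_error")
})

test_that("generator reports round-trip to the generating truth", {
  res <- local_cohort(n = 6L, seed = 31L)
  truth <- res$truth$patients
  for (pid in res$patients$patient_id[res$patients$platform != "none"]) {
    rd <- file.path(res$dir, "raw", pid)
    parsed <- if (file.exists(file.path(rd, "variants.xml"))) {
      parse_variant_xml(file.path(rd, "variants.xml"))
    } else {
      parse_somatic_vcf(file.path(rd, "variants.vcf"))
    }
    somatic <- filter_somatic(parsed)
    want <- truth[[pid]]$somatic_variants
    expect_identical(nrow(somatic), length(want))
    key <- function(g, p) sort(paste(g, p))
    expect_identical(
      key(somatic$gene, somatic$protein_change),
      key(vapply(want, function(v) v$gene, ""),
          vapply(want, function(v) v$protein_change, "")))
  }
})

test_that("cohort summaries obey all conservation invariants", {
  single <- variant_calls(gene = "KRAS", protein_change = "G12D",
                          status = "unknown", effect = "missense",
                          patient_id = fresh_uuid(1))
  s <- summarize_cohort(single)
  expect_identical(s$n_variants, 1L)
  expect_identical(s$effect_counts$n[s$effect_counts$effect == "missense"], 1L)
  expect_length(s$recurrent_genes, 0L)

  withr::with_seed(17, {
    for (k in 1:10) {
      n_pat <- sample(2:6, 1L)
      pats <- ruuid4(n_pat)
      n <- sample(10:60, 1L)
      calls <- variant_calls(
        gene = sample(c("KRAS", "TP53", "ARID1A", "MLL2", "APC", "ATM"),
                      n, replace = TRUE),
        protein_change = paste0("P", sample.int(20L, n, replace = TRUE), "L"),
        status = sample(c("known", "likely", "unknown"), n, replace = TRUE),
        effect = sample(c("missense", "nonsense", "frameshift", "splice",
                          "indel", "other"), n, replace = TRUE),
        patient_id = sample(pats, n, replace = TRUE))
      s <- summarize_cohort(calls)
      expect_identical(sum(s$per_patient$total), s$n_variants)
      expect_identical(sum(s$effect_counts$n), s$n_variants)
      expect_identical(sum(s$per_gene$n_calls), s$n_variants)
      expect_identical(s$per_patient$known + s$per_patient$likely +
                         s$per_patient$unknown, s$per_patient$total)
      expect_identical(s$n_genes, nrow(s$per_gene))
      expect_true(all(s$per_gene$carriers <= s$n_patients))
      # carrier counts equal brute-force set sizes
      for (g in s$per_gene$gene) {
        expect_identical(
          s$per_gene$carriers[s$per_gene$gene == g],
          length(unique(calls$patient_id[calls$gene == g])))
      }
    }
  })
})

test_that("recurrence ordering is total and deterministic", {
  calls <- variant_calls(
    gene = c("AAA", "AAA", "BBB", "BBB", "CCC", "CCC", "DDD"),
    protein_change = c("P1L", "P2L", "P1L", "P1L", "P1L", "P2L", "P1L"),
    patient_id = c(fresh_uuid(1), fresh_uuid(2), fresh_uuid(1), fresh_uuid(2),
                   fresh_uuid(1), fresh_uuid(2), fresh_uuid(1)))
  s <- summarize_cohort(calls)
  # AAA and CCC both have 2 unique variants and 2 carriers; alphabetical
  # tie-break; BBB has 1 unique variant; DDD has a single carrier
  expect_identical(s$recurrent_genes, c("AAA", "CCC", "BBB"))
})

test_that("an empty call set cannot be summarized", {
  expect_error_class(summarize_cohort(variant_calls(character(0))),
                     "genetrust_type_error")
})
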