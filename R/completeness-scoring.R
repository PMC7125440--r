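#' The ten gold-standard clinical data elements
#'
#' The subset of the community-recommended core clinical elements that both
#' a cancer-registry export and an OMOP extract can in principle capture
#' without curation, against which completeness is scored.
#'
#' @return Character vector of the ten element names.
#' @export
gold_elements <- function() {
  c("Gender", "Ethnicity", "Race", "Date of Diagnosis", "Basis of Diagnosis",
    "Cancer Site", "Cancer Histology", "Therapeutic Agent",
    "Treatment Start Date", "Treatment End Date")
}

#' Score one element's completeness on the 0-5 rubric
#'
#' Completeness of a candidate representation against the gold-standard
#' facts for one element: with f the captured fraction
#' `|candidate intersect gold| / |gold|`, the score is `round(5 f)` rounded
#' half away from zero, so 0 means no presence of the element, 5 complete
#' representation, and intermediate values are 20% increments.
#'
#' @param gold_facts Non-empty character set of atomic gold fact tokens.
#' @param candidate_facts Character set of facts found in the candidate
#'   document (may be empty).
#' @return Integer score in 0..5.
#' @export
score_element <- function(gold_facts, candidate_facts) {
  gold_facts <- unique(as.character(gold_facts))
  if (length(gold_facts) == 0L) {
    stop(errorCondition("gold fact set must be non-empty",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  f <- length(intersect(unique(as.character(candidate_facts)), gold_facts)) /
    length(gold_facts)
  round_half_away(5 * f)
}

# round half away from zero, isolated so the rubric's rounding rule lives in
# exactly one place
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Score one patient across all ten elements and both modalities
#'
#' A missing modality document scores 0 on every element; per-modality
#' totals are sums over the ten element scores (maximum 50).
#'
#' @param gold Named list of gold fact sets, one per [gold_elements()] name.
#' @param registry_facts,omop_facts Named lists of captured fact sets per
#'   element (missing names score 0), or `NULL` for an absent modality.
#' @return List with `elements` (tibble: element, registry, omop) and
#'   `totals` (named integer vector).
#' @export
score_patient <- function(gold, registry_facts = NULL, omop_facts = NULL) {
  missing_el <- setdiff(gold_elements(), names(gold))
  if (length(missing_el)) {
    stop(errorCondition(paste0("gold facts missing for element(s): ",
                               paste(missing_el, collapse = ", ")),
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  one <- function(facts, el) {
    if (is.null(facts)) return(0L)
    score_element(gold[[el]], facts[[el]] %||% character(0))
  }
  elements <- tibble::tibble(
    element = gold_elements(),
    registry = vapply(gold_elements(), function(el) one(registry_facts, el),
                      integer(1)),
    omop = vapply(gold_elements(), function(el) one(omop_facts, el),
                  integer(1)))
  list(elements = elements,
       totals = c(registry = sum(elements$registry),
                  omop = sum(elements$omop)))
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Paired test on `value_a - value_b`: zero differences are dropped,
#' absolute differences are ranked with average ranks for ties, and V is
#' the sum of ranks of the positive differences. When the differences are
#' tie-free and at most `exact_threshold` remain, the two-sided p-value is
#' computed from the exact null distribution of V (enumeration over all
#' 2^n sign assignments, evaluated by convolution); otherwise a normal
#' approximation is used with tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48` and a continuity correction of 0.5
#' toward the mean.
#'
#' @param value_a,value_b Paired numeric vectors of equal length.
#' @param exact_threshold Largest tie-free n for which the exact
#'   distribution is used (default 25).
#' @return Object of class `wilcoxon_result`: list with `n_effective`, `V`,
#'   `z` (standardized statistic under the tie-corrected normal
#'   approximation), `p_two_sided`, and `method`.
#' @export
wilcoxon_signed_rank <- function(value_a, value_b, exact_threshold = 25L) {
  stopifnot(length(value_a) == length(value_b))
  d <- as.numeric(value_a) - as.numeric(value_b)
  if (anyNA(d)) {
    stop(errorCondition("missing values in paired differences",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop(errorCondition("all paired differences are zero",
                        class = c("genetrust_degenerate_input",
                                  "genetrust_error")))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- as.integer(table(abs(d)))
  has_ties <- any(ties > 1L)
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  correction <- 0.5 * sign(V - mu)
  z <- if (sigma2 > 0) (V - mu - correction) / sqrt(sigma2) else NA_real_
  if (!has_ties && n <= exact_threshold) {
    p <- exact_signrank_p(V, n)
    method <- "exact-enumeration"
  } else {
    if (sigma2 <= 0) {
      stop(errorCondition("zero variance in signed-rank statistic",
                          class = c("genetrust_degenerate_input",
                                    "genetrust_error")))
    }
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx-tie-corrected"
  }
  structure(list(n_effective = n, V = V, z = z, p_two_sided = p,
                 method = method),
            class = "wilcoxon_result")
}

# Null distribution of V for tie-free ranks 1..n: the number of subsets of
# {1..n} with each rank sum, built by convolution; equivalent to enumerating
# the 2^n sign assignments.
exact_signrank_counts <- function(n) {
  counts <- 1  # index s+1 holds the count of subsets summing to s
  for (rk in seq_len(n)) {
    shifted <- c(rep(0, rk), counts)
    counts <- c(counts, rep(0, rk)) + shifted
  }
  counts
}

exact_signrank_p <- function(V, n) {
  counts <- exact_signrank_counts(n)
  total <- 2^n
  lower <- sum(counts[seq_len(V + 1)]) / total        # P(V <= v)
  upper <- sum(counts[(V + 1):length(counts)]) / total  # P(V >= v)
  min(1, 2 * min(lower, upper))
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon signed-rank (two-sided, ", x$method, ")\n",
      "  n = ", x$n_effective, ", V = ", x$V,
      ", p = ", signif(x$p_two_sided, 3), "\n", sep = "")
  invisible(x)
}

#' Score matrix across patients, elements and modalities
#'
#' Container for per-patient completeness scores in both modalities. Built
#' either from element-level scores (`score_matrix()`) or, when only
#' per-patient totals are known (as in a published totals table), from
#' totals alone (`score_matrix_from_totals()`).
#'
#' @param element_scores Tibble with columns `patient_id`, `element`,
#'   `registry`, `omop` (integer scores 0..5).
#' @return Object of class `cgt_score_matrix` with `elements` (tibble or
#'   `NULL`) and `totals` (tibble: patient_id, registry, omop).
#' @export
score_matrix <- function(element_scores) {
  es <- tibble::as_tibble(element_scores)
  stopifnot(all(c("patient_id", "element", "registry", "omop") %in% names(es)))
  if (any(es$registry < 0 | es$registry > 5 | es$omop < 0 | es$omop > 5)) {
    stop(errorCondition("element scores must lie in 0..5",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  bad <- setdiff(unique(es$element), gold_elements())
  if (length(bad)) {
    stop(errorCondition(paste0("unknown element: ",
                               paste(bad, collapse = ", ")),
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  patients <- unique(es$patient_id)
  totals <- do.call(rbind, lapply(patients, function(p) {
    sub <- es[es$patient_id == p, ]
    tibble::tibble(patient_id = p, registry = sum(sub$registry),
                   omop = sum(sub$omop))
  }))
  structure(list(elements = es, totals = totals), class = "cgt_score_matrix")
}

#' @rdname score_matrix
#' @param totals Tibble with columns `patient_id`, `registry`, `omop`
#'   (per-patient totals, 0..50).
#' @export
score_matrix_from_totals <- function(totals) {
  totals <- tibble::as_tibble(totals)
  stopifnot(all(c("patient_id", "registry", "omop") %in% names(totals)))
  if (any(totals$registry < 0 | totals$registry > 50 |
          totals$omop < 0 | totals$omop > 50)) {
    stop(errorCondition("patient totals must lie in 0..50",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  structure(list(elements = NULL,
                 totals = totals[c("patient_id", "registry", "omop")]),
            class = "cgt_score_matrix")
}

#' @export
print.cgt_score_matrix <- function(x, ...) {
  cat("<cgt_score_matrix> ", nrow(x$totals), " patients",
      if (is.null(x$elements)) " (totals only)\n" else "\n", sep = "")
  print(x$totals, n = 5)
  invisible(x)
}

#' Compare registry and OMOP completeness across a cohort
#'
#' Computes, from a score matrix alone: grand totals per modality, per-
#' modality mean and sample (n-1) standard deviation of patient totals, the
#' count of patients above a completeness threshold (strictly greater than
#' `threshold`, i.e. more than 90% complete at the default of 45), and the
#' two-sided Wilcoxon signed-rank test on paired patient totals. The
#' reported `V` is the positive-rank sum of the OMOP-minus-registry
#' differences; the opposite direction is also reported. When element-level
#' scores are present, the same test is run per element.
#'
#' @param matrix A `cgt_score_matrix`.
#' @param threshold Total-score threshold for the strict-inequality count
#'   (default 45 of a maximum 50).
#' @return Object of class `modality_comparison`: list with `n_patients`,
#'   `totals`, `means`, `sds`, `n_above_threshold`, `threshold`,
#'   `test_total` (a `wilcoxon_result` on OMOP - registry),
#'   `V_registry_minus_omop`, and `per_element` (tibble or `NULL`).
#' @export
compare_modalities <- function(matrix, threshold = 45L) {
  stopifnot(inherits(matrix, "cgt_score_matrix"))
  tt <- matrix$totals
  if (nrow(tt) < 2L) {
    stop(errorCondition("need at least two patients to compare modalities",
                        class = c("genetrust_type_error", "genetrust_error")))
  }
  test_total <- wilcoxon_signed_rank(tt$omop, tt$registry)
  reverse <- wilcoxon_signed_rank(tt$registry, tt$omop)
  per_element <- NULL
  if (!is.null(matrix$elements)) {
    per_element <- do.call(rbind, lapply(gold_elements(), function(el) {
      sub <- matrix$elements[matrix$elements$element == el, ]
      res <- tryCatch(wilcoxon_signed_rank(sub$omop, sub$registry),
                      genetrust_degenerate_input = function(e) NULL)
      tibble::tibble(element = el,
                     V = if (is.null(res)) NA_real_ else res$V,
                     p = if (is.null(res)) NA_real_ else res$p_two_sided,
                     method = if (is.null(res)) "degenerate" else res$method)
    }))
  }
  structure(list(
    n_patients = nrow(tt),
    totals = c(registry = sum(tt$registry), omop = sum(tt$omop)),
    means = c(registry = mean(tt$registry), omop = mean(tt$omop)),
    sds = c(registry = stats::sd(tt$registry), omop = stats::sd(tt$omop)),
    threshold = threshold,
    n_above_threshold = c(registry = sum(tt$registry > threshold),
                          omop = sum(tt$omop > threshold)),
    test_total = test_total,
    V_registry_minus_omop = reverse$V,
    per_element = per_element
  ), class = "modality_comparison")
}

#' @export
print.modality_comparison <- function(x, ...) {
  cat("Registry vs OMOP completeness (", x$n_patients, " patients)\n",
      "  totals: registry ", x$totals[["registry"]], ", OMOP ",
      x$totals[["omop"]], "\n",
      "  means (SD): registry ", round(x$means[["registry"]], 2), " (",
      round(x$sds[["registry"]], 2), "), OMOP ",
      round(x$means[["omop"]], 2), " (", round(x$sds[["omop"]], 2), ")\n",
      "  patients > ", x$threshold, ": registry ",
      x$n_above_threshold[["registry"]], ", OMOP ",
      x$n_above_threshold[["omop"]], "\n",
      "  signed-rank (OMOP - registry): V = ", x$test_total$V, ", p = ",
      signif(x$test_total$p_two_sided, 3), "\n", sep = "")
  invisible(x)
}
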