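test_that("the 0-5 rubric rounds 20% increments half away from zero", {
  gold10 <- paste0("f", 1:10)
  expect_identical(score_element(gold10, gold10), 5L)
  expect_identical(score_element(gold10, character(0)), 0L)
  expect_identical(score_element(gold10, c("f1", "f2", "f3")), 2L)  # 1.5 -> 2
  expect_identical(score_element(gold10, "f1"), 1L)                 # 0.5 -> 1
  expect_identical(score_element(paste0("f", 1:3), c("f1", "f2")), 3L)
  expect_identical(score_element("only", "only"), 5L)
  expect_identical(score_element("only", "other"), 0L)
  expect_error_class(score_element(character(0), "x"),
                     "genetrust_type_error")
})

test_that("score_element is monotone under added matches", {
  withr::with_seed(3, {
    for (k in 1:50) {
      gold <- paste0("g", seq_len(sample.int(8L, 1L)))
      cand <- sample(gold, sample.int(length(gold), 1L) - 1L)
      s0 <- score_element(gold, cand)
      extra <- setdiff(gold, cand)
      if (length(extra)) {
        s1 <- score_element(gold, c(cand, extra[1L]))
        expect_gte(s1, s0)
      }
      # adding non-gold facts never changes the score
      expect_identical(score_element(gold, c(cand, "unrelated")), s0)
    }
  })
})

test_that("patient scores sum per modality and cap at 50", {
  gold <- simple_gold()
  full <- score_patient(gold, registry_facts = gold, omop_facts = gold)
  expect_identical(unname(full$totals), c(50L, 50L))
  none <- score_patient(gold, registry_facts = gold, omop_facts = NULL)
  expect_identical(unname(none$totals["omop"]), 0L)
  expect_true(all(none$elements$omop == 0L))
  withr::with_seed(21, {
    for (k in 1:10) {
      reg <- lapply(gold, function(f) f[stats::runif(length(f)) < 0.6])
      om <- lapply(gold, function(f) f[stats::runif(length(f)) < 0.6])
      got <- score_patient(gold, reg, om)
      brute_r <- sum(vapply(gold_elements(), function(el)
        score_element(gold[[el]], reg[[el]]), integer(1)))
      brute_o <- sum(vapply(gold_elements(), function(el)
        score_element(gold[[el]], om[[el]]), integer(1)))
      expect_identical(unname(got$totals), c(brute_r, brute_o))
      expect_lte(max(got$totals), 50L)
    }
  })
})

# independent oracle: enumerate all 2^n sign assignments literally
brute_force_signrank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[signs == 1L])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  p <- if (V > mu) 2 * mean(vs >= V) else if (V < mu) 2 * mean(vs <= V) else 1
  list(V = V, p = min(1, p))
}

test_that("exact p equals brute-force enumeration for tie-free inputs", {
  r <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_identical(r$V, 6)
  expect_identical(r$p_two_sided, 0.25)  # 2/8 enumerated by hand
  expect_identical(r$method, "exact-enumeration")

  withr::with_seed(29, {
    for (k in 1:40) {
      n <- sample.int(10L, 1L)
      mags <- sample(seq(0.5, 50, by = 0.5), n)  # distinct -> tie-free
      signs <- sample(c(-1, 1), n, replace = TRUE)
      d <- mags * signs
      got <- wilcoxon_signed_rank(d, rep(0, n))
      want <- brute_force_signrank(d)
      expect_identical(got$method, "exact-enumeration")
      expect_identical(got$V, want$V)
      expect_equal(got$p_two_sided, want$p, tolerance = 1e-12)
    }
  })
})

test_that("V(a,b) + V(b,a) partitions the total rank sum, ties included", {
  withr::with_seed(37, {
    for (k in 1:40) {
      n <- sample(2:20, 1L)
      a <- sample.int(50L, n, replace = TRUE)
      b <- sample.int(50L, n, replace = TRUE)
      if (all(a == b)) a[1L] <- a[1L] + 1L
      f <- wilcoxon_signed_rank(a, b)
      g <- wilcoxon_signed_rank(b, a)
      expect_equal(f$V + g$V,
                   f$n_effective * (f$n_effective + 1) / 2)
    }
  })
})

test_that("tie-corrected normal approximation matches the reference test", {
  withr::with_seed(41, {
    for (k in 1:20) {
      n <- sample(12:30, 1L)
      a <- sample.int(12L, n, replace = TRUE)
      b <- sample.int(12L, n, replace = TRUE)
      if (all(a == b)) a[1L] <- a[1L] + 1L
      d <- a - b
      has_ties <- anyDuplicated(abs(d[d != 0]))
      if (!has_ties) next  # force the approximation path via ties
      got <- wilcoxon_signed_rank(a, b)
      expect_identical(got$method, "normal-approx-tie-corrected")
      ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                 exact = FALSE,
                                                 correct = TRUE))
      expect_equal(got$V, unname(ref$statistic))
      expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("all-zero differences are a degenerate input", {
  expect_error_class(wilcoxon_signed_rank(c(3, 3), c(3, 3)),
                     "genetrust_degenerate_input")
})

test_that("score matrices validate their ranges", {
  expect_error_class(
    score_matrix_from_totals(tibble::tibble(patient_id = c("a", "b"),
                                            registry = c(10L, 60L),
                                            omop = c(5L, 5L))),
    "genetrust_type_error")
  es <- tibble::tibble(patient_id = "a", element = "Gender",
                       registry = 6L, omop = 0L)
  expect_error_class(score_matrix(es), "genetrust_type_error")
  es2 <- tibble::tibble(patient_id = "a", element = "Eye Color",
                        registry = 3L, omop = 0L)
  expect_error_class(score_matrix(es2), "genetrust_type_error")
})

test_that("element-level matrices aggregate to patient totals", {
  withr::with_seed(43, {
    rows <- expand.grid(patient_id = c("p1", "p2", "p3"),
                        element = gold_elements(),
                        stringsAsFactors = FALSE)
    rows$registry <- sample(0:5, nrow(rows), replace = TRUE)
    rows$omop <- sample(0:5, nrow(rows), replace = TRUE)
    m <- score_matrix(tibble::as_tibble(rows))
    for (p in c("p1", "p2", "p3")) {
      expect_identical(m$totals$registry[m$totals$patient_id == p],
                       sum(rows$registry[rows$patient_id == p]))
    }
    cmp <- compare_modalities(m)
    expect_identical(nrow(cmp$per_element), 10L)
  })
})
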