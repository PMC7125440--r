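# shared fixtures built in code; everything is seeded and disposable

local_store <- function(env = parent.frame()) {
  path <- withr::local_tempdir(.local_envir = env)
  content_store(file.path(path, "store"))
}

local_ledger <- function(env = parent.frame()) {
  path <- withr::local_tempdir(.local_envir = env)
  cgt_ledger(file.path(path, "ledger"))
}

# a small deterministic cohort on disk; returns list(dir, patients, truth)
local_cohort <- function(n = 6L, seed = 42L, env = parent.frame(), ...) {
  dir <- withr::local_tempdir(.local_envir = env)
  cfg <- cohort_config(n_patients = n, seed = seed,
                       n_no_ehr = min(1L, n - 1L),
                       n_fmi = max(1L, n %/% 2L),
                       n_ucsf500 = max(0L, min(2L, n - 1L - n %/% 2L)),
                       n_imaging = min(2L, n - 1L), ...)
  res <- generate_cohort(cfg, dir)
  res$config <- cfg
  res
}

fresh_uuid <- function(seed = 1L) {
  withr::with_seed(seed, ruuid4(1L))
}

# gold/candidate helper for scoring tests
simple_gold <- function() {
  g <- stats::setNames(vector("list", 10L), gold_elements())
  for (el in gold_elements()) g[[el]] <- paste0(el, ":fact")
  g[["Basis of Diagnosis"]] <- c("basis:pathology", "basisproc:biopsy")
  g[["Cancer Site"]] <- c("site:C25.0", "sitegroup:Pancreas")
  g[["Therapeutic Agent"]] <- c("drug:gemcitabine", "drug:cisplatin")
  g
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
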