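---
title: "Methods: provenance, deidentification and completeness scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: provenance, deidentification and completeness scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetrust)
```

`genetrust` models the data-sharing workflow of a content-addressed cancer
data commons end to end: raw identified inputs are deidentified, assembled
into per-patient bundles, stored under cryptographic hashes, anchored to a
steward-level provenance chain, and evaluated for clinical completeness.
This vignette explains the models and procedures, the tunable parameters,
and the design choices made where the design was genuinely open.

## Content addressing and the canonical JSON dialect

A content address is the lowercase-hex SHA-256 digest of a payload's bytes.
For *structured* payloads the bytes must themselves be deterministic, so the
package defines one canonical serialization: object keys sorted
lexicographically by Unicode code point, no insignificant whitespace, UTF-8
encoding, and each number rendered in the shortest decimal form that parses
back to the same double. `canonicalize()` is pure and idempotent through a
parse round trip, which is what makes hashes comparable across
implementations and sessions. Hex SHA-256 was chosen over multihash/CID
encodings to keep addresses dependency-free and bit-exact; a conversion
adapter could be layered on without touching stored bytes.

The store itself is a flat directory with a two-character fan-out
(`store/<aa>/<digest>`), chosen for inspectability: every object can be
checked with any external SHA-256 tool.

## Steward provenance

A submission is a manifest — deidentified scalar fields plus *named file
references*, each a content address — so the submission's own address
covers the referenced bytes transitively (Merkle-style indirection). The
manifest hash deliberately covers the manifest only, never concatenated
file bytes; files are already self-verified by their own addresses.

Each steward's state is its ordered list of submission addresses; the
top-level hash is the SHA-256 of the canonicalized list (an empty steward
hashes the two bytes `[]`). After every submission the new top hash is
appended to an append-only anchor log with a strictly increasing sequence
number. This local log stands in for an on-chain anchor: the verification
contract it preserves is that (a) every listed object re-hashes to its
address, (b) the recomputed top hash equals the latest anchored one, and
(c) the log is strictly ordered. Timestamps live only in the anchor log,
never in hashed material, so hashes are reproducible. Duplicate
submissions are deduplicated at the byte layer but appended again to the
list — position in the provenance history matters.

## Deidentification

Three transforms, all gated by a scanner:

- **Dates to ages.** Every calendar date becomes a whole-day age since
  birth (`date_to_age_days()`; event on the birth date = 0). The transform
  preserves intervals exactly, which is what downstream clinical narratives
  need; only the person-level age in *years* is additionally capped at 89
  (Safe Harbor aggregates ages above 89; the cap is a `deid_config()` flag,
  default on). Ages in years use birthday arithmetic, not division by
  365.25, which is off by one exactly on birthdays.
- **Allow/deny lists.** OMOP output columns are restricted to per-table
  allow-lists (concept identifiers, within-bundle ids, `*_age_days`
  columns); registry output to the curated field set. Keys like `mrn`,
  `name`, `date_of_birth`, `address` are denied outright. Both deidentify
  operations are idempotent, so re-running the pipeline on already-clean
  data is safe.
- **Germline removal.** Only variants flagged `somatic` are shareable;
  `unknown-origin` calls are dropped too — the privacy-conservative
  default.

`phi_scan()` walks any document and reports date literals (ISO, US and
month-name forms), SSN/phone/email shapes, 7–9 digit integers under
medical-record-style keys, person-name fields and denied keys, each with a
path and truncated excerpt. It is a regex heuristic designed to catch the
identifier shapes this pipeline could leak — a gate for synthetic and test
data, documented as **not** a certified deidentification audit. Retained
free-text registry fields are additionally pattern-scrubbed at ingest as
defense in depth.

## Variant reports and cohort summaries

Commercial-panel reports are parsed from a documented XML schema carrying
gene, protein change, functional effect, knowledge status and origin per
short variant (real vendor schemas are proprietary; adapting one is a
parser concern, not a model concern). VCF input keeps `FILTER == PASS`
records and reads the same fields from INFO keys; a record without a
status is of unknown significance, and effect sub-categories (stop-gain,
in-frame indels, …) collapse onto six classes via a shipped mapping.

`summarize_cohort()` aggregates per-patient burdens split by status,
effect counts, and per-gene statistics. *Unique* variants are keyed by
(gene, protein change): the same change in two patients is two call
instances but one unique variant — nucleotide-level keying was the
alternative, but protein keying matches how panel reports describe
recurrence. Recurrent genes (carrier count > 1) are ordered by unique
variant count, then carrier count, then symbol, a total and deterministic
ordering. Conservation invariants (per-patient totals, effect counts and
per-gene call counts all sum to the variant total; known + likely +
unknown partitions each patient's calls) are enforced by tests on every
generated cohort.

## Completeness scoring and the paired test

Ten gold-standard elements are scored per patient and modality. Each
element has a non-empty set of atomic gold fact tokens; with captured
fraction $f$, the score is $\mathrm{round}(5f)$ — the rubric fixes the
scale but not the rounding rule, so *half away from zero* was chosen and
isolated in one function. A missing modality scores 0 everywhere; a
patient's per-modality total is at most 50. What counts as an atomic fact
is configuration, not biology: the shipped tokenization
(`fact_vocabulary()`) is artifact-defined and shared between the generator
and the extractors, so expected scores are exactly recoverable.

Registry and OMOP totals are compared with a two-sided Wilcoxon
signed-rank test: differences $d_i = \mathrm{OMOP}_i -
\mathrm{registry}_i$, zeros dropped, absolute values ranked with average
ranks, $V$ = sum of positive-difference ranks. With tie-free differences
and $n \le 25$ the p-value comes from the exact null distribution
(convolution over rank subsets, equivalent to enumerating all $2^n$ sign
assignments); otherwise from a normal approximation with tie-corrected
variance $n(n+1)(2n+1)/24 - \sum_t (t^3 - t)/48$ and a continuity
correction of 0.5 toward the mean. The direction convention (OMOP minus
registry) is reported explicitly and the reverse rank sum alongside, since
$V_{ab} + V_{ba} = n(n+1)/2$. Per-element tests use the same machinery and
report raw p-values; no multiple-testing correction is applied, matching
how such field-level screens are usually read. A degenerate input (all
differences zero) raises rather than fabricating a p-value.

```{r}
cmp <- compare_modalities(load_table4_fixture())
cmp
```

## The synthetic cohort generator

The generator emulates a small late-stage gastrointestinal oncology pilot:
18 patients by default, one-third male, race 11:5:2 white:asian:unknown,
2 of 18 Hispanic/Latino, ages $\mathcal{N}(59.3, 13.3^2)$ years truncated
to [21, 95]; 13 patients on an XML-report panel and 4 on a VCF panel; a
disease mix dominated by pancreatic and biliary primaries.

Somatic burden is drawn from a negative binomial (mean 10.69, dispersion
6.4) clipped to [3, 21] — a Poisson cannot hold that spread at that mean,
and the clipped negative binomial is a documented modelling choice, not a
claim about the generating process of any real cohort. Knowledge status
uses weights 8.07 : 2.18 : 1.43 (unknown : known : likely) and effects are
83.5% missense. An exact cohort-wide total (e.g. 139 calls over 13
patients) can be requested; counts are then nudged ±1 within the clip
range until the total matches. Germline calls (Poisson, mean 2) are mixed
into the raw reports so the filtering stage has real work to do.

The completeness model is generative: per element and modality, each gold
token survives into the document with a configured capture probability —
registry 0.85 per token unless the record is in a minimum "suspense"
abstraction state (probability 0.25), which zeroes the basis-of-diagnosis
and therapy elements; OMOP captures steadily (0.6–0.9 per element) but the
SEER site group has no standard OMOP home (structural 0 by default) and
histology detail is poorly encoded (0.15). These rates were fixed once
from the qualitative pattern the score table shows — higher registry mean
*and* variance, steadier OMOP — and are deliberately soft: tests assert
exact *recoverability* of expected scores from the truth sidecar, not
these rates themselves. Raw inputs carry real dates, names and MRNs, and
a configurable fraction of patients receives one extra injected PHI item
whose category and location are recorded in the sidecar, giving the
scanner a known target set.

Determinism: one master seed; each patient draws from a derived substream
(`derive_seed(seed, i)`), so enlarging a cohort does not reshuffle
existing patients, and equal seeds give byte-identical output trees.
Patient UUIDs come from a seedable UUID-4 generator for the same reason.

What the generator does **not** emulate: longitudinal disease
trajectories, treatment response, realistic concept vocabularies (concept
identifiers are artifact-defined), free-text notes, or image content
(blobs are random bytes). Passing tests therefore demonstrate the
pipeline's contracts — hashing, tamper detection, interval preservation,
gate soundness, score recoverability — on data whose *shape* matches the
domain, and say nothing about scanner recall on real clinical free text.

## Numerical and scale choices

Test and acceptance workloads are sized for a laptop-class single core:
property tests use 20–50 seeded repetitions, tamper detection 50 random
byte flips over a 10-patient ledger, deidentification soundness a
100-patient cohort, and the exact-vs-enumeration Wilcoxon check covers all
$n \le 10$ (the $2^n$ oracle is literal enumeration). Exact p-values use
integer convolution (no floating-point accumulation); score rounding is
the single `round_half_away()`; all tabular I/O is UTF-8 TSV/CSV with
empty string as missing and embedded tabs/newlines rejected at write time.

## Known limitations

- The PHI scanner is pattern-based; names inside free text, dates spelled
  unusually, or quasi-identifiers (rare diagnosis + age + zip) are out of
  scope, as is image-pixel PHI.
- The anchor log simulates a blockchain: it preserves the verification
  contract but provides no consensus, replication or gas accounting.
- The steward's MRN-to-UUID re-identification appendix is modelled as a
  steward-local file outside the shared path and is never hashed or
  stored.
- Per-element published comparisons depend on element-level score tables
  that are not public; the machinery supports them, but only total-score
  statistics are asserted against printed values.
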