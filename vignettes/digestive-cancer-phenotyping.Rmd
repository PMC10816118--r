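---
title: "Methods: digestive-cancer case finding and validation in primary-care EHRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digestive-cancer case finding and validation in primary-care EHRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digephen)
```

## The phenotyping problem

Spanish primary-care databases code episodes with two dictionaries at once —
ICPC-2 (plus local high-granularity extensions) and ICD-9 — in three fields:
incident diagnosis (ID), personal history (PH) and clinical problem list
(CPL). Physicians freely edit the textual *descriptor* attached to a code and
write unstructured clinical notes, so a substantial fraction of cancers never
receives a cancer code at all. Hospital-discharge ICD-9 codes are linked for
part of the population. `digephen` finds *incident* digestive-cancer cases
(esophageal, gastric, pancreatic, hepato-biliary, colorectal) in such
extracts and implements the statistics used to validate the algorithm by
stratified manual review and to check external consistency through
standardized incidence rates.

## Cohort eligibility

A patient contributes follow-up from the latest of the study start, one year
after registration with their primary-care physician, and their 40th
birthday, until the earliest of the study end, registry end and their 90th
birthday (defaults 2001-01-01 to 2019-12-31; all configurable in
`build_eligibility()`). Patients with any malignancy code before entry are
excluded, with non-melanoma skin cancer (ICD-9 173.x) exempt. The "any
malignancy" screen needs a code set wider than the five digestive lists; the
shipped default covers ICD-9 140–208.9 plus in-situ 230–234.9 (minus 173.x)
and the ICPC-2 malignancy rubrics across chapters, and is user-replaceable
(`any_cancer_patterns()`) because local dictionaries differ.

Dates are day-resolution throughout: the databases being emulated do not
expose a finer clock, and day precision makes person-time arithmetic exact.

## Code lists and matching semantics

The five shipped code lists combine ICPC-family shorthand (`D77.2/8`
expands over the stem to `D77.2`, `D77.8`), closed ICD-9 numeric ranges and
opaque morphology codes. Three decisions deserve justification:

* **Ranges are closed intervals at one-decimal granularity.** `150–150.9`
  matches both endpoints, and a deeper sub-code such as `150.91` matches via
  its one-decimal parent. Registry convention treats printed ranges as
  inclusive; nothing in the dictionaries suggests otherwise.
* **In-situ rubrics (230.x) count as cases by default** since they appear in
  the lists without qualification; `include_in_situ = FALSE` removes them
  for studies restricted to invasive disease.
* **Morphology codes are exact strings.** Implementing ICD-O hierarchy for
  six printed codes would add surface without evidence.

Cross-list disjointness is asserted by brute-force enumeration
(`check_codelists()`): no exact code may be claimed by two cancer types,
which is what makes the downstream hierarchy a *tie-break* rather than a
correctness requirement.

## Text mining

The miner is deliberately lexicon-based — the phenotype is carried by a
small, stable Spanish vocabulary, and a rule system is auditable by the
clinicians who must sign off on a validation study. Text is case- and
accent-folded, split into clauses at sentence punctuation, and a hit
requires either a generic malignancy word co-occurring with an organ term in
the same clause, or a standalone term (`hepatocarcinoma`, `ampuloma`).
Clause-scoped markers cancel hits with a recorded reason: suspicion
(*descartar*, *sospecha*), screening (*cribado*), family history and
negation. Clause scope is the simplest mechanism that keeps "descartar
neoplasia gástrica. adenocarcinoma de colon confirmado" half-excluded,
half-kept; full dependency parsing is out of scope and unnecessary at the
precision levels the gold corpus demonstrates.

Ordered reassignment rules then fix three known misrouting patterns —
hepatic-angle colorectal tumours read as liver cancer, gastroesophageal
junction tumours (assigned to esophageal cancer), and ampulloma (assigned to
hepato-biliary) — and neuroendocrine / hereditary-syndrome contexts are
excluded *after* reassignment, so an "ampuloma neuroendocrino" is dropped
rather than reassigned and kept. The shipped lexicon is the package's own
emulation of this class of rule set, shipped as editable YAML, and its
behaviour is pinned by a 66-snippet hand-labelled gold corpus
(`inst/extdata/textmine_gold_corpus.csv`, labels assigned at construction)
on which precision and recall are asserted ≥ 0.95 in the test suite.

## Incident cases, hierarchy and strata

A case requires at least one in-window *incident* signal: an ID-field
episode matching a code list, a hospital-discharge code, or a dated
non-excluded text hit. PH/CPL codes alone are treated as prevalent disease
imported as history and never create a case, though they widen the
candidate type set of a patient who does have an incident signal. Each
patient yields at most one case at the earliest qualifying date.

When several cancer types compete, metastasis phrasings in the patient's
pooled text suppress the metastatic-site candidate ("cáncer de recto con
metástasis hepáticas" keeps colorectal, drops hepato-biliary); remaining
ties fall to a fixed rank, default colorectal > esophageal > gastric >
pancreatic > hepato-biliary — descending order of frequency of these
cancers, so ties break toward the a-priori likelier type. The rank is
config data (`hierarchy_rank` in the code-list YAML), not code, because no
published source fixes the order beyond the metastasis rule.

Cases are stratified by information completeness: S1 = diagnosis + notes +
supporting information (stage, location, surgery, chemo/radiotherapy,
discharge or specialist codes, histopathology, imaging/colonoscopy), S2 =
diagnosis + notes, S3 = diagnosis only. Supporting records and notes count
when dated within ±6 months of the index date — a linkage window the source
databases leave unspecified; it is a `link_months` argument, and 6 months
spans the typical diagnostic work-up around an index contact.

## Validation statistics

**Kappa.** Inter-reviewer agreement uses linearly weighted Cohen's kappa,
`w_ij = 1 − |i−j|/(k−1)` over the four ordered review categories. The
category order materially changes the statistic and no convention fixes it,
so `cohen_kappa_linear()` takes the order as an explicit argument (default
valid < inconclusive < non_valid < unsupported, ordered by how far the
record sits from a confirmed case).

**PPV.** The main analysis counts inconclusive cases as non-valid and drops
unsupported cases from numerator and denominator; sensitivity scenarios
re-count unsupported as valid or as non-valid. Group-level PPVs are stratum
PPVs weighted by each stratum's share of the *full* case pool, not of the
review sample — the whole point of stratified review is that the sample
over-represents thin strata.

**Confidence intervals.** The default is Wald: back-calculation shows that
the intervals conventionally printed with validation PPVs (e.g. 92.4% on
n = 760 giving 90.5–94.3) match the normal approximation, not the exact
interval, so Wald is what reproduces published tables. Clopper–Pearson and
Wilson are provided for boundary proportions (a stratum PPV of 100% gets a
degenerate Wald interval) and small strata. The weighted-mean CI applies
the chosen method at the weighted point with effective n = Σ nₛ, again
matching printed practice; a delta-method variance-weighted alternative
(`ci_method = "weighted"`) is available when strict propagation is wanted.
Coverage experiments in the test suite use Clopper–Pearson, whose coverage
is guaranteed ≥ nominal, so the assertion tests the pipeline rather than
the known small-sample under-coverage of Wald.

## Person-time and standardized rates

Follow-up is split exactly at 5-year-band birthdays (completed age at each
day), conserving total person-time to the day; a day-level accumulator in
the test suite confirms cellwise equality. Direct standardization uses
`SIR = Σ w_b (d_b/T_b) × 10⁵` with ESP age weights truncated to 40–89 and
renormalized, applied within sex and combined 50/50. Both ESP-2013
(default) and ESP-1976 are shipped since published comparisons use either
vintage. The default CI is the normal approximation on
`var = Σ w_b² d_b/T_b²` (Poisson counts); `ci_method = "gamma"` gives the
Fay–Feuer exact-Poisson interval, preferable at low event counts. Bands
with standard weight but no observed person-time are dropped with
renormalization and a warning rather than silently contributing zero.

## The synthetic cohort generator

`generate_cohort()` emits patients, coded episodes with descriptors, notes
and supporting evidence, plus a ground-truth table the case-finding path
never reads. Defaults mirror the documented shape of this phenotype in
production data: stratum shares 84/10/6, about a third of cases detectable
only through descriptor text, colorectal the dominant site, and per-site
base rates at age 65 of 48/13.5/7.2/6.3/2.8 per 100,000 person-years
(colorectal/gastric/hepato-biliary/pancreatic/esophageal) with a log-linear
age slope of 0.05 per year. A `hazard_scale` multiplier (default 5) raises
all rates so that cohorts of 2×10⁴ patients — the size used throughout the
test suite and acceptance script — yield case pools of several hundred,
large enough for review-sized samples; set it to 1 for
population-realistic incidence. Noise channels (miscoding
`p_false_positive_code = 0.003`, prevalent history records, rule-out notes,
co-occurrence phrasings, neuroendocrine/Lynch mentions) exercise every
disambiguation rule and pull the end-to-end PPV into the low-90s range
typical of validated algorithms of this family.

What the generator does *not* emulate: realistic clinical prose (templated
phrases only), drift of coding practice over calendar time, correlated
multi-morbidity, and reviewer behaviour beyond adjacent-category flips.
Passing tests therefore demonstrate the algorithm's logic and the
statistics' correctness, not the PPV the algorithm would achieve on any
real database.

Determinism: every stream derives its seed from the single global seed via
a fixed hash, so a configuration reproduces byte-identically; growing
`n_patients` reshuffles draws (R's generator is sequential, not
counter-based), which is acceptable because experiments fix the cohort size
first.

Simulated adjudication gives each sampled case a truth-derived category
(with configurable shares reviewing as unsupported/inconclusive), flips
each reviewer to an adjacent category with probability `reviewer_error`,
and restores the truth category on disagreement — mimicking committee
arbitration, which in the real workflow never auto-resolves.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use cohorts of 2,000–20,000
patients, 500-replicate coverage experiments at review samples of n = 150,
and 1,000 random tables for the kappa oracle — sizes at which every
Monte-Carlo assertion has comfortable error margins while a full run stays
in the tens of seconds. Tie-breaks and degenerate inputs are handled
explicitly: empty strata draw zero with a warning, zero-denominator PPVs
return an `NA`-flagged estimate rather than `NaN`, kappa errors on
degenerate marginals, and Wald intervals are clipped to [0, 1].

## Known limitations

* Sensitivity cannot be estimated without an external gold standard; the
  package measures it only against planted synthetic truth.
* The lexicon is Spanish-only by design; other languages need a new YAML,
  not new code.
* ICPC private extensions beyond the shipped lists are not catalogued
  publicly; unknown codes simply never match.
* The exact per-cancer stratum weights behind published weighted means are
  not printed anywhere; `validation_report()` computes weights from the
  actual case pool, which is the defensible choice but will not digit-match
  a table built from unpublished weights.
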