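---
title: "Measuring performance-status documentation in cancer EHRs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring performance-status documentation in cancer EHRs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdocr)
library(dplyr)
```

## The problem

The performance status (PS) — ECOG/WHO/Zubrod 0–4 or Karnofsky 100–10 —
summarises a cancer patient's functional ability and gates many treatment
decisions and trial inclusions. In hospital information systems it usually
lives only in free text, so before one can ask *who gets a documented PS
and who does not*, one needs (i) a reliable rule-based extractor for PS
mentions, (ii) a reproducible incident-cancer cohort built from claims
codes, and (iii) the descriptive and regression machinery to relate
documentation to patient and hospital characteristics. psdocr implements
all three, plus a synthetic-data generator that emulates the joint
structure of patients, ICD-10 claims events, and annotated clinical
documents, so the entire pipeline is testable without access to protected
health data.

## Rule-based extraction

`find_ps_mentions()` scans text left-to-right for a score keyword
(ECOG family: *ECOG, PS, OMS, WHO, Zubrod, performance status*;
Karnofsky family: *Karnofsky, IK, indice de Karnofsky*), an optional
connector run (`:`, `=`, *à*, *de*, copulas and negation words such as
*est* / *is not* / *pas*, or whitespace) and a numeric value. ECOG-family
values must lie in 0–4 (optional `/4`, optional range such as `PS 1-2`,
kept as one mention with an upper bound); Karnofsky values must be
10–100 in steps of 10 (optional `%` or `/100`). Keywords match
case-insensitively and must not be followed by a letter, so *PSA* and
*IPS* can never fire. A bare ECOG keyword with a Karnofsky-range value
("PS 80") is read as Karnofsky: clinicians mix conventions, and the value
range is the safest arbiter. Offsets are 0-based and half-open
throughout.

Two scoping rules qualify each candidate:

* **Negation** (`qualify_negation()`): a cue (*not, no, pas, non, sans,
  aucun(e)*) in the same sentence within 5 tokens before the mention, or
  inside it ("PS is not 0"). Sentences are delimited by periods and
  newlines; the 5-token window mirrors common clinical-NLP negation-scope
  defaults and is configurable.
* **Family attribution** (`qualify_family()`): a kinship cue (*mère,
  père, mother, father, …*) earlier in the same sentence. Cues after the
  mention do not count, so "PS 2; family informed" stays a patient
  mention — a deliberately conservative scope.

A document *contains* a PS when at least one mention survives both
filters; a patient *has* a documented PS when any of their in-window
documents does. `evaluate_extraction()` scores these document-level
decisions per report type (accuracy, per-class precision/recall/F1,
macro and support-weighted F1).

```{r extract-demo}
txt <- "Etat général : OMS 1. PSA 4.5 ng/mL. Sa mère : PS 3."
extract_ps_mentions(tibble::tibble(doc_id = "d1", text = txt))
```

Known limitations: the grammar accepts short connector runs, so an
English sentence like "patients who had 3 relapses" would produce a
spurious WHO mention; real deployments should review the keyword and
connector lexicons against their corpus. Scores expressed without a
number ("patient in good condition") are out of scope by design.

## Cohort construction

`build_cohort()` reproduces a claims-based incident-cancer design:

* **Incidence with washout.** A patient is incident when their earliest
  cancer code (C00–C97; in-situ and uncertain-behaviour D ranges
  opt-in) inside the study window (defaults 2019-01-01 to 2021-06-01)
  has no cancer code in the preceding 730 days. The look-back interval
  is open: a code exactly 730 days earlier does not block incidence.
* **Group and hospital at first code.** Ten primary-site groups from
  standard ICD-10 ranges (Breast C50; Colorectal C18–C21; Lung C33–C34;
  Prostate C61; Gynaecological C51–C58; Genitourinary C60, C62–C68;
  Skin C43–C44; Haematological C81–C96; other gastrointestinal C15–C17,
  C22–C26; everything else Other). Later codes are never re-checked;
  same-day ties resolve by lexicographic code.
* **Exclusion cascade**, ordered and logged: age under 18; hospitals
  below 1% of incident diagnoses (share computed once, before any
  exclusion — the most natural reading of a share "of diagnoses") or
  flagged paediatric; male gynaecological and female prostate codings
  (male breast cancer is retained); no in-window document.
* **Window and outcomes.** Documents count when dated within −90 and
  +365 days of index, both bounds inclusive. Metastatic at diagnosis
  means a secondary-neoplasm code (C77–C79, the standard claims proxy)
  within 0 to +90 days of index; one-year death means a death date at
  or most 365 days after index. A death date before index is
  inconsistent data: it warns and counts as a one-year death rather
  than silently vanishing.

Every convention above is pinned by a boundary test, and on small
cohorts the whole builder is checked against an independent brute-force
re-derivation written as plain loops.

## Statistics

`patient_prevalence()` / `document_prevalence()` are thin, tested
cross-tabulations (counts and proportions by any stratifiers, including
the restriction of hospitalization reports to cancer-coded stays).
Reported percentages round half away from zero (`round_half_up()`), the
convention of published clinical tables, which matters when comparing to
printed values.

`spearman_volume_correlation()` relates per-hospital document volume to
per-hospital documentation proportion: average-rank Spearman rho with a
two-sided p from the t approximation
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) on \(n-2\) degrees of freedom — what
standard software reports at the 15-hospital scale this is used at. An
exact permutation null is available behind `exact = TRUE`; it
enumerates all permutations and is therefore supported up to n = 8
(40,320 permutations), which covers the sizes where the t approximation
is least comfortable.

`mortality_by_documentation()` splits one-year mortality by
documentation status. In both the real phenomenon and the generator,
documented patients die more: documentation is informative presence,
not a random sample — the central caveat for reusing such EHR variables
as real-world data.

### The propensity model

`fit_ps_model()` fits a logistic regression of the documentation
outcome on sex, age, cancer group, hospital, and the number of MDT,
consultation and hospitalization reports (untransformed linear terms —
the simplest defensible reading), optionally plus metastatic status.
Age enters as a restricted cubic spline with 3 knots at the 0.10 / 0.50
/ 0.90 quantiles — the default of the usual spline-regression software.
`rcs_basis()` builds the natural-spline columns from truncated cubes
with the two linearity constraints beyond the boundary knots imposed
analytically, nonlinear terms scaled by \(1/(t_k - t_1)^2\). Fitting is
IRLS (`stats::glm`) with relative convergence `1e-8` and at most 100
iterations; intervals are Wald on the odds-ratio scale (the
conventional reporting choice, rather than profile likelihood).
Reference levels default to female sex, breast cancer and the largest
hospital, and are always recorded in the fit object, since odds ratios
are meaningless without them. Guard rails: rank deficiency is an error
naming the collinear terms; any |log-odds| above 15 is flagged as
probable separation. `compare_ps_models()` fits the model with and
without metastatic status and tabulates per-term odds-ratio shifts.

## The synthetic-data generator

`simulate_ehr()` emulates the study conditions end to end; its defaults
are fixed study conditions, not tuning knobs:

* 15 hospitals with strongly skewed volume shares (largest ≈ 13× the
  smallest) and ten cancer groups with realistic frequencies; ~22%
  metastatic at diagnosis overall, varying by site (lung high, skin and
  haematological low).
* Ages normal(65, 14) truncated to 18–95; sex ~53% male with
  site-consistent assignment (gynaecological female, prostate male).
* Document counts per patient Poisson with type-specific means (MDT
  1.5, consultation 2.5, hospitalization 2.0), chosen to give a median
  near six reports per patient; 15% of documents fall outside the
  −90/+365 window to exercise the date filter.
* **Documentation truth first, text second.** Whether a patient has a
  documented PS is drawn from an additive log-odds model (baseline
  −1.65; male +0.08; +0.15 per decade of age; metastatic log 3.3;
  site effects from −1.05 for skin to +1.19 for lung; hospital effects
  spanning ≈ −1.1 to +0.9; per-document increments 0.25 / 0.12 / 0.18).
  Positive patients then receive clean score mentions spread over their
  in-window documents (each with probability 0.45, at least one
  forced). Because the generating model is exactly the model the
  regression module fits, parameter recovery is a well-posed check, and
  `simulate_cohort_table()` provides a fast path that skips text
  assembly for large-n recovery runs.
* **Gold labels are template facts.** Sentences come from template
  families — ECOG-style and Karnofsky-style positives, negated forms
  ("PS non évaluable", "pas de PS à 2", "PS is not 0"), family
  attributions ("mère : PS 3"), and decoys that must never match (PSA
  values, ankle-brachial "IPS", phone numbers, blood pressure) — mixed
  according to `mention_mix`. Gold spans and labels derive from
  template identity alone; the extractor is never consulted at
  generation time, so extractor evaluation is not circular. Documents
  of undocumented patients receive only non-asserting families, which
  keeps the patient-level truth exact.
* A latent true ECOG score (worse when metastatic) feeds both the
  mention values and one-year mortality (baseline 10%, log-odds +log 3
  when the latent score is ≥ 2), reproducing the informative-presence
  pattern qualitatively.
* 5% of patients are washout violators: they carry an extra cancer code
  1–24 months before index, dated before the study window so the
  incident filter must remove them; their index dates are drawn within
  698 days of study start so such a code always exists.
* French is the primary template language (the extractor's main
  dialect), with an English set behind `language = "en"`.

What the generator does **not** emulate: realistic narrative prose,
inter-hospital transfers, coding errors, multiple primaries, or
ambiguous mentions whose gold label reasonable annotators would dispute.
Perfect extractor scores on this corpus therefore demonstrate the
scoping rules work as specified, not that real clinical text is this
clean; published validations of comparable rule sets report performance
above 0.95, which is the bound the acceptance corpus checks against.

## Problem sizes and numerical choices

The test suite runs the extractor corpus at ~600 patients (≥ 500
documents per report type), oracle comparisons at 50 patients, and
parameter recovery at 50,000 patients × 20 seeds via the fast path —
sizes at which every check is sharp yet the whole suite stays in the
minutes range. All randomness flows from a single integer seed through
per-stage derived seeds (`withr::with_seed`), so every table, document
and fit is bit-reproducible. Proportions are exact ratios; only
display-level rounding uses `round_half_up()`. One published
inconsistency is worth noting for anyone comparing outputs to the
literature: abstract-level reports of patient prevalence sometimes use
a different denominator than the characteristics table (35% vs 41% for
the same cohort); the package's desk-checks use the table counts, where
numerator and denominator are both printed.
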