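---
title: "Rule-based staging extraction and quality management: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based staging extraction and quality management: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: what the rule
engine assumes, which choices were genuinely open and how they were made,
what the synthetic test bed does and does not emulate, and what the tests
therefore do and do not show about real data.

## The problem

Clinical libraries assembled from electronic medical records carry a
patient-level table (demographics, treatment, outcome, staging) alongside
free-text pathology and imaging reports. The staging variables — AJCC TNM
components and the SEER summary stage — are the strongest prognostic
factors for colorectal cancer, yet in the profile this package targets
they are missing in 75.3% (TNM) and 24.3% (SEER) of 6491 records, and
wrong in roughly half / a third of the nonmissing cells. The package
implements a quality management process (QMP): extract stage from the
reports with an auditable rule lexicon, fill the missing cells, and
measure the improvement.

## The lexicon and matcher

The shipped lexicon (`inst/extdata/tables_3_4.lexicon`, YAML) encodes the
staging phrase inventory of the Korean clinical guideline for colon and
rectal cancer (TNM, pathology and imaging dialects) and SEER Summary
Stage 2018. Each rule binds phrase patterns to one component (T/N/M/SEER),
a value, a source modality, and a kind: `explicit_code` (stage-code tokens
such as `(ypT3)` or the imaging shorthand `T3`), `descriptive`
(e.g. *invades subserosa*), or `negative_evidence` (e.g. *no metastasis
in … regional lymph nodes*).

Matching operates on normalized text: case folding, whitespace collapse,
and synonym canonicalization (`L/N(s)`, `LN(s)`, `lymph nodes` →
`lymph node`; `metastases` → `metastasis`), with an offset map so that
every evidence span quotes the original report verbatim. Normalization is
idempotent and is the package's full normalization contract — the lexicon
and the report dialects it targets are ASCII, so no Unicode
compatibility-form pass is applied. Sentences are delimited at `.` and
`;`.

Three pattern-language features cover the guideline's template style:

* `~` — a gap of at most 5 tokens, for templates with elided counts
  (*no metastasis in — regional lymph nodes*);
* `<count>` — an integer slot with per-rule bounds, implementing the
  node-count mapping 1 → N1a, 2–3 → N1b, ≥4 → N2a;
* `requires:` — a sentence-level co-occurrence group. The guideline's
  footnotes state that the synonym terms must be "used together with" the
  N and M stage labels; imaging fragments such as *regional* or *liver*
  therefore only count in sentences that also mention a lymph-node or
  metastasis term. This is deliberately not a general negation or section
  detector: negative phrases are ordinary rules, exactly as printed.

One pattern was added beyond the printed inventory: the pathology Tis rule
also carries *intraepithelial carcinoma*. The printed in-situ vocabulary
is otherwise inconsistent — the mucosal-confinement phrases that label Tis
are simultaneously summary-stage *localized* (code 1) patterns, and the
only code-0 pattern is *intraepithelial* — so without this addition no
pathology report could express an in-situ tumor recoverably. It is
clinically the definition of Tis.

## Conflict resolution and derivation

Per component and report: explicit stage-code tokens outrank descriptive
phrases (they are the pathologist's own staging statement); within a kind,
the highest stage wins — the registry convention of recording the worst
documented extent. No match leaves a component `x` (not determined).
Prefixes (`p`, `yp`, `c`) are recorded from explicit tokens but never
alter the value used for imputation, since the target table stores plain
codes.

The SEER summary stage is derived with the precedence: **7** if M = 1 or a
distant-site pattern matched; **4** if both a code-2 (direct extension)
and a code-3 (nodes) candidate hold; **3** from a direct pattern or — on
imaging, where node counts are not available — from N ≥ 1; then **2**,
**1**, **0** from direct patterns; **9** when a document was searched and
nothing matched. `missing` is reserved for patients with no document at
all: 9 asserts "examined, unknown", which is information, not absence.
Code 5 (regional NOS) is accepted on input but never produced.

Patient-level merging: within a modality, multiple documents combine by
worst extent; across modalities, pathology wins wherever it is determined
(pathological staging is the clinical gold standard), imaging fills the
rest — in particular M0, which pathology reports never assert. Two
refinements are the package's own choices: a definite imaging SEER code
outranks a pathology code 9 (ignorance should not veto evidence), and the
merged result is re-checked against the distant-disease rule (merged M = 1
forces SEER 7).

## Imputation semantics

`qmp_impute()` defaults to `fill_missing`: derived codes are written into
missing cells only, every write logged with its evidence rule ids.
`fill_and_flag` additionally flags nonmissing cells that disagree with the
derived code but never overwrites them — destructive correction is
excluded by design, keeping the change log a complete audit trail. A
derived SEER 9 is never written into a missing cell (it would convert one
representation of "unknown" into another while destroying the distinction
between "no document" and "document without evidence"). The combined TNM
string is written whenever at least one component is determined, with `x`
placeholders (`TxN2M0`), matching how partially staged records are
printed.

## Metrics

Percentages are reported on the 0–100 scale rounded **half-up** to one
decimal — base `round()`'s round-half-even would print 0.25% as 0.2%,
unlike clinical tables. The audit error rate divides by *nonmissing*
audited cells only. Concordance excludes pairs missing on either side and
counts them separately; with no comparable pair the rate is flagged
undefined rather than invented. Classification metrics default to
support-weighted averaging over both classes (under which recall equals
accuracy); AUROC is the midrank Mann–Whitney statistic — deterministic and
tie-aware — and is flagged undefined for single-class truths.

## The prognostic model

`qmp_evaluate()` fits gradient-boosted decision trees (xgboost,
`binary:logistic`) to 5-year survival on one-hot encoded features, before
and after imputation. Defaults: depth 3, learning rate 0.1, 100 rounds,
no row/column subsampling, single thread — the classic gradient-boosting
configuration, chosen deterministic so that a fixed seed makes the whole
evaluation bit-reproducible; the stratified 80/20 split is the only
seeded step. Class imbalance (~5.5% deaths) is handled by stratification
only. Feature importances are normalized total gain. Encoded feature
names follow registry-export style — `SEER_2.0`, `perineural
invasion_nan`, `TNM_T4N2M1` — with numeric-coded categorical levels
printed to one decimal and an explicit `nan` level so that each
categorical block sums to one per row. `patient_id`, the outcome, and the
`death` flag (which determines the outcome) are excluded from the feature
matrix.

## The synthetic test bed

The generator (`sim_config()`, `build_cohort()`) emulates the profiled
cohort: n = 6491; stage distribution following the table's nonmissing
frequencies (T and N/M sampled independently, in-situ/T0 constrained to
N0 M0); TNM masked jointly at 0.753 and SEER at 0.243; erroneous codes in
50% / 31.1% of nonmissing cells (one randomly chosen TNM component, or
the SEER code, replaced by a uniformly drawn *different* code); report
coverage 0.40 per modality, which reproduces the order of magnitude of
the post-QMP missingness observed in the profiled data; phrase styles
(descriptive vs explicit-code) mixed 50/50.

Survival follows
`logit P = 5.1 − 0.35·T − 0.5·N − 2.0·M − 0.35·(age−66.79)/10 −
0.4·(perineural−1) − 0.3·(lymphatic−1)`
with T mapped 0, 0.5 (in situ), 1–4. The covariates are the
literature-supported prognostic factors available in the schema (stage,
age, perineural and lymphatic invasion); the intercept was calibrated once
to ~94.5% survival prevalence and frozen. Node counts are tied to the true
N so that `positive lymph node` behaves like the real proxy it is. An
optional `tnm_scramble` mode draws stored TNM codes uniformly and
independently of truth — the "uninformative stored stage" condition used
to show that stage features carry no model importance before quality
management; note that the default error model does *not* make stored
codes uninformative (a binary M code corrupted at rate 0.5 toward "the
other code" would retain, and at rate 1.0 would maximize, its
information). An `imperfect_phrasing` mode (token dropout) exists to make
concordance < 100% demonstrable; both are off by default.

What the generator does **not** emulate: real report style (section
headers, Korean-English mixtures, abbreviations beyond the synonym
table), inter-observer staging disagreement, informative missingness
(masks are drawn independently of stage), and any correlation structure
beyond the outcome model. Passing tests therefore demonstrate the
engine's correctness on text the lexicon can express and the pipeline's
end-to-end arithmetic — not extraction recall on arbitrary clinical
prose.

Distractor boilerplate drawn into every rendered report is verified by
test to match zero lexicon rules, so extraction precision on rendered
reports is measurable.

## Validation design and problem sizes

The test suite checks, among others: a golden table mapping every printed
guideline phrase to its component and value; an exhaustive
truth → report → extraction round trip over the full stage grid
{0, is, 1–4} × {0–2} × {0, 1} in both phrase styles and both modalities
(merged assignments recover truth exactly; per-modality checks cover what
each modality can express — pathology never asserts M0, and imaging
cannot express in situ, which is why the round trip is defined at the
merged patient level); equivalence of the summary-stage derivation with a
brute-force precedence oracle over all 768 candidate-set × N × M × source
combinations; parameter recovery on a full-coverage cohort of 6491
(post-imputation TNM missingness equals the no-document fraction, zero,
and 100% of >15 000 filled cells match truth); the feature-importance
property over five fixed seeds; and bit-reproducibility of imputation and
evaluation, including through the command-line interface. Cohort sizes in
the suite (250–6491) were chosen so the full run completes in a few
minutes on one CPU while keeping the binomial noise on every rate check
well inside its asserted band.

## Known limitations

* The lexicon is colorectal-specific and English-only; no negation or
  section detection beyond the printed negative-evidence phrases, so
  promiscuous imaging fragments (e.g. *regional*) can over-trigger in
  free prose — the co-occurrence groups bound, but do not eliminate,
  this.
* Imaging summary-stage vocabulary is structurally incomplete (no code-0
  patterns; no code-2 pattern for serosal invasion), so imaging-only
  patients can be underdetermined or, rarely, understaged; pathology
  coverage resolves this.
* `N1c` (tumor deposits) and subcategories are recorded but the target
  table stores plain codes.
* Imputation quality on real reports is bounded by lexicon coverage; the
  change log and `fill_and_flag` mode are the intended instruments for
  auditing it against a manual sample.
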