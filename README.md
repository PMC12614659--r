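# crcqmp

Rule-based quality management for colorectal-cancer EMR staging data.

Cancer registries and hospital clinical libraries routinely carry patient
tables in which the staging variables — the AJCC TNM components (T: depth
of tumor invasion, N: regional lymph-node involvement, M: distant
metastasis) and the SEER summary stage (single-digit extent-of-disease
code: 0 in situ, 1 localized, 2 regional by direct extension, 3 regional
nodes, 4 both, 7 distant, 9 unknown) — are largely missing or erroneous,
even though the information exists in free-text pathology and imaging
reports. `crcqmp` implements a four-stage quality management process (QMP)
for exactly this situation:

1. **Profile** — per-variable missing counts and rates of the cohort table
   (`qmp_profile()`).
2. **Extract** — a phrase lexicon grounded in the Korean clinical guideline
   for colorectal cancer and SEER Summary Stage 2018 is compiled into a
   rule matcher (`load_lexicon()`); `extract_tnm()` and
   `extract_seer_direct()` + `derive_seer()` turn report text into staging
   assignments with a verbatim evidence trail. Conflicts resolve by
   *explicit stage-code tokens over descriptive phrases*, then *worst
   documented extent*; the summary stage follows the precedence
   7 (distant, M=1) > 4 (codes 2+3) > 3 (nodes, or N≥1 on imaging) >
   2 > 1 > 0, with 9 when a report was searched and nothing matched.
3. **Impute** — `qmp_impute()` stages every patient from their documents
   (pathology over imaging, worst extent across same-modality documents)
   and writes derived codes into *missing* cells only, logging every write
   with its evidence rule ids (`fill_and_flag` mode additionally flags,
   never overwrites, disagreeing nonmissing cells).
4. **Evaluate** — `qmp_evaluate()` compares missing rates before vs after,
   audits concordance against manually generated reference codes, and fits
   a gradient-boosted decision-tree classifier of 5-year survival to each
   version of the cohort, reporting accuracy / precision / recall / F1 /
   AUROC and normalized feature importances.

Because the source clinical library is not public, the package ships a
first-class synthetic cohort generator (`sim_config()`, `build_cohort()`)
that emulates its profile: 6491 patients, TNM 75.3% missing, SEER 24.3%
missing, erroneous codes in 50% / 31.1% of nonmissing cells,
stage-dependent 5-year survival (~94.5% prevalence), and report text
rendered from the lexicon's own phrase inventory with known ground truth —
so every extraction and imputation step is auditable against truth.

## Worked example

```r
library(crcqmp)
lex <- load_lexicon()

extract_tnm(
  "Invades pericolic adipose tissue. Metastasis in 2 of 16 regional lymph nodes (2/16).",
  "pathology", lex)
#> TNM assignment (pathology): T3N1Mx  (2 evidence spans)

sim <- build_cohort(sim_config(seed = 1))
qmp_profile(sim$records)
#> Variable missingness profile
#>   T stage                missing  4836 / 6491 (74.5%)
#>   N stage                missing  4836 / 6491 (74.5%)
#>   M stage                missing  4836 / 6491 (74.5%)
#>   TNM                    missing  4836 / 6491 (74.5%)
#>   SEER                   missing  1538 / 6491 (23.7%)

imp <- qmp_impute(sim$records, sim$documents, lex)
imp
#> QMP imputation (fill_missing): 11892 cells filled, 0 flagged
#>   2458 patient(s) without documents, 0 without evidence

report <- qmp_evaluate(sim$records, imp$records, seed = 1)
print(report)
#> Quality management report
#>
#>   T stage                missing 74.5% -> 28.1%
#>   N stage                missing 74.5% -> 28.1%
#>   M stage                missing 74.5% -> 44.6%
#>   TNM                    missing 74.5% -> 28.1%
#>   SEER                   missing 23.7% -> 9.6%
#>
#>   Model AUROC: 0.6405 -> 0.6622 (outcome five_year_survival, seed 1)
#>   Top features after QMP: age, M stage_1.0, total lymph node, SEER_7.0, ...
```

Reading the output: the first line is a single-report extraction — the
tumor phrase maps to T3, the node-count phrase (2 of 16) to N1; pathology
reports never assert the *absence* of distant disease, so M stays `x`
until an imaging report supplies M0. At cohort scale, imputation from the
reports cuts TNM missingness from ~75% to ~28% (the residue is patients
with no usable report; M lags because it needs imaging), and stage-derived
features such as `M stage_1.0` enter the top model importances only after
quality management — the pattern the QMP is designed to produce.

The combined stage string uses `x` for undetermined components
(`"TxN2M0"`), and one-hot feature names follow registry-export style:
`SEER_2.0`, `perineural invasion_nan`, `TNM_T4N2M1`.

## Command line

```sh
Rscript inst/cli/qmp.R profile  --cohort cohort.csv
Rscript inst/cli/qmp.R impute   --cohort cohort.csv --docs docs.jsonl --out out/
Rscript inst/cli/qmp.R evaluate --before cohort.csv --after out/cohort_imputed.csv --seed 1
```

Cohort tables are RFC-4180 CSV against a documented schema (aliases
configurable); documents are JSON-lines with `patient_id`, `modality`,
`text`. The lexicon ships as an editable YAML file
(`inst/extdata/tables_3_4.lexicon`).

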