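## Synthetic cohort and report generator.
##
## Builds cohorts with known ground-truth staging, renders pathology and
## imaging report text from the lexicon's phrase inventory, and injects
## missingness and erroneous codes at configurable rates. This is the test
## bed standing in for the (non-deposited) clinical library: every stored
## stage code can be audited against its generating truth.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the profiled colorectal-cancer clinical library: cohort
#' size 6491; stage distribution following the table's nonmissing
#' frequencies; TNM missing at 75.3% and SEER at 24.3%; erroneous codes in
#' 50% / 31.1% of nonmissing TNM / SEER cells; 5-year survival from a
#' logistic model in stage, age and perineural/lymphatic invasion
#' calibrated to ~94.5% prevalence.
#'
#' @param n cohort size.
#' @param seed integer seed; the whole cohort (truths, covariates,
#'   documents) is reproducible from `(config, seed)`.
#' @param t_probs,n_probs,m_probs named probability vectors over the stage
#'   component codes (must each sum to 1 within 1e-9). In-situ and T0
#'   truths are constrained to N0 M0.
#' @param miss_tnm,miss_seer per-variable missingness probabilities (TNM
#'   components and the combined string are masked jointly).
#' @param err_tnm,err_seer probability that a nonmissing stored code is
#'   wrong: one randomly chosen TNM component (or the SEER code) is
#'   replaced by a code sampled uniformly from the other valid codes.
#' @param tnm_scramble if `TRUE`, nonmissing stored TNM components are
#'   instead drawn uniformly over all valid codes, independent of truth —
#'   a fully uninformative stored value (used to study feature selection
#'   when the stored stage carries no signal). Off by default.
#' @param coverage_pathology,coverage_imaging probability that a patient
#'   has a report of that modality.
#' @param style_weights weights for the `descriptive` vs `explicit`
#'   phrase styles when rendering reports.
#' @param outcome_coefs named coefficients of the survival model
#'   `logit P(5-year survival) = intercept - t*T - n*N - m*M -
#'   age*(age-66.79)/10 - perineural*(code-1) - lymphatic*(code-1)` with T
#'   mapped 0, 0.5 (in situ), 1, 2, 3, 4. Stage, age, perineural and
#'   lymphatic invasion are the literature-supported prognostic factors
#'   available in the cohort schema.
#' @param imperfect_phrasing if `TRUE`, staging sentences occasionally
#'   drop a token, so extraction concordance falls below 100% (for
#'   demonstrations; off by default).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n = 6491, seed = 1,
                       t_probs = c("0" = 0.001, "is" = 0.001, "1" = 0.189,
                                   "2" = 0.148, "3" = 0.507, "4" = 0.154),
                       n_probs = c("0" = 0.603, "1" = 0.249, "2" = 0.148),
                       m_probs = c("0" = 0.908, "1" = 0.092),
                       miss_tnm = 0.753, miss_seer = 0.243,
                       err_tnm = 0.50, err_seer = 0.311,
                       tnm_scramble = FALSE,
                       coverage_pathology = 0.4, coverage_imaging = 0.4,
                       style_weights = c(descriptive = 0.5, explicit = 0.5),
                       outcome_coefs = c(intercept = 5.1, t = 0.35,
                                         n = 0.5, m = 2.0, age = 0.35,
                                         perineural = 0.4,
                                         lymphatic = 0.3),
                       imperfect_phrasing = FALSE) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop("n must be positive")
  for (p in list(t_probs = t_probs, n_probs = n_probs, m_probs = m_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("stage distribution must be nonnegative and sum to 1 (within 1e-9)")
    }
  }
  probs <- c(miss_tnm, miss_seer, err_tnm, err_seer,
             coverage_pathology, coverage_imaging)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(names(t_probs) %in% .t_levels[-1]) ||
      !all(names(n_probs) %in% .n_levels[-1]) ||
      !all(names(m_probs) %in% .m_levels[-1])) {
    stop("stage distribution names must be valid component codes")
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    t_probs = t_probs, n_probs = n_probs, m_probs = m_probs,
    miss_tnm = miss_tnm, miss_seer = miss_seer,
    err_tnm = err_tnm, err_seer = err_seer,
    tnm_scramble = isTRUE(tnm_scramble),
    coverage_pathology = coverage_pathology,
    coverage_imaging = coverage_imaging,
    style_weights = style_weights,
    outcome_coefs = outcome_coefs,
    imperfect_phrasing = isTRUE(imperfect_phrasing)
  ), class = "sim_config")
}

t_numeric <- function(t) {
  unname(c("0" = 0, "is" = 0.5, "1" = 1, "2" = 2, "3" = 3, "4" = 4)[t])
}

#' Derive the true SEER summary stage from true TNM
#'
#' Summary Stage 2018 semantics on the component grid: distant disease
#' (M=1) is code 7; nodal disease is code 4 when the tumor also extends
#' directly beyond the wall (T3/T4) and code 3 otherwise; without nodes,
#' T3/T4 is code 2 (regional by direct extension), T1/T2 code 1
#' (localized), in situ code 0, and T0 (no residual/identifiable tumor)
#' code 9 (extent not determinable).
#'
#' @param t,n,m character code vectors (recycled to a common length).
#' @return character vector of SEER codes.
#' @examples
#' seer_from_tnm("3", "1", "0")  # "4"
#' @export
seer_from_tnm <- function(t, n, m) {
  k <- max(length(t), length(n), length(m))
  t <- rep_len(as.character(t), k)
  n <- rep_len(as.character(n), k)
  m <- rep_len(as.character(m), k)
  out <- rep("9", k)
  direct_ext <- t %in% c("3", "4")
  nodal <- n %in% c("1", "2")
  out[m == "1"] <- "7"
  out[m != "1" & nodal & direct_ext] <- "4"
  out[m != "1" & nodal & !direct_ext] <- "3"
  out[m != "1" & !nodal & direct_ext] <- "2"
  out[m != "1" & !nodal & t %in% c("1", "2")] <- "1"
  out[m != "1" & !nodal & t == "is"] <- "0"
  out[m != "1" & !nodal & t == "0"] <- "9"
  out
}

#' Sample ground-truth patients
#'
#' Draws `n` truths from the configured stage distribution (T and N/M
#' independent except that T0/Tis truths are localized: N0 M0), derives the
#' true SEER code, samples age and the perineural/lymphatic invasion
#' codes, and draws
#' 5-year survival from the logistic outcome model. Deterministic given the
#' config's seed.
#'
#' @param config a [sim_config()].
#' @return data frame of class `crc_truths` with columns `patient_id`, `t`,
#'   `n`, `m`, `seer`, `age`, `perineural`, `lymphatic`,
#'   `five_year_survival`, and the
#'   injected-missing/error flags `mask_tnm`, `mask_seer`, `err_tnm`,
#'   `err_seer`.
#' @export
sample_truths <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  t <- sample(names(config$t_probs), n, TRUE, config$t_probs)
  nn <- sample(names(config$n_probs), n, TRUE, config$n_probs)
  m <- sample(names(config$m_probs), n, TRUE, config$m_probs)
  early <- t %in% c("0", "is")
  nn[early] <- "0"
  m[early] <- "0"
  age <- pmin(pmax(round(stats::rnorm(n, 66.79, 13.4)), 20), 100)
  perineural <- sample(1:3, n, TRUE, c(0.55, 0.27, 0.18))
  lymphatic <- sample(1:3, n, TRUE, c(0.60, 0.25, 0.15))
  b <- config$outcome_coefs
  lin <- b[["intercept"]] - b[["t"]] * t_numeric(t) -
    b[["n"]] * as.numeric(nn) - b[["m"]] * as.numeric(m) -
    b[["age"]] * (age - 66.79) / 10 -
    b[["perineural"]] * (perineural - 1) -
    b[["lymphatic"]] * (lymphatic - 1)
  surv <- stats::rbinom(n, 1, stats::plogis(lin))
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    t = t, n = nn, m = m,
    seer = seer_from_tnm(t, nn, m),
    age = age, perineural = perineural, lymphatic = lymphatic,
    five_year_survival = surv,
    mask_tnm = stats::runif(n) < config$miss_tnm,
    mask_seer = stats::runif(n) < config$miss_seer,
    err_tnm = stats::runif(n) < config$err_tnm,
    err_seer = stats::runif(n) < config$err_seer,
    stringsAsFactors = FALSE
  )
  class(out) <- c("crc_truths", "data.frame")
  out
}

## ---- report rendering --------------------------------------------------

path_distractors <- c(
  "Specimen consists of a segment of colon measuring 25 cm",
  "Resection margins are free of tumor",
  "Microscopic examination was performed",
  "Immunohistochemical staining was carried out"
)

img_distractors <- c(
  "Contrast-enhanced abdominopelvic CT was obtained",
  "Comparison was made with the prior study",
  "Clinical correlation is recommended",
  "The remainder of the examination is unremarkable"
)

#' Distractor sentences used by the report renderer
#'
#' Boilerplate sentences verified (by test) to match no lexicon rule, so
#' extraction precision on rendered reports is measurable.
#'
#' @param modality `"pathology"` or `"imaging"`.
#' @return character vector of sentences.
#' @export
distractor_sentences <- function(modality = c("pathology", "imaging")) {
  modality <- match.arg(modality)
  if (modality == "pathology") path_distractors else img_distractors
}

pick <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

render_pathology <- function(truth, explicit) {
  sen <- character(0)
  tv <- truth$t
  t_sen <- switch(tv,
    "0" = "No residual tumor is identified",
    "is" = "Intraepithelial carcinoma is identified",
    "1" = pick(c("Invades submucosa", "Invasion to submucosa")),
    "2" = "Invades muscularis propria",
    "3" = pick(c("Invades pericolic adipose tissue",
                 "Invades perirectal adipose tissue",
                 "Invades subserosa")),
    "4" = "Penetrates visceral peritoneum")
  t_code <- switch(tv, "is" = "(pTis)",
                   "1" = pick(c("(pT1)", "(ypT1)")), "2" = "(pT2)",
                   "3" = pick(c("(pT3)", "(ypT3)")), "4" = "(pT4a)",
                   NULL)
  if (explicit && !is.null(t_code)) t_sen <- paste(t_sen, t_code)
  sen <- c(sen, t_sen)

  total <- sample(12:25, 1L)
  nv <- truth$n
  if (nv == "0") {
    n_sen <- sprintf("No metastasis in %d regional lymph nodes (0/%d)",
                     total, total)
    n_code <- "(pN0)"
  } else if (nv == "1") {
    k <- sample(1:3, 1L)
    n_sen <- sprintf("Metastasis in %d of %d regional lymph nodes (%d/%d)",
                     k, total, k, total)
    n_code <- if (k == 1L) "(pN1a)" else "(pN1b)"
  } else {
    k <- sample(4:9, 1L)
    n_sen <- sprintf("Metastasis in %d of %d regional lymph nodes (%d/%d)",
                     k, total, k, total)
    n_code <- "(pN2a)"
  }
  if (explicit) n_sen <- paste(n_sen, n_code)
  sen <- c(sen, n_sen)

  if (truth$m == "1") {
    sen <- c(sen, pick(c("Metastatic adenocarcinoma",
                         "Metastatic colonic adenocarcinoma")))
  }
  sen
}

render_imaging <- function(truth, explicit) {
  sen <- character(0)
  tv <- truth$t
  t_sen <- switch(tv,
    "0" = "No evidence of abnormal wall thickening",
    "is" = "Invasion of lamina propria",
    "1" = "Submucosal invasion",
    "2" = "Irregular bowel wall thickening",
    "3" = pick(c("Pericolic fat infiltration",
                 "Perirectal fat infiltration")),
    "4" = "Tumor invasion of visceral peritoneum")
  t_code <- switch(tv, "is" = "Tis", "1" = "T1", "2" = "T2", "3" = "T3",
                   "4" = pick(c("T4", "T4a")), NULL)
  ## imaging T2 has no descriptive phrase in the lexicon: the stage-code
  ## token is the only way to express it, so it is rendered in both styles
  if (!is.null(t_code) && (explicit || tv == "2")) {
    t_sen <- paste0(t_sen, ", ", t_code)
  }
  sen <- c(sen, t_sen)

  nv <- truth$n
  n_sen <- switch(nv,
    "0" = "No significant enlarged peritumoral lymph nodes",
    "1" = "With regional lymph node metastasis",
    "2" = "Multiple regional metastatic lymph nodes")
  if (explicit) n_sen <- paste0(n_sen, ", N", nv)
  sen <- c(sen, n_sen)

  if (truth$m == "1") {
    organ <- pick(c("Liver", "Hepatic", "Pulmonary", "Bone"))
    sen <- c(sen, sprintf("%s metastasis is suspected", organ))
  } else {
    sen <- c(sen, "No evidence of distant metastasis")
  }
  sen
}

drop_token <- function(sentence) {
  words <- strsplit(sentence, " ", fixed = TRUE)[[1]]
  if (length(words) < 3L) return(sentence)
  paste(words[-sample.int(length(words), 1L)], collapse = " ")
}

#' Render a synthetic report for one ground-truth patient
#'
#' Assembles a report whose lexicon matches imply exactly the truth's stage
#' components: one T sentence, one N sentence, an M sentence where the
#' modality can express it (pathology reports carry no M0 statement;
#' imaging reports always address distant disease), plus distractor
#' boilerplate matching no rule. The `explicit` style appends stage-code
#' tokens such as `"(pT3)"` (pathology) or `", T3"` (imaging).
#'
#' @param truth one row of [sample_truths()] output (or any list with
#'   `t`, `n`, `m` codes and a `patient_id`).
#' @param modality `"pathology"` or `"imaging"`.
#' @param style `"descriptive"` or `"explicit"`.
#' @param seed optional integer; if given, rendering is a pure function of
#'   `(truth, modality, style, seed)`.
#' @param imperfect if `TRUE`, each staging sentence may drop a token
#'   (probability 0.15), degrading extraction on purpose.
#' @return a one-row data frame with `patient_id`, `modality`, `text`.
#' @export
render_report <- function(truth, modality = c("pathology", "imaging"),
                          style = c("descriptive", "explicit"),
                          seed = NULL, imperfect = FALSE) {
  modality <- match.arg(modality)
  style <- match.arg(style)
  if (!is.null(seed)) set.seed(seed)
  explicit <- style == "explicit"
  staging <- if (modality == "pathology") {
    render_pathology(truth, explicit)
  } else {
    render_imaging(truth, explicit)
  }
  if (imperfect) {
    drop <- stats::runif(length(staging)) < 0.15
    staging[drop] <- vapply(staging[drop], drop_token, character(1))
  }
  boiler <- distractor_sentences(modality)
  sen <- c(pick(boiler), staging, pick(boiler))
  data.frame(patient_id = truth$patient_id, modality = modality,
             text = paste0(paste(sen, collapse = ". "), "."),
             stringsAsFactors = FALSE)
}

## Corrupt one stored TNM triple: flip one randomly chosen component to a
## uniformly drawn *different* code.
corrupt_tnm <- function(t, n, m) {
  comp <- sample(c("t", "n", "m"), 1L)
  alt <- function(value, levels) pick(setdiff(levels, value))
  if (comp == "t") t <- alt(t, .t_levels[-1])
  else if (comp == "n") n <- alt(n, .n_levels[-1])
  else m <- alt(m, .m_levels[-1])
  list(t = t, n = n, m = m)
}

#' Build a full synthetic cohort: records, documents, truths
#'
#' Samples ground truths, generates the covariate columns of the canonical
#' cohort schema (demographics, treatment and outcome flags, node counts
#' tied to the true N), stores stage codes masked per the missingness flags
#' and corrupted per the error flags, and renders pathology/imaging
#' documents per the coverage probabilities. Fully reproducible from the
#' config.
#'
#' @param config a [sim_config()].
#' @return list of class `crc_sim` with `records` (cohort data frame),
#'   `documents` (data frame: `patient_id`, `modality`, `text`), `truths`
#'   (the [sample_truths()] output) and `config`.
#' @export
build_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truths <- sample_truths(config)  # seeds the stream
  n <- config$n

  sex <- sample(c("M", "F"), n, TRUE, c(0.606, 0.394))
  height <- round(stats::rnorm(n, 162.0, 9.15), 1)
  weight <- round(stats::rnorm(n, 62.44, 11.88), 1)
  bmi <- round(weight / (height / 100)^2, 1)
  mask_body <- stats::runif(n) < 0.33
  height[mask_body] <- NA; weight[mask_body] <- NA; bmi[mask_body] <- NA
  year <- sample(2010:2022, n, TRUE)
  site <- sample(c("C18", "C18.1", "C18.2", "C18.3", "C18.5", "C18.7",
                   "C19", "C20", "C17.0", "K83.8"), n, TRUE,
                 c(0.08, 0.08, 0.06, 0.10, 0.14, 0.12, 0.12, 0.22,
                   0.04, 0.06))
  histo <- sample(c(16, 23, 26, 8, 31), n, TRUE,
                  c(0.45, 0.20, 0.15, 0.10, 0.10))
  lymphatic <- truths$lymphatic
  lymphatic[stats::runif(n) < 0.20] <- NA
  perineural <- truths$perineural
  perineural[stats::runif(n) < 0.25] <- NA
  total_ln <- pmax(round(stats::rnorm(n, 20.25, 12.05)), 1)
  pos_ln <- integer(n)
  pos_ln[truths$n == "1"] <- sample(1:3, sum(truths$n == "1"), TRUE)
  pos_ln[truths$n == "2"] <- sample(4:12, sum(truths$n == "2"), TRUE)
  pos_ln <- pmin(pos_ln, total_ln)
  mask_ln <- stats::runif(n) < 0.406
  total_ln[mask_ln] <- NA; pos_ln[mask_ln] <- NA
  operation <- stats::rbinom(n, 1, 0.405)
  chemo <- stats::rbinom(n, 1, 0.035)
  radio <- stats::rbinom(n, 1, 0.059)
  complication <- stats::rbinom(n, 1, 0.081)
  death <- ifelse(truths$five_year_survival == 0L, 1L,
                  stats::rbinom(n, 1, 0.006))

  st <- truths$t; sn <- truths$n; sm <- truths$m
  if (config$tnm_scramble) {
    idx <- which(!truths$mask_tnm)
    st[idx] <- sample(.t_levels[-1], length(idx), TRUE)
    sn[idx] <- sample(.n_levels[-1], length(idx), TRUE)
    sm[idx] <- sample(.m_levels[-1], length(idx), TRUE)
  } else {
    for (i in which(truths$err_tnm & !truths$mask_tnm)) {
      cc <- corrupt_tnm(st[i], sn[i], sm[i])
      st[i] <- cc$t; sn[i] <- cc$n; sm[i] <- cc$m
    }
  }
  tnm_str <- paste0("T", st, "N", sn, "M", sm)
  st[truths$mask_tnm] <- NA; sn[truths$mask_tnm] <- NA
  sm[truths$mask_tnm] <- NA; tnm_str[truths$mask_tnm] <- NA

  sseer <- truths$seer
  for (i in which(truths$err_seer & !truths$mask_seer)) {
    sseer[i] <- pick(setdiff(.seer_levels, sseer[i]))
  }
  sseer[truths$mask_seer] <- NA
  sseer <- as.numeric(sseer)

  records <- data.frame(
    patient_id = truths$patient_id, sex = sex, age = truths$age,
    height = height, weight = weight, BMI = bmi,
    `year of initial visit` = year, `primary site` = site,
    `histological diagnosis` = histo, `lymphatic invasion` = lymphatic,
    `perineural invasion` = perineural,
    `total lymph node` = total_ln, `positive lymph node` = pos_ln,
    operation = operation, chemotherapy = chemo, radiotherapy = radio,
    `complication after surgery` = complication, death = death,
    five_year_survival = truths$five_year_survival,
    `T stage` = st, `N stage` = sn, `M stage` = sm,
    TNM = tnm_str, SEER = sseer,
    stringsAsFactors = FALSE, check.names = FALSE
  )

  has_path <- stats::runif(n) < config$coverage_pathology
  has_img <- stats::runif(n) < config$coverage_imaging
  sw <- config$style_weights / sum(config$style_weights)
  docs <- list()
  for (i in seq_len(n)) {
    if (!has_path[i] && !has_img[i]) next
    truth <- truths[i, ]
    if (has_path[i]) {
      style <- sample(names(sw), 1L, prob = sw)
      docs[[length(docs) + 1L]] <-
        render_report(truth, "pathology", style,
                      imperfect = config$imperfect_phrasing)
    }
    if (has_img[i]) {
      style <- sample(names(sw), 1L, prob = sw)
      docs[[length(docs) + 1L]] <-
        render_report(truth, "imaging", style,
                      imperfect = config$imperfect_phrasing)
    }
  }
  documents <- if (length(docs)) do.call(rbind, docs) else
    data.frame(patient_id = character(0), modality = character(0),
               text = character(0), stringsAsFactors = FALSE)
  structure(list(records = records, documents = documents, truths = truths,
                 config = config),
            class = "crc_sim")
}

#' @export
print.crc_sim <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d documents (seed %d)\n",
              nrow(x$records), nrow(x$documents), x$config$seed))
  invisible(x)
}
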