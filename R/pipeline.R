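## The four-stage quality management process (QMP) over a cohort:
## profile (identification), impute (operation), evaluate (before/after
## comparison including prognostic-model performance and feature
## importance).

#' Profile missingness of cohort variables
#'
#' Frequency analysis of the requested variables: per-variable missing
#' counts and rates (percent, one decimal), plus category frequency tables
#' for categorical variables.
#'
#' @param records cohort data frame.
#' @param variables variables to profile; defaults to the staging target
#'   variables. An empty vector yields an empty profile.
#' @return a `qmp_profile`: list with `variables` (data frame: variable,
#'   n_total, n_missing, missing_rate) and `frequencies` (named list of
#'   tables for categorical variables).
#' @examples
#' cohort <- build_cohort(sim_config(n = 50, seed = 1))
#' qmp_profile(cohort$records)
#' @export
qmp_profile <- function(records, variables = target_variables()) {
  unknown <- setdiff(variables, names(records))
  if (length(unknown) > 0L) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(names(records), collapse = ", "))
  }
  sch <- crc_schema()
  rows <- list()
  freqs <- list()
  for (v in variables) {
    x <- records[[v]]
    n_missing <- sum(is_missing_cell(x))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, n_total = length(x), n_missing = n_missing,
      missing_rate = missing_rate(n_missing, length(x)),
      stringsAsFactors = FALSE
    )
    if (v %in% sch$categorical || is.character(x)) {
      freqs[[v]] <- table(x[!is_missing_cell(x)])
    }
  }
  vars_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), n_total = integer(0),
               n_missing = integer(0), missing_rate = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(variables = vars_df, frequencies = freqs),
            class = "qmp_profile")
}

#' @export
print.qmp_profile <- function(x, ...) {
  cat("Variable missingness profile\n")
  if (nrow(x$variables) == 0L) {
    cat("  (no variables)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$variables))) {
    cat(sprintf("  %-22s missing %5d / %d (%.1f%%)\n",
                x$variables$variable[i], x$variables$n_missing[i],
                x$variables$n_total[i], x$variables$missing_rate[i]))
  }
  invisible(x)
}

derived_values <- function(a) {
  vals <- list()
  if (a$t != "x") vals[["T stage"]] <- a$t
  if (a$n != "x") vals[["N stage"]] <- a$n
  if (a$m != "x") vals[["M stage"]] <- a$m
  if (a$t != "x" || a$n != "x" || a$m != "x") {
    vals[["TNM"]] <- format_tnm_string(a)
  }
  if (!a$seer_code %in% c("9", "missing")) vals[["SEER"]] <- a$seer_code
  vals
}

evidence_ids <- function(a, variable, value) {
  ev <- a$evidence
  if (is.null(ev) || nrow(ev) == 0L) return("")
  ids <- switch(variable,
    "T stage" = ev$rule_id[ev$component == "T" & ev$value == value],
    "N stage" = ev$rule_id[ev$component == "N" & ev$value == value],
    "M stage" = ev$rule_id[ev$component == "M" & ev$value == value],
    "TNM" = ev$rule_id[ev$component %in% c("T", "N", "M")],
    "SEER" = ev$rule_id[ev$component == "SEER"]
  )
  paste(unique(ids), collapse = ";")
}

#' Impute missing staging variables from report text
#'
#' Runs the staging engine over each patient's documents (see
#' [stage_cohort()]), merges modalities, and writes the derived T/N/M
#' codes, combined TNM string and SEER summary stage into the cohort. In
#' `fill_missing` mode (the default) only missing cells are written;
#' `fill_and_flag` additionally flags — never overwrites — nonmissing
#' cells that disagree with the derived code. A derived SEER 9 ("no
#' evidence") is never written into a missing cell: it asserts ignorance,
#' not extent. Every write and flag is logged with its evidence rule ids;
#' non-target variables are never touched.
#'
#' @param records cohort data frame.
#' @param documents documents data frame (`patient_id`, `modality`,
#'   `text`).
#' @param lexicon a compiled lexicon from [load_lexicon()].
#' @param mode `"fill_missing"` or `"fill_and_flag"`.
#' @return a `qmp_imputation`: list with `records` (imputed copy),
#'   `change_log` (data frame: patient_id, variable, old, new, action,
#'   evidence), `n_no_document` (patients without any report, untouched)
#'   and `n_no_evidence` (patients whose reports yielded no stage
#'   evidence).
#' @export
qmp_impute <- function(records, documents, lexicon,
                       mode = c("fill_missing", "fill_and_flag")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lexicon, "crc_lexicon"))
  docs <- documents[documents$patient_id %in% records$patient_id, ,
                    drop = FALSE]
  assignments <- stage_cohort(docs, lexicon)
  out <- records
  log_rows <- list()
  n_no_evidence <- 0L
  for (pid in names(assignments)) {
    a <- assignments[[pid]]
    i <- match(pid, out$patient_id)
    vals <- derived_values(a)
    if (length(vals) == 0L) {
      n_no_evidence <- n_no_evidence + 1L
      next
    }
    for (v in names(vals)) {
      new <- vals[[v]]
      old <- out[[v]][i]
      if (is_missing_cell(old)) {
        out[[v]][i] <- if (is.numeric(out[[v]])) as.numeric(new) else new
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          patient_id = pid, variable = v, old = NA_character_,
          new = new, action = "fill",
          evidence = evidence_ids(a, v, new), stringsAsFactors = FALSE)
      } else if (mode == "fill_and_flag") {
        old_chr <- if (is.numeric(old)) format_level(old) else
          as.character(old)
        new_chr <- if (v == "SEER") format_level(as.numeric(new)) else new
        if (!identical(old_chr, new_chr)) {
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            patient_id = pid, variable = v, old = old_chr,
            new = new_chr, action = "flag",
            evidence = evidence_ids(a, v, new), stringsAsFactors = FALSE)
        }
      }
    }
  }
  change_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(patient_id = character(0), variable = character(0),
               old = character(0), new = character(0),
               action = character(0), evidence = character(0),
               stringsAsFactors = FALSE)
  structure(list(
    records = out, change_log = change_log, mode = mode,
    n_no_document = sum(!records$patient_id %in% docs$patient_id),
    n_no_evidence = n_no_evidence
  ), class = "qmp_imputation")
}

#' @export
print.qmp_imputation <- function(x, ...) {
  cat(sprintf("QMP imputation (%s): %d cells filled, %d flagged\n",
              x$mode, sum(x$change_log$action == "fill"),
              sum(x$change_log$action == "flag")))
  cat(sprintf("  %d patient(s) without documents, %d without evidence\n",
              x$n_no_document, x$n_no_evidence))
  invisible(x)
}

#' Default hyperparameters of the prognostic gradient-boosting model
#'
#' Tree depth 3, learning rate 0.1, 100 boosting rounds, no row or column
#' subsampling (so a fixed seed gives bit-identical fits), and a 20%
#' stratified test split. Override any element via the `model_params`
#' argument of [qmp_evaluate()].
#'
#' @return named list of defaults.
#' @export
default_model_params <- function() {
  list(max_depth = 3, eta = 0.1, nrounds = 100, min_child_weight = 1,
       subsample = 1, colsample_bytree = 1, test_fraction = 0.2)
}

## Stratified train/test split, gradient-boosted trees, metrics and
## normalized gain importances. Deterministic given the seed (single
## thread, no row/column subsampling by default).
fit_gbm <- function(records, outcome, seed, params = list()) {
  p <- utils::modifyList(default_model_params(), params)
  y <- as.integer(records[[outcome]])
  if (length(unique(y[!is.na(y)])) < 2L) {
    warning("outcome '", outcome, "' is constant; model stage skipped")
    return(NULL)
  }
  X <- encode_features(records,
                       exclude = c("patient_id", outcome, "death"))
  set.seed(seed)
  test_idx <- unlist(lapply(unique(y), function(cls) {
    idx <- which(y == cls)
    sample(idx, max(1L, round(length(idx) * p$test_fraction)))
  }))
  train_idx <- setdiff(seq_along(y), test_idx)
  dtrain <- xgboost::xgb.DMatrix(X[train_idx, , drop = FALSE],
                                 label = y[train_idx])
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = p$max_depth, eta = p$eta,
                  min_child_weight = p$min_child_weight,
                  subsample = p$subsample,
                  colsample_bytree = p$colsample_bytree,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = p$nrounds, verbose = 0
  )
  scores <- stats::predict(bst, xgboost::xgb.DMatrix(
    X[test_idx, , drop = FALSE]))
  eval <- classification_metrics(y[test_idx], y_score = scores)
  imp <- xgboost::xgb.importance(model = bst)
  gain <- stats::setNames(rep(0, ncol(X)), colnames(X))
  gain[imp$Feature] <- imp$Gain
  gain <- gain / sum(gain)
  importance <- data.frame(feature = names(sort(gain, decreasing = TRUE)),
                           importance = unname(sort(gain,
                                                    decreasing = TRUE)),
                           stringsAsFactors = FALSE)
  list(eval = eval, importance = importance, n_train = length(train_idx),
       n_test = length(test_idx))
}

#' Evaluate the quality management process before vs after
#'
#' Compares two versions of the same cohort (before and after imputation):
#' missingness profiles of the target variables, optional concordance of
#' the after-cohort's codes against a manually generated reference set,
#' and a gradient-boosted decision-tree prognostic model (binary outcome,
#' stratified 80/20 split, deterministic given the seed) fitted to each
#' version, with normalized feature importances.
#'
#' @param before,after cohort data frames sharing the same `patient_id`
#'   set.
#' @param outcome binary outcome column (default `"five_year_survival"`).
#' @param reference optional data frame with `patient_id` plus any target
#'   variables, holding manually generated reference codes for an audit
#'   subsample; concordance of the after-cohort against it is reported per
#'   variable.
#' @param seed integer seed controlling the split (and any model
#'   stochasticity).
#' @param variables target variables to profile.
#' @param model_params overrides for [default_model_params()] (tree depth,
#'   learning rate, rounds, test fraction).
#' @return a `qmp_report`: profiles, optional `concordance` (named list),
#'   `model_before` / `model_after` (metrics + importance; `NULL` when the
#'   outcome is constant), `seed`.
#' @export
qmp_evaluate <- function(before, after, outcome = "five_year_survival",
                         reference = NULL, seed = 1,
                         variables = target_variables(),
                         model_params = list()) {
  if (!setequal(before$patient_id, after$patient_id)) {
    stop("'before' and 'after' must share the same patient_id set")
  }
  profile_before <- qmp_profile(before, variables)
  profile_after <- qmp_profile(after, variables)

  conc <- NULL
  if (!is.null(reference)) {
    stopifnot("patient_id" %in% names(reference))
    idx <- match(reference$patient_id, after$patient_id)
    conc <- list()
    for (v in intersect(names(reference), variables)) {
      ref_v <- reference[[v]]
      obs_v <- after[[v]][idx]
      if (v == "SEER") {
        ref_v <- format_level(suppressWarnings(as.numeric(ref_v)))
        ref_v[ref_v == "nan"] <- NA
        obs_v <- format_level(suppressWarnings(as.numeric(obs_v)))
        obs_v[obs_v == "nan"] <- NA
      }
      conc[[v]] <- concordance(ref_v, obs_v, ids = reference$patient_id)
    }
  }

  model_before <- fit_gbm(before, outcome, seed, model_params)
  model_after <- fit_gbm(after, outcome, seed, model_params)

  structure(list(
    before = profile_before, after = profile_after,
    concordance = conc,
    model_before = if (is.null(model_before)) NULL else model_before$eval,
    model_after = if (is.null(model_after)) NULL else model_after$eval,
    importance_before = if (is.null(model_before)) NULL else
      model_before$importance,
    importance_after = if (is.null(model_after)) NULL else
      model_after$importance,
    outcome = outcome, seed = seed
  ), class = "qmp_report")
}

#' @export
print.qmp_report <- function(x, top = 10L, ...) {
  cat("Quality management report\n\n")
  b <- x$before$variables; a <- x$after$variables
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-22s missing %.1f%% -> %.1f%%\n", b$variable[i],
                b$missing_rate[i], a$missing_rate[i]))
  }
  if (!is.null(x$concordance)) {
    cat("\n  Concordance vs reference codes:\n")
    for (v in names(x$concordance)) {
      r <- x$concordance[[v]]
      cat(sprintf("    %-20s %s (n=%d)\n", v,
                  if (r$undefined) "undefined" else
                    sprintf("%.1f%%", r$concordance_rate),
                  r$n_compared))
    }
  }
  if (!is.null(x$model_before)) {
    cat(sprintf("\n  Model AUROC: %.4f -> %.4f (outcome %s, seed %d)\n",
                x$model_before$auroc, x$model_after$auroc, x$outcome,
                x$seed))
    cat(sprintf("  Top features after QMP: %s\n",
                paste(utils::head(x$importance_after$feature, top),
                      collapse = ", ")))
  }
  invisible(x)
}
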