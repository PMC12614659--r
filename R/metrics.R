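## Data-quality and model-evaluation statistics: missing rates, audit error
## rates, concordance between code sets, and standard classification
## metrics. Percentages are reported on the 0-100 scale rounded half-up to
## one decimal, matching how registry quality tables print them.

#' Missing-data rate
#'
#' `100 * n_missing / n_total`, rounded half-up to one decimal.
#'
#' @param n_missing number of records with the value absent.
#' @param n_total total number of records (must be positive).
#' @return percentage on the 0-100 scale.
#' @examples
#' missing_rate(4885, 6491)  # 75.3
#' @export
missing_rate <- function(n_missing, n_total) {
  stopifnot(length(n_missing) == 1L, length(n_total) == 1L)
  if (n_total <= 0) stop("missing rate undefined: n_total must be positive")
  if (n_missing < 0 || n_missing > n_total) {
    stop("n_missing must lie in [0, n_total]")
  }
  round_half_up(100 * n_missing / n_total, 1)
}

#' Audit error rate
#'
#' `100 * n_errors / n_nonmissing`, rounded half-up to one decimal. The
#' denominator is the number of audited cases whose stored code was present
#' (pairs with a missing stored value are excluded before counting errors).
#'
#' @param n_errors number of discrepant codes.
#' @param n_nonmissing number of audited nonmissing cases (positive).
#' @return percentage on the 0-100 scale.
#' @examples
#' error_rate(43, 86)   # 50.0
#' error_rate(47, 151)  # 31.1
#' @export
error_rate <- function(n_errors, n_nonmissing) {
  stopifnot(length(n_errors) == 1L, length(n_nonmissing) == 1L)
  if (n_nonmissing <= 0) {
    stop("error rate undefined: n_nonmissing must be positive")
  }
  if (n_errors < 0 || n_errors > n_nonmissing) {
    stop("n_errors must lie in [0, n_nonmissing]")
  }
  round_half_up(100 * n_errors / n_nonmissing, 1)
}

#' Concordance between reference and observed code lists
#'
#' Compares two equal-length code vectors pairwise. Pairs with a missing
#' value on either side are excluded from the comparison and counted
#' separately; agreement and error rates are computed over the compared
#' pairs (0-100 scale, one decimal). When no pair is comparable the rates
#' are `NA` and `undefined` is `TRUE`.
#'
#' @param reference reference codes (e.g. manually generated stage codes).
#' @param observed observed codes (e.g. derived by the staging library).
#' @param ids optional identifiers used in the discrepancy list.
#' @return a `concordance_report`: list with `n_compared`, `n_agree`,
#'   `n_discordant`, `n_excluded`, `concordance_rate`, `error_rate`,
#'   `undefined`, and a `discrepancies` data frame (id, reference,
#'   observed).
#' @export
concordance <- function(reference, observed, ids = NULL) {
  if (length(reference) != length(observed)) {
    stop("reference and observed must have equal length")
  }
  if (is.null(ids)) ids <- seq_along(reference)
  ref <- as.character(reference)
  obs <- as.character(observed)
  comparable <- !is_missing_cell(ref) & !is_missing_cell(obs)
  n_compared <- sum(comparable)
  agree <- comparable & ref == obs
  n_agree <- sum(agree, na.rm = TRUE)
  n_disc <- n_compared - n_agree
  disc_idx <- which(comparable & ref != obs)
  structure(list(
    n_compared = n_compared,
    n_agree = n_agree,
    n_discordant = n_disc,
    n_excluded = length(ref) - n_compared,
    concordance_rate = if (n_compared > 0)
      round_half_up(100 * n_agree / n_compared, 1) else NA_real_,
    error_rate = if (n_compared > 0)
      round_half_up(100 * n_disc / n_compared, 1) else NA_real_,
    undefined = n_compared == 0L,
    discrepancies = data.frame(id = ids[disc_idx],
                               reference = ref[disc_idx],
                               observed = obs[disc_idx],
                               stringsAsFactors = FALSE)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  if (x$undefined) {
    cat("Concordance: undefined (no comparable pairs;",
        x$n_excluded, "excluded)\n")
  } else {
    cat(sprintf(
      "Concordance: %.1f%% (%d/%d agree, %d discordant, %d excluded)\n",
      x$concordance_rate, x$n_agree, x$n_compared, x$n_discordant,
      x$n_excluded))
  }
  invisible(x)
}

## Midrank (Mann-Whitney) AUROC; deterministic, handles ties.
auroc <- function(y_true, y_score) {
  y <- as.integer(y_true)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(y_score, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for a binary outcome
#'
#' Accuracy, precision, recall, F1 and AUROC. Precision/recall/F1 use the
#' configured averaging: `"weighted"` (per-class metrics averaged with class
#' support weights, the default) or `"binary"` (positive class only, in
#' which case F1 is exactly the harmonic mean of the reported precision and
#' recall). AUROC uses the midrank Mann-Whitney statistic; with a
#' single-class truth it is `NA` and `auroc_undefined` is `TRUE` (no error).
#'
#' @param y_true 0/1 labels.
#' @param y_score predicted probabilities in `[0, 1]` (optional; needed for
#'   AUROC).
#' @param y_pred predicted 0/1 labels; defaults to `y_score > 0.5`.
#' @param average `"weighted"` or `"binary"`.
#' @return a `model_eval` list: `accuracy`, `precision`, `recall`, `f1`,
#'   `auroc`, `auroc_undefined`, `average`, `n`.
#' @export
classification_metrics <- function(y_true, y_score = NULL, y_pred = NULL,
                                   average = c("weighted", "binary")) {
  average <- match.arg(average)
  y <- as.integer(y_true)
  stopifnot(all(y %in% c(0L, 1L)))
  if (is.null(y_pred)) {
    if (is.null(y_score)) stop("supply y_pred or y_score")
    y_pred <- as.integer(y_score > 0.5)
  }
  y_pred <- as.integer(y_pred)
  if (length(y) != length(y_pred)) stop("length mismatch")
  if (!is.null(y_score)) {
    stopifnot(length(y_score) == length(y),
              all(y_score >= 0 & y_score <= 1))
  }
  acc <- mean(y == y_pred)
  per_class <- function(cls) {
    tp <- sum(y == cls & y_pred == cls)
    fp <- sum(y != cls & y_pred == cls)
    fn <- sum(y == cls & y_pred != cls)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f, support = sum(y == cls))
  }
  if (average == "binary") {
    m <- per_class(1L)
    precision <- m["precision"]; recall <- m["recall"]; f1 <- m["f1"]
  } else {
    m0 <- per_class(0L); m1 <- per_class(1L)
    w <- c(m0["support"], m1["support"]) / length(y)
    precision <- w[1] * m0["precision"] + w[2] * m1["precision"]
    recall <- w[1] * m0["recall"] + w[2] * m1["recall"]
    f1 <- w[1] * m0["f1"] + w[2] * m1["f1"]
  }
  auc <- if (is.null(y_score)) NA_real_ else auroc(y, y_score)
  structure(list(
    accuracy = acc,
    precision = unname(precision),
    recall = unname(recall),
    f1 = unname(f1),
    auroc = auc,
    auroc_undefined = is.na(auc),
    average = average,
    n = length(y)
  ), class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf(
    "Model evaluation (n=%d, %s averaging)\n", x$n, x$average))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  if (x$auroc_undefined) cat("  AUROC undefined (single-class truth)\n")
  else cat(sprintf("  AUROC %.4f\n", x$auroc))
  invisible(x)
}
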