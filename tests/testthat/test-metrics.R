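test_that("rates use half-up rounding on the percentage scale", {
  ## 0.25% rounds up, where round() would go to even
  expect_equal(missing_rate(1, 400), 0.3)
  expect_equal(round(1 / 400 * 100, 1), 0.2)
  expect_equal(missing_rate(0, 100), 0.0)
  expect_equal(error_rate(0, 10), 0.0)
  expect_error(missing_rate(1, 0), "undefined")
  expect_error(error_rate(1, 0), "undefined")
  expect_error(missing_rate(5, 4))
  ## agreement with exact rational arithmetic before rounding
  set.seed(42)
  for (i in 1:200) {
    n_total <- sample(1:5000, 1)
    n_miss <- sample(0:n_total, 1)
    got <- missing_rate(n_miss, n_total)
    exact <- 100 * n_miss / n_total
    expect_lte(abs(got - exact), 0.05 + 1e-12)
    expect_equal(got * 10, round(got * 10))  # one decimal
    expect_identical(error_rate(n_miss, n_total), got)
  }
})

test_that("concordance compares pairwise and excludes missing pairs", {
  x <- sample(c("T1", "T2", "T3"), 164, replace = TRUE)
  r <- concordance(x, x)
  expect_equal(r$concordance_rate, 100.0)
  expect_equal(r$n_compared, 164L)
  expect_equal(r$n_discordant, 0L)

  r2 <- concordance(c("T1", "T2", "T3"), c("T1", "T2", "T4"))
  expect_equal(r2$concordance_rate, 66.7)
  expect_equal(r2$error_rate, 33.3)
  expect_equal(r2$discrepancies$reference, "T3")
  expect_equal(r2$discrepancies$observed, "T4")

  r3 <- concordance(c("T1", NA, "T3"), c(NA, "T2", "T3"),
                    ids = c("a", "b", "c"))
  expect_equal(r3$n_compared, 1L)
  expect_equal(r3$n_excluded, 2L)
  expect_equal(r3$concordance_rate, 100.0)

  r4 <- concordance(c(NA, "T1"), c("T1", NA))
  expect_true(r4$undefined)
  expect_true(is.na(r4$concordance_rate))
  expect_error(concordance(1:3, 1:2), "equal length")
})

test_that("classification metrics match a hand confusion-matrix oracle", {
  ## exhaustive over all (tp, fp, fn, tn) grids with n <= 12
  oracle <- function(tp, fp, fn, tn, average) {
    n <- tp + fp + fn + tn
    acc <- (tp + tn) / n
    prec1 <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec1 <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1_1 <- if (prec1 + rec1 > 0) 2 * prec1 * rec1 / (prec1 + rec1) else 0
    if (average == "binary") return(c(acc, prec1, rec1, f1_1))
    prec0 <- if (tn + fn > 0) tn / (tn + fn) else 0
    rec0 <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1_0 <- if (prec0 + rec0 > 0) 2 * prec0 * rec0 / (prec0 + rec0) else 0
    w1 <- (tp + fn) / n; w0 <- (tn + fp) / n
    c(acc, w0 * prec0 + w1 * prec1, w0 * rec0 + w1 * rec1,
      w0 * f1_0 + w1 * f1_1)
  }
  grid <- expand.grid(tp = 0:3, fp = 0:3, fn = 0:3, tn = 0:3)
  grid <- grid[rowSums(grid) > 0, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    y <- c(rep(1, g$tp), rep(0, g$fp), rep(1, g$fn), rep(0, g$tn))
    p <- c(rep(1, g$tp), rep(1, g$fp), rep(0, g$fn), rep(0, g$tn))
    for (avg in c("binary", "weighted")) {
      m <- classification_metrics(y, y_pred = p, average = avg)
      want <- oracle(g$tp, g$fp, g$fn, g$tn, avg)
      expect_equal(c(m$accuracy, m$precision, m$recall, m$f1), want,
                   info = sprintf("%s tp=%d fp=%d fn=%d tn=%d", avg,
                                  g$tp, g$fp, g$fn, g$tn))
    }
  }
})

test_that("weighted recall equals accuracy; binary F1 is the harmonic mean", {
  set.seed(9)
  y <- rbinom(200, 1, 0.3)
  p <- rbinom(200, 1, 0.4)
  m <- classification_metrics(y, y_pred = p, average = "weighted")
  expect_equal(m$recall, m$accuracy)
  mb <- classification_metrics(y, y_pred = p, average = "binary")
  expect_equal(mb$f1, 2 * mb$precision * mb$recall /
                 (mb$precision + mb$recall))
})

test_that("perfect and majority-class predictions score as expected", {
  m <- classification_metrics(c(0, 1, 0, 1), y_score = c(0, 1, 0, 1))
  expect_equal(c(m$accuracy, m$precision, m$recall, m$f1, m$auroc),
               rep(1, 5))
  y <- c(rep(0, 90), rep(1, 10))
  m2 <- classification_metrics(y, y_pred = rep(0, 100))
  expect_equal(m2$accuracy, 0.9)
})

test_that("AUROC is rank-based, tie-aware, and flagged when undefined", {
  set.seed(11)
  y <- rbinom(1000, 1, 0.5)
  s <- runif(1000)
  m <- classification_metrics(y, y_score = s)
  expect_gt(m$auroc, 0.45)
  expect_lt(m$auroc, 0.55)
  ## cross-check against an independent implementation
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$auroc, ref, tolerance = 1e-12)
  ## ties
  s2 <- round(s, 1)
  m2 <- classification_metrics(y, y_score = s2)
  ref2 <- as.numeric(pROC::auc(pROC::roc(y, s2, quiet = TRUE,
                                         direction = "<")))
  expect_equal(m2$auroc, ref2, tolerance = 1e-12)
  ## single-class truth: undefined flag, no error
  m3 <- classification_metrics(rep(1, 5), y_score = runif(5))
  expect_true(m3$auroc_undefined)
})
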