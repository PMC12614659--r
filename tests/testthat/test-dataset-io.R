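test_that("cohort read/write round-trips values and missingness", {
  sim <- build_cohort(sim_config(n = 40, seed = 5))
  tmp <- tempfile(fileext = ".csv")
  write_cohort(sim$records, tmp)
  back <- read_cohort(tmp)$records
  expect_equal(nrow(back), nrow(sim$records))
  for (col in names(sim$records)) {
    expect_equal(back[[col]], sim$records[[col]], info = col)
  }
  tmp2 <- tempfile(fileext = ".csv")
  write_cohort(back, tmp2)
  expect_identical(readLines(tmp2), readLines(tmp))
})

test_that("document JSON-lines read/write round-trips", {
  sim <- build_cohort(sim_config(n = 30, seed = 6))
  tmp <- tempfile(fileext = ".jsonl")
  write_documents(sim$documents, tmp)
  back <- read_documents(tmp)
  expect_equal(back$patient_id, sim$documents$patient_id)
  expect_equal(back$modality, sim$documents$modality)
  expect_equal(back$text, sim$documents$text)
})

test_that("header aliases map onto the canonical schema", {
  df <- data.frame(patient_id = c("a", "b", "c"),
                   t_stage = c("3", NA, "1"), n_stage = c("0", NA, "1"),
                   m_stage = c("0", NA, NA), tnm = c("T3N0M0", NA, NA),
                   seer = c("2", "", "1"),
                   five_year_survival = c(1, 1, 0),
                   stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE, na = "")
  cohort <- read_cohort(tmp)
  rec <- cohort$records
  expect_true(all(c("T stage", "N stage", "M stage", "TNM", "SEER")
                  %in% names(rec)))
  expect_equal(sum(is.na(rec$SEER)), 1L)
  expect_equal(rec$SEER, c(2, NA, 1))
})

test_that("schema violations are rejected, orphans counted", {
  df <- data.frame(patient_id = c("a", "a"), `T stage` = NA,
                   `N stage` = NA, `M stage` = NA, TNM = NA, SEER = NA,
                   check.names = FALSE)
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE, na = "")
  expect_error(read_cohort(tmp), "duplicate patient_id")

  df2 <- data.frame(patient_id = c("a", "b"))
  tmp2 <- tempfile(fileext = ".csv")
  write.csv(df2, tmp2, row.names = FALSE)
  expect_error(read_cohort(tmp2), "mandatory column")

  df$patient_id <- c("a", "b")
  write.csv(df, tmp, row.names = FALSE, na = "")
  docs <- data.frame(patient_id = c("a", "ghost"),
                     modality = c("pathology", "imaging"),
                     text = c("t", "t"), stringsAsFactors = FALSE)
  dtmp <- tempfile(fileext = ".jsonl")
  write_documents(docs, dtmp)
  expect_warning(cohort <- read_cohort(tmp, dtmp), "not present")
  expect_equal(cohort$n_orphans, 1L)

  writeLines('{"patient_id": "", "modality": "imaging", "text": "x"}', dtmp)
  expect_error(read_documents(dtmp), "empty patient_id")
  writeLines('{"patient_id": "a", "modality": "xray", "text": "x"}', dtmp)
  expect_error(read_documents(dtmp), "invalid modality")
})

test_that("one-hot encoding names levels as printed and keeps nan level", {
  rec <- toy_records(4)
  rec$`perineural invasion` <- c(1, 2, NA, 3)
  rec$SEER <- c(2, NA, 7, 2)
  rec$TNM <- c("T4N2M1", NA, NA, "TxN2M0")
  X <- encode_features(rec, exclude = c("patient_id", "death",
                                        "five_year_survival"))
  expect_true(all(c("perineural invasion_nan", "perineural invasion_2.0",
                    "SEER_2.0", "SEER_7.0", "SEER_nan",
                    "TNM_T4N2M1", "TNM_TxN2M0", "TNM_nan")
                  %in% colnames(X)))
  expect_equal(unname(X[3, "perineural invasion_nan"]), 1)
  expect_equal(unname(X[1, "SEER_2.0"]), 1)
  ## indicators of each categorical variable sum to 1 per row
  types <- attr(X, "types")
  for (v in c("perineural invasion", "SEER", "TNM", "sex")) {
    cols <- grep(paste0("^", v, "_"), names(types), value = TRUE)
    expect_equal(unname(rowSums(X[, cols, drop = FALSE])),
                 rep(1, nrow(rec)), info = v)
  }
})

test_that("all-numeric records encode to numeric columns only", {
  rec <- data.frame(patient_id = c("a", "b"), age = c(50, 60),
                    BMI = c(21.2, NA), stringsAsFactors = FALSE)
  X <- encode_features(rec)
  expect_equal(colnames(X), c("age", "BMI"))
  expect_true(is.na(X[2, "BMI"]))
  expect_error(encode_features(rec[0, ]), "no records")
})
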