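lex <- load_lexicon()

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n = 0), "positive")
  expect_error(sim_config(t_probs = c("1" = 0.6, "2" = 0.6)), "sum to 1")
  expect_error(sim_config(miss_tnm = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(t_probs = c("9" = 1)), "valid component codes")
})

test_that("true SEER derives from true TNM per summary-stage semantics", {
  expect_equal(seer_from_tnm("3", "1", "0"), "4")
  expect_equal(seer_from_tnm("1", "2", "0"), "3")
  expect_equal(seer_from_tnm("2", "0", "0"), "1")
  expect_equal(seer_from_tnm("4", "0", "0"), "2")
  expect_equal(seer_from_tnm("is", "0", "0"), "0")
  expect_equal(seer_from_tnm("0", "0", "0"), "9")
  expect_equal(seer_from_tnm("1", "0", "1"), "7")
  ## invariants over sampled truths
  tr <- sample_truths(sim_config(n = 500, seed = 3))
  expect_true(all(tr$seer[tr$m == "1"] == "7"))
  nodal <- tr$n %in% c("1", "2") & tr$m == "0"
  expect_true(all(tr$seer[nodal] %in% c("3", "4")))
  expect_true(all(tr$t[tr$seer == "0"] == "is"))
})

test_that("degenerate stage distribution yields a constant cohort", {
  cfg <- sim_config(n = 25, seed = 2, t_probs = c("3" = 1),
                    n_probs = c("1" = 1), m_probs = c("0" = 1))
  tr <- sample_truths(cfg)
  expect_true(all(tr$t == "3" & tr$n == "1" & tr$m == "0"))
  expect_true(all(tr$seer == "4"))
  cfg2 <- sim_config(n = 25, seed = 2, t_probs = c("2" = 1),
                     n_probs = c("1" = 1), m_probs = c("0" = 1))
  expect_true(all(sample_truths(cfg2)$seer == "3"))
})

test_that("empirical stage frequencies track the configured distribution", {
  cfg <- sim_config(n = 10000, seed = 8,
                    t_probs = c("1" = 0.25, "2" = 0.25, "3" = 0.25,
                                "4" = 0.25),
                    n_probs = c("0" = 1 / 3, "1" = 1 / 3, "2" = 1 / 3),
                    m_probs = c("0" = 0.5, "1" = 0.5))
  tr <- sample_truths(cfg)
  freq <- table(tr$t, tr$n, tr$m) / nrow(tr)
  expect_equal(length(freq), 24L)
  expect_true(all(abs(freq - 1 / 24) < 0.02))
})

test_that("report rendering is deterministic given a seed", {
  tr <- list(patient_id = "P1", t = "3", n = "1", m = "1")
  a <- render_report(tr, "pathology", "explicit", seed = 10)
  b <- render_report(tr, "pathology", "explicit", seed = 10)
  expect_identical(a, b)
  d <- render_report(tr, "imaging", "descriptive", seed = 10)
  expect_false(identical(a$text, d$text))
})

test_that("rendered staging sentences imply exactly the truth", {
  tr <- list(patient_id = "P1", t = "1", n = "0", m = "0")
  doc <- render_report(tr, "pathology", "descriptive", seed = 1)
  expect_match(tolower(doc$text), "submucosa")
  expect_match(tolower(doc$text), "no metastasis in \\d+ regional lymph")
  trm <- list(patient_id = "P1", t = "3", n = "2", m = "1")
  docm <- render_report(trm, "pathology", "descriptive", seed = 1)
  expect_match(tolower(docm$text), "metastatic \\w*\\s*adenocarcinoma")
})

test_that("distractor boilerplate matches no lexicon rule", {
  for (modality in c("pathology", "imaging")) {
    for (s in distractor_sentences(modality)) {
      ml <- raw_matches(s, modality, lex)
      expect_length(ml$rule_id, 0L)
    }
  }
})

test_that("masking and corruption touch only the stage columns", {
  base <- build_cohort(sim_config(n = 120, seed = 21, miss_tnm = 0,
                                  miss_seer = 0, err_tnm = 0,
                                  err_seer = 0))
  noisy <- build_cohort(sim_config(n = 120, seed = 21))
  stage_cols <- target_variables()
  for (col in setdiff(names(base$records), stage_cols)) {
    expect_equal(noisy$records[[col]], base$records[[col]], info = col)
  }
  ## clean cohort's stored stage equals truth
  expect_equal(base$records$`T stage`, base$truths$t)
  expect_equal(as.character(base$records$SEER), base$truths$seer)
  ## error flags corrupt, masks hide
  tr <- noisy$truths
  masked <- tr$mask_tnm
  expect_true(all(is.na(noisy$records$`T stage`[masked])))
  err <- !masked & tr$err_tnm
  stored <- noisy$records[!masked & tr$err_tnm, c("T stage", "N stage",
                                                  "M stage")]
  truthv <- tr[!masked & tr$err_tnm, c("t", "n", "m")]
  expect_true(all(rowSums(stored != truthv) >= 1))
})

test_that("cohort generation is fully reproducible from the config", {
  a <- build_cohort(sim_config(n = 80, seed = 33))
  b <- build_cohort(sim_config(n = 80, seed = 33))
  expect_identical(a$records, b$records)
  expect_identical(a$documents, b$documents)
  expect_identical(a$truths, b$truths)
  c2 <- build_cohort(sim_config(n = 80, seed = 34))
  expect_false(identical(a$documents$text, c2$documents$text))
})

test_that("full TNM masking and zero error rates behave as configured", {
  all_missing <- build_cohort(sim_config(n = 50, seed = 4, miss_tnm = 1))
  expect_true(all(is.na(all_missing$records$`T stage`)))
  expect_true(all(is.na(all_missing$records$TNM)))
  clean <- build_cohort(sim_config(n = 200, seed = 4, err_tnm = 0,
                                   err_seer = 0))
  rec <- clean$records; tr <- clean$truths
  nm <- !is.na(rec$TNM)
  audit <- concordance(paste0("T", tr$t, "N", tr$n, "M", tr$m)[nm],
                       rec$TNM[nm])
  expect_equal(audit$error_rate, 0.0)
})
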