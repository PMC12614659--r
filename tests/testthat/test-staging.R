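lex <- load_lexicon()

test_that("extract_tnm resolves report text to stage components", {
  a <- extract_tnm(paste("Invades pericolic adipose tissue.",
                         "No metastasis in 12 regional lymph nodes (0/12)."),
                   "pathology", lex)
  expect_equal(c(a$t, a$n, a$m), c("3", "0", "x"))
  expect_true(nrow(a$evidence) >= 2)
  expect_true(all(a$evidence$text != ""))

  b <- extract_tnm(paste("Metastasis in 4 of 16 regional lymph nodes.",
                         "Metastatic adenocarcinoma."), "pathology", lex)
  expect_equal(c(b$n, b$m), c("2", "1"))
  expect_equal(b$sub$n, "a")

  d <- extract_tnm(paste("rectal wall thickening, T3;",
                         "no significant enlarged peritumoral LN;",
                         "no evidence of distant metastasis"),
                   "imaging", lex)
  expect_equal(c(d$t, d$n, d$m), c("3", "0", "0"))

  e <- extract_tnm("", "pathology", lex)
  expect_equal(c(e$t, e$n, e$m), c("x", "x", "x"))
  expect_equal(nrow(e$evidence), 0L)

  expect_error(extract_tnm("text", "radiology", lex))
})

test_that("evidence spans quote the original text (0-based half-open)", {
  txt <- "Report:   Invades   subserosa. Margins clear."
  a <- extract_tnm(txt, "pathology", lex)
  ev <- a$evidence[a$evidence$component == "T", ]
  expect_equal(substr(txt, ev$start + 1L, ev$end), ev$text)
  expect_match(ev$text, "^Invades +subserosa$")
})

test_that("explicit stage-code tokens outrank descriptive phrases", {
  a <- extract_tnm("Invades subserosa (pT2)", "pathology", lex)
  expect_equal(a$t, "2")
  expect_equal(a$prefix, "p")
  b <- extract_tnm("Invades submucosa (ypT3)", "pathology", lex)
  expect_equal(b$t, "3")
  expect_equal(b$prefix, "yp")
})

test_that("node-count slots map onto N subcategories", {
  for (case in list(list(k = 1, n = "1", sub = "a"),
                    list(k = 2, n = "1", sub = "b"),
                    list(k = 3, n = "1", sub = "b"),
                    list(k = 4, n = "2", sub = "a"),
                    list(k = 11, n = "2", sub = "a"))) {
    a <- extract_tnm(sprintf(
      "Metastasis in %d of 21 regional lymph nodes.", case$k),
      "pathology", lex)
    expect_equal(a$n, case$n)
    expect_equal(a$sub$n, case$sub)
  }
})

test_that("extract_seer_direct returns direct pattern candidates", {
  expect_equal(extract_seer_direct("Invades subserosa", "pathology",
                                   lex)$codes, "2")
  expect_equal(extract_seer_direct("Tumor deposit", "pathology",
                                   lex)$codes, "3")
  expect_equal(extract_seer_direct("", "pathology", lex)$codes,
               character(0))
  both <- extract_seer_direct(
    "Invades subserosa. Tumor deposit present.", "pathology", lex)
  expect_setequal(both$codes, c("2", "3"))
})

test_that("derive_seer applies the summary-stage precedence", {
  tnm_x <- extract_tnm("", "imaging", lex)
  expect_equal(derive_seer(list(codes = c("2", "3")), tnm_x,
                           "pathology")$code, "4")
  expect_equal(derive_seer(list(codes = c("2", "3")), tnm_x,
                           "pathology")$derivation, "combination_2_3")
  tnm_m1 <- tnm_x; tnm_m1$m <- "1"
  s <- derive_seer(list(codes = character(0)), tnm_m1, "imaging")
  expect_equal(s$code, "7")
  expect_equal(s$derivation, "from_M")
  s9 <- derive_seer(list(codes = character(0)), tnm_x, "pathology")
  expect_equal(s9$code, "9")
  expect_equal(s9$derivation, "no_evidence")
  expect_equal(derive_seer(list(codes = "1"), tnm_x, "pathology")$code, "1")
  expect_equal(derive_seer(list(codes = character(0)), tnm_x, "pathology",
                           document_present = FALSE)$code, "missing")
})

test_that("derive_seer agrees with the brute-force precedence oracle", {
  codes_all <- c("0", "1", "2", "3", "7")
  subsets <- lapply(0:(2^5 - 1), function(b) {
    codes_all[bitwAnd(b, 2^(0:4)) > 0]
  })
  tnm_base <- extract_tnm("", "imaging", lex)
  for (src in c("pathology", "imaging")) {
    for (nn in c("x", "0", "1", "2")) {
      for (mm in c("x", "0", "1")) {
        tnm <- tnm_base; tnm$n <- nn; tnm$m <- mm
        for (cs in subsets) {
          got <- derive_seer(list(codes = cs), tnm, src)$code
          want <- seer_oracle(cs, nn, mm, src)
          expect_identical(got, want,
                           info = sprintf("%s n=%s m=%s {%s}", src, nn, mm,
                                          paste(cs, collapse = ",")))
        }
      }
    }
  }
})

test_that("merge prefers pathology, fills from imaging, enforces M=>7", {
  p <- fake_modal(t = "3", n = "1", m = "x", seer = "4",
                  deriv = "combination_2_3")
  i <- fake_modal(t = "3", n = "x", m = "0", seer = "3", deriv = "from_N")
  m <- merge_assignments(p, i)
  expect_equal(c(m$t, m$n, m$m), c("3", "1", "0"))
  expect_equal(m$provenance$m, "imaging")
  expect_equal(m$seer_code, "4")

  m2 <- merge_assignments(NULL, fake_modal(t = "2", n = "0", m = "0",
                                           seer = "1",
                                           deriv = "direct_pattern"))
  expect_equal(c(m2$t, m2$n, m2$m), c("2", "0", "0"))
  expect_equal(m2$provenance$t, "imaging")
  expect_equal(m2$seer_code, "1")

  ## distant disease dominates a localized imaging code
  m3 <- merge_assignments(fake_modal(m = "1", seer = "7", deriv = "from_M"),
                          fake_modal(t = "1", n = "0", m = "0", seer = "1",
                                     deriv = "direct_pattern"))
  expect_equal(m3$seer_code, "7")
  expect_error(merge_assignments(NULL, NULL))
})

test_that("merged SEER matches the precedence oracle over all code pairs", {
  codes <- c("0", "1", "2", "3", "4", "7", "9")
  for (pc in codes) {
    for (ic in codes) {
      for (mm in c("x", "0", "1")) {
        p <- fake_modal(m = mm, seer = pc)
        i <- fake_modal(seer = ic)
        got <- merge_assignments(p, i)$seer_code
        want <- merge_seer_oracle(pc, ic, mm)
        expect_identical(got, want,
                         info = sprintf("path=%s img=%s m=%s", pc, ic, mm))
      }
    }
  }
})

test_that("format_tnm_string renders undetermined components as x", {
  expect_equal(format_tnm_string(list(t = "4", n = "2", m = "1")), "T4N2M1")
  expect_equal(format_tnm_string(list(t = "x", n = "2", m = "0")), "TxN2M0")
  expect_equal(format_tnm_string(list(t = "x", n = "x", m = "x")), "TxNxMx")
  expect_equal(format_tnm_string(list(t = "is", n = "0", m = "0")),
               "TisN0M0")
})

test_that("extraction is deterministic and monotone under added evidence", {
  txt <- "Invades submucosa. No metastasis in 15 regional lymph nodes."
  a1 <- extract_tnm(txt, "pathology", lex)
  a2 <- extract_tnm(txt, "pathology", lex)
  expect_identical(a1, a2)
  ## appending a higher-stage sentence never lowers any component
  rank_of <- function(v, comp) crcqmp:::stage_rank(v, comp)
  additions <- c("Invades subserosa.",
                 "Metastasis in 5 of 15 regional lymph nodes.",
                 "Metastatic adenocarcinoma.")
  for (add in additions) {
    b <- extract_tnm(paste(txt, add), "pathology", lex)
    expect_gte(rank_of(b$t, "T"), rank_of(a1$t, "T"))
    expect_gte(rank_of(b$n, "N"), rank_of(a1$n, "N"))
    expect_gte(rank_of(b$m, "M"), rank_of(a1$m, "M"))
  }
})

test_that("stage_cohort pools multiple documents per modality", {
  docs <- data.frame(
    patient_id = c("A", "A", "A", "B"),
    modality = c("pathology", "pathology", "imaging", "imaging"),
    text = c("Invades submucosa.",
             "Metastasis in 2 of 18 regional lymph nodes.",
             "No evidence of distant metastasis.",
             "Pericolic fat infiltration, T3; liver metastases"),
    stringsAsFactors = FALSE)
  out <- stage_cohort(docs, lex)
  expect_setequal(names(out), c("A", "B"))
  a <- out[["A"]]
  ## worst extent across pathology documents, M filled from imaging
  expect_equal(c(a$t, a$n, a$m), c("1", "1", "0"))
  expect_equal(a$seer_code, "3")
  b <- out[["B"]]
  expect_equal(c(b$t, b$m), c("3", "1"))
  expect_equal(b$seer_code, "7")
})
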