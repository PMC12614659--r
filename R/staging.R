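## The staging engine: apply the compiled lexicon to report text to produce
## TNM and SEER summary-stage assignments, including the derivation and
## combination rules (codes 2+3 -> 4, N >= 1 -> 3, M = 1 -> 7, no evidence
## -> 9) and pathology-over-imaging merging.

new_tnm_assignment <- function(t = "x", n = "x", m = "x",
                               sub = list(t = NA_character_,
                                          n = NA_character_,
                                          m = NA_character_),
                               prefix = "none", source = "merged",
                               evidence = NULL) {
  if (is.null(evidence)) evidence <- evidence_frame(NULL, integer(0))
  structure(list(t = t, n = n, m = m, sub = sub, prefix = prefix,
                 source = source, evidence = evidence),
            class = "tnm_assignment")
}

## Resolve one component from match indices `idx` into the match set `ml`:
## explicit codes outrank descriptive/negative phrases; within equal kind
## the highest stage value wins (registry convention: worst documented
## extent).
resolve_component <- function(ml, idx, component) {
  cand <- idx[ml$component[idx] == component]
  if (length(cand) == 0L) {
    return(list(value = "x", subcategory = NA_character_, prefix = "none",
                win = cand))
  }
  explicit <- cand[ml$kind[cand] == "explicit_code"]
  if (length(explicit) > 0L) cand <- explicit
  win_val <- max_stage(unique(ml$value[cand]), component)
  win <- cand[ml$value[cand] == win_val]
  sub <- NA_character_
  prefix <- "none"
  for (j in win) {
    if (ml$kind[j] == "explicit_code") {
      tok <- parse_explicit_token(ml$token[j])
      if (prefix == "none") prefix <- tok$prefix
      if (is.na(sub) && !is.na(tok$subcategory)) sub <- tok$subcategory
    } else if (is.na(sub) && !is.na(ml$subcategory[j])) {
      sub <- ml$subcategory[j]
    }
  }
  list(value = win_val, subcategory = sub, prefix = prefix, win = win)
}

resolve_tnm <- function(ml, idx, source, ev_fn) {
  rT <- resolve_component(ml, idx, "T")
  rN <- resolve_component(ml, idx, "N")
  rM <- resolve_component(ml, idx, "M")
  prefix <- "none"
  for (r in list(rT, rN, rM)) {
    if (r$prefix != "none") { prefix <- r$prefix; break }
  }
  new_tnm_assignment(
    t = rT$value, n = rN$value, m = rM$value,
    sub = list(t = rT$subcategory, n = rN$subcategory, m = rM$subcategory),
    prefix = prefix, source = source,
    evidence = ev_fn(c(rT$win, rN$win, rM$win))
  )
}

#' Extract a TNM assignment from one report
#'
#' Matches the lexicon's T, N and M rules for the given modality against the
#' report text. Each component is resolved by (1) collecting all matching
#' rules, (2) letting explicit stage-code tokens (e.g. `"(ypT3)"`) outrank
#' descriptive phrases, and (3) taking the highest stage value within the
#' winning kind; a component with no match is `"x"` (not determined). The
#' prefix (`p`, `yp`, `c`) is captured from explicit tokens.
#'
#' @param text report text (a single string).
#' @param source `"pathology"` or `"imaging"`.
#' @param lexicon a compiled lexicon from [load_lexicon()].
#' @return a `tnm_assignment`: list with components `t`, `n`, `m` (character
#'   codes, `"x"` = not determined), `sub` (per-component subcategory a/b/c
#'   or `NA`), `prefix`, `source`, and an `evidence` data frame of matched
#'   rules with 0-based half-open character offsets into the original text.
#' @examples
#' lex <- load_lexicon()
#' extract_tnm(
#'   "Invades pericolic adipose tissue. No metastasis in 12 regional lymph nodes (0/12).",
#'   "pathology", lex)
#' @export
extract_tnm <- function(text, source, lexicon) {
  source <- match.arg(source, .sources)
  stopifnot(inherits(lexicon, "crc_lexicon"))
  docs <- data.frame(modality = source, text = text,
                     stringsAsFactors = FALSE)
  pool <- build_sentence_pool(docs, lexicon)
  ml <- match_pool(pool, lexicon)
  idx <- which(ml$component != "SEER")
  resolve_tnm(ml, idx, source, function(win) {
    evidence_frame(ml, win, pool$norms[[1L]], text)
  })
}

#' Extract direct SEER summary-stage candidates from one report
#'
#' Returns every SEER code for which a lexicon pattern of the given modality
#' matches the text directly (codes 0, 1, 2, 3, 7). Codes 4 (regional by
#' both direct extension and nodes), 3-from-N, 7-from-M and 9 (no evidence)
#' are derivation-time rules applied by [derive_seer()].
#'
#' @inheritParams extract_tnm
#' @return list with `codes` (character vector, sorted unique) and
#'   `evidence` (data frame as in [extract_tnm()]).
#' @examples
#' lex <- load_lexicon()
#' extract_seer_direct("Invades subserosa", "pathology", lex)$codes
#' @export
extract_seer_direct <- function(text, source, lexicon) {
  source <- match.arg(source, .sources)
  stopifnot(inherits(lexicon, "crc_lexicon"))
  docs <- data.frame(modality = source, text = text,
                     stringsAsFactors = FALSE)
  pool <- build_sentence_pool(docs, lexicon)
  ml <- match_pool(pool, lexicon)
  idx <- which(ml$component == "SEER")
  list(codes = sort(unique(ml$value[idx])),
       evidence = evidence_frame(ml, idx, pool$norms[[1L]], text))
}

#' Derive the SEER summary stage from candidates and TNM
#'
#' Applies the summary-stage precedence: code 7 if the M code is 1 (or a
#' distant-site pattern matched directly); code 4 if both a code-2 (regional
#' by direct extension) and a code-3 (regional nodes) candidate hold; code 3
#' from a direct pattern or, for imaging, when the N code is 1 or higher;
#' then codes 2, 1, 0 from direct patterns; code 9 (unknown) when a document
#' was searched but yielded no stage evidence; `"missing"` only when no
#' document exists.
#'
#' @param direct a candidate set from [extract_seer_direct()] (or a
#'   character vector of codes).
#' @param tnm a `tnm_assignment` for the same document/patient.
#' @param source `"pathology"` or `"imaging"`.
#' @param document_present `FALSE` when no report exists for this patient
#'   (yields code `"missing"` rather than 9).
#' @return a `seer_assignment`: list with `code` (character), `derivation`
#'   (`direct_pattern`, `combination_2_3`, `from_N`, `from_M`,
#'   `no_evidence`, or `missing`), and `evidence`.
#' @examples
#' lex <- load_lexicon()
#' tnm <- extract_tnm("", "imaging", lex)
#' derive_seer(list(codes = c("2", "3")), tnm, "pathology")$code  # "4"
#' @export
derive_seer <- function(direct, tnm, source, document_present = TRUE) {
  source <- match.arg(source, .sources)
  codes <- if (is.list(direct)) direct$codes else direct
  evidence <- if (is.list(direct) && !is.null(direct$evidence)) {
    direct$evidence
  } else {
    evidence_frame(NULL, integer(0))
  }
  mk <- function(code, derivation) {
    structure(list(code = code, derivation = derivation, evidence = evidence),
              class = "seer_assignment")
  }
  if (!document_present) return(mk("missing", "missing"))
  if (identical(tnm$m, "1") || "7" %in% codes) {
    return(mk("7", if ("7" %in% codes) "direct_pattern" else "from_M"))
  }
  n_high <- tnm$n %in% c("1", "2")
  cand3 <- "3" %in% codes || (source == "imaging" && n_high)
  cand2 <- "2" %in% codes
  if (cand2 && cand3) return(mk("4", "combination_2_3"))
  if (cand3) {
    return(mk("3", if ("3" %in% codes) "direct_pattern" else "from_N"))
  }
  if (cand2) return(mk("2", "direct_pattern"))
  if ("1" %in% codes) return(mk("1", "direct_pattern"))
  if ("0" %in% codes) return(mk("0", "direct_pattern"))
  mk("9", "no_evidence")
}

#' Merge pathology and imaging assignments for one patient
#'
#' Component-wise: the pathology value is used when determined, otherwise
#' the imaging value (pathological staging is the clinical gold standard).
#' The SEER code is merged the same way, except that a definite imaging code
#' outranks a pathology code 9 (a statement of ignorance, not extent); the
#' merged result is then re-checked against the distant-disease rule (merged
#' M = 1 forces SEER 7).
#'
#' @param pathology,imaging each `NULL` (no document of that modality) or a
#'   list with elements `tnm` (a `tnm_assignment`) and `seer` (a
#'   `seer_assignment`).
#' @return a `patient_assignment`: merged `t`, `n`, `m`, `sub`, `prefix`,
#'   `seer_code`, `seer_derivation`, per-component `provenance`, and the
#'   combined `evidence`.
#' @export
merge_assignments <- function(pathology = NULL, imaging = NULL) {
  if (is.null(pathology) && is.null(imaging)) {
    stop("at least one of 'pathology' and 'imaging' must be supplied")
  }
  get_tnm <- function(x) if (is.null(x)) new_tnm_assignment() else x$tnm
  get_seer <- function(x) {
    if (is.null(x) || is.null(x$seer)) {
      structure(list(code = "missing", derivation = "missing",
                     evidence = NULL), class = "seer_assignment")
    } else {
      x$seer
    }
  }
  pt <- get_tnm(pathology); it <- get_tnm(imaging)
  ps <- get_seer(pathology); is_ <- get_seer(imaging)

  pick_comp <- function(comp) {
    pv <- pt[[comp]]; iv <- it[[comp]]
    if (!identical(pv, "x")) {
      list(value = pv, sub = pt$sub[[comp]], from = "pathology")
    } else if (!identical(iv, "x")) {
      list(value = iv, sub = it$sub[[comp]], from = "imaging")
    } else {
      list(value = "x", sub = NA_character_, from = NA_character_)
    }
  }
  t_ <- pick_comp("t"); n_ <- pick_comp("n"); m_ <- pick_comp("m")

  definite <- function(s) !s$code %in% c("9", "missing")
  if (definite(ps)) {
    seer <- ps; seer_from <- "pathology"
  } else if (definite(is_)) {
    seer <- is_; seer_from <- "imaging"
  } else if (ps$code == "9" || is_$code == "9") {
    seer <- if (ps$code == "9") ps else is_
    seer_from <- if (ps$code == "9") "pathology" else "imaging"
  } else {
    seer <- ps; seer_from <- NA_character_
  }
  seer_code <- seer$code
  seer_deriv <- seer$derivation
  if (identical(m_$value, "1") && seer_code != "7") {
    seer_code <- "7"
    seer_deriv <- "from_M"
  }
  prefix <- if (pt$prefix != "none") pt$prefix else it$prefix
  evidence <- rbind(pt$evidence, it$evidence)
  structure(list(
    t = t_$value, n = n_$value, m = m_$value,
    sub = list(t = t_$sub, n = n_$sub, m = m_$sub),
    prefix = prefix,
    seer_code = seer_code, seer_derivation = seer_deriv,
    provenance = list(t = t_$from, n = n_$from, m = m_$from,
                      seer = seer_from),
    evidence = evidence
  ), class = "patient_assignment")
}

#' Format a combined TNM stage string
#'
#' Renders `"T{t}N{n}M{m}"` with `"x"` for undetermined components and
#' `"is"` rendered as `"Tis"` (e.g. `"T4N2M1"`, `"TxN2M0"`).
#'
#' @param tnm a `tnm_assignment` or `patient_assignment` (anything with
#'   `t`, `n`, `m` elements).
#' @return a single string.
#' @examples
#' format_tnm_string(list(t = "4", n = "2", m = "1"))  # "T4N2M1"
#' @export
format_tnm_string <- function(tnm) {
  paste0("T", tnm$t, "N", tnm$n, "M", tnm$m)
}

## ---- patient/cohort level staging -------------------------------------

## Combine several per-document TNM assignments of one modality:
## component-wise worst documented extent across documents.
combine_modality_tnm <- function(assignments, source) {
  if (length(assignments) == 0L) return(NULL)
  if (length(assignments) == 1L) {
    out <- assignments[[1L]]
    out$source <- source
    return(out)
  }
  out <- new_tnm_assignment(source = source)
  for (comp in c("t", "n", "m")) {
    vals <- vapply(assignments, function(a) a[[comp]], character(1))
    win <- max_stage(vals[vals != "x"], toupper(comp))
    out[[comp]] <- win
    if (win != "x") {
      first <- which(vals == win)[1L]
      out$sub[[comp]] <- assignments[[first]]$sub[[comp]]
    }
  }
  pref <- vapply(assignments, function(a) a$prefix, character(1))
  out$prefix <- if (any(pref != "none")) pref[pref != "none"][1L] else "none"
  out$evidence <- unique(do.call(rbind,
                                 lapply(assignments, `[[`, "evidence")))
  out
}

## Stage one patient from its documents (possibly several per modality).
## docs: data.frame(modality, text). Returns a patient_assignment, or NULL
## when docs is empty.
stage_patient <- function(docs, lexicon) {
  if (nrow(docs) == 0L) return(NULL)
  out <- stage_cohort(
    data.frame(patient_id = "patient", modality = docs$modality,
               text = docs$text, stringsAsFactors = FALSE),
    lexicon, evidence = "full")
  out[["patient"]]
}

#' Stage every patient in a document collection
#'
#' Cohort-scale version of the per-report extraction: normalizes and matches
#' all documents in one vectorized pass, resolves each document, pools
#' documents per patient and modality (worst documented extent, with SEER
#' candidates pooled across documents before derivation), and merges
#' modalities. Used by [qmp_impute()].
#'
#' @param documents data frame with columns `patient_id`, `modality`
#'   (`"pathology"`/`"imaging"`) and `text`.
#' @param lexicon a compiled lexicon from [load_lexicon()].
#' @param evidence `"ids"` (default; evidence rows carry rule ids only —
#'   the fast path for imputation, whose change log needs nothing more) or
#'   `"full"` (evidence also quotes the original text with 0-based
#'   half-open character offsets).
#' @return a named list (by `patient_id`) of `patient_assignment` objects;
#'   patients absent from `documents` are absent from the list.
#' @export
stage_cohort <- function(documents, lexicon, evidence = c("ids", "full")) {
  evidence <- match.arg(evidence)
  stopifnot(all(c("patient_id", "modality", "text") %in% names(documents)))
  if (nrow(documents) == 0L) return(structure(list(), names = character(0)))
  pool <- build_sentence_pool(documents, lexicon)
  ml <- match_pool(pool, lexicon)
  is_seer <- ml$component == "SEER"
  by_doc <- split(seq_along(ml$doc),
                  factor(ml$doc, levels = seq_len(nrow(documents))))

  doc_tnm <- vector("list", nrow(documents))
  doc_seer_codes <- vector("list", nrow(documents))
  doc_seer_idx <- vector("list", nrow(documents))
  for (d in seq_len(nrow(documents))) {
    idx <- by_doc[[d]]
    ev_fn <- if (evidence == "full") {
      function(win) evidence_frame(ml, win, pool$norms[[d]],
                                   documents$text[d])
    } else {
      function(win) evidence_frame(ml, win)
    }
    doc_tnm[[d]] <- resolve_tnm(ml, idx[!is_seer[idx]],
                                documents$modality[d], ev_fn)
    sidx <- idx[is_seer[idx]]
    doc_seer_codes[[d]] <- unique(ml$value[sidx])
    doc_seer_idx[[d]] <- if (evidence == "full") {
      evidence_frame(ml, sidx, pool$norms[[d]], documents$text[d])
    } else {
      evidence_frame(ml, sidx)
    }
  }

  out <- list()
  idx_by_patient <- split(seq_len(nrow(documents)),
                          factor(documents$patient_id,
                                 levels = unique(documents$patient_id)))
  for (pid in names(idx_by_patient)) {
    idx <- idx_by_patient[[pid]]
    per_mod <- function(src) {
      dd <- idx[documents$modality[idx] == src]
      if (length(dd) == 0L) return(NULL)
      tnm <- combine_modality_tnm(doc_tnm[dd], src)
      codes <- sort(unique(unlist(doc_seer_codes[dd])))
      ev <- unique(do.call(rbind, doc_seer_idx[dd]))
      seer <- derive_seer(list(codes = codes, evidence = ev), tnm, src,
                          document_present = TRUE)
      list(tnm = tnm, seer = seer)
    }
    out[[pid]] <- merge_assignments(pathology = per_mod("pathology"),
                                    imaging = per_mod("imaging"))
  }
  out
}

#' @export
print.tnm_assignment <- function(x, ...) {
  cat(sprintf("TNM assignment (%s): %s", x$source, format_tnm_string(x)))
  if (x$prefix != "none") cat(sprintf("  [prefix %s]", x$prefix))
  cat(sprintf("  (%d evidence span%s)\n", nrow(x$evidence),
              if (nrow(x$evidence) == 1L) "" else "s"))
  invisible(x)
}

#' @export
print.seer_assignment <- function(x, ...) {
  cat(sprintf("SEER summary stage: %s (derivation: %s)\n",
              x$code, x$derivation))
  invisible(x)
}

#' @export
print.patient_assignment <- function(x, ...) {
  cat(sprintf("Patient staging: %s, SEER %s (%s)\n",
              format_tnm_string(x), x$seer_code, x$seer_derivation))
  invisible(x)
}
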