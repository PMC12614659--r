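## Vectorized rule matching over sentence pools.
##
## The staging engine normalizes each report, splits it into sentences, and
## then applies every compiled pattern of the matching modality across the
## whole sentence pool in one vectorized regex call per pattern. This keeps
## cohort-scale imputation (thousands of reports) fast.

## Build the sentence pool for a set of documents.
## docs: data.frame(modality, text). Returns list(sentences, norms):
## sentences is a list of parallel vectors (text, start, doc, modality, and
## one logical req_<group> flag per co-occurrence group); norms is the list
## of normalization states indexed like docs rows.
build_sentence_pool <- function(docs, lexicon) {
  nd <- nrow(docs)
  norms <- vector("list", nd)
  texts <- vector("list", nd)
  starts <- vector("list", nd)
  doc_of <- vector("list", nd)
  for (i in seq_len(nd)) {
    nm <- normalize_one(docs$text[i], lexicon)
    norms[[i]] <- nm
    sen <- split_sentences(nm$text)
    if (length(sen$text) == 0L) next
    texts[[i]] <- sen$text
    starts[[i]] <- sen$start
    doc_of[[i]] <- rep.int(i, length(sen$text))
  }
  sentences <- list(
    text = unlist(texts, use.names = FALSE) %||% character(0),
    start = unlist(starts, use.names = FALSE) %||% integer(0),
    doc = unlist(doc_of, use.names = FALSE) %||% integer(0)
  )
  sentences$modality <- docs$modality[sentences$doc]
  for (g in names(lexicon$require_groups)) {
    terms <- tolower(lexicon$require_groups[[g]])
    rx <- paste0("\\b(?:", paste(escape_regex(terms), collapse = "|"),
                 ")\\b")
    sentences[[paste0("req_", g)]] <-
      grepl(rx, sentences$text, perl = TRUE)
  }
  list(sentences = sentences, norms = norms)
}

empty_match_set <- function() {
  list(doc = integer(0), rule_id = character(0), component = character(0),
       value = character(0), subcategory = character(0),
       kind = character(0), sent = integer(0), start = integer(0),
       end = integer(0), count = integer(0), token = character(0))
}

## Match every lexicon pattern against the sentence pool.
## Returns a list of parallel vectors (see empty_match_set) with start/end
## in normalized document coordinates (1-based inclusive).
match_pool <- function(pool, lexicon) {
  sen <- pool$sentences
  if (length(sen$text) == 0L) return(empty_match_set())
  pat <- lexicon$patterns
  acc <- lapply(empty_match_set(), function(x) list())
  k <- 0L
  for (i in seq_len(nrow(pat))) {
    idx <- which(sen$modality == pat$source[i])
    if (!is.na(pat$requires[i])) {
      idx <- idx[sen[[paste0("req_", pat$requires[i])]][idx]]
    }
    if (length(idx) == 0L) next
    m <- regexpr(pat$regex[i], sen$text[idx], perl = TRUE)
    hit <- which(m > 0L)
    if (length(hit) == 0L) next
    counts <- rep(NA_integer_, length(hit))
    if (pat$has_count[i]) {
      cs <- attr(m, "capture.start")[hit, 1L]
      cl <- attr(m, "capture.length")[hit, 1L]
      counts <- as.integer(substr(sen$text[idx][hit], cs, cs + cl - 1L))
      keep <- rep(TRUE, length(hit))
      if (!is.na(pat$count_min[i])) keep <- keep & counts >= pat$count_min[i]
      if (!is.na(pat$count_max[i])) keep <- keep & counts <= pat$count_max[i]
      hit <- hit[keep]; counts <- counts[keep]
      if (length(hit) == 0L) next
    }
    st <- as.integer(m[hit])
    len <- attr(m, "match.length")[hit]
    rows <- idx[hit]
    k <- k + 1L
    acc$doc[[k]] <- sen$doc[rows]
    acc$rule_id[[k]] <- rep.int(pat$rule_id[i], length(rows))
    acc$component[[k]] <- rep.int(pat$component[i], length(rows))
    acc$value[[k]] <- rep.int(pat$value[i], length(rows))
    acc$subcategory[[k]] <- rep.int(pat$subcategory[i], length(rows))
    acc$kind[[k]] <- rep.int(pat$kind[i], length(rows))
    acc$sent[[k]] <- rows
    acc$start[[k]] <- sen$start[rows] + st - 1L
    acc$end[[k]] <- sen$start[rows] + st + len - 2L
    acc$count[[k]] <- counts
    acc$token[[k]] <- substr(sen$text[rows], st, st + len - 1L)
  }
  if (k == 0L) return(empty_match_set())
  lapply(acc, function(col) unlist(col, use.names = FALSE))
}

## Parse prefix (p / yp / c) and subcategory (a/b/c) out of an explicit
## stage-code token like "(ypt3)" or "t4a".
parse_explicit_token <- function(token) {
  m <- regmatches(token, regexec(.explicit_token_re, token, perl = TRUE))[[1]]
  if (length(m) == 0L) {
    return(list(prefix = "none", subcategory = NA_character_))
  }
  prefix <- m[2]
  if (prefix == "") prefix <- "none"
  if (prefix == "y") prefix <- "yp"  # "(yN0)" shorthand for post-therapy
  sub <- m[5]
  if (is.na(sub) || sub == "") sub <- NA_character_
  list(prefix = prefix, subcategory = sub)
}

## Build an evidence data frame from match indices. When `norm` and
## `original` are supplied, spans are converted to 0-based half-open
## offsets in the original text and the original slice is quoted;
## otherwise only rule/component/value are recorded (fast path used for
## cohort-scale imputation, whose change log needs rule ids only).
evidence_frame <- function(ml, idx, norm = NULL, original = NULL) {
  if (length(idx) == 0L) {
    return(data.frame(rule_id = character(0), component = character(0),
                      value = character(0), text = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(norm)) {
    txt <- rep(NA_character_, length(idx))
    s0 <- rep(NA_integer_, length(idx))
    e0 <- rep(NA_integer_, length(idx))
  } else {
    s0 <- norm$o_start[ml$start[idx]] - 1L      # 0-based
    e0 <- norm$o_end[ml$end[idx]]               # half-open
    txt <- substring(original, s0 + 1L, e0)
  }
  out <- data.frame(
    rule_id = ml$rule_id[idx], component = ml$component[idx],
    value = ml$value[idx], text = txt, start = s0, end = e0,
    stringsAsFactors = FALSE
  )
  unique(out)
}
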