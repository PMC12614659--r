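## Staging label lexicon: loading, validation, compilation.
##
## The lexicon is a human-editable YAML file of labeling rules. Each rule
## binds a set of phrase patterns to one stage component (T, N, M or SEER
## summary stage), a value, and a source modality (pathology or imaging).
## The shipped default, `tables_3_4.lexicon`, encodes the TNM labeling of
## the Korean clinical guideline for colorectal cancer and the SEER Summary
## Stage 2018 labeling for both report modalities.

.components <- c("T", "N", "M", "SEER")
.kinds <- c("explicit_code", "descriptive", "negative_evidence")
.sources <- c("pathology", "imaging")

.value_vocab <- list(
  T = c("0", "is", "1", "2", "3", "4"),
  N = c("0", "1", "2"),
  M = c("0", "1"),
  SEER = .seer_pattern_levels
)

## Regex for an explicit stage-code token, e.g. "(pT3)", "(ypN1a)", "T4a",
## "Tis", "N0" (imaging tokens are printed without parentheses).
.explicit_token_re <- "^\\(?(yp|p|c|y)?([tnm])(is|[0-9])([abc])?\\)?$"

escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

## Compile one pattern of the mini-language to a PCRE regex.
## "~"       -> gap of up to gap_max whitespace-separated tokens
## "<count>" -> captured integer slot
pattern_to_regex <- function(pattern, gap_max = 5L) {
  p <- gsub("<count>", "\x01", pattern, fixed = TRUE)
  p <- gsub("~", "\x02", p, fixed = TRUE)
  p <- escape_regex(p)
  p <- gsub("\x01", "(\\\\d+)", p)
  gap <- sprintf("(?:\\\\S+ ){0,%d}", gap_max)
  p <- gsub(" \x02 ", paste0(" ", gap), p)
  p <- gsub("\x02", gap, p)  # defensive: gap at pattern edge
  if (grepl("^[a-z0-9]", p)) p <- paste0("\\b", p)
  if (grepl("[a-z0-9]$", p)) p <- paste0(p, "\\b")
  p
}

#' Load and compile a staging label lexicon
#'
#' Reads a lexicon file (YAML), validates it, and compiles every pattern to
#' a matcher-ready regular expression. With no argument the default shipped
#' lexicon is loaded, which encodes the TNM stage labeling of the Korean
#' clinical guideline for colorectal cancer and the SEER Summary Stage 2018
#' labeling, for pathology and imaging report dialects.
#'
#' Validation enforces: at least one rule; at least one nonempty pattern per
#' rule; unique rule ids; components in `T/N/M/SEER`; values within each
#' component's vocabulary (`T`: 0, is, 1–4; `N`: 0–2; `M`: 0/1; `SEER`:
#' 0,1,2,3,7,9); sources in `pathology/imaging`; `explicit_code` patterns
#' must be stage-code tokens such as `"(pT3)"` or `"T4a"`.
#'
#' @param path path to a lexicon file; defaults to the shipped
#'   `tables_3_4.lexicon`.
#' @return an object of class `crc_lexicon`: a list with `patterns` (one row
#'   per compiled pattern), `rules` (one row per rule), `synonyms`,
#'   `require_groups`, `normalization`, and `source_spec` (the parsed file,
#'   kept for round-trip serialization via [write_lexicon()]).
#' @examples
#' lex <- load_lexicon()
#' subset(lex$patterns, component == "T" & value == "1")$pattern
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tables_3_4.lexicon", package = "crcqmp")
  }
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  spec <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("failed to parse lexicon file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  compile_lexicon(spec, path)
}

compile_lexicon <- function(spec, path = "<in-memory>") {
  fail <- function(...) stop("invalid lexicon (", path, "): ", ...,
                             call. = FALSE)
  rules <- spec$rules
  if (is.null(rules) || length(rules) == 0L) fail("no rules")

  gap_max <- as.integer(spec$normalization$gap_max_tokens %||% 5L)

  ## synonyms
  syn_list <- spec$synonyms %||% list()
  synonyms <- do.call(rbind, lapply(syn_list, function(s) {
    if (is.null(s$canonical) || length(s$variants) == 0L) {
      fail("synonym group needs 'canonical' and nonempty 'variants'")
    }
    v <- tolower(unlist(s$variants))
    if (tolower(s$canonical) %in% v) fail("canonical must not be a variant: ",
                                          s$canonical)
    data.frame(canonical = tolower(s$canonical), variant = v,
               stringsAsFactors = FALSE)
  }))
  if (is.null(synonyms)) {
    synonyms <- data.frame(canonical = character(0), variant = character(0),
                           stringsAsFactors = FALSE)
  }
  ## longest variants first so "l/ns" wins over "l/n"
  synonyms <- synonyms[order(-nchar(synonyms$variant)), , drop = FALSE]
  synonyms$regex <- paste0("\\b", escape_regex(synonyms$variant), "\\b")

  req_groups <- spec$require_groups %||% list()

  rule_rows <- list()
  pat_rows <- list()
  for (r in rules) {
    for (f in c("id", "component", "value", "source", "kind")) {
      if (is.null(r[[f]])) fail("rule missing field '", f, "'")
    }
    comp <- as.character(r$component)
    if (!comp %in% .components) fail("unknown component '", comp,
                                     "' in rule ", r$id)
    val <- as.character(r$value)
    if (!val %in% .value_vocab[[comp]]) {
      fail("value '", val, "' out of vocabulary for component ", comp,
           " in rule ", r$id)
    }
    if (!r$source %in% .sources) fail("unknown source '", r$source,
                                      "' in rule ", r$id)
    if (!r$kind %in% .kinds) fail("unknown kind '", r$kind,
                                  "' in rule ", r$id)
    pats <- unlist(r$patterns)
    if (length(pats) == 0L || any(!nzchar(trimws(pats)))) {
      fail("rule ", r$id, " has no nonempty pattern")
    }
    if (!is.null(r$requires) && !r$requires %in% names(req_groups)) {
      fail("rule ", r$id, " requires unknown group '", r$requires, "'")
    }
    rule_rows[[length(rule_rows) + 1L]] <- data.frame(
      rule_id = as.character(r$id), component = comp, value = val,
      subcategory = as.character(r$subcategory %||% NA_character_),
      source = r$source, kind = r$kind,
      requires = as.character(r$requires %||% NA_character_),
      count_min = as.integer(r$count_min %||% NA_integer_),
      count_max = as.integer(r$count_max %||% NA_integer_),
      priority = as.integer(r$priority %||% 1L),
      stringsAsFactors = FALSE
    )
    for (p in pats) {
      ## patterns are normalized exactly like report text
      pn <- tolower(trimws(gsub("[[:space:]]+", " ", p)))
      if (r$kind == "explicit_code" &&
          !grepl(.explicit_token_re, pn, perl = TRUE)) {
        fail("explicit_code pattern '", p, "' in rule ", r$id,
             " is not a stage-code token")
      }
      pat_rows[[length(pat_rows) + 1L]] <- data.frame(
        rule_id = as.character(r$id), pattern = pn,
        regex = pattern_to_regex(pn, gap_max),
        has_count = grepl("<count>", pn, fixed = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  rules_df <- do.call(rbind, rule_rows)
  if (anyDuplicated(rules_df$rule_id)) {
    fail("duplicate rule_id: ",
         paste(unique(rules_df$rule_id[duplicated(rules_df$rule_id)]),
               collapse = ", "))
  }
  patterns <- merge(do.call(rbind, pat_rows), rules_df, by = "rule_id",
                    sort = FALSE)
  lex <- structure(list(
    rules = rules_df, patterns = patterns, synonyms = synonyms,
    require_groups = req_groups,
    normalization = list(gap_max_tokens = gap_max),
    source_spec = spec
  ), class = "crc_lexicon")
  ## pattern matching on normalized text: re-normalize patterns with the
  ## full synonym table (so e.g. a pattern written "lymph nodes" still
  ## compiles to the canonical "lymph node")
  renorm <- vapply(lex$patterns$pattern, function(p) {
    normalize_text(p, lex)$text
  }, character(1))
  changed <- renorm != lex$patterns$pattern
  if (any(changed)) {
    lex$patterns$pattern[changed] <- renorm[changed]
    lex$patterns$regex[changed] <-
      vapply(renorm[changed], pattern_to_regex, character(1), gap_max = gap_max)
  }
  lex
}

#' Serialize a compiled lexicon back to its file format
#'
#' Writes the lexicon as YAML such that reloading with [load_lexicon()]
#' yields rule-for-rule equality with the original.
#'
#' @param lexicon a `crc_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "crc_lexicon"))
  yaml::write_yaml(lexicon$source_spec, path)
  invisible(path)
}

#' @export
print.crc_lexicon <- function(x, ...) {
  cat("Staging label lexicon\n")
  cat(sprintf("  %d rules, %d patterns, %d synonym variants\n",
              nrow(x$rules), nrow(x$patterns), nrow(x$synonyms)))
  tab <- table(x$rules$component, x$rules$source)
  print(tab)
  invisible(x)
}
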