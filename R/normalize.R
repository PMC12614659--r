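## Text normalization with offset tracking.
##
## Matching happens on normalized text (lower case, collapsed whitespace,
## synonym variants replaced by canonical forms), but evidence spans must
## refer back to the original report string. Normalization therefore carries
## an offset map: for every character of the normalized text, the 1-based
## range of original characters it came from.

## Apply non-overlapping replacement edits to `text`, composing the offset
## maps. `o_start`/`o_end` map current characters to the original string;
## edits is a list of integer vectors `start`, `end` (1-based inclusive, in
## current-text coordinates, sorted by start) and character vector `repl`.
apply_edits <- function(text, o_start, o_end, edits) {
  k <- length(edits$start)
  if (k == 0L) {
    return(list(text = text, o_start = o_start, o_end = o_end))
  }
  n <- nchar(text)
  pieces <- character(2L * k + 1L)
  ns <- vector("list", 2L * k + 1L)
  ne <- vector("list", 2L * k + 1L)
  pos <- 1L
  for (i in seq_len(k)) {
    s <- edits$start[i]; e <- edits$end[i]; repl <- edits$repl[i]
    if (s > pos) {
      pieces[2L * i - 1L] <- substr(text, pos, s - 1L)
      ns[[2L * i - 1L]] <- o_start[pos:(s - 1L)]
      ne[[2L * i - 1L]] <- o_end[pos:(s - 1L)]
    }
    m <- nchar(repl)
    if (m > 0L) {
      pieces[2L * i] <- repl
      ## every replacement character maps to the whole replaced span
      ns[[2L * i]] <- rep.int(min(o_start[s:e]), m)
      ne[[2L * i]] <- rep.int(max(o_end[s:e]), m)
    }
    pos <- e + 1L
  }
  if (pos <= n) {
    pieces[2L * k + 1L] <- substr(text, pos, n)
    ns[[2L * k + 1L]] <- o_start[pos:n]
    ne[[2L * k + 1L]] <- o_end[pos:n]
  }
  list(text = paste(pieces, collapse = ""),
       o_start = unlist(ns, use.names = FALSE),
       o_end = unlist(ne, use.names = FALSE))
}

## Locate all matches of `regexes` in `text`, returning sorted,
## non-overlapping edits replacing each match with `repls`. Earlier/longer
## matches win on overlap.
find_edits <- function(text, regexes, repls) {
  starts <- integer(0); ends <- integer(0); repl <- character(0)
  for (i in seq_along(regexes)) {
    m <- gregexpr(regexes[i], text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    starts <- c(starts, as.integer(m))
    ends <- c(ends, as.integer(m) + len - 1L)
    repl <- c(repl, rep.int(repls[i], length(m)))
  }
  if (length(starts) == 0L) {
    return(list(start = integer(0), end = integer(0), repl = character(0)))
  }
  o <- order(starts, -(ends - starts))
  starts <- starts[o]; ends <- ends[o]; repl <- repl[o]
  keep <- rep(TRUE, length(starts))
  last_end <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] <= last_end) keep[i] <- FALSE else last_end <- ends[i]
  }
  list(start = starts[keep], end = ends[keep], repl = repl[keep])
}

normalize_one <- function(text, lexicon) {
  if (is.na(text)) text <- ""
  x <- tolower(text)
  n <- nchar(x)
  state <- list(text = x, o_start = seq_len(n), o_end = seq_len(n))
  if (n > 0L) {
    ## pass 1: whitespace runs -> single space; leading/trailing -> removed
    ws <- find_edits(state$text, "[\\s]+", " ")
    k <- length(ws$start)
    if (k > 0L) {
      if (ws$start[1] == 1L) ws$repl[1] <- ""
      if (ws$end[k] == nchar(state$text)) ws$repl[k] <- ""
    }
    state <- apply_edits(state$text, state$o_start, state$o_end, ws)
    ## pass 2: synonym variants -> canonical
    syn <- lexicon$synonyms
    if (!is.null(syn) && nrow(syn) > 0L) {
      ed <- find_edits(state$text, syn$regex, syn$canonical)
      state <- apply_edits(state$text, state$o_start, state$o_end, ed)
    }
  }
  state
}

#' Normalize report text for lexicon matching
#'
#' Lower-cases the text, collapses runs of whitespace to single spaces,
#' trims the ends, and replaces synonym variants (e.g. `"L/N"`,
#' `"lymph nodes"`) with their canonical form as declared in the lexicon.
#' The returned offset map recovers original character spans for any slice
#' of the normalized text, so matched evidence can be quoted verbatim from
#' the source report. Normalization is idempotent and total (the empty
#' string maps to itself).
#'
#' @param text a single report string (UTF-8).
#' @param lexicon a compiled lexicon from [load_lexicon()]; its synonym
#'   table drives the replacements.
#' @return an object of class `crc_norm`: a list with `text` (normalized
#'   string), and integer vectors `o_start`, `o_end` giving, for each
#'   normalized character, the 1-based inclusive range of original
#'   characters it derives from.
#' @examples
#' lex <- load_lexicon()
#' normalize_text("Metastatic L/N enlargement", lex)$text
#' @export
normalize_text <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1L)
  structure(normalize_one(text, lexicon), class = "crc_norm")
}

## Split a normalized text into sentences at '.' ';'. Returns list(text,
## start) with start the 1-based offset of each (trimmed, nonempty)
## sentence within the normalized string.
split_sentences <- function(norm_text) {
  n <- nchar(norm_text)
  if (n == 0L) return(list(text = character(0), start = integer(0)))
  delim <- gregexpr("[.;]", norm_text, perl = TRUE)[[1]]
  bounds <- if (delim[1] == -1L) integer(0) else as.integer(delim)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds - 1L, n)
  ok <- starts <= ends
  starts <- starts[ok]; ends <- ends[ok]
  seg <- substring(norm_text, starts, ends)
  lead <- attr(regexpr("^ +", seg, perl = TRUE), "match.length")
  lead[lead < 0L] <- 0L
  starts <- starts + lead
  seg <- substring(norm_text, starts, ends)
  seg <- sub(" +$", "", seg, perl = TRUE)
  ok <- nzchar(seg)
  list(text = seg[ok], start = starts[ok])
}
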