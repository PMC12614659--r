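## Cohort table and report-document I/O, plus the one-hot feature encoding
## used for the before/after prognostic models.
##
## The canonical cohort schema mirrors the profiled patient-characteristics
## table of a colorectal-cancer clinical library: demographics, treatment
## and outcome flags, and the staging target variables (T/N/M stage, the
## combined TNM string, and the SEER summary stage). Column names use the
## human-readable forms ("perineural invasion", "T stage") so that encoded
## feature names come out as printed in registry exports (e.g.
## "perineural invasion_nan", "SEER_2.0", "TNM_T4N2M1").

crc_schema <- function() {
  list(
    id = "patient_id",
    numeric = c("age", "height", "weight", "BMI",
                "total lymph node", "positive lymph node"),
    flag = c("operation", "chemotherapy", "radiotherapy",
             "complication after surgery", "death", "five_year_survival"),
    categorical = c("sex", "year of initial visit", "primary site",
                    "histological diagnosis", "lymphatic invasion",
                    "perineural invasion",
                    "T stage", "N stage", "M stage", "TNM", "SEER"),
    ## categorical variables whose codes are numeric in EMR exports
    categorical_numeric = c("year of initial visit",
                            "histological diagnosis",
                            "lymphatic invasion", "perineural invasion",
                            "SEER"),
    mandatory = c("patient_id", "T stage", "N stage", "M stage",
                  "TNM", "SEER")
  )
}

#' Staging target variables of the quality management process
#'
#' @return character vector of the cohort columns the QMP imputes.
#' @export
target_variables <- function() {
  c("T stage", "N stage", "M stage", "TNM", "SEER")
}

.default_aliases <- c(
  t_stage = "T stage", n_stage = "N stage", m_stage = "M stage",
  tnm = "TNM", tnm_string = "TNM", seer = "SEER", seer_code = "SEER",
  bmi = "BMI", year_of_initial_visit = "year of initial visit",
  primary_site = "primary site",
  histological_diagnosis = "histological diagnosis",
  lymphatic_invasion = "lymphatic invasion",
  perineural_invasion = "perineural invasion",
  total_lymph_node = "total lymph node",
  positive_lymph_node = "positive lymph node",
  complication = "complication after surgery"
)

.default_na_strings <- c("", "NA", "NULL", "nan", "NaN")

canonicalize_names <- function(nms, aliases) {
  key <- tolower(gsub("[[:space:]]+", "_", trimws(nms)))
  canon_key <- tolower(gsub("[[:space:]]+", "_",
                            c(crc_schema()$id, crc_schema()$numeric,
                              crc_schema()$flag, crc_schema()$categorical)))
  canon_val <- c(crc_schema()$id, crc_schema()$numeric,
                 crc_schema()$flag, crc_schema()$categorical)
  out <- nms
  for (i in seq_along(nms)) {
    if (key[i] %in% names(aliases)) {
      out[i] <- aliases[[key[i]]]
    } else if (key[i] %in% canon_key) {
      out[i] <- canon_val[match(key[i], canon_key)]
    }
  }
  out
}

#' Read a patient-level cohort table (and optional report documents)
#'
#' Reads an RFC-4180 CSV cohort table into a typed data frame. Header names
#' are mapped onto the canonical schema via a configurable alias table
#' (EMR exports vary); empty cells and the configured sentinel strings
#' become missing; unparseable numeric cells become missing with one logged
#' warning; row count and order are preserved. When `documents_path` is
#' given, the JSON-lines report file is read alongside and documents whose
#' `patient_id` does not appear in the table are counted as orphans (kept,
#' with a warning).
#'
#' @param table_path path to the cohort CSV.
#' @param documents_path optional path to a JSON-lines document file (keys
#'   `patient_id`, `modality`, `text`, optional `date`).
#' @param config optional list with `na_strings` and/or `aliases` (named
#'   character vector mapping lower-snake-case header keys to canonical
#'   column names).
#' @return a list of class `crc_cohort` with `records` (data frame),
#'   `documents` (data frame or `NULL`) and `n_orphans`.
#' @export
read_cohort <- function(table_path, documents_path = NULL, config = NULL) {
  na_strings <- config$na_strings %||% .default_na_strings
  aliases <- c(config$aliases, .default_aliases)
  aliases <- aliases[!duplicated(names(aliases))]

  raw <- utils::read.csv(table_path, check.names = FALSE,
                         colClasses = "character",
                         fileEncoding = "UTF-8")
  names(raw) <- canonicalize_names(names(raw), aliases)
  sch <- crc_schema()
  missing_cols <- setdiff(sch$mandatory, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$patient_id)) {
    stop("duplicate patient_id in cohort table: ",
         paste(unique(raw$patient_id[duplicated(raw$patient_id)])[1:5],
               collapse = ", "))
  }
  for (col in names(raw)) {
    raw[[col]][raw[[col]] %in% na_strings] <- NA_character_
  }
  n_bad <- 0L
  for (col in intersect(c(sch$numeric, sch$flag, sch$categorical_numeric),
                        names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    n_bad <- n_bad + sum(is.na(v) & !is.na(raw[[col]]))
    raw[[col]] <- v
  }
  if (n_bad > 0L) {
    warning(n_bad, " unparseable numeric cell(s) set to missing")
  }
  if (all(c("total lymph node", "positive lymph node") %in% names(raw))) {
    bad <- stats::na.omit(raw[["positive lymph node"]] >
                            raw[["total lymph node"]])
    if (any(bad)) {
      warning(sum(bad), " row(s) with positive lymph nodes exceeding total")
    }
  }
  seer_bad <- !is.na(raw$SEER) &
    !as.character(as.numeric(raw$SEER)) %in% .seer_levels
  if (any(seer_bad)) {
    warning(sum(seer_bad), " SEER value(s) outside {0,1,2,3,4,5,7,9} ",
            "set to missing")
    raw$SEER[seer_bad] <- NA
  }
  raw$SEER <- suppressWarnings(as.numeric(raw$SEER))

  documents <- NULL
  n_orphans <- 0L
  if (!is.null(documents_path)) {
    documents <- read_documents(documents_path)
    orphans <- setdiff(documents$patient_id, raw$patient_id)
    n_orphans <- length(orphans)
    if (n_orphans > 0L) {
      warning(n_orphans, " document patient_id(s) not present in the ",
              "cohort table")
    }
  }
  structure(list(records = raw, documents = documents,
                 n_orphans = n_orphans),
            class = "crc_cohort")
}

#' Read report documents from a JSON-lines file
#'
#' One JSON object per line with keys `patient_id`, `modality`
#' (`"pathology"` or `"imaging"`), `text`, and optional `date`.
#'
#' @param path file path.
#' @return data frame with columns `patient_id`, `modality`, `text`, `date`.
#' @export
read_documents <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSON on line ", i,
                                             " of ", path, ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    if (is.null(obj$patient_id) || !nzchar(as.character(obj$patient_id))) {
      stop("document on line ", i, " has empty patient_id")
    }
    if (is.null(obj$modality) || !obj$modality %in% .sources) {
      stop("document on line ", i, " has invalid modality")
    }
    data.frame(patient_id = as.character(obj$patient_id),
               modality = obj$modality,
               text = as.character(obj$text %||% ""),
               date = as.character(obj$date %||% NA_character_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a cohort table / documents file
#'
#' Inverse of [read_cohort()] / [read_documents()]: missing values are
#' written as empty cells, so a read-write-read round trip preserves all
#' values including missingness.
#'
#' @param records cohort data frame.
#' @param documents documents data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_documents <- function(documents, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(documents))) {
    row <- list(patient_id = documents$patient_id[i],
                modality = documents$modality[i],
                text = documents$text[i])
    if (!is.null(documents$date) && !is.na(documents$date[i])) {
      row$date <- documents$date[i]
    }
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
  }
  invisible(path)
}

format_level <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  out <- as.character(x)
  out[!is.na(num)] <- sprintf("%.1f", num[!is.na(num)])
  out[is.na(x)] <- "nan"
  out
}

#' One-hot encode cohort records for modeling
#'
#' Numeric variables pass through unchanged (missing kept as `NA`);
#' categorical variables are expanded to indicator columns named
#' `"<var>_<level>"` with an explicit missing-indicator level
#' `"<var>_nan"`, so each categorical variable's indicators sum to 1 per
#' row. Numeric-coded categorical levels are printed with one decimal
#' (`"SEER_2.0"`), other levels verbatim (`"primary site_C18.5"`,
#' `"TNM_T4N2M1"`).
#'
#' @param records cohort data frame.
#' @param exclude columns to drop before encoding (identifier columns and,
#'   for modeling, the outcome and anything that leaks it).
#' @return a numeric matrix with named columns; attribute `"types"` maps
#'   each column to `"numeric"` or `"indicator"`.
#' @export
encode_features <- function(records, exclude = "patient_id") {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no records to encode")
  }
  sch <- crc_schema()
  cols <- setdiff(names(records), exclude)
  num_cols <- intersect(cols, c(sch$numeric, sch$flag))
  cat_cols <- intersect(cols, sch$categorical)
  ## any unrecognized character column is treated as categorical
  other <- setdiff(cols, c(num_cols, cat_cols))
  for (col in other) {
    if (is.numeric(records[[col]])) num_cols <- c(num_cols, col)
    else cat_cols <- c(cat_cols, col)
  }
  blocks <- list()
  types <- character(0)
  for (col in num_cols) {
    m <- matrix(as.numeric(records[[col]]), ncol = 1,
                dimnames = list(NULL, col))
    blocks[[length(blocks) + 1L]] <- m
    types <- c(types, stats::setNames("numeric", col))
  }
  for (col in cat_cols) {
    lev <- format_level(records[[col]])
    ulev <- sort(unique(lev[lev != "nan"]))
    if (any(lev == "nan")) ulev <- c(ulev, "nan")
    ind <- matrix(0, nrow = nrow(records), ncol = length(ulev),
                  dimnames = list(NULL, paste0(col, "_", ulev)))
    ind[cbind(seq_len(nrow(records)), match(lev, ulev))] <- 1
    blocks[[length(blocks) + 1L]] <- ind
    types <- c(types, stats::setNames(rep("indicator", length(ulev)),
                                      colnames(ind)))
  }
  X <- do.call(cbind, blocks)
  attr(X, "types") <- types
  X
}
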