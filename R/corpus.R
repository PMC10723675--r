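# Document model and corpus ingestion: plain text with form-feed page breaks,
# simple text-layer PDFs, and the product metadata table.

#' Split text into word tokens
#'
#' Tokens are maximal runs of non-whitespace characters after Unicode NFC
#' normalisation. Punctuation stays attached and casing is preserved; the
#' embedding backend owns any further normalisation. This is the word
#' definition used for chunk sizing throughout the package.
#'
#' @param text A character scalar (an `NA` or empty string yields no tokens).
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("Hello,  world\n")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stopf("tokenize() expects a single character string")
  }
  if (is.na(text) || !nzchar(text)) return(character(0))
  norm <- stringi::stri_trans_nfc(text)
  toks <- stringi::stri_split_regex(norm, "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Construct a document
#'
#' A document is an ordered sequence of pages, each an ordered token vector.
#' Page order and within-page token order are preserved from the source; a
#' document must contain at least one page and one token.
#'
#' @param doc_id Unique document identifier within its corpus.
#' @param role `"query"` (e.g. an assessment report) or `"reference"`
#'   (e.g. a guideline).
#' @param pages List of non-empty character vectors of tokens.
#' @param source_path Optional path the document was read from.
#' @return An object of class `docmatch_document`.
#' @export
new_document <- function(doc_id, role = c("query", "reference"), pages,
                         source_path = "") {
  role <- match.arg(role)
  if (length(doc_id) != 1L || !nzchar(doc_id)) stopf("doc_id must be a non-empty string")
  if (!is.list(pages) || length(pages) == 0L) {
    stopf("empty document '%s': no pages", doc_id)
  }
  ok <- vapply(pages, function(p) is.character(p) && length(p) > 0L && all(nzchar(p)),
               logical(1))
  if (!all(ok)) stopf("document '%s': every page must be a non-empty token vector", doc_id)
  structure(
    list(doc_id = doc_id, corpus_role = role, pages = pages,
         source_path = source_path),
    class = "docmatch_document"
  )
}

#' @export
print.docmatch_document <- function(x, ...) {
  cat(sprintf("<docmatch_document> %s [%s]: %d page(s), %d word(s)\n",
              x$doc_id, x$corpus_role, length(x$pages), n_words(x)))
  invisible(x)
}

#' Total word count of a document
#' @param doc A `docmatch_document`.
#' @return Integer token count over all pages.
#' @export
n_words <- function(doc) {
  stopifnot(inherits(doc, "docmatch_document"))
  sum(lengths(doc$pages))
}

#' Read a plain-text document with page structure
#'
#' Pages are encoded in plain text by a delimiter character (form feed,
#' `"\f"`, by default — the conventional page break in text dumps). Each page
#' is tokenized with [tokenize()]; pages left empty after tokenization are
#' dropped.
#'
#' @param path Path to a UTF-8 text file, or `NULL` when `text` is given.
#' @param doc_id Document identifier.
#' @param role `"query"` or `"reference"`.
#' @param page_delimiter Page-break string (fixed, not a regex).
#' @param text Raw text to parse instead of reading `path`.
#' @return A `docmatch_document`.
#' @export
read_plaintext_document <- function(path = NULL, doc_id, role = "query",
                                    page_delimiter = "\f", text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stopf("either `path` or `text` must be supplied")
    text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }
  src <- if (is.null(path)) "<text>" else path
  if (!nzchar(trimws(text))) stopf("empty document: no content in %s", src)
  raw_pages <- strsplit(text, page_delimiter, fixed = TRUE)[[1]]
  pages <- lapply(raw_pages, tokenize)
  pages <- pages[lengths(pages) > 0L]
  if (length(pages) == 0L) stopf("empty document: no tokens in %s", src)
  new_document(doc_id, role, pages, source_path = if (is.null(path)) "" else path)
}

#' Read a PDF document
#'
#' Extracts the text layer of a PDF, one document page per PDF page, using the
#' package's built-in reader for simple PDFs (see [pdf_text_pages()] for the
#' dialect supported). Pages with no extractable tokens (e.g. figure-only
#' pages, common in regulatory documents) are dropped.
#'
#' @inheritParams read_plaintext_document
#' @param path Path to the PDF file.
#' @return A `docmatch_document`.
#' @export
read_pdf_document <- function(path, doc_id, role = "query") {
  texts <- pdf_text_pages(path)
  pages <- lapply(texts, tokenize)
  pages <- pages[lengths(pages) > 0L]
  if (length(pages) == 0L) stopf("empty document: no extractable text in %s", path)
  new_document(doc_id, role, pages, source_path = path)
}

#' Serialise a document back to delimited plain text
#'
#' Joins tokens with single spaces and pages with the page delimiter, the
#' inverse of [read_plaintext_document()] up to whitespace.
#'
#' @param doc A `docmatch_document`.
#' @param page_delimiter Page-break string.
#' @return A character scalar.
#' @export
document_to_text <- function(doc, page_delimiter = "\f") {
  stopifnot(inherits(doc, "docmatch_document"))
  paste(vapply(doc$pages, paste, character(1), collapse = " "),
        collapse = page_delimiter)
}

metadata_columns <- c(
  "doc_id", "approval_date", "atc_level1", "atc_level2", "rapporteur_country",
  "additional_monitoring", "orphan", "biosimilar", "conditional_approval",
  "doc_length_words"
)

parse_bool <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "1", "yes")] <- TRUE
  out[lx %in% c("false", "0", "no")] <- FALSE
  out
}

#' Read the product metadata table
#'
#' Reads the per-query-document covariate table: approval date, ATC category
#' codes at levels 1 and 2, rapporteur country, four regulatory boolean flags
#' (additional monitoring, orphan designation, biosimilar, conditional
#' approval) and the document word count. Dates must be ISO-8601
#' (`YYYY-MM-DD`); booleans accept `true/false/1/0/yes/no`; empty categorical
#' cells become `NA`.
#'
#' @param path CSV file with header
#'   `doc_id,approval_date,atc_level1,atc_level2,rapporteur_country,additional_monitoring,orphan,biosimilar,conditional_approval,doc_length_words`.
#' @return A data.frame with one row per product, typed columns, class
#'   `Date` for `approval_date`.
#' @export
read_metadata_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!identical(sort(names(raw)), sort(metadata_columns))) {
    bad <- c(setdiff(names(raw), metadata_columns), setdiff(metadata_columns, names(raw)))
    stopf("metadata table: unknown or missing column(s): %s", paste(bad, collapse = ", "))
  }
  raw <- raw[, metadata_columns]
  if (anyDuplicated(raw$doc_id)) {
    stopf("metadata table: duplicate doc_id '%s'",
          raw$doc_id[duplicated(raw$doc_id)][1])
  }
  n <- nrow(raw)
  out <- data.frame(doc_id = raw$doc_id, stringsAsFactors = FALSE)

  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", raw$approval_date)
  dates <- as.Date(ifelse(iso, raw$approval_date, NA), format = "%Y-%m-%d")
  bad <- which(!iso | is.na(dates))
  if (length(bad)) {
    stopf("metadata table row %d (doc_id %s): unparseable date '%s' (expected YYYY-MM-DD)",
          bad[1], raw$doc_id[bad[1]], raw$approval_date[bad[1]])
  }
  out$approval_date <- dates

  for (col in c("atc_level1", "atc_level2", "rapporteur_country")) {
    v <- trimws(raw[[col]])
    v[!nzchar(v)] <- NA_character_
    out[[col]] <- v
  }
  for (col in c("additional_monitoring", "orphan", "biosimilar", "conditional_approval")) {
    b <- parse_bool(raw[[col]])
    bad <- which(is.na(b))
    if (length(bad)) {
      stopf("metadata table row %d (doc_id %s): unparseable boolean '%s' in %s",
            bad[1], raw$doc_id[bad[1]], raw[[col]][bad[1]], col)
    }
    out[[col]] <- b
  }
  len <- suppressWarnings(as.integer(raw$doc_length_words))
  bad <- which(is.na(len) | len <= 0L)
  if (length(bad)) {
    stopf("metadata table row %d (doc_id %s): doc_length_words must be a positive integer, got '%s'",
          bad[1], raw$doc_id[bad[1]], raw$doc_length_words[bad[1]])
  }
  out$doc_length_words <- len
  out
}

#' Write documents to a line-oriented JSON corpus file
#'
#' One JSON object per line with fields `doc_id`, `role`, `pages` (array of
#' token arrays) and `source_path`.
#'
#' @param docs List of `docmatch_document` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(docs, path) {
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) stopf("duplicate doc_id in corpus: '%s'", ids[duplicated(ids)][1])
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(
      list(doc_id = jsonlite::unbox(d$doc_id),
           role = jsonlite::unbox(d$corpus_role),
           pages = d$pages,
           source_path = jsonlite::unbox(d$source_path %||% "")),
      auto_unbox = FALSE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a line-oriented JSON corpus file
#' @param path File written by [write_corpus_jsonl()].
#' @return List of `docmatch_document` objects.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyMatrix = FALSE)
    pages <- x$pages
    if (is.character(pages)) pages <- list(pages)  # single page collapses
    pages <- lapply(pages, as.character)
    new_document(x$doc_id, x$role, pages, source_path = x$source_path %||% "")
  })
}
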