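# Overlapping fixed-size word windows, restarted at every page break.

#' Compute chunk spans for one page
#'
#' Splits a page of `L` tokens into overlapping word windows. A page no longer
#' than `window` yields a single span `(0, L)`. Otherwise spans start at
#' `0, stride, 2*stride, ...`; each span covers up to `window` tokens and
#' generation stops once a span reaches the end of the page. With the default
#' window of 200 and stride of 150, consecutive chunks overlap by exactly 50
#' words. A terminal span shorter than `min_tail` tokens (reachable for other
#' window/stride settings) is merged backward: the previous span extends to
#' the page end, so its length may exceed `window` by up to `min_tail - 1`.
#'
#' @param tokens Character vector of page tokens (non-empty), or a single
#'   positive integer token count.
#' @param window Maximum chunk size in words.
#' @param stride Distance between consecutive chunk starts; must be smaller
#'   than `window`.
#' @param min_tail Minimum length of a terminal span before it is merged into
#'   its predecessor.
#' @return A data.frame with integer columns `start_word` (0-based,
#'   inclusive) and `end_word` (exclusive).
#' @examples
#' chunk_page(500, window = 200, stride = 150)
#' @export
chunk_page <- function(tokens, window = 200L, stride = 150L, min_tail = 25L) {
  L <- if (is.numeric(tokens) && length(tokens) == 1L) as.integer(tokens) else length(tokens)
  if (is.na(L) || L < 1L) stopf("chunk_page: page has no tokens")
  if (!is_count(window) || !is_count(stride) || !is_count(min_tail)) {
    stopf("chunk_page: window, stride and min_tail must be positive integers")
  }
  if (stride >= window) {
    stopf("chunk_page: stride (%d) must be smaller than window (%d)", stride, window)
  }
  if (L <= window) {
    return(data.frame(start_word = 0L, end_word = L))
  }
  starts <- integer(0)
  ends <- integer(0)
  s <- 0L
  repeat {
    e <- min(s + as.integer(window), L)
    starts <- c(starts, s)
    ends <- c(ends, e)
    if (e >= L) break
    s <- s + as.integer(stride)
  }
  n <- length(starts)
  if (n > 1L && (ends[n] - starts[n]) < min_tail) {
    ends[n - 1L] <- L
    starts <- starts[-n]
    ends <- ends[-n]
  }
  data.frame(start_word = starts, end_word = ends)
}

#' Chunk a document into overlapping word windows
#'
#' Applies [chunk_page()] to every page in order; no chunk ever crosses a
#' page break. Chunk text is the space-join of the covered tokens.
#'
#' @param doc A `docmatch_document`.
#' @inheritParams chunk_page
#' @return A data.frame with columns `doc_id`, `chunk_index` (0-based,
#'   document-wide, increasing in page/start order), `page_index` (0-based),
#'   `start_word`, `end_word` and `text`.
#' @export
chunk_document <- function(doc, window = 200L, stride = 150L, min_tail = 25L) {
  stopifnot(inherits(doc, "docmatch_document"))
  per_page <- lapply(seq_along(doc$pages), function(p) {
    toks <- doc$pages[[p]]
    spans <- chunk_page(toks, window = window, stride = stride, min_tail = min_tail)
    spans$page_index <- p - 1L
    spans$text <- vapply(seq_len(nrow(spans)), function(i) {
      paste(toks[(spans$start_word[i] + 1L):spans$end_word[i]], collapse = " ")
    }, character(1))
    spans
  })
  out <- do.call(rbind, per_page)
  data.frame(
    doc_id = doc$doc_id,
    chunk_index = seq_len(nrow(out)) - 1L,
    page_index = out$page_index,
    start_word = out$start_word,
    end_word = out$end_word,
    text = out$text,
    stringsAsFactors = FALSE
  )
}

#' Write chunks to a line-oriented JSON file
#' @param chunks Data.frame from [chunk_document()].
#' @param path Output file; one JSON object per chunk line.
#' @return `path`, invisibly.
#' @export
write_chunks_jsonl <- function(chunks, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(chunks))) {
    writeLines(jsonlite::toJSON(as.list(chunks[i, , drop = FALSE]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read chunks from a line-oriented JSON file
#' @param path File written by [write_chunks_jsonl()].
#' @return Data.frame of chunks.
#' @export
read_chunks_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    as.data.frame(jsonlite::fromJSON(ln), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
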