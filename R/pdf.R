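# Minimal reader and writer for simple text-layer PDFs.
#
# The reader targets the "classic" PDF dialect: an unencrypted file with a
# conventional cross-reference table, page content stored in plain or
# FlateDecode streams, and text painted with the standard Tj / TJ / ' / "
# operators in a simple (ASCII/WinAnsi) encoding. That covers PDFs produced
# by pdf_write_simple() below and by many text-first generators; it does not
# attempt object streams (PDF 1.5+ compressed xref), encryption, CID fonts or
# OCR. Pages whose content paints no text yield an empty string.

mask_to_ascii <- function(r, replacement) {
  bad <- r == as.raw(0L) | r > as.raw(126L)
  r[bad] <- replacement
  r
}

decode_pdf_string <- function(s) {
  # s: the bytes between ( and ) with PDF escapes.
  out <- character(0)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i < n) {
      nxt <- chars[i + 1L]
      if (nxt %in% c("n", "r", "t", "b", "f")) {
        out <- c(out, switch(nxt, n = "\n", r = "\r", t = "\t", b = "\b", f = "\f"))
        i <- i + 2L
      } else if (grepl("[0-7]", nxt)) {
        oct <- nxt
        j <- i + 2L
        while (j <= n && nchar(oct) < 3L && grepl("[0-7]", chars[j])) {
          oct <- paste0(oct, chars[j]); j <- j + 1L
        }
        out <- c(out, rawToChar(as.raw(strtoi(oct, base = 8L))))
        i <- j
      } else {
        out <- c(out, nxt)  # \( \) \\ and friends
        i <- i + 2L
      }
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# Extract the text painted by one content stream: strings shown by Tj, ', "
# and the string elements of TJ arrays. Each showing operator contributes one
# whitespace-separated piece; kerning inside TJ is ignored.
content_stream_text <- function(content) {
  starts <- integer(0)
  texts <- character(0)
  # (string) Tj  |  (string) '  |  (string) "
  m <- gregexpr("\\(((?:[^()\\\\]|\\\\.)*)\\)\\s*(Tj|'|\")", content, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      frag <- substr(content, m[k], m[k] + lens[k] - 1L)
      inner <- sub("\\)\\s*(Tj|'|\")$", "", sub("^\\(", "", frag))
      starts <- c(starts, m[k])
      texts <- c(texts, decode_pdf_string(inner))
    }
  }
  # [ ... ] TJ arrays
  mt <- gregexpr("\\[((?:[^][\\\\]|\\\\.)*)\\]\\s*TJ", content, perl = TRUE)[[1]]
  if (mt[1] != -1L) {
    lens <- attr(mt, "match.length")
    for (k in seq_along(mt)) {
      frag <- substr(content, mt[k], mt[k] + lens[k] - 1L)
      strs <- gregexpr("\\(((?:[^()\\\\]|\\\\.)*)\\)", frag, perl = TRUE)[[1]]
      if (strs[1] == -1L) next
      slens <- attr(strs, "match.length")
      txt <- paste(vapply(seq_along(strs), function(j) {
        decode_pdf_string(substr(frag, strs[j] + 1L, strs[j] + slens[j] - 2L))
      }, character(1)), collapse = "")
      starts <- c(starts, mt[k])
      texts <- c(texts, txt)
    }
  }
  if (length(texts) == 0L) return("")
  paste(texts[order(starts)], collapse = " ")
}

pdf_dict_ref <- function(dict, key) {
  # single indirect reference: /Key 12 0 R
  m <- regmatches(dict, regexec(paste0("/", key, "\\s+(\\d+)\\s+\\d+\\s+R"), dict))[[1]]
  if (length(m) < 2L) return(NA_integer_)
  as.integer(m[2])
}

pdf_dict_refs <- function(dict, key) {
  # reference array: /Key [12 0 R 13 0 R]  (or a single ref)
  m <- regmatches(dict, regexec(paste0("/", key, "\\s*\\[([^]]*)\\]"), dict))[[1]]
  if (length(m) >= 2L) {
    refs <- gregexpr("(\\d+)\\s+\\d+\\s+R", m[2], perl = TRUE)[[1]]
    if (refs[1] == -1L) return(integer(0))
    lens <- attr(refs, "match.length")
    return(vapply(seq_along(refs), function(j) {
      as.integer(sub("\\s.*", "", substr(m[2], refs[j], refs[j] + lens[j] - 1L)))
    }, integer(1)))
  }
  r <- pdf_dict_ref(dict, key)
  if (is.na(r)) integer(0) else r
}

#' Extract per-page text from a simple PDF
#'
#' Reads the text layer of an unencrypted, classic-xref PDF whose content
#' streams are plain or Flate-compressed and whose text uses the standard
#' `Tj`/`TJ` operators. Suitable for programmatically generated and other
#' simple text-first PDFs; see [pdf_write_simple()] for the matching writer.
#'
#' @param path Path to a PDF file.
#' @return Character vector, one element per page in page-tree order
#'   (possibly an empty string for pages without text).
#' @export
pdf_text_pages <- function(path) {
  if (!file.exists(path)) stopf("cannot read PDF: no such file '%s'", path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  # ASCII text view for regex work: one byte per character, so character
  # positions equal byte offsets. Non-ASCII and NUL bytes (possible inside
  # compressed streams) are masked; stream payloads are re-read from `bytes`.
  txt <- rawToChar(mask_to_ascii(bytes, as.raw(1L)))
  if (!startsWith(txt, "%PDF")) stopf("cannot read '%s': not a PDF file", path)
  if (grepl("/Encrypt", txt, fixed = TRUE)) {
    stopf("cannot read '%s': encrypted PDFs are not supported", path)
  }

  # index all "<num> <gen> obj ... endobj" spans
  m <- gregexpr("(\\d+)\\s+\\d+\\s+obj", txt, perl = TRUE)[[1]]
  if (m[1] == -1L) stopf("cannot read '%s': no PDF objects found", path)
  lens <- attr(m, "match.length")
  obj_start <- as.integer(m) + lens
  obj_num <- vapply(seq_along(m), function(j) {
    as.integer(sub("\\s.*", "", substr(txt, m[j], m[j] + lens[j] - 1L)))
  }, integer(1))
  ends <- gregexpr("endobj", txt, fixed = TRUE)[[1]]
  obj_body <- vapply(seq_along(obj_start), function(j) {
    e <- ends[ends > obj_start[j]]
    if (length(e) == 0L) return("")
    substr(txt, obj_start[j], min(e) - 1L)
  }, character(1))
  names(obj_body) <- as.character(obj_num)
  obj_offset <- obj_start  # absolute position of each body's first character
  names(obj_offset) <- as.character(obj_num)

  get_obj <- function(num) {
    b <- obj_body[[as.character(num)]]
    if (is.null(b)) stopf("cannot read '%s': missing object %d", path, num)
    b
  }

  # page tree: catalog -> /Pages -> recurse /Kids over /Type /Pages nodes
  cat_idx <- which(grepl("/Type\\s*/Catalog", obj_body))
  if (length(cat_idx) == 0L) stopf("cannot read '%s': no document catalog", path)
  pages_root <- pdf_dict_ref(obj_body[[cat_idx[1]]], "Pages")
  if (is.na(pages_root)) stopf("cannot read '%s': catalog has no /Pages", path)

  collect_pages <- function(num) {
    body <- get_obj(num)
    if (grepl("/Type\\s*/Pages", body)) {
      kids <- pdf_dict_refs(body, "Kids")
      unlist(lapply(kids, collect_pages))
    } else {
      num
    }
  }
  page_nums <- collect_pages(pages_root)
  if (length(page_nums) == 0L) stopf("cannot read '%s': empty page tree", path)

  stream_data <- function(num) {
    key <- as.character(num)
    body <- obj_body[[key]]
    if (is.null(body)) return("")
    sm <- regexpr("stream\r?\n", body)
    if (sm == -1L) return("")
    data_start <- obj_offset[[key]] + (sm + attr(sm, "match.length")) - 1L
    dict <- substr(body, 1L, sm)
    lenm <- regmatches(dict, regexec("/Length\\s+(\\d+)(?!\\s+\\d+\\s+R)", dict,
                                     perl = TRUE))[[1]]
    if (length(lenm) >= 2L) {
      data_len <- as.integer(lenm[2])
    } else {
      em <- regexpr("\r?\n?endstream", body)
      if (em == -1L) return("")
      data_len <- (obj_offset[[key]] + em - 1L) - data_start
    }
    if (data_len <= 0L) return("")
    raw_part <- bytes[data_start:(data_start + data_len - 1L)]
    if (grepl("/FlateDecode", dict, fixed = TRUE)) {
      raw_part <- memDecompress(raw_part, type = "gzip")
    }
    # supported dialect is ASCII text; other bytes degrade to '?'
    rawToChar(mask_to_ascii(raw_part, charToRaw("?")))
  }

  vapply(page_nums, function(pn) {
    body <- get_obj(pn)
    contents <- pdf_dict_refs(body, "Contents")
    if (length(contents) == 0L) return("")
    content <- paste(vapply(contents, stream_data, character(1)), collapse = "\n")
    content_stream_text(content)
  }, character(1))
}

escape_pdf_string <- function(s) {
  gsub("([()\\\\])", "\\\\\\1", s)
}

#' Write a simple single-column PDF
#'
#' Emits a minimal classic-xref PDF with one content stream per page, painting
#' the page text line by line in Helvetica. ASCII text only. Used to build PDF
#' fixtures programmatically (round-trip partner of [pdf_text_pages()]); a
#' page given as an empty string is emitted with no text operators, emulating
#' a figure-only page.
#'
#' @param pages Character vector, one element per page.
#' @param path Output path.
#' @param compress Flate-compress the content streams.
#' @return `path`, invisibly.
#' @export
pdf_write_simple <- function(pages, path, compress = FALSE) {
  stopifnot(is.character(pages), length(pages) >= 1L)
  n <- length(pages)
  # object numbering: 1 catalog, 2 pages root, 3 font,
  # 4..(3+n) page objects, (4+n)..(3+2n) content streams
  objs <- character(3 + 2 * n)
  kids <- paste(sprintf("%d 0 R", 4:(3 + n)), collapse = " ")
  objs[1] <- "<< /Type /Catalog /Pages 2 0 R >>"
  objs[2] <- sprintf("<< /Type /Pages /Kids [%s] /Count %d >>", kids, n)
  objs[3] <- "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>"
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    objs[3 + i] <- sprintf(
      "<< /Type /Page /Parent 2 0 R /MediaBox [0 0 612 792] /Resources << /Font << /F1 3 0 R >> >> /Contents %d 0 R >>",
      3 + n + i)
    if (nzchar(pages[i])) {
      lines <- strsplit(pages[i], "\n", fixed = TRUE)[[1]]
      ops <- sprintf("(%s) Tj T*", escape_pdf_string(lines))
      body <- paste0("BT /F1 11 Tf 14 TL 72 740 Td\n",
                     paste(ops, collapse = "\n"), "\nET")
    } else {
      body <- "0 0 m"  # no text operators: figure-only page stand-in
    }
    raw_body <- charToRaw(body)
    filter <- ""
    if (compress) {
      raw_body <- memCompress(raw_body, type = "gzip")
      filter <- " /Filter /FlateDecode"
    }
    streams[[i]] <- raw_body
    objs[3 + n + i] <- sprintf("<< /Length %d%s >>", length(raw_body), filter)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  offset <- 0L
  put <- function(x) {
    r <- if (is.raw(x)) x else charToRaw(x)
    writeBin(r, con)
    offset <<- offset + length(r)
  }
  offsets <- integer(length(objs))
  put("%PDF-1.4\n")
  for (k in seq_along(objs)) {
    offsets[k] <- offset
    put(sprintf("%d 0 obj\n%s\n", k, objs[k]))
    if (k > 3 + n) {  # stream object
      put("stream\n"); put(streams[[k - 3 - n]]); put("\nendstream\n")
    }
    put("endobj\n")
  }
  xref_at <- offset
  put(sprintf("xref\n0 %d\n0000000000 65535 f \n", length(objs) + 1L))
  for (k in seq_along(objs)) put(sprintf("%010d 00000 n \n", offsets[k]))
  put(sprintf("trailer\n<< /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
              length(objs) + 1L, xref_at))
  invisible(path)
}
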