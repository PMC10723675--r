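# Encoder contract and chunk embedding. Everything downstream depends only on
# the contract text -> unit vector, so the whole pipeline runs offline with
# the deterministic mock encoder; the pretrained sentence-encoder backend is
# an optional extra.

#' Construct an encoder handle
#'
#' An encoder is a function from a character vector of chunk texts to a
#' numeric matrix with one row per text, plus an advertised output dimension.
#' Rows need not be unit-norm; [embed_chunks()] re-normalises defensively.
#'
#' @param encode Function `character -> matrix(n, dim)`.
#' @param dim Output dimension.
#' @param description Short human-readable backend description.
#' @return An object of class `docmatch_encoder`.
#' @export
new_encoder <- function(encode, dim, description = "custom") {
  stopifnot(is.function(encode), is_count(dim))
  structure(list(encode = encode, dim = as.integer(dim), description = description),
            class = "docmatch_encoder")
}

#' @export
print.docmatch_encoder <- function(x, ...) {
  cat(sprintf("<docmatch_encoder> %s (dim = %d)\n", x$description, x$dim))
  invisible(x)
}

#' Deterministic mock encoder
#'
#' Encodes a chunk as the L2-normalised sum of per-token vectors, where each
#' distinct token maps, via a seeded hash, to a fixed pseudo-random unit
#' vector. Fully deterministic given `(dim, seed)` and independent of the
#' caller's RNG state. Chunks sharing vocabulary get graded cosine
#' similarity, mimicking semantic overlap; chunks over disjoint vocabularies
#' are nearly orthogonal in high dimension. This makes the mock a faithful
#' stand-in for a sentence encoder in end-to-end tests, without any model
#' download.
#'
#' @param dim Embedding dimension (>= 2; 768 matches the pretrained backend).
#' @param seed Integer seed fixing the token -> vector map.
#' @return A `docmatch_encoder`.
#' @examples
#' enc <- mock_encoder(dim = 16, seed = 1)
#' v <- enc$encode(c("factor viii potency", "potency assay"))
#' tcrossprod(v / sqrt(rowSums(v^2)))
#' @export
mock_encoder <- function(dim = 768L, seed = 0L) {
  if (!is_count(dim) || dim < 2) stopf("mock_encoder: dim must be an integer >= 2")
  dim <- as.integer(dim)
  cache <- new.env(parent = emptyenv())
  token_vector <- function(tok) {
    v <- cache[[tok]]
    if (is.null(v)) {
      v <- with_seed(derive_seed(seed, tok), stats::rnorm(dim))
      v <- v / sqrt(sum(v^2))
      cache[[tok]] <- v
    }
    v
  }
  encode <- function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      toks <- tokenize(texts[i])
      if (length(toks) == 0L) stopf("mock encoder: chunk %d has no tokens", i)
      counts <- table(toks)
      acc <- rep(0, dim)
      for (j in seq_along(counts)) {
        acc <- acc + as.numeric(counts[j]) * token_vector(names(counts)[j])
      }
      nrm <- sqrt(sum(acc^2))
      if (nrm < 1e-12) stopf("mock encoder: chunk %d sums to the zero vector", i)
      out[i, ] <- acc / nrm
    }
    out
  }
  new_encoder(encode, dim, sprintf("mock(dim=%d, seed=%d)", dim, seed))
}

#' Pretrained sentence-encoder backend
#'
#' Wraps an external sentence-transformer model through a `python`
#' subprocess. Requires the `sentence_transformers` python package and the
#' named model weights (downloaded or locally cached); when either is
#' missing, a clear error points offline users at [mock_encoder()], which
#' exercises the identical contract.
#'
#' @param model_name Model identifier passed to the backend (the
#'   768-dimensional `all-mpnet-base-v2` family is the intended default).
#' @param dim Advertised output dimension of the model.
#' @param python Python executable to use.
#' @param batch_size Encoding batch size.
#' @return A `docmatch_encoder`.
#' @export
pretrained_encoder <- function(model_name = "sentence-transformers/all-mpnet-base-v2",
                               dim = 768L, python = "python", batch_size = 32L) {
  probe <- suppressWarnings(system2(
    python, c("-c", shQuote("import sentence_transformers")),
    stdout = FALSE, stderr = FALSE))
  if (!identical(probe, 0L)) {
    stopf(paste0(
      "pretrained encoder backend unavailable: python package ",
      "'sentence_transformers' not importable via '%s'. Offline users can run ",
      "the full pipeline with mock_encoder(), which satisfies the same ",
      "encoder contract."), python)
  }
  encode <- function(texts) {
    if (any(!nzchar(trimws(texts)))) stopf("pretrained encoder: empty chunk text")
    inp <- tempfile(fileext = ".json")
    outp <- tempfile(fileext = ".json")
    on.exit(unlink(c(inp, outp)), add = TRUE)
    jsonlite::write_json(texts, inp)
    code <- sprintf(paste0(
      "import json,sys; from sentence_transformers import SentenceTransformer; ",
      "m=SentenceTransformer(%s); ",
      "t=json.load(open(%s)); ",
      "e=m.encode(t, batch_size=%d, normalize_embeddings=True); ",
      "json.dump([list(map(float,r)) for r in e], open(%s,'w'))"),
      deparse(model_name), deparse(inp), as.integer(batch_size), deparse(outp))
    status <- system2(python, c("-c", shQuote(code)))
    if (!identical(status, 0L)) {
      stopf("pretrained encoder: backend call failed (model '%s')", model_name)
    }
    do.call(rbind, lapply(jsonlite::fromJSON(outp, simplifyVector = FALSE), unlist))
  }
  new_encoder(encode, dim, sprintf("pretrained(%s)", model_name))
}

#' Construct an embedding set
#'
#' Per-document matrix of unit-norm chunk vectors, rows aligned with chunk
#' order. Rows are L2-normalised on construction.
#'
#' @param doc_id Document identifier.
#' @param vectors Numeric matrix, one row per chunk.
#' @return An object of class `docmatch_embedding`.
#' @export
embedding_set <- function(doc_id, vectors) {
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1)
  if (nrow(vectors) < 1L) stopf("embedding set '%s' is empty", doc_id)
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm < 1e-9)) {
    stopf("embedding set '%s': row %d has (near-)zero norm", doc_id, which(nrm < 1e-9)[1])
  }
  structure(
    list(doc_id = doc_id, vectors = vectors / nrm, dim = ncol(vectors)),
    class = "docmatch_embedding"
  )
}

#' @export
print.docmatch_embedding <- function(x, ...) {
  cat(sprintf("<docmatch_embedding> %s: %d chunk(s) x %d dims\n",
              x$doc_id, nrow(x$vectors), x$dim))
  invisible(x)
}

#' Embed a document's chunks
#'
#' Encodes every chunk of one document with the given encoder, in chunk-index
#' order, and re-normalises the rows so that cosine distance downstream is a
#' pure dot product.
#'
#' @param chunks Data.frame from [chunk_document()]; all rows must share one
#'   `doc_id`.
#' @param encoder A `docmatch_encoder`.
#' @return A `docmatch_embedding` with one unit-norm row per chunk.
#' @export
embed_chunks <- function(chunks, encoder) {
  stopifnot(inherits(encoder, "docmatch_encoder"))
  if (!is.data.frame(chunks) || nrow(chunks) == 0L) stopf("embed_chunks: no chunks")
  ids <- unique(chunks$doc_id)
  if (length(ids) != 1L) {
    stopf("embed_chunks: chunks mix doc_ids (%s)", paste(ids, collapse = ", "))
  }
  chunks <- chunks[order(chunks$chunk_index), , drop = FALSE]
  mat <- tryCatch(encoder$encode(chunks$text), error = function(e) {
    stopf("embed_chunks: encoder failed for document '%s': %s", ids, conditionMessage(e))
  })
  if (!is.matrix(mat) || nrow(mat) != nrow(chunks) || ncol(mat) != encoder$dim) {
    stopf("embed_chunks: encoder returned %s, expected %d x %d matrix",
          paste(dim(mat), collapse = " x "), nrow(chunks), encoder$dim)
  }
  embedding_set(ids, mat)
}

#' Persist an embedding set
#'
#' Writes the vector matrix as a TSV alongside a JSON sidecar recording
#' `doc_id`, `dim`, `n_chunks` and the encoder description.
#'
#' @param emb A `docmatch_embedding`.
#' @param path Matrix output path (`.tsv`); the sidecar is `path` +
#'   `".json"`.
#' @param encoder_description Free-text provenance stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path, encoder_description = "") {
  stopifnot(inherits(emb, "docmatch_embedding"))
  utils::write.table(emb$vectors, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(doc_id = emb$doc_id, dim = emb$dim, n_chunks = nrow(emb$vectors),
         encoder = encoder_description),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load an embedding set written by [write_embedding()]
#' @param path Matrix path passed to [write_embedding()].
#' @return A `docmatch_embedding`.
#' @export
read_embedding <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  if (ncol(mat) != meta$dim || nrow(mat) != meta$n_chunks) {
    stopf("embedding file '%s' does not match its sidecar", path)
  }
  embedding_set(meta$doc_id, mat)
}
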