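# End-to-end pipeline: ingest -> chunk -> embed -> match -> score
# (-> regress), with persisted intermediates so that matching and scoring can
# be re-run with different aggregators or best-match fractions without
# re-embedding.

#' Load and validate a run configuration
#'
#' Reads a YAML configuration for [run_pipeline()]. Unknown keys are
#' rejected. Recognised keys (all optional unless noted): `window`, `stride`,
#' `min_tail`, `encoder` (map with `type` `"mock"`/`"pretrained"`, `dim`,
#' `seed`, `model_name`), `method`, `aggregator`, `fraction`,
#' `reference_date`, `seed`, `paths` (map with `query_corpus`,
#' `reference_corpus` — required — plus optional `metadata` and required
#' `out_dir`).
#'
#' @param path YAML file, or a list already parsed.
#' @return Validated config list of class `docmatch_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known <- c("window", "stride", "min_tail", "encoder", "method", "aggregator",
             "fraction", "reference_date", "seed", "paths")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stopf("config: unknown key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg$window <- as.integer(cfg$window %||% 200L)
  cfg$stride <- as.integer(cfg$stride %||% 150L)
  cfg$min_tail <- as.integer(cfg$min_tail %||% 25L)
  cfg$method <- match.arg(cfg$method %||% "piecewise", c("piecewise", "mean_pool"))
  cfg$aggregator <- match.arg(cfg$aggregator %||% "arithmetic",
                              c("arithmetic", "geometric"))
  cfg$fraction <- as.numeric(cfg$fraction %||% 0.05)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  enc <- cfg$encoder %||% list()
  enc_known <- c("type", "dim", "seed", "model_name")
  if (length(setdiff(names(enc), enc_known))) {
    stopf("config: unknown encoder key(s): %s",
          paste(setdiff(names(enc), enc_known), collapse = ", "))
  }
  enc$type <- match.arg(enc$type %||% "mock", c("mock", "pretrained"))
  enc$dim <- as.integer(enc$dim %||% if (enc$type == "mock") 768L else 768L)
  enc$seed <- as.integer(enc$seed %||% cfg$seed)
  cfg$encoder <- enc
  paths <- cfg$paths %||% list()
  if (is.null(paths$query_corpus) || is.null(paths$reference_corpus) ||
      is.null(paths$out_dir)) {
    stopf("config: paths.query_corpus, paths.reference_corpus and paths.out_dir are required")
  }
  structure(cfg, class = "docmatch_config")
}

make_encoder <- function(enc) {
  if (enc$type == "mock") mock_encoder(dim = enc$dim, seed = enc$seed)
  else pretrained_encoder(model_name = enc$model_name %||%
                            "sentence-transformers/all-mpnet-base-v2",
                          dim = enc$dim)
}

log_stage <- function(fmt, ...) {
  message(sprintf("[docmatch %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full comparison pipeline
#'
#' Reads the two corpora (line-oriented JSON, see [write_corpus_jsonl()]),
#' chunks and embeds every document, computes the full query x reference
#' distance grid, scores each query against its best-matching fraction of
#' references, and — when a metadata path is configured — fits the covariate
#' regression. Each stage writes its artifact under `paths$out_dir`
#' (`chunks_*.jsonl`, `embeddings/`, `distances.csv`, `scores.csv`,
#' `reference_scores.csv`, `regression.csv`). Deterministic given the
#' configuration.
#'
#' @param config A `docmatch_config`, or a path/list accepted by
#'   [read_run_config()].
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "docmatch_config")) config else read_run_config(config)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "embeddings"), showWarnings = FALSE)
  artifacts <- list()

  log_stage("ingest: reading corpora")
  queries <- read_corpus_jsonl(cfg$paths$query_corpus)
  references <- read_corpus_jsonl(cfg$paths$reference_corpus)
  log_stage("ingest: %d query, %d reference document(s)",
            length(queries), length(references))

  encoder <- make_encoder(cfg$encoder)
  embed_corpus <- function(docs, label) {
    chunk_rows <- lapply(docs, chunk_document, window = cfg$window,
                         stride = cfg$stride, min_tail = cfg$min_tail)
    chunks <- do.call(rbind, chunk_rows)
    cpath <- file.path(out_dir, sprintf("chunks_%s.jsonl", label))
    write_chunks_jsonl(chunks, cpath)
    artifacts[[paste0("chunks_", label)]] <<- cpath
    log_stage("chunk: %s corpus -> %d chunk(s)", label, nrow(chunks))
    sets <- lapply(chunk_rows, function(ch) {
      emb <- embed_chunks(ch, encoder)
      write_embedding(emb, file.path(out_dir, "embeddings",
                                     paste0(emb$doc_id, ".tsv")),
                      encoder_description = encoder$description)
      emb
    })
    log_stage("embed: %s corpus embedded with %s", label, encoder$description)
    sets
  }
  q_sets <- embed_corpus(queries, "query")
  r_sets <- embed_corpus(references, "reference")

  log_stage("match: %s distances over %d x %d grid",
            cfg$method, length(q_sets), length(r_sets))
  grid <- distance_grid(q_sets, r_sets, method = cfg$method,
                        aggregator = cfg$aggregator)
  dpath <- file.path(out_dir, "distances.csv")
  utils::write.csv(grid, dpath, row.names = FALSE)
  artifacts$distances <- dpath

  scores <- score_all_queries(grid, fraction = cfg$fraction)
  spath <- file.path(out_dir, "scores.csv")
  flat <- scores
  flat$contributing_reference_ids <- vapply(scores$contributing_reference_ids,
                                            paste, character(1), collapse = ";")
  utils::write.csv(flat, spath, row.names = FALSE)
  artifacts$scores <- spath
  log_stage("score: fraction %.2f -> k = %d reference(s) per query",
            cfg$fraction, scores$k[1])

  refsc <- reference_contribution_scores(scores, grid)
  rpath <- file.path(out_dir, "reference_scores.csv")
  utils::write.csv(refsc, rpath, row.names = FALSE)
  artifacts$reference_scores <- rpath

  if (!is.null(cfg$paths$metadata)) {
    log_stage("regress: fitting covariate model")
    metadata <- read_metadata_table(cfg$paths$metadata)
    built <- build_design(metadata, scores,
                          reference_date = cfg$reference_date %||% NULL)
    fit <- fit_ols(built$design, built$response)
    gpath <- file.path(out_dir, "regression.csv")
    utils::write.csv(fit$coefficients, gpath, row.names = FALSE)
    artifacts$regression <- gpath
    sig <- summarize_significant(fit)
    sigpath <- file.path(out_dir, "regression_significant.csv")
    utils::write.csv(sig, sigpath, row.names = FALSE)
    artifacts$regression_significant <- sigpath
  }
  log_stage("done: artifacts in %s", out_dir)
  invisible(artifacts)
}
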