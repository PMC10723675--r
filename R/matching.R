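# Global document distance by all-vs-all piecewise chunk matching, plus the
# mean-pooling comparator.
#
# Piecewise matching compares two documents chunk by chunk: every chunk
# embedding of document A is compared against every chunk embedding of
# document B, and the global distance is the mean of the N lowest cosine
# distances, where N is the chunk count of the smaller document. A chunk may
# contribute more than once when it matches several chunks of the other
# document well. This preserves semantic granularity that single-vector
# document representations (mean pooling) average away.

#' Cosine distance between two unit vectors
#'
#' `1 - u . v`, in `[0, 2]`: 0 for identical directions, 1 for orthogonal,
#' 2 for antipodal. Lower distance means higher semantic similarity.
#'
#' @param u,v Unit-norm numeric vectors of equal dimension.
#' @return Distance in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stopf("cosine_distance: dimension mismatch (%d vs %d)", length(u), length(v))
  }
  for (x in list(u, v)) {
    if (abs(sum(x^2) - 1) > 1e-6) stopf("cosine_distance: inputs must be unit-norm")
  }
  min(max(1 - sum(u * v), 0), 2)
}

#' All-vs-all chunk distance matrix
#'
#' @param A,B `docmatch_embedding` sets of equal dimension.
#' @return Numeric matrix of shape `n_A x n_B`; entry `(i, j)` is the cosine
#'   distance between chunk `i` of `A` and chunk `j` of `B`.
#' @export
pairwise_distance_matrix <- function(A, B) {
  stopifnot(inherits(A, "docmatch_embedding"), inherits(B, "docmatch_embedding"))
  if (A$dim != B$dim) {
    stopf("pairwise_distance_matrix: dimension mismatch (%d vs %d)", A$dim, B$dim)
  }
  D <- 1 - tcrossprod(A$vectors, B$vectors)
  pmin(pmax(D, 0), 2)
}

pair_distance_row <- function(query_id, reference_id, method, aggregator, distance) {
  data.frame(query_id = query_id, reference_id = reference_id, method = method,
             aggregator = aggregator, distance = distance, stringsAsFactors = FALSE)
}

#' Piecewise document distance
#'
#' The global semantic distance between two documents: with
#' `N = min(n_A, n_B)` chunks in the smaller document, the `N` smallest
#' entries of the full all-vs-all chunk distance matrix are selected by value
#' (a chunk may be selected repeatedly) and averaged. The aggregate is the
#' arithmetic mean by default; the geometric mean (computed on values floored
#' at `1e-12` before taking logs, since identical chunks give exact zeros) is
#' selectable. Symmetric in its two arguments.
#'
#' @param A,B `docmatch_embedding` sets of equal dimension.
#' @param aggregator `"arithmetic"` or `"geometric"`.
#' @return One-row data.frame: `query_id`, `reference_id`, `method`
#'   (`"piecewise"`), `aggregator`, `distance`.
#' @export
piecewise_distance <- function(A, B, aggregator = c("arithmetic", "geometric")) {
  aggregator <- match.arg(aggregator)
  D <- pairwise_distance_matrix(A, B)
  N <- min(nrow(D), ncol(D))
  vals <- sort(as.numeric(D), method = "radix")[seq_len(N)]
  d <- if (aggregator == "arithmetic") mean(vals) else geometric_mean(vals)
  pair_distance_row(A$doc_id, B$doc_id, "piecewise", aggregator, d)
}

#' Mean-pooling document distance
#'
#' Baseline comparator: average each document's chunk embeddings into one
#' vector, re-normalise, and take a single cosine distance between the two
#' means. Loses within-document granularity by construction.
#'
#' @param A,B `docmatch_embedding` sets of equal dimension.
#' @return One-row data.frame as in [piecewise_distance()], with `method`
#'   `"mean_pool"` and aggregator `NA`.
#' @export
mean_pool_distance <- function(A, B) {
  stopifnot(inherits(A, "docmatch_embedding"), inherits(B, "docmatch_embedding"))
  if (A$dim != B$dim) {
    stopf("mean_pool_distance: dimension mismatch (%d vs %d)", A$dim, B$dim)
  }
  pooled <- lapply(list(A, B), function(E) {
    m <- colMeans(E$vectors)
    nrm <- sqrt(sum(m^2))
    if (nrm < 1e-9) {
      stopf("mean_pool_distance: document '%s' has a degenerate (cancelling) mean embedding",
            E$doc_id)
    }
    m / nrm
  })
  d <- min(max(1 - sum(pooled[[1]] * pooled[[2]]), 0), 2)
  pair_distance_row(A$doc_id, B$doc_id, "mean_pool", NA_character_, d)
}

#' Distance grid over a query and a reference corpus
#'
#' Computes the document distance for every (query, reference) pair.
#'
#' @param queries,references Lists of `docmatch_embedding` sets.
#' @param method `"piecewise"` or `"mean_pool"`.
#' @param aggregator Aggregator for the piecewise method.
#' @return Data.frame with one row per pair, columns as in
#'   [piecewise_distance()].
#' @export
distance_grid <- function(queries, references,
                          method = c("piecewise", "mean_pool"),
                          aggregator = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  aggregator <- match.arg(aggregator)
  rows <- lapply(queries, function(q) {
    do.call(rbind, lapply(references, function(r) {
      if (method == "piecewise") piecewise_distance(q, r, aggregator)
      else mean_pool_distance(q, r)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
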