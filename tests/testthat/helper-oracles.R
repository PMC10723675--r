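# Independent reference implementations and small fixture builders used
# across the suite. These deliberately use brute-force formulations (explicit
# loops, full sorts, normal equations) so they share no code path with the
# package internals they check.

# Brute-force chunk spans: walk starts at multiples of `stride`, emit the
# covered range, stop once the page end is reached, then apply the
# short-terminal merge rule.
naive_chunk_spans <- function(L, window, stride, min_tail) {
  if (L <= window) return(cbind(start = 0L, end = as.integer(L)))
  starts <- integer(0)
  ends <- integer(0)
  s <- 0L
  repeat {
    e <- min(s + window, L)
    starts <- c(starts, as.integer(s))
    ends <- c(ends, as.integer(e))
    if (e == L) break
    s <- s + stride
  }
  k <- length(starts)
  if (k > 1L && ends[k] - starts[k] < min_tail) {
    starts <- starts[-k]
    ends <- ends[-k]
    ends[k - 1L] <- as.integer(L)
  }
  cbind(start = starts, end = ends)
}

# Brute-force piecewise distance: explicit double loop over all chunk pairs,
# full sort of every entry, then the aggregate over the first N.
naive_piecewise <- function(A, B, aggregator = "arithmetic") {
  va <- A$vectors
  vb <- B$vectors
  d <- numeric(0)
  for (i in seq_len(nrow(va))) {
    for (j in seq_len(nrow(vb))) {
      d <- c(d, 1 - sum(va[i, ] * vb[j, ]))
    }
  }
  d <- pmin(pmax(d, 0), 2)
  N <- min(nrow(va), nrow(vb))
  sel <- sort(d)[seq_len(N)]
  if (aggregator == "arithmetic") mean(sel) else exp(mean(log(pmax(sel, 1e-12))))
}

# Textbook OLS by normal equations, with t-based inference.
ols_normal_equations <- function(X, y, conf_level = 0.95) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  se <- unname(se)
  tval <- as.numeric(beta) / se
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  list(beta = as.numeric(beta), se = se,
       p = unname(2 * pt(-abs(tval), df)),
       ci_low = as.numeric(beta) - tcrit * se,
       ci_high = as.numeric(beta) + tcrit * se)
}

# Random unit-row embedding set.
random_embedding <- function(doc_id, n, dim) {
  m <- matrix(rnorm(n * dim), nrow = n)
  embedding_set(doc_id, m)
}

# Embedding set whose rows are the given vectors (normalised on entry).
vec_embedding <- function(doc_id, ...) {
  embedding_set(doc_id, do.call(rbind, list(...)))
}

basis <- function(i, dim) {
  v <- rep(0, dim)
  v[i] <- 1
  v
}

# Tiny complete pair-distance grid from a matrix (queries x references).
grid_from_matrix <- function(m, method = "piecewise", aggregator = "arithmetic") {
  qs <- rownames(m)
  rs <- colnames(m)
  do.call(rbind, lapply(qs, function(q) {
    data.frame(query_id = q, reference_id = rs, method = method,
               aggregator = aggregator, distance = as.numeric(m[q, ]),
               stringsAsFactors = FALSE)
  }))
}

# Write a temporary metadata CSV from raw field vectors.
write_meta_csv <- function(path, rows) {
  writeLines(c(paste(c("doc_id", "approval_date", "atc_level1", "atc_level2",
                       "rapporteur_country", "additional_monitoring", "orphan",
                       "biosimilar", "conditional_approval", "doc_length_words"),
                     collapse = ","),
               rows), path)
  path
}
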