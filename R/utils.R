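# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded draws inside the package
#' (mock encoder token vectors, synthetic corpora) never perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic 31-bit polynomial hash of a string; stable across sessions and
# platforms (exact in double precision: intermediate values stay below 2^53).
hash_string <- function(x) {
  codes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  h
}

# Derive a bounded child seed from a base seed and a label, for splittable
# deterministic generation.
derive_seed <- function(seed, label) {
  (hash_string(paste0(label, ":", seed)) + seed) %% 2147483647
}

geometric_mean <- function(x, floor = 1e-12) {
  exp(mean(log(pmax(x, floor))))
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == as.integer(x) && x > 0
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
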