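# Linear-model analysis of query total distances against product covariates:
# design construction with [0,1]-normalised columns and largest-subgroup
# baselines, ordinary least squares, and the significant-findings report.

minmax_scale <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Pool categorical levels observed fewer than `min_n` times into "other",
# turn NA into an explicit "(missing)" level, and return the factor with the
# largest subgroup as its first (baseline) level.
prepare_categorical <- function(x, min_n = 2L) {
  x <- as.character(x)
  x[is.na(x)] <- "(missing)"
  tab <- table(x)
  rare <- names(tab)[tab < min_n]
  if (length(rare)) x[x %in% rare] <- "other"
  tab <- table(x)
  baseline <- names(tab)[order(-tab, names(tab))][1]
  factor(x, levels = c(baseline, setdiff(sort(names(tab)), baseline)))
}

#' Build the regression design from metadata and query scores
#'
#' Assembles the design matrix for modelling total distance on product
#' covariates: product age in days at `reference_date` and document word
#' count, both min-max scaled to `[0, 1]`; boolean regulatory flags as 0/1;
#' and the level-2 category code and rapporteur country dummy-coded with the
#' largest subgroup as the contrasting baseline (levels with fewer than two
#' observations are pooled into `"other"` first). Every non-intercept column
#' therefore lies in `[0, 1]`, making coefficients directly comparable. The
#' response is the unscaled total distance. Covariate columns without any
#' variation (for instance a flag never set in a small corpus) are dropped
#' with a message; genuinely collinear columns raise an error.
#'
#' @param metadata Data.frame from [read_metadata_table()] (or
#'   [generate_metadata()]).
#' @param scores Data.frame from [score_all_queries()], or any data.frame
#'   with `query_id` and `total_distance`.
#' @param reference_date Date at which product age is measured; defaults to
#'   the latest approval date present.
#' @return List with elements `design` (list: `row_ids`, `column_names`,
#'   `values` matrix, `baseline_levels`) and `response` (numeric vector).
#' @export
build_design <- function(metadata, scores, reference_date = NULL) {
  missing_ids <- setdiff(scores$query_id, metadata$doc_id)
  if (length(missing_ids)) {
    stopf("build_design: no metadata for query document(s): %s",
          paste(missing_ids, collapse = ", "))
  }
  md <- metadata[match(scores$query_id, metadata$doc_id), , drop = FALSE]
  if (is.null(reference_date)) reference_date <- max(md$approval_date)
  reference_date <- as.Date(reference_date)
  if (any(md$approval_date > reference_date)) {
    stopf("build_design: reference_date precedes an approval date")
  }

  n <- nrow(md)
  cols <- list(`(Intercept)` = rep(1, n),
               product_age = minmax_scale(as.numeric(reference_date - md$approval_date)),
               doc_length = minmax_scale(as.numeric(md$doc_length_words)))
  for (flag in c("additional_monitoring", "orphan", "biosimilar", "conditional_approval")) {
    cols[[flag]] <- as.numeric(md[[flag]])
  }
  baselines <- list()
  for (cat in c("atc_level2", "rapporteur_country")) {
    f <- prepare_categorical(md[[cat]])
    baselines[[cat]] <- levels(f)[1]
    for (lev in levels(f)[-1]) {
      cols[[paste0(cat, "_", lev)]] <- as.numeric(f == lev)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  # a covariate with no variation (e.g. a flag never set in a small corpus)
  # carries no information and would alias the intercept
  constant <- vapply(seq_len(ncol(X)), function(j) {
    j > 1L && length(unique(X[, j])) == 1L
  }, logical(1))
  dropped_constant <- colnames(X)[constant]
  if (length(dropped_constant)) {
    message("build_design: dropping constant column(s): ",
            paste(dropped_constant, collapse = ", "))
    X <- X[, !constant, drop = FALSE]
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("build_design: rank-deficient design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  list(
    design = list(row_ids = scores$query_id, column_names = colnames(X),
                  values = X, baseline_levels = baselines,
                  dropped_constant = dropped_constant),
    response = scores$total_distance
  )
}

#' Ordinary least squares with t-based inference
#'
#' Fits the linear model by QR least squares and reports, per column, the
#' coefficient, its standard error from the unbiased residual variance,
#' the two-sided p-value and the 95% confidence interval from the
#' t-distribution with `n - p` degrees of freedom.
#'
#' @param design Design list from [build_design()], or a plain numeric
#'   matrix (intercept included by the caller).
#' @param response Numeric response vector.
#' @param conf_level Confidence level for the intervals.
#' @return An object of class `docmatch_ols`: data.frame `coefficients`
#'   (`term`, `estimate`, `std_error`, `p_value`, `ci_low`, `ci_high`) plus
#'   `residual_df`, `r_squared`, `sigma`.
#' @export
fit_ols <- function(design, response, conf_level = 0.95) {
  X <- if (is.list(design) && !is.data.frame(design) && !is.matrix(design)) {
    design$values
  } else {
    as.matrix(design)
  }
  y <- as.numeric(response)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stopf("fit_ols: response length %d != %d rows", length(y), n)
  if (n <= p) stopf("fit_ols: need more observations (%d) than columns (%d)", n, p)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) stopf("fit_ols: singular design matrix")
  beta <- fit$coefficients
  res <- fit$residuals
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(fit$qr))[order(fit$qr$pivot), order(fit$qr$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  has_icpt <- any(apply(X, 2, function(cc) all(cc == cc[1]) && cc[1] != 0))
  tss <- if (has_icpt) sum((y - mean(y))^2) else sum(y^2)
  coefs <- data.frame(
    term = colnames(X) %||% paste0("x", seq_len(p)),
    estimate = unname(beta),
    std_error = unname(se),
    p_value = unname(pval),
    ci_low = unname(beta - tcrit * se),
    ci_high = unname(beta + tcrit * se),
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coefs, residual_df = df,
         r_squared = 1 - sum(res^2) / tss, sigma = sqrt(sigma2),
         conf_level = conf_level),
    class = "docmatch_ols"
  )
}

#' @export
print.docmatch_ols <- function(x, digits = 4, ...) {
  cat(sprintf("Linear model: %d terms, residual df = %d, R^2 = %.3f\n",
              nrow(x$coefficients), x$residual_df, x$r_squared))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Significant findings, ordered by evidence
#'
#' Filters the fitted model to terms with `p < alpha` and sorts them by
#' ascending p-value, the layout used to report which covariates predict
#' distance. The intercept is excluded by default since it is not a finding.
#'
#' @param result A `docmatch_ols` fit.
#' @param alpha Significance level.
#' @param include_intercept Keep the intercept row if significant.
#' @return Data.frame with columns `term`, `estimate`, `p_value`, `ci_low`,
#'   `ci_high` (possibly zero rows).
#' @export
summarize_significant <- function(result, alpha = 0.05, include_intercept = FALSE) {
  stopifnot(inherits(result, "docmatch_ols"))
  co <- result$coefficients
  if (!include_intercept) co <- co[co$term != "(Intercept)", , drop = FALSE]
  co <- co[co$p_value < alpha, c("term", "estimate", "p_value", "ci_low", "ci_high")]
  co <- co[order(co$p_value), , drop = FALSE]
  rownames(co) <- NULL
  co
}
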