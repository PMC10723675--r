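make_meta <- function(n, seed = 1) {
  spec <- synthetic_corpus_spec(n_queries = n, seed = seed)
  generate_metadata(spec, doc_ids = sprintf("Q%03d", seq_len(n)))
}

test_that("the design matrix is [0,1]-normalised with largest-subgroup baselines", {
  gm <- make_meta(60)
  scores <- data.frame(query_id = gm$metadata$doc_id,
                       total_distance = gm$latent_distance)
  built <- build_design(gm$metadata, scores)
  X <- built$design$values
  expect_equal(colnames(X)[1], "(Intercept)")
  expect_true(all(X[, -1] >= 0 & X[, -1] <= 1))
  # continuous min-max columns reach both ends
  expect_equal(range(X[, "product_age"]), c(0, 1))
  expect_equal(range(X[, "doc_length"]), c(0, 1))
  # dummies are 0/1 and the baseline level has no column
  dummy_cols <- grep("^atc_level2_|^rapporteur_country_", colnames(X), value = TRUE)
  expect_true(all(X[, dummy_cols] %in% c(0, 1)))
  for (cat in c("atc_level2", "rapporteur_country")) {
    base <- built$design$baseline_levels[[cat]]
    expect_false(paste0(cat, "_", base) %in% colnames(X))
    # the baseline is the largest subgroup
    expect_equal(base, names(which.max(table(gm$metadata[[cat]]))))
  }
  expect_equal(built$response, scores$total_distance)
})

test_that("min-max scaling maps [10, 20, 30] to [0, 0.5, 1]", {
  md <- make_meta(3)$metadata
  md$doc_length_words <- c(10L, 20L, 30L)
  # keep the tiny design full-rank: no varying flags or categories
  md[c("additional_monitoring", "orphan", "biosimilar", "conditional_approval")] <- FALSE
  md$atc_level2 <- "L01"
  md$rapporteur_country <- "SE"
  md$approval_date <- as.Date(c("2020-01-01", "2020-06-01", "2019-01-01"))
  scores <- data.frame(query_id = md$doc_id, total_distance = c(0.3, 0.4, 0.5))
  built <- build_design(md, scores)
  expect_equal(unname(built$design$values[, "doc_length"]), c(0, 0.5, 1))
  # products approved on the same date get identical product_age entries
  md$approval_date <- as.Date(c("2020-01-01", "2020-01-01", "2019-01-01"))
  built2 <- build_design(md, scores, reference_date = as.Date("2021-01-01"))
  age <- built2$design$values[, "product_age"]
  expect_identical(age[1], age[2])
  expect_equal(unname(age), c(0, 0, 1))
})

test_that("covariates without variation are dropped rather than fitted", {
  gm <- make_meta(50)
  md <- gm$metadata
  md$biosimilar <- FALSE  # never set
  scores <- data.frame(query_id = md$doc_id, total_distance = gm$latent_distance)
  expect_message(built <- build_design(md, scores), "constant column")
  expect_false("biosimilar" %in% built$design$column_names)
  expect_equal(built$design$dropped_constant, "biosimilar")
})

test_that("build_design reports missing metadata and collinear columns", {
  gm <- make_meta(40)
  scores <- data.frame(query_id = c(gm$metadata$doc_id, "ghost"),
                       total_distance = runif(41))
  expect_error(build_design(gm$metadata, scores), "ghost")

  md <- gm$metadata
  md$orphan <- md$additional_monitoring  # exact duplicate column
  scores <- data.frame(query_id = md$doc_id, total_distance = gm$latent_distance)
  expect_error(build_design(md, scores), "collinear")

  expect_error(build_design(gm$metadata, scores,
                            reference_date = min(gm$metadata$approval_date) - 1),
               "reference_date")
})

test_that("categorical levels below two observations are pooled into 'other'", {
  md <- make_meta(30)$metadata
  md$atc_level2[1] <- "Z99"  # singleton level
  scores <- data.frame(query_id = md$doc_id, total_distance = runif(30, 0.2, 0.6))
  built <- build_design(md, scores)
  expect_false("atc_level2_Z99" %in% built$design$column_names)
  expect_true("atc_level2_other" %in% built$design$column_names)
})

test_that("fit_ols handles exact fits, constants and degenerate sizes", {
  # slope 2, intercept 1, zero residual (n = 3 so df = 1)
  X <- cbind(`(Intercept)` = rep(1, 3), x = c(0, 1, 2))
  fit <- fit_ols(X, c(1, 3, 5))
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(fit$sigma, 0, tolerance = 1e-8)

  # constant response: zero slope, intercept = constant
  fitc <- fit_ols(X, rep(4, 3))
  expect_equal(fitc$coefficients$estimate, c(4, 0), tolerance = 1e-10)

  expect_error(fit_ols(X[1:2, ], c(1, 3)), "more observations")
  Xs <- cbind(a = c(1, 1, 1, 1), b = c(1, 1, 1, 1))
  expect_error(fit_ols(Xs, 1:4), "singular")
})

test_that("fit_ols agrees with an explicit normal-equations oracle", {
  set.seed(2024)
  for (rep in 1:30) {
    n <- sample(20:60, 1)
    p <- sample(2:6, 1)
    X <- cbind(1, matrix(runif(n * (p - 1)), nrow = n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    y <- X %*% runif(p, -1, 1) + rnorm(n, 0, 0.3)
    fit <- fit_ols(X, y)
    ref <- ols_normal_equations(X, as.numeric(y))
    expect_equal(fit$coefficients$estimate, ref$beta, tolerance = 1e-8)
    expect_equal(fit$coefficients$std_error, unname(ref$se), tolerance = 1e-8)
    expect_equal(fit$coefficients$p_value, unname(ref$p), tolerance = 1e-8)
    expect_equal(fit$coefficients$ci_low, ref$ci_low, tolerance = 1e-8)
    expect_equal(fit$coefficients$ci_high, ref$ci_high, tolerance = 1e-8)
  }
})

test_that("fitted values are invariant to affine rescaling of a covariate", {
  set.seed(5)
  n <- 50
  X <- cbind(`(Intercept)` = 1, x1 = runif(n), x2 = runif(n))
  y <- X %*% c(0.3, -0.05, 0.02) + rnorm(n, 0, 0.01)
  f1 <- fit_ols(X, y)
  X2 <- X
  X2[, "x1"] <- 10 + 5 * X[, "x1"]
  f2 <- fit_ols(X2, y)
  yhat1 <- X %*% f1$coefficients$estimate
  yhat2 <- X2 %*% f2$coefficients$estimate
  expect_equal(yhat1, yhat2, tolerance = 1e-8)
  expect_equal(f2$coefficients$estimate[2] * 5, f1$coefficients$estimate[2],
               tolerance = 1e-8)
})

test_that("summarize_significant filters and orders by p-value", {
  set.seed(6)
  n <- 80
  X <- cbind(`(Intercept)` = 1, strong = runif(n), noise = runif(n))
  y <- X %*% c(0.3, -0.2, 0) + rnorm(n, 0, 0.02)
  fit <- fit_ols(X, y)
  sig <- summarize_significant(fit, alpha = 0.05)
  expect_true("strong" %in% sig$term)
  expect_false("(Intercept)" %in% sig$term)
  expect_true(all(diff(sig$p_value) >= 0))

  none <- summarize_significant(fit, alpha = 1e-300)
  expect_equal(nrow(none), 0L)
  all_rows <- summarize_significant(fit, alpha = 1)
  expect_equal(nrow(all_rows), nrow(fit$coefficients) - 1L)
})
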