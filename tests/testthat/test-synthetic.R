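test_that("topic vocabularies share exactly the configured fraction", {
  tp <- topic_model_spec(n_topics = 3, vocab_size_per_topic = 100,
                         shared_vocab_fraction = 0.2)
  expect_length(tp$vocab, 3L)
  expect_true(all(lengths(tp$vocab) == 100L))
  shared <- Reduce(intersect, tp$vocab)
  expect_length(shared, 20L)
  # beyond the shared pool, topics are disjoint
  uniq1 <- setdiff(tp$vocab[[1]], shared)
  expect_length(intersect(uniq1, tp$vocab[[2]]), 0L)

  tp0 <- topic_model_spec(n_topics = 2, shared_vocab_fraction = 0)
  expect_length(intersect(tp0$vocab[[1]], tp0$vocab[[2]]), 0L)
  expect_error(topic_model_spec(n_topics = 1), "n_topics")
  expect_error(topic_model_spec(vocab_size_per_topic = 10), "vocab_size")
})

test_that("corpus generation is deterministic and reports mixture overlap", {
  spec <- synthetic_corpus_spec(n_queries = 3, n_references = 2, seed = 11)
  a <- generate_corpus(spec)
  b <- generate_corpus(spec)
  expect_identical(lapply(a$queries, `[[`, "pages"),
                   lapply(b$queries, `[[`, "pages"))
  expect_identical(a$overlap, b$overlap)
  expect_equal(dim(a$overlap), c(3L, 2L))

  # identical mixtures -> overlap 1; disjoint one-hot mixtures -> overlap 0
  tp <- topic_model_spec(n_topics = 2, shared_vocab_fraction = 0)
  mix_q <- rbind(c(1, 0), c(0, 1))
  mix_r <- rbind(c(1, 0), c(0, 1))
  sp <- synthetic_corpus_spec(n_queries = 2, n_references = 2, topics = tp,
                              query_topic_mixtures = mix_q,
                              reference_topic_mixtures = mix_r, seed = 4)
  ov <- generate_corpus(sp)$overlap
  expect_equal(unname(diag(ov)), c(1, 1))
  expect_equal(unname(ov[1, 2]), 0)

  # documents respect the page and word ranges
  doc <- a$queries[[1]]
  expect_true(length(doc$pages) >= 2 && length(doc$pages) <= 4)
  expect_true(all(lengths(doc$pages) >= 120 & lengths(doc$pages) <= 280))

  expect_error(synthetic_corpus_spec(query_topic_mixtures = rbind(c(2, -1, 0, 0))),
               "mixtures")
})

test_that("generated corpora keep the caller's RNG stream intact", {
  spec <- synthetic_corpus_spec(n_queries = 2, n_references = 2, seed = 3)
  set.seed(999)
  before <- .Random.seed
  invisible(generate_corpus(spec))
  expect_identical(.Random.seed, before)
})

test_that("metadata planting: near-zero noise makes latent distance affine in a covariate", {
  spec <- synthetic_corpus_spec(
    n_queries = 200, seed = 21, noise_sd = 1e-9,
    planted_effects = c(product_age = -0.04))
  gm <- generate_metadata(spec)
  age <- as.numeric(max(gm$metadata$approval_date) - gm$metadata$approval_date)
  age01 <- (age - min(age)) / (max(age) - min(age))
  expect_equal(gm$latent_distance, 0.33 - 0.04 * age01, tolerance = 1e-6)
})

test_that("a planted negative age effect shows as negative sample correlation", {
  cors <- sapply(1:20, function(s) {
    spec <- synthetic_corpus_spec(n_queries = 500, seed = s,
                                  planted_effects = c(product_age = -0.04),
                                  noise_sd = 0.01)
    gm <- generate_metadata(spec)
    age <- as.numeric(max(gm$metadata$approval_date) - gm$metadata$approval_date)
    cor(age, gm$latent_distance)
  })
  expect_true(all(cors < 0))
})

test_that("with all effects zero, per-covariate false-positive rates stay near alpha", {
  set.seed(31)
  hits <- replicate(120, {
    spec <- synthetic_corpus_spec(n_queries = 120, noise_sd = 0.01,
                                  planted_effects = c(product_age = 0),
                                  seed = sample.int(1e6, 1))
    gm <- generate_metadata(spec)
    scores <- data.frame(query_id = gm$metadata$doc_id,
                         total_distance = gm$latent_distance)
    built <- build_design(gm$metadata, scores)
    fit <- fit_ols(built$design, built$response)
    co <- fit$coefficients
    co$p_value[co$term == "product_age"] < 0.05
  })
  # binomial(120, 0.05): reject if far outside the expected band
  expect_lt(mean(hits), 0.12)
})

test_that("metadata generation validates planted effect names", {
  spec <- synthetic_corpus_spec(n_queries = 10,
                                planted_effects = c(not_a_covariate = 1))
  expect_error(generate_metadata(spec), "unknown planted effect")
})

test_that("mean piecewise distance decreases as ground-truth overlap increases", {
  # three queries engineered to overlap a single-topic reference by 0, 0.5, 1
  tp <- topic_model_spec(n_topics = 2, vocab_size_per_topic = 60,
                         shared_vocab_fraction = 0)
  enc <- mock_encoder(dim = 64, seed = 100)
  dists <- t(sapply(1:20, function(s) {
    sp <- synthetic_corpus_spec(
      n_queries = 3, n_references = 1, topics = tp,
      pages_per_doc = c(2, 3), words_per_page = c(120, 200),
      query_topic_mixtures = rbind(c(0, 1), c(0.5, 0.5), c(1, 0)),
      reference_topic_mixtures = rbind(c(1, 0)),
      seed = s)
    corp <- generate_corpus(sp)
    r <- embed_chunks(chunk_document(corp$references[[1]]), enc)
    sapply(corp$queries, function(q) {
      piecewise_distance(embed_chunks(chunk_document(q), enc), r)$distance
    })
  }))
  means <- colMeans(dists)  # overlap 0, 0.5, 1
  expect_true(means[1] > means[2] && means[2] > means[3])
  overlap <- rep(c(0, 0.5, 1), each = 20)
  rho <- cor(overlap, as.numeric(dists), method = "spearman")
  expect_lt(rho, -0.8)
})

test_that("piecewise beats mean pooling on minority-topic references", {
  # reference matches only a 30% minority topic of the query: piecewise can
  # match the minority chunks piece by piece, pooling averages them away
  tp <- topic_model_spec(n_topics = 2, vocab_size_per_topic = 60,
                         shared_vocab_fraction = 0)
  enc <- mock_encoder(dim = 64, seed = 200)
  wins <- sapply(1:20, function(s) {
    sp <- synthetic_corpus_spec(
      n_queries = 1, n_references = 1, topics = tp,
      pages_per_doc = c(3, 4), words_per_page = c(150, 250),
      query_topic_mixtures = rbind(c(0.7, 0.3)),
      reference_topic_mixtures = rbind(c(0, 1)),
      seed = s)
    corp <- generate_corpus(sp)
    q <- embed_chunks(chunk_document(corp$queries[[1]]), enc)
    r <- embed_chunks(chunk_document(corp$references[[1]]), enc)
    piecewise_distance(q, r)$distance < mean_pool_distance(q, r)$distance
  })
  expect_gte(mean(wins), 0.9)
})
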