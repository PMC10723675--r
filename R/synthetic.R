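# Seeded synthetic corpora: paged multi-topic documents with controllable
# inter-corpus semantic overlap, plus metadata tables with planted covariate
# effects on distance. Word-sampling topic models (rather than direct
# embedding-space simulation) are used deliberately so that every pipeline
# stage -- tokenize, chunk, mock-embed, match -- is exercised end to end.

#' Topic vocabulary specification
#'
#' Defines `n_topics` topic vocabularies of `vocab_size_per_topic` word types
#' each. A `shared_vocab_fraction` of every topic's vocabulary is drawn from
#' a common shared pool (emulating boilerplate common to all regulatory
#' documents); the remainder is unique to the topic. Topic identity stands in
#' for therapeutic-area topicality.
#'
#' @param n_topics Number of topics (>= 2).
#' @param vocab_size_per_topic Word types per topic (>= 50).
#' @param shared_vocab_fraction Fraction of each topic vocabulary common to
#'   all topics, in `[0, 1)`.
#' @return Object of class `docmatch_topics`: list of per-topic character
#'   vectors plus the spec fields.
#' @export
topic_model_spec <- function(n_topics = 4L, vocab_size_per_topic = 100L,
                             shared_vocab_fraction = 0.1) {
  if (!is_count(n_topics) || n_topics < 2) stopf("n_topics must be an integer >= 2")
  if (!is_count(vocab_size_per_topic) || vocab_size_per_topic < 50) {
    stopf("vocab_size_per_topic must be an integer >= 50")
  }
  if (shared_vocab_fraction < 0 || shared_vocab_fraction >= 1) {
    stopf("shared_vocab_fraction must be in [0, 1)")
  }
  n_shared <- round(shared_vocab_fraction * vocab_size_per_topic)
  shared <- if (n_shared > 0) sprintf("shared%03d", seq_len(n_shared)) else character(0)
  vocab <- lapply(seq_len(n_topics), function(t) {
    c(shared, sprintf("t%02dw%04d", t, seq_len(vocab_size_per_topic - n_shared)))
  })
  structure(list(n_topics = as.integer(n_topics),
                 vocab_size_per_topic = as.integer(vocab_size_per_topic),
                 shared_vocab_fraction = shared_vocab_fraction,
                 vocab = vocab),
            class = "docmatch_topics")
}

#' Synthetic corpus specification
#'
#' Conditions under which synthetic corpora are generated. Defaults define a
#' small two-corpus study: 12 query documents and 8 references of 2--4 pages
#' with 120--280 words per page, over 4 topics. References default to
#' single-topic documents (cycling through topics); queries default to a
#' random two-topic mixture, emulating an assessment report that spans one
#' therapeutic topic plus generic regulatory content.
#'
#' @param n_queries,n_references Corpus sizes.
#' @param topics A [topic_model_spec()].
#' @param pages_per_doc Length-2 integer range of pages per document.
#' @param words_per_page Length-2 integer range of words per page.
#' @param query_topic_mixtures,reference_topic_mixtures Optional matrices
#'   (documents x topics) of non-negative weights summing to 1 per row;
#'   `NULL` for the defaults above.
#' @param approval_date_range Length-2 `Date` range for metadata approval
#'   dates.
#' @param planted_effects Named numeric vector of covariate effects on the
#'   latent distance used by [generate_metadata()]. Defaults plant the
#'   qualitative structure seen in real corpora: older products and longer
#'   documents closer to references (negative age and length effects), two
#'   category codes with negative effects, one positive safety-flag effect.
#' @param intercept Baseline latent distance.
#' @param noise_sd Gaussian noise s.d. on the latent distance.
#' @param seed Integer seed; all generation is deterministic given the spec.
#' @return Object of class `docmatch_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_queries = 12L, n_references = 8L,
                                  topics = topic_model_spec(),
                                  pages_per_doc = c(2L, 4L),
                                  words_per_page = c(120L, 280L),
                                  query_topic_mixtures = NULL,
                                  reference_topic_mixtures = NULL,
                                  approval_date_range = as.Date(c("2008-01-01", "2022-11-18")),
                                  planted_effects = c(product_age = -0.0424,
                                                      doc_length = -0.0177,
                                                      additional_monitoring = 0.0045,
                                                      `atc_level2_B02` = -0.0174,
                                                      `atc_level2_J05` = -0.0069),
                                  intercept = 0.33,
                                  noise_sd = 0.01,
                                  seed = 1L) {
  # allow plain-list inputs, e.g. from a YAML spec file
  if (is.list(topics) && !inherits(topics, "docmatch_topics")) {
    topics <- do.call(topic_model_spec, topics)
  }
  if (is.list(planted_effects)) planted_effects <- unlist(planted_effects)
  stopifnot(inherits(topics, "docmatch_topics"),
            is_count(n_queries), is_count(n_references),
            length(pages_per_doc) == 2L, length(words_per_page) == 2L,
            noise_sd > 0)
  check_mix <- function(m, n, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != topics$n_topics) {
      stopf("%s mixtures must be %d x %d", what, n, topics$n_topics)
    }
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
      stopf("%s mixtures must be non-negative and sum to 1 per document", what)
    }
    m
  }
  structure(list(
    n_queries = as.integer(n_queries), n_references = as.integer(n_references),
    topics = topics,
    pages_per_doc = as.integer(pages_per_doc),
    words_per_page = as.integer(words_per_page),
    query_topic_mixtures = check_mix(query_topic_mixtures, n_queries, "query"),
    reference_topic_mixtures = check_mix(reference_topic_mixtures, n_references, "reference"),
    approval_date_range = as.Date(approval_date_range),
    planted_effects = planted_effects,
    intercept = intercept, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "docmatch_corpus_spec")
}

default_query_mixtures <- function(spec) {
  nt <- spec$topics$n_topics
  t(vapply(seq_len(spec$n_queries), function(i) {
    main <- sample.int(nt, 1L)
    second <- sample(setdiff(seq_len(nt), main), 1L)
    w <- rep(0, nt)
    share <- stats::runif(1, 0.6, 0.9)
    w[main] <- share
    w[second] <- 1 - share
    w
  }, numeric(nt)))
}

default_reference_mixtures <- function(spec) {
  nt <- spec$topics$n_topics
  t(vapply(seq_len(spec$n_references), function(i) {
    w <- rep(0, nt)
    w[((i - 1L) %% nt) + 1L] <- 1
    w
  }, numeric(nt)))
}

sample_document <- function(doc_id, role, mixture, spec) {
  n_pages <- sample(seq(spec$pages_per_doc[1], spec$pages_per_doc[2]), 1L)
  pages <- lapply(seq_len(n_pages), function(p) {
    n_words <- sample(seq(spec$words_per_page[1], spec$words_per_page[2]), 1L)
    topic <- sample.int(spec$topics$n_topics, n_words, replace = TRUE, prob = mixture)
    words <- character(n_words)
    for (t in unique(topic)) {
      idx <- topic == t
      words[idx] <- sample(spec$topics$vocab[[t]], sum(idx), replace = TRUE)
    }
    words
  })
  new_document(doc_id, role, pages)
}

#' Generate a synthetic query/reference corpus
#'
#' Draws every document's pages as i.i.d. words from its topic-mixture
#' vocabulary. The ground-truth semantic overlap of a (query, reference)
#' pair is the dot product of their topic mixtures, which downstream
#' distances should decrease in.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @return List with `queries` and `references` (lists of
#'   `docmatch_document`), `overlap` (matrix `n_queries x n_references` of
#'   mixture dot products), and the mixture matrices actually used.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "docmatch_corpus_spec"))
  with_seed(derive_seed(spec$seed, "corpus"), {
    qmix <- spec$query_topic_mixtures %||% default_query_mixtures(spec)
    rmix <- spec$reference_topic_mixtures %||% default_reference_mixtures(spec)
    queries <- lapply(seq_len(spec$n_queries), function(i) {
      sample_document(sprintf("Q%03d", i), "query", qmix[i, ], spec)
    })
    references <- lapply(seq_len(spec$n_references), function(i) {
      sample_document(sprintf("R%03d", i), "reference", rmix[i, ], spec)
    })
    overlap <- qmix %*% t(rmix)
    dimnames(overlap) <- list(vapply(queries, `[[`, character(1), "doc_id"),
                              vapply(references, `[[`, character(1), "doc_id"))
    list(queries = queries, references = references, overlap = overlap,
         query_topic_mixtures = qmix, reference_topic_mixtures = rmix)
  })
}

#' Generate a metadata table with planted covariate effects
#'
#' Samples product covariates (approval dates uniform over the spec's range,
#' category codes multinomial with one dominant level, rapporteur countries
#' with one dominant level, Bernoulli flags) and a latent distance
#' `intercept + sum(beta * covariate) + N(0, noise_sd)`, where continuous
#' covariates enter min-max scaled to `[0, 1]` and planted effect names use
#' the design-column vocabulary of [build_design()] (`product_age`,
#' `doc_length`, flag names, `atc_level2_<code>`,
#' `rapporteur_country_<code>`). The latent distance is returned for use as
#' a regression response in recovery experiments.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @param doc_ids Query document ids; defaults to the ids
#'   [generate_corpus()] assigns.
#' @param doc_lengths Optional word counts (e.g. from the generated corpus);
#'   sampled uniformly from 500--5000 when omitted.
#' @return List with `metadata` (data.frame in the layout of
#'   [read_metadata_table()]) and `latent_distance` (numeric vector aligned
#'   with rows).
#' @export
generate_metadata <- function(spec, doc_ids = sprintf("Q%03d", seq_len(spec$n_queries)),
                              doc_lengths = NULL) {
  stopifnot(inherits(spec, "docmatch_corpus_spec"))
  n <- length(doc_ids)
  with_seed(derive_seed(spec$seed, "metadata"), {
    date_range <- as.numeric(spec$approval_date_range)
    dates <- as.Date(round(stats::runif(n, date_range[1], date_range[2])),
                     origin = "1970-01-01")
    atc2 <- sample(c("L01", "B02", "J05", "N05", "A08"), n, replace = TRUE,
                   prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
    atc1 <- substr(atc2, 1L, 1L)
    rapporteur <- sample(c("SE", "DE", "NL", "HR", "MT"), n, replace = TRUE,
                         prob = c(0.35, 0.25, 0.2, 0.1, 0.1))
    flags <- list(additional_monitoring = stats::rbinom(n, 1, 0.3) == 1,
                  orphan = stats::rbinom(n, 1, 0.2) == 1,
                  biosimilar = stats::rbinom(n, 1, 0.15) == 1,
                  conditional_approval = stats::rbinom(n, 1, 0.1) == 1)
    lengths <- doc_lengths %||% round(stats::runif(n, 500, 5000))

    md <- data.frame(doc_id = doc_ids, approval_date = dates,
                     atc_level1 = atc1, atc_level2 = atc2,
                     rapporteur_country = rapporteur,
                     additional_monitoring = flags$additional_monitoring,
                     orphan = flags$orphan, biosimilar = flags$biosimilar,
                     conditional_approval = flags$conditional_approval,
                     doc_length_words = as.integer(lengths),
                     stringsAsFactors = FALSE)

    covariate_column <- function(name) {
      if (name == "product_age") {
        return(minmax_scale(as.numeric(max(md$approval_date) - md$approval_date)))
      }
      if (name == "doc_length") return(minmax_scale(as.numeric(md$doc_length_words)))
      if (name %in% names(flags)) return(as.numeric(flags[[name]]))
      if (startsWith(name, "atc_level2_")) {
        return(as.numeric(md$atc_level2 == sub("^atc_level2_", "", name)))
      }
      if (startsWith(name, "rapporteur_country_")) {
        return(as.numeric(md$rapporteur_country == sub("^rapporteur_country_", "", name)))
      }
      stopf("generate_metadata: unknown planted effect '%s'", name)
    }
    latent <- rep(spec$intercept, n)
    for (nm in names(spec$planted_effects)) {
      latent <- latent + spec$planted_effects[[nm]] * covariate_column(nm)
    }
    latent <- latent + stats::rnorm(n, 0, spec$noise_sd)
    list(metadata = md, latent_distance = latent)
  })
}

#' Write a metadata table as CSV
#' @param metadata Data.frame in [read_metadata_table()] layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(metadata, path) {
  md <- metadata
  md$approval_date <- format(md$approval_date, "%Y-%m-%d")
  for (col in c("additional_monitoring", "orphan", "biosimilar", "conditional_approval")) {
    md[[col]] <- ifelse(md[[col]], "true", "false")
  }
  utils::write.csv(md, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
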