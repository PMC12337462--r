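# Shared simulation helpers for the test suite. All generators take explicit
# seeds so every test is reproducible in isolation.

# Sentiment table drawn from the mixed model's data-generating process:
# document random intercept, additive model/gender/max-tokens effects.
sim_sentiment_table <- function(n_docs, beta_gender = -0.01, seed,
                                models = c("bart", "gemma"),
                                levels = c("50", "100"),
                                sd_doc = 0.05, sd_e = 0.03,
                                beta_inter_tokens = 0) {
  set.seed(seed)
  ids <- sprintf("d%04d", seq_len(n_docs))
  g <- expand.grid(doc_id = ids, gender = c("female", "male"), model = models,
                   max_tokens = levels, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  u <- stats::rnorm(n_docs, 0, sd_doc)
  names(u) <- ids
  is_male <- g$gender == "male"
  g$sentiment <- 0.4 +
    0.02 * (g$model != models[1]) +
    beta_gender * is_male +
    0.01 * (g$max_tokens != levels[1]) +
    beta_inter_tokens * (g$max_tokens != levels[1]) * is_male +
    u[g$doc_id] + stats::rnorm(nrow(g), 0, sd_e)
  g
}

# Minimal doc_term_matrix wrapper around a single simulated lemma, for
# regression recovery tests that bypass text processing.
sim_word_dtm <- function(n_docs, beta_gender, seed, base_log_rate = 0.3,
                         levels = c("50", "100"), beta_tokens = 0.2,
                         sd_doc = 0.3) {
  set.seed(seed)
  ids <- sprintf("d%04d", seq_len(n_docs))
  ann <- expand.grid(doc_id = ids, gender = c("female", "male"),
                     max_tokens = levels, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  ann$model <- "sim"
  d_eff <- stats::rnorm(n_docs, 0, sd_doc)
  names(d_eff) <- ids
  eta <- base_log_rate + d_eff[ann$doc_id] +
    beta_gender * (ann$gender == "male") +
    beta_tokens * (ann$max_tokens != levels[1])
  y <- stats::rpois(nrow(ann), exp(eta))
  counts <- Matrix::Matrix(matrix(y, ncol = 1, dimnames = list(NULL, "simword")),
                           sparse = TRUE)
  structure(list(counts = counts,
                 annotations = ann[, c("doc_id", "gender", "model", "max_tokens")],
                 vocabulary = "simword"),
            class = "doc_term_matrix")
}

# Tiny corpus of hand-written documents for corpus-prep tests.
make_doc <- function(doc_id, text, gender = "female") {
  data.frame(doc_id = doc_id, text = text, gender = gender,
             stringsAsFactors = FALSE)
}

words_of_length <- function(n, word = "note") {
  paste(rep(word, n), collapse = " ")
}
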