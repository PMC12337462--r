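test_that("eligibility filter keeps the inclusive 200-500 word band and partitions the input", {
  docs <- do.call(rbind, lapply(c(199, 200, 500, 501), function(n) {
    make_doc(paste0("len", n), words_of_length(n))
  }))
  res <- filter_eligible(as_care_corpus(docs))
  expect_setequal(res$corpus$doc_id, c("len200", "len500"))
  expect_equal(unname(res$report["n_too_short"]), 1L)
  expect_equal(unname(res$report["n_too_long"]), 1L)
  expect_equal(sum(res$report[c("n_too_short", "n_too_long", "n_excluded_terms",
                                "n_near_duplicate", "n_kept")]),
               unname(res$report["n_input"]))
})

test_that("exclusion terms remove sex-specific content case-insensitively at word boundaries", {
  base <- words_of_length(250)
  docs <- rbind(
    make_doc("a", paste(base, "There is a history of Mastectomy.")),
    make_doc("b", paste(base, "No relevant surgical history.")),
    make_doc("c", paste(base, "mastectomyish is not a word match."))
  )
  res <- filter_eligible(as_care_corpus(docs))
  expect_equal(unname(res$report["n_excluded_terms"]), 1L)
  expect_setequal(res$corpus$doc_id, c("b", "c"))
})

test_that("filter report sums to input size across mixed outcomes", {
  lens <- c(50, 120, 180, rep(250, 7))
  docs <- do.call(rbind, lapply(seq_along(lens), function(i) {
    make_doc(paste0("d", i), words_of_length(lens[i]))
  }))
  res <- filter_eligible(as_care_corpus(docs))
  expect_equal(unname(res$report["n_kept"]), 7L)
  expect_equal(unname(res$report["n_input"]), 10L)
  expect_equal(nrow(res$corpus), 7L)
})

test_that("empty corpus filters to an empty result with a zeroed report", {
  empty <- as_care_corpus(data.frame(doc_id = character(0), text = character(0),
                                     gender = character(0)))
  res <- filter_eligible(empty)
  expect_equal(nrow(res$corpus), 0L)
  expect_true(all(res$report == 0))
})

test_that("near-duplicate removal matches a brute-force Jaccard oracle", {
  set.seed(7)
  vocab <- c("care", "support", "visit", "home", "plan", "daily", "meal",
             "family", "review", "worker", "morning", "evening", "week")
  words <- sample(vocab, 300, replace = TRUE)
  doc1 <- paste(words, collapse = " ")
  words2 <- words
  words2[150] <- "changed"
  doc2 <- paste(words2, collapse = " ")
  # independent oracle: direct shingle-set Jaccard
  shingle <- function(w, k = 5) {
    vapply(seq_len(length(w) - k + 1), function(i) paste(w[i:(i + k - 1)], collapse = " "),
           character(1))
  }
  s1 <- unique(shingle(words)); s2 <- unique(shingle(words2))
  jac <- length(intersect(s1, s2)) / length(union(s1, s2))
  expect_gt(jac, 0.9)  # the construction really is a near-duplicate
  corp <- as_care_corpus(rbind(make_doc("orig", doc1), make_doc("copy", doc2)))
  res <- dedupe_near(corp, shingle_size = 5, jaccard_threshold = 0.9)
  expect_equal(res$corpus$doc_id, "orig")
  expect_equal(res$n_removed, 1L)
})

test_that("dedupe keeps disjoint documents and collapses k identical copies to one", {
  a <- paste(rep("alpha beta gamma delta epsilon", 20), collapse = " ")
  b <- paste(rep("one two three four five", 20), collapse = " ")
  corp <- as_care_corpus(rbind(make_doc("a", a), make_doc("b", b)))
  expect_equal(nrow(dedupe_near(corp)$corpus), 2L)
  for (k in c(2, 4)) {
    copies <- do.call(rbind, lapply(seq_len(k), function(i) make_doc(paste0("c", i), a)))
    res <- dedupe_near(as_care_corpus(copies))
    expect_equal(res$corpus$doc_id, "c1")
  }
})

test_that("gender swap reproduces the worked counterfactual sentence pair", {
  orig <- paste("Mrs Smith is an 87 year old, white British woman with reduced mobility.",
                "She cannot mobilise independently at home in her one-bedroom flat.")
  swapped <- paste("Mr Smith is an 87 year old, white British man with reduced mobility.",
                   "He cannot mobilise independently at home in his one-bedroom flat.")
  expect_equal(swap_gender(orig, direction = "f2m"), swapped)
})

test_that("possessive and objective 'her' are disambiguated by context", {
  expect_equal(swap_gender("I saw her leave her coat.", direction = "f2m"),
               "I saw him leave his coat.")
  expect_equal(swap_gender("Staff spoke to her about her medication.", direction = "f2m"),
               "Staff spoke to him about his medication.")
})

test_that("swap is an involution on texts with only unambiguous gendered tokens", {
  texts <- c(
    "Mrs Jones is a woman who lives with herself in mind. She is settled.",
    "The lady spoke to the social worker. She was happy.",
    "His wife and daughter visit him. He is a man of routine."
  )
  for (tx in texts[1:2]) {
    expect_equal(swap_gender(swap_gender(tx, direction = "f2m"), direction = "m2f"), tx)
  }
  # non-gendered tokens are byte-identical after a swap
  out <- swap_gender(texts[1], direction = "f2m")
  toks_in <- strsplit(texts[1], " ")[[1]]
  toks_out <- strsplit(out, " ")[[1]]
  gendered <- c("Mrs", "woman", "She", "herself", "Mr", "man", "He", "himself")
  same <- !(gsub("[^A-Za-z]", "", toks_in) %in% gendered)
  expect_identical(toks_in[same], toks_out[same])
})

test_that("pair validation accepts the worked example and identical texts", {
  f <- paste("Mrs Smith is an 87 year old, white British woman with reduced mobility.",
             "She cannot mobilise independently at home in her one-bedroom flat.")
  m <- swap_gender(f, direction = "f2m")
  v <- validate_pair(list(doc_id = "t1", female_text = f, male_text = m))
  expect_true(v$validated)
  v2 <- validate_pair(list(doc_id = "t2", female_text = f, male_text = f))
  expect_true(v2$validated)
})

test_that("an appended sentence on one side fails validation with a sentence-count mismatch", {
  f <- "She is capable of supporting herself. She does not require support."
  m <- paste(swap_gender(f, direction = "f2m"),
             "He continues to make unwise decisions about his care needs.")
  v <- validate_pair(list(doc_id = "t3", female_text = f, male_text = m))
  expect_false(v$validated)
  expect_match(v$mismatch, "sentence_count")
})

test_that("an altered non-gendered word count fails validation at the right sentence", {
  f <- "She is settled at home. The care plan works well for the family."
  m <- "He is settled at home. The new care plan works very well for the family."
  v <- validate_pair(list(doc_id = "t4", female_text = f, male_text = m))
  expect_false(v$validated)
  expect_match(v$mismatch, "sentence 2")
})
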