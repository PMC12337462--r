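test_that("theme terms are counted at lemma level within summaries", {
  rec <- data.frame(doc_id = "d1", gender = "female", model = "m",
                    max_tokens = "50",
                    summary_text = "He is anxious and agitated.",
                    stringsAsFactors = FALSE)
  lex <- list(mental_health = c("anxious", "agitated"))
  counts <- count_theme_terms(rec, lex)
  expect_equal(counts$count_female, 2L)
  # inflections count through the lemmatiser
  rec$summary_text <- "There were several falls and constant pain."
  counts2 <- count_theme_terms(rec, list(physical_health = c("fall", "pain")))
  expect_equal(counts2$count_female, 2L)
})

test_that("identical texts in both genders give identical counts", {
  txt <- "The person is anxious about the fall."
  rec <- data.frame(doc_id = c("d1", "d1"), gender = c("female", "male"),
                    model = "m", max_tokens = "50",
                    summary_text = c(txt, txt), stringsAsFactors = FALSE)
  counts <- count_theme_terms(rec, list(mental_health = "anxious",
                                        physical_health = "fall"))
  expect_equal(counts$count_female, counts$count_male)
})

test_that("planted term occurrences are recovered exactly", {
  f <- c(rep("She is anxious today.", 5), rep("She is settled.", 2),
         "She is anxious and anxious again.")
  m <- c(rep("He is anxious today.", 3), rep("He is settled.", 5))
  rec <- data.frame(doc_id = paste0("d", seq_along(c(f, m))),
                    gender = rep(c("female", "male"), c(length(f), length(m))),
                    model = "m", max_tokens = "50",
                    summary_text = c(f, m), stringsAsFactors = FALSE)
  counts <- count_theme_terms(rec, list(mental_health = "anxious"))
  expect_equal(counts$count_female, 7L)
  expect_equal(counts$count_male, 3L)
})

test_that("the goodness-of-fit chi-squared matches its closed form", {
  expect_equal(theme_chisq(10, 10)$statistic, 0)
  expect_equal(theme_chisq(10, 10)$p, 1)
  r <- theme_chisq(30, 10)
  expect_equal(r$statistic, 10)  # (30-20)^2/20 + (10-20)^2/20
  expect_equal(r$p, stats::pchisq(10, df = 1, lower.tail = FALSE))
  expect_equal(theme_chisq(0, 20)$statistic, 20)
  z <- theme_chisq(0, 0)
  expect_true(z$undefined)
  expect_true(is.na(z$p))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696)
  # independent step-up oracle: cumulative minimum of m*p/i from the largest
  m <- length(p); o <- order(p, decreasing = TRUE)
  oracle <- numeric(m); running <- 1
  for (i in seq_along(o)) {
    k <- o[i]
    running <- min(running, m * p[k] / rank(p)[k])
    oracle[k] <- running
  }
  expect_equal(bh_adjust(p), oracle)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted values never fall below raw ones and are capped at 1
  set.seed(1)
  q <- runif(50)
  adj <- bh_adjust(q)
  expect_true(all(adj >= q) && all(adj <= 1))
})

test_that("the theme test family is BH-adjusted jointly across models", {
  counts <- data.frame(model = rep(c("m1", "m2"), each = 2),
                       theme = rep(c("a", "b"), 2),
                       count_female = c(30, 10, 12, 200),
                       count_male = c(10, 11, 12, 210),
                       stringsAsFactors = FALSE)
  res <- test_inclusion_bias(counts)
  expect_equal(res$p_adjusted, bh_adjust(res$p))
  expect_equal(res$statistic[1], 10)
})

test_that("gendered-token-free lexicons count equally across genders of a null run", {
  pairs <- generate_pairs(synthetic_config(n_docs = 12, seed = 31))
  rec <- run_summarization(pairs, mock_summarizer(),
                           build_grid(pairs$doc_id, "mock", c("75", "None")))
  counts <- count_theme_terms(rec)
  expect_equal(counts$count_female, counts$count_male)
})
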