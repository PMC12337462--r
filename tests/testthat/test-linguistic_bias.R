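word_rec <- function(texts, genders = rep("female", length(texts)),
                     doc_ids = paste0("d", seq_along(texts))) {
  data.frame(doc_id = doc_ids, gender = genders, model = "m",
             max_tokens = "50", summary_text = texts, stringsAsFactors = FALSE)
}

test_that("the document-term matrix lemmatises, drops stop words and out-of-dictionary tokens", {
  dtm <- build_doc_term_matrix(word_rec("She was walking and walked daily. The zzqx is here."))
  expect_equal(unname(dtm$counts[1, "walk"]), 2)
  expect_false("zzqx" %in% dtm$vocabulary)
  expect_false(any(c("the", "and", "was") %in% dtm$vocabulary))
  # an empty summary row is all zero but keeps the shared vocabulary
  dtm2 <- build_doc_term_matrix(word_rec(c("He walked home.", "Mr Mr Mr.")))
  expect_equal(sum(dtm2$counts[2, ]), 0)
  expect_error(build_doc_term_matrix(word_rec("zzqx qxzz.")), "empty vocabulary")
})

test_that("count tests route to Fisher below 5 and to chi-squared otherwise", {
  fis <- word_count_test(12, 4, 1000, 1000)
  expect_equal(fis$test, "fisher")
  chi <- word_count_test(12, 5, 1000, 1000)
  expect_equal(chi$test, "chisq")
  sym <- word_count_test(50, 50, 2000, 2000)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p, 1)
  z <- word_count_test(0, 0, 100, 100)
  expect_true(z$skipped)
})

test_that("the Fisher branch matches full hypergeometric enumeration", {
  # oracle: sum P(X = k) over all tables with P(k) <= P(observed)
  fisher_oracle <- function(a, b, tf, tm) {
    n1 <- tf; n2 <- tm; k_tot <- a + b
    ks <- max(0, k_tot - n2):min(n1, k_tot)
    pr <- stats::dhyper(ks, n1, n2, k_tot)
    sum(pr[pr <= stats::dhyper(a, n1, n2, k_tot) * (1 + 1e-7)])
  }
  for (tbl in list(c(3, 9, 1000, 1000), c(0, 7, 500, 600), c(4, 4, 50, 80))) {
    got <- word_count_test(tbl[1], tbl[2], tbl[3], tbl[4])
    expect_equal(got$test, "fisher")
    expect_equal(got$p, fisher_oracle(tbl[1], tbl[2], tbl[3], tbl[4]),
                 tolerance = 1e-6)
  }
})

test_that("Firth Poisson matches brute-force penalised-likelihood maximisation", {
  X <- cbind(`(Intercept)` = 1, gendermale = c(0, 0, 1, 1),
             max_tokens100 = c(0, 1, 0, 1))
  y <- c(3, 2, 0, 1)
  pen_ll <- function(b) {
    mu <- exp(drop(X %*% b))
    I <- crossprod(X * mu, X)
    sum(y * log(mu) - mu) + 0.5 * as.numeric(determinant(I)$modulus)
  }
  oracle <- stats::optim(c(0, 0, 0), function(b) -pen_ll(b), method = "BFGS",
                         control = list(reltol = 1e-14))
  fit <- carefair:::firth_poisson(X, y)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients - oracle$par)), 1e-4)
})

test_that("perfect separation still yields finite estimates with finite standard errors", {
  # lemma never used for males: the unpenalised MLE diverges to -Inf
  texts <- c(rep("She walked to the garden daily.", 4),
             rep("He stayed in the flat.", 4))
  dtm <- build_doc_term_matrix(word_rec(c(texts),
                                        genders = rep(c("female", "male"), each = 4),
                                        doc_ids = rep(paste0("d", 1:4), 2)))
  fit <- fit_word_regression("garden", dtm)
  expect_true(is.finite(fit$beta_gender))
  expect_true(is.finite(fit$se_gender))
  expect_lt(fit$beta_gender, 0)  # female-leaning
})

test_that("Firth estimates approach the unpenalised MLE as documents grow", {
  gap <- function(n_docs) {
    dtm <- sim_word_dtm(n_docs, beta_gender = 0.4, seed = 50 + n_docs)
    d <- carefair:::word_design("simword", dtm)
    firth <- carefair:::firth_poisson(d$X, d$y)$coefficients["gendermale"]
    mle <- stats::glm.fit(d$X, d$y, family = stats::poisson())$coefficients["gendermale"]
    abs(firth - mle)
  }
  expect_lt(gap(400), gap(50))
})

test_that("the gender rate ratio is recovered across simulated replicates", {
  ests <- vapply(1:30, function(r) {
    dtm <- sim_word_dtm(100, beta_gender = log(1.5), seed = 600 + r)
    fit_word_regression("simword", dtm)$beta_gender
  }, numeric(1))
  expect_lt(abs(mean(ests) - log(1.5)), 0.05)
})

test_that("overdispersion arithmetic and flagging follow the Pearson ratio rule", {
  fake <- structure(list(pearson_residuals = c(2, 2), df_residual = 2),
                    class = "word_regression")
  r <- check_overdispersion(fake)
  expect_equal(r$ratio, 4)
  expect_true(r$flagged)
  perfect <- structure(list(pearson_residuals = c(0, 0, 0), df_residual = 3),
                       class = "word_regression")
  expect_false(check_overdispersion(perfect)$flagged)
  bad <- structure(list(pearson_residuals = 1, df_residual = 0),
                   class = "word_regression")
  expect_error(check_overdispersion(bad), "degrees of freedom")
})

test_that("equidispersed Poisson data rarely trips the overdispersion flag", {
  flags <- vapply(1:40, function(r) {
    dtm <- sim_word_dtm(40, beta_gender = 0.2, seed = 900 + r, sd_doc = 0.2)
    check_overdispersion(fit_word_regression("simword", dtm))$flagged
  }, logical(1))
  expect_lt(mean(flags), 0.15)
})

test_that("the negative binomial agrees with Poisson on equidispersed data and needs df", {
  dtm <- sim_word_dtm(60, beta_gender = 0.3, seed = 77)
  pois <- fit_word_regression("simword", dtm)
  nb <- fit_negative_binomial("simword", dtm)
  expect_lt(abs(nb$beta_gender - pois$beta_gender), 2 * pois$se_gender)
  tiny <- sim_word_dtm(1, beta_gender = 0, seed = 5, levels = "50")
  expect_error(fit_negative_binomial("simword", tiny), "degrees of freedom")
})

test_that("the dual criterion is the conjunction of both tests and a subset of each", {
  mk_reg <- function(lemma, p) {
    structure(list(lemma = lemma, beta_gender = 0.5, p_gender = p,
                   method = "firth_poisson"), class = "word_regression")
  }
  regs <- list(mk_reg("a", 0.001), mk_reg("b", 0.5), mk_reg("c", 0.01))
  cts <- data.frame(lemma = c("a", "b", "c"), count_female = c(10, 10, 10),
                    count_male = c(30, 30, 30), test = "chisq",
                    p = c(0.001, 0.001, 0.9), stringsAsFactors = FALSE)
  res <- apply_dual_criterion(regs, cts, alpha = 0.05)
  expect_true(res$dual_significant[res$lemma == "a"])
  expect_false(res$dual_significant[res$lemma == "b"])  # regression-only misses
  expect_false(res$dual_significant[res$lemma == "c"])  # count-only misses
  dual <- res$lemma[res$dual_significant]
  expect_true(all(dual %in% res$lemma[res$regression_p < 0.05]))
  expect_true(all(dual %in% res$lemma[res$p_adjusted < 0.05]))
  expect_error(apply_dual_criterion(regs[1:2], cts), "mismatch")
})
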