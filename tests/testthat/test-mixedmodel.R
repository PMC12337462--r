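test_that("an all-constant response gives the degenerate fit", {
  tab <- sim_sentiment_table(5, 0, seed = 1)
  tab$sentiment <- 0.37
  fit <- fit_sentiment_mixed_model(tab)
  expect_true(fit$degenerate)
  expect_equal(unname(coef(fit)["(Intercept)"]), 0.37)
  expect_equal(fit$sigma, 0)
})

test_that("one-gender data is a singular design error", {
  tab <- sim_sentiment_table(5, 0, seed = 2)
  expect_error(fit_sentiment_mixed_model(tab[tab$gender == "female", ]),
               "both genders")
})

test_that("with no cluster effect the fixed effects match an OLS oracle", {
  tab <- sim_sentiment_table(40, -0.02, seed = 3, sd_doc = 0, sd_e = 0.05)
  fit <- fit_sentiment_mixed_model(tab, random = "intercept")
  ols <- stats::lm(sentiment ~ model * gender + max_tokens,
                   data = transform(tab,
                                    model = factor(model, levels = c("bart", "gemma")),
                                    gender = factor(gender, levels = c("female", "male")),
                                    max_tokens = factor(max_tokens, levels = c("50", "100"))))
  expect_equal(coef(fit)[names(coef(ols))], coef(ols), tolerance = 1e-3)
  # fitted document variance collapses toward zero
  expect_lt(fit$ranef_vcov[1, 1], 1e-4)
})

test_that("the gender coefficient is recovered from its own data-generating process", {
  fit <- fit_sentiment_mixed_model(sim_sentiment_table(200, -0.01, seed = 4))
  b <- fit$coefficients["gendermale", ]
  expect_lt(abs(b$estimate - (-0.01)), 3 * b$se)
  expect_true(fit$converged)
})

test_that("EMM contrasts obey the exact algebra and match the emmeans oracle", {
  tab <- sim_sentiment_table(40, -0.02, seed = 5)
  fit <- fit_sentiment_mixed_model(tab)
  emm <- estimate_gender_emm(fit)
  b <- coef(fit)
  expect_equal(emm$estimate[emm$model == "bart"], unname(-b["gendermale"]))
  expect_equal(emm$estimate[emm$model == "gemma"],
               unname(-(b["gendermale"] + b["modelgemma:gendermale"])))
  skip_if_not_installed("emmeans")
  em <- emmeans::emmeans(fit$fit, ~ gender | model, lmer.df = "asymptotic")
  ctr <- as.data.frame(emmeans::contrast(em, method = list(fm = c(1, -1))))
  expect_equal(emm$estimate, ctr$estimate, tolerance = 1e-8)
  expect_equal(emm$se, ctr$SE, tolerance = 1e-6)
})

test_that("all-zero gender and interaction coefficients give zero contrasts", {
  beta <- c(`(Intercept)` = 0.3, modelgemma = 0.1, gendermale = 0,
            `modelgemma:gendermale` = 0)
  emm <- estimate_gender_emm(beta, models = c("bart", "gemma"))
  expect_equal(emm$estimate, c(0, 0))
})

test_that("the likelihood ratio test is zero on identical fits and rejects non-nested pairs", {
  tab <- sim_sentiment_table(20, -0.01, seed = 6)
  fit <- fit_sentiment_mixed_model(tab)
  lr <- likelihood_ratio_test(fit, fit)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)
  other <- fit_sentiment_mixed_model(sim_sentiment_table(21, -0.01, seed = 7))
  expect_error(likelihood_ratio_test(fit, other), "same data")
})

test_that("the LRT detects a true max-tokens by gender interaction", {
  n_rej <- 0
  for (r in 1:40) {
    tab <- sim_sentiment_table(60, -0.01, seed = 100 + r, models = "m1",
                               beta_inter_tokens = 0.03)
    full <- fit_sentiment_mixed_model(tab, max_tokens_gender_interaction = TRUE)
    red <- fit_sentiment_mixed_model(tab)
    if (likelihood_ratio_test(full, red)$p < 0.05) n_rej <- n_rej + 1
  }
  expect_gt(n_rej / 40, 0.8)
})

test_that("the cluster bootstrap is seed-deterministic with a degenerate B = 1 interval", {
  tab <- sim_sentiment_table(15, -0.02, seed = 8)
  b1 <- cluster_bootstrap(tab, B = 5, seed = 42, random = "intercept")
  b2 <- cluster_bootstrap(tab, B = 5, seed = 42, random = "intercept")
  expect_identical(b1$ci, b2$ci)
  expect_error(cluster_bootstrap(tab, B = 0, seed = 1), "B")
  single <- cluster_bootstrap(tab, B = 1, seed = 7, random = "intercept")
  expect_equal(single$ci$lower, single$ci$upper)
  # interval from a moderate B covers the point estimate
  fit <- fit_sentiment_mixed_model(tab, random = "intercept")
  g <- which(b1$ci$term == "gendermale")
  est <- unname(coef(fit)["gendermale"])
  boot <- cluster_bootstrap(tab, B = 30, seed = 9, random = "intercept")
  expect_true(boot$ci$lower[g] <= est && est <= boot$ci$upper[g])
})
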