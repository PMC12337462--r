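#' Build a lemma-level document-term matrix from summaries
#'
#' Tokenises each summary, removes stop words and punctuation, lemmatises,
#' and drops tokens whose lemma is not in the shipped dictionary snapshot.
#' The vocabulary is the union across all summaries, so both genders share
#' identical columns.
#'
#' @param records Summary records (from [run_summarization()]).
#' @param exclude_gendered Drop lemmas of gender-lexicon entries (default
#'   TRUE): on counterfactual pairs these differ between versions by
#'   construction, so they carry no information about summariser bias.
#' @return A `doc_term_matrix`: list with `counts` (sparse dgCMatrix, one row
#'   per summary), `annotations` (doc_id, gender, model, max_tokens) and
#'   `vocabulary`.
#' @export
build_doc_term_matrix <- function(records, exclude_gendered = TRUE) {
  dict <- carefair_dictionary()
  drop <- if (exclude_gendered) unique(lemmatize(gendered_forms(default_gender_lexicon()))) else character(0)
  lemma_lists <- lapply(records$summary_text, function(t) {
    lem <- content_lemmas(t, remove_stopwords = TRUE)
    lem[lem %in% dict & !(lem %in% drop)]
  })
  vocab <- sort(unique(unlist(lemma_lists)))
  if (length(vocab) == 0) stop("empty vocabulary after filtering", call. = FALSE)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (r in seq_along(lemma_lists)) {
    if (!length(lemma_lists[[r]])) next
    tab <- table(lemma_lists[[r]])
    ii <- c(ii, rep(r, length(tab)))
    jj <- c(jj, match(names(tab), vocab))
    xx <- c(xx, as.integer(tab))
  }
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(length(lemma_lists), length(vocab)),
                                 dimnames = list(NULL, vocab))
  structure(list(counts = counts,
                 annotations = records[, c("doc_id", "gender", "model", "max_tokens")],
                 vocabulary = vocab),
            class = "doc_term_matrix")
}

#' @export
print.doc_term_matrix <- function(x, ...) {
  cat(sprintf("Document-term matrix: %d summaries x %d lemmas (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  invisible(x)
}

#' Aggregate word-count test for one lemma
#'
#' Chi-squared test on the 2x2 table of (lemma count, all-other-token count)
#' by gender, except when either gender's count is below 5, where Fisher's
#' exact test is used instead. A goodness-of-fit variant testing the raw
#' count pair against equal expectation is available for the balanced
#' counterfactual design.
#'
#' @param count_female,count_male Aggregate lemma counts by gender.
#' @param total_female,total_male Total token counts by gender (exposure).
#' @param method `"exposure"` (2x2, default) or `"goodness_of_fit"`.
#' @return List (`test`, `statistic`, `p`, `skipped`). Both counts zero is
#'   untestable and returned skipped.
#' @export
word_count_test <- function(count_female, count_male, total_female, total_male,
                            method = c("exposure", "goodness_of_fit")) {
  method <- match.arg(method)
  stopifnot(total_female >= count_female, total_male >= count_male)
  if (count_female + count_male == 0) {
    return(list(test = NA_character_, statistic = NA_real_, p = NA_real_, skipped = TRUE))
  }
  use_fisher <- count_female < 5 || count_male < 5
  if (use_fisher) {
    tab <- rbind(c(count_female, total_female - count_female),
                 c(count_male, total_male - count_male))
    ht <- stats::fisher.test(tab)
    return(list(test = "fisher", statistic = NA_real_, p = ht$p.value, skipped = FALSE))
  }
  if (method == "exposure") {
    tab <- rbind(c(count_female, total_female - count_female),
                 c(count_male, total_male - count_male))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  } else {
    ht <- suppressWarnings(stats::chisq.test(c(count_female, count_male), p = c(0.5, 0.5)))
  }
  list(test = "chisq", statistic = unname(ht$statistic), p = unname(ht$p.value),
       skipped = FALSE)
}

# --- Firth-penalised Poisson regression -------------------------------------
#
# Maximises l(beta) + 0.5 log det I(beta) for a log-link Poisson GLM. For the
# canonical link the penalised score is X' (y - mu + h/2) with h the hat
# diagonal, so a damped Newton iteration on the modified score yields finite
# estimates even under perfect separation.
firth_poisson <- function(X, y, tol = 1e-8, maxit = 100) {
  p <- ncol(X); n <- nrow(X)
  beta <- numeric(p)
  if ("(Intercept)" %in% colnames(X)) beta[colnames(X) == "(Intercept)"] <- log(mean(y) + 0.1)
  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    if (any(eta > 30)) return(-Inf)
    mu <- exp(eta)
    I <- crossprod(X * mu, X)
    ld <- determinant(I, logarithm = TRUE)
    if (ld$sign <= 0) return(-Inf)
    sum(y * eta - mu) + 0.5 * as.numeric(ld$modulus)
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(pmin(eta, 30))
    I <- crossprod(X * mu, X)
    Iinv <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(Iinv)) {
      Iinv <- solve(I + diag(1e-8, p))
    }
    h <- rowSums((X %*% Iinv) * X) * mu
    score <- drop(crossprod(X, y - mu + h / 2))
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    step <- drop(Iinv %*% score)
    # damp the step until the penalised log-likelihood does not decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- pen_ll(cand)
      if (ll_new >= ll_old - 1e-10 || lam < 1e-6) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    ll_old <- pen_ll(beta)
  }
  eta <- drop(X %*% beta)
  mu <- exp(pmin(eta, 30))
  I <- crossprod(X * mu, X)
  Iinv <- tryCatch(solve(I), error = function(e) solve(I + diag(1e-8, p)))
  se <- sqrt(diag(Iinv))
  list(coefficients = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       fitted = mu, penalized_loglik = ll_old,
       converged = converged, iterations = it)
}

word_design <- function(lemma, dtm, model = NULL) {
  ann <- dtm$annotations
  sel_model <- if (is.null(model)) rep(TRUE, nrow(ann)) else ann$model == model
  y_all <- dtm$counts[, lemma]
  docs_with <- unique(ann$doc_id[sel_model & y_all > 0])
  rows <- which(sel_model & ann$doc_id %in% docs_with)
  if (!length(rows)) stop("lemma '", lemma, "' appears in no summary", call. = FALSE)
  df <- data.frame(y = as.integer(y_all[rows]),
                   gender = factor(ann$gender[rows], levels = c("female", "male")),
                   max_tokens = factor(as.character(ann$max_tokens[rows]),
                                       levels = intersect(c(default_max_tokens_levels(),
                                                            unique(as.character(ann$max_tokens[rows]))),
                                                          unique(as.character(ann$max_tokens[rows])))),
                   doc_id = factor(ann$doc_id[rows]))
  terms <- "gender"
  if (nlevels(df$max_tokens) > 1) terms <- c(terms, "max_tokens")
  if (nlevels(df$doc_id) > 1) terms <- c(terms, "doc_id")
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, df)
  list(X = X, y = df$y, df = df)
}

#' Firth-penalised Poisson regression for one lemma
#'
#' Document-level word-count regression: for the given lemma, rows are all
#' summaries belonging to documents where the lemma appears at least once
#' (structural zeros within those documents are retained, since the gender
#' contrast lives in within-document zero/nonzero variation). The linear
#' predictor contains gender, the max-tokens factor and document fixed
#' effects; Jeffreys-prior penalisation keeps estimates finite under perfect
#' separation (a lemma never used for one gender). Document coefficients are
#' estimated but not reported.
#'
#' @param lemma A vocabulary entry of `dtm`.
#' @param dtm A `doc_term_matrix`.
#' @param model Restrict to one summarisation model's rows (default: all).
#' @param tol Convergence tolerance on the modified-score norm.
#' @param maxit Maximum Newton iterations.
#' @return A `word_regression` object: gender coefficient with SE and Wald p,
#'   Pearson-residual dispersion diagnostics, method flag, full coefficient
#'   vector.
#' @export
fit_word_regression <- function(lemma, dtm, model = NULL, tol = 1e-8, maxit = 100) {
  d <- word_design(lemma, dtm, model)
  fit <- firth_poisson(d$X, d$y, tol = tol, maxit = maxit)
  mu <- fit$fitted
  pearson <- (d$y - mu) / sqrt(mu)
  df_resid <- nrow(d$X) - ncol(d$X)
  b <- fit$coefficients["gendermale"]
  se <- fit$se["gendermale"]
  z <- b / se
  structure(list(lemma = lemma,
                 beta_gender = unname(b), se_gender = unname(se),
                 p_gender = unname(2 * stats::pnorm(-abs(z))),
                 coefficients = fit$coefficients, se = fit$se,
                 pearson_residuals = pearson, df_residual = df_resid,
                 dispersion_ratio = if (df_resid > 0) sum(pearson^2) / df_resid else NA_real_,
                 method = "firth_poisson", converged = fit$converged,
                 iterations = fit$iterations, n = nrow(d$X),
                 penalized_loglik = fit$penalized_loglik),
            class = "word_regression")
}

#' @export
print.word_regression <- function(x, ...) {
  cat(sprintf("Word regression (%s) for '%s': beta_gender = %.3f (SE %.3f, p = %.3g)%s\n",
              x$method, x$lemma, x$beta_gender, x$se_gender, x$p_gender,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  cat(sprintf("  n = %d, df_residual = %d, dispersion ratio = %.3f\n",
              x$n, x$df_residual, x$dispersion_ratio))
  invisible(x)
}

#' Overdispersion check for a word regression
#'
#' Ratio of the Pearson residual sum of squares to the residual degrees of
#' freedom; ratios above the threshold flag the lemma for a
#' negative-binomial refit.
#'
#' @param result A `word_regression`.
#' @param threshold Flagging threshold (default 1.25).
#' @return List (`ratio`, `flagged`).
#' @export
check_overdispersion <- function(result, threshold = 1.25) {
  if (is.na(result$df_residual) || result$df_residual <= 0) {
    stop("no residual degrees of freedom", call. = FALSE)
  }
  ratio <- sum(result$pearson_residuals^2) / result$df_residual
  list(ratio = ratio, flagged = ratio > threshold)
}

#' Negative-binomial refit for an overdispersed lemma
#'
#' Maximum-likelihood negative binomial (log link) on the same design as the
#' Poisson word regression. On non-convergence the Firth Poisson result is
#' returned instead, flagged as a fallback.
#'
#' @inheritParams fit_word_regression
#' @return A `word_regression` with `method = "negative_binomial"` (or the
#'   Poisson fallback with `nb_fallback = TRUE`).
#' @export
fit_negative_binomial <- function(lemma, dtm, model = NULL) {
  d <- word_design(lemma, dtm, model)
  if (nrow(d$X) <= ncol(d$X)) stop("insufficient residual degrees of freedom", call. = FALSE)
  nb <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ . - 1, data = cbind(d$df["y"], as.data.frame(d$X)))),
    error = function(e) NULL)
  if (is.null(nb) || !nb$converged) {
    out <- fit_word_regression(lemma, dtm, model)
    out$nb_fallback <- TRUE
    return(out)
  }
  co <- summary(nb)$coefficients
  gk <- grep("gendermale", rownames(co))
  mu <- stats::fitted(nb)
  pearson <- (d$y - mu) / sqrt(mu + mu^2 / nb$theta)
  df_resid <- nrow(d$X) - ncol(d$X)
  structure(list(lemma = lemma,
                 beta_gender = co[gk, 1], se_gender = co[gk, 2],
                 p_gender = co[gk, 4],
                 coefficients = stats::setNames(co[, 1], rownames(co)),
                 se = stats::setNames(co[, 2], rownames(co)),
                 pearson_residuals = pearson, df_residual = df_resid,
                 dispersion_ratio = if (df_resid > 0) sum(pearson^2) / df_resid else NA_real_,
                 method = "negative_binomial", converged = TRUE,
                 theta = nb$theta, n = nrow(d$X), nb_fallback = FALSE),
            class = "word_regression")
}

#' Combine regression and count tests into the dual criterion
#'
#' A lemma counts as used significantly differently by gender only when its
#' regression p-value and its BH-adjusted count-test p-value are both below
#' `alpha`. Output is sorted by gender direction, then by absolute gender
#' coefficient, descending.
#'
#' @param regression_results List of `word_regression` objects.
#' @param count_tests Data frame with columns `lemma`, `count_female`,
#'   `count_male`, `test`, `p` (one row per lemma; the BH family).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `word_test_results`: counts, direction,
#'   coefficient, regression p, count-test p, BH-adjusted p,
#'   `dual_significant`.
#' @export
apply_dual_criterion <- function(regression_results, count_tests, alpha = 0.05) {
  reg_lemmas <- vapply(regression_results, function(r) r$lemma, character(1))
  if (!setequal(reg_lemmas, count_tests$lemma)) {
    stop("vocabulary mismatch between regression and count-test results", call. = FALSE)
  }
  count_tests$p_adjusted <- bh_adjust(count_tests$p)
  ord <- match(count_tests$lemma, reg_lemmas)
  count_tests$coefficient <- vapply(regression_results[ord], function(r) r$beta_gender, numeric(1))
  count_tests$regression_p <- vapply(regression_results[ord], function(r) r$p_gender, numeric(1))
  count_tests$method <- vapply(regression_results[ord], function(r) r$method, character(1))
  count_tests$direction <- ifelse(count_tests$coefficient > 0, "male", "female")
  count_tests$dual_significant <- !is.na(count_tests$regression_p) &
    !is.na(count_tests$p_adjusted) &
    count_tests$regression_p < alpha & count_tests$p_adjusted < alpha
  out <- count_tests[order(count_tests$direction,
                           -abs(count_tests$coefficient)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("word_test_results", class(out))
  out
}

#' Word-level linguistic-bias analysis for one or all models
#'
#' Orchestrates, per summarisation model: aggregate count tests
#' (chi-squared / Fisher routing) for every lemma passing the minimum-count
#' gate, Firth-penalised Poisson regressions with negative-binomial refits
#' where overdispersed, BH adjustment of the count-test family within the
#' model, and the dual criterion.
#'
#' @param dtm A `doc_term_matrix`.
#' @param alpha Significance level (default 0.05).
#' @param count_method Passed to [word_count_test()].
#' @param min_count Lemmas with total count below this are skipped as
#'   untestable (default 2).
#' @param overdispersion_threshold Pearson ratio above which the
#'   negative-binomial refit replaces the Poisson inference (default 1.25).
#' @return A `word_test_results` data frame with a `model` column.
#' @export
analyze_linguistic_bias <- function(dtm, alpha = 0.05,
                                    count_method = "exposure", min_count = 2,
                                    overdispersion_threshold = 1.25) {
  ann <- dtm$annotations
  out <- list()
  for (m in unique(ann$model)) {
    sel_f <- ann$model == m & ann$gender == "female"
    sel_m <- ann$model == m & ann$gender == "male"
    cf <- Matrix::colSums(dtm$counts[sel_f, , drop = FALSE])
    cm <- Matrix::colSums(dtm$counts[sel_m, , drop = FALSE])
    tf <- sum(cf); tm <- sum(cm)
    testable <- names(which(cf + cm >= min_count))
    if (!length(testable)) next
    counts <- data.frame(lemma = testable, count_female = cf[testable],
                         count_male = cm[testable], test = NA_character_,
                         p = NA_real_, stringsAsFactors = FALSE, row.names = NULL)
    regs <- vector("list", length(testable))
    for (k in seq_along(testable)) {
      w <- testable[k]
      ct <- word_count_test(counts$count_female[k], counts$count_male[k], tf, tm,
                            method = count_method)
      counts$test[k] <- ct$test
      counts$p[k] <- ct$p
      reg <- fit_word_regression(w, dtm, model = m)
      od <- check_overdispersion(reg, overdispersion_threshold)
      if (od$flagged) reg <- fit_negative_binomial(w, dtm, model = m)
      regs[[k]] <- reg
    }
    res <- apply_dual_criterion(regs, counts, alpha = alpha)
    res$model <- m
    out[[length(out) + 1L]] <- res
  }
  res <- do.call(rbind, out)
  class(res) <- c("word_test_results", "data.frame")
  res
}
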