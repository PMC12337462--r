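sentiment_factors <- function(table) {
  table <- as.data.frame(table)
  stopifnot(all(c("doc_id", "model", "gender", "max_tokens", "sentiment") %in% names(table)))
  if (length(unique(table$gender)) < 2) stop("both genders required", call. = FALSE)
  if (length(unique(table$doc_id)) < 2) stop("at least 2 documents required", call. = FALSE)
  models <- unique(table$model)
  if ("bart" %in% models) models <- c("bart", setdiff(models, "bart"))
  lvls <- default_max_tokens_levels()
  present <- unique(as.character(table$max_tokens))
  lvl_order <- c(intersect(lvls, present), setdiff(present, lvls))
  table$model <- factor(table$model, levels = models)
  table$gender <- factor(table$gender, levels = c("female", "male"))
  table$max_tokens <- factor(as.character(table$max_tokens), levels = lvl_order)
  table$doc_id <- factor(table$doc_id)
  table
}

#' Fit the sentiment mixed model
#'
#' Linear mixed model for per-summary sentiment: fixed effects for
#' summarisation model, gender, their interaction and the max-tokens factor
#' (reference levels BART and 50); random per-document intercepts varying by
#' model (unstructured covariance), collapsing to a plain document intercept
#' when only one model is present. Fitted by maximum likelihood so nested
#' fits can be compared with a likelihood ratio test.
#'
#' @param table A `sentiment_table` (columns `doc_id`, `model`, `gender`,
#'   `max_tokens`, `sentiment`).
#' @param gender_interaction Include model x gender interaction (default TRUE).
#' @param max_tokens_gender_interaction Also include max-tokens x gender
#'   (default FALSE; kept for likelihood-ratio comparisons).
#' @param covariates Optional character vector of extra fixed-effect columns
#'   (e.g. age, ethnicity); off by default.
#' @param random Random-effects structure: `"by_model"` (default; intercept
#'   varying by model when >1 model) or `"intercept"` (document intercept
#'   only, useful for large simulation studies).
#' @return A `sentiment_lmm` object: coefficient table with Wald z tests,
#'   fixed-effect covariance, log-likelihood, random-effect variances,
#'   convergence/singularity flags, and the underlying lme4 fit.
#' @export
fit_sentiment_mixed_model <- function(table, gender_interaction = TRUE,
                                      max_tokens_gender_interaction = FALSE,
                                      covariates = NULL,
                                      random = c("by_model", "intercept")) {
  random <- match.arg(random)
  table <- sentiment_factors(table)
  n_models <- nlevels(table$model)
  n_levels <- nlevels(table$max_tokens)

  if (stats::var(table$sentiment) == 0) {
    return(degenerate_lmm(table))
  }

  fixed <- if (n_models > 1 && gender_interaction) "model * gender" else
    if (n_models > 1) "model + gender" else "gender"
  if (n_levels > 1) fixed <- paste(fixed, "+ max_tokens")
  if (max_tokens_gender_interaction && n_levels > 1) {
    fixed <- paste(fixed, "+ max_tokens:gender")
  }
  if (!is.null(covariates)) fixed <- paste(fixed, "+", paste(covariates, collapse = " + "))
  ranef_term <- if (n_models > 1 && random == "by_model") "(1 + model | doc_id)" else "(1 | doc_id)"
  fml <- stats::as.formula(paste("sentiment ~", fixed, "+", ranef_term))

  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = table, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(conv_msgs) || !any(grepl("failed to converge", conv_msgs))
  singular <- lme4::isSingular(fit, tol = 1e-5)

  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "se", "t")[seq_len(min(3, ncol(co)))]
  co$z <- co$estimate / co$se
  co$p <- 2 * stats::pnorm(-abs(co$z))

  vc <- lme4::VarCorr(fit)
  structure(list(
    coefficients = co,
    vcov = as.matrix(stats::vcov(fit)),
    logLik = as.numeric(stats::logLik(fit)),
    df = attr(stats::logLik(fit), "df"),
    sigma = stats::sigma(fit),
    ranef_vcov = as.matrix(Matrix::bdiag(lapply(vc, function(m) matrix(as.numeric(m), nrow = nrow(m))))),
    converged = converged,
    singular = singular,
    models = levels(table$model),
    formula = fml,
    n_docs = nlevels(table$doc_id),
    n_obs = nrow(table),
    fit = fit,
    degenerate = FALSE
  ), class = "sentiment_lmm")
}

degenerate_lmm <- function(table) {
  # all responses identical: intercept = the constant, everything else 0
  fml <- sentiment ~ 1
  mm_terms <- "(Intercept)"
  co <- data.frame(estimate = table$sentiment[1], se = 0, z = NA_real_, p = NA_real_,
                   row.names = mm_terms)
  structure(list(coefficients = co, vcov = matrix(0, 1, 1, dimnames = list(mm_terms, mm_terms)),
                 logLik = NA_real_, df = 1, sigma = 0,
                 ranef_vcov = matrix(0, 1, 1), converged = TRUE, singular = TRUE,
                 models = levels(table$model), formula = fml,
                 n_docs = nlevels(table$doc_id), n_obs = nrow(table),
                 fit = NULL, degenerate = TRUE),
            class = "sentiment_lmm")
}

#' @export
print.sentiment_lmm <- function(x, ...) {
  cat("Sentiment linear mixed model (ML)\n")
  cat("  ", deparse(x$formula), "\n")
  cat(sprintf("  %d observations, %d documents; logLik = %.2f%s%s\n",
              x$n_obs, x$n_docs, x$logLik,
              if (!x$converged) "; NOT CONVERGED" else "",
              if (x$singular) "; singular random-effects fit" else ""))
  stats::printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "z", "p")]),
                      P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
summary.sentiment_lmm <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    cat("\nRandom effects:\n")
    print(lme4::VarCorr(object$fit))
  }
  invisible(object)
}

#' @export
coef.sentiment_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, rownames(object$coefficients))
}

#' @export
logLik.sentiment_lmm <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' Estimated marginal gender contrasts per model
#'
#' For each summarisation model, the female minus male contrast of estimated
#' marginal means over a balanced max-tokens grid. Because max-tokens enters
#' additively, the contrast reduces algebraically to `-(beta_gender)` for the
#' reference model and `-(beta_gender + beta_interaction[m])` otherwise;
#' standard errors follow by the delta method from the fixed-effect
#' covariance.
#'
#' @param object A converged `sentiment_lmm`, or a named coefficient vector
#'   (names as in the fitted model: `gendermale`, `modelX:gendermale`).
#' @param vcov Optional fixed-effect covariance matrix when `object` is a
#'   plain coefficient vector.
#' @param models Model names; taken from the fit, or inferred from
#'   interaction coefficient names for a plain vector.
#' @param reference Reference model name (first of `models` by default).
#' @param ... Unused.
#' @return Data frame (`model`, `estimate`, `se`, `statistic`, `p`) of class
#'   `emm_contrasts`; `estimate` is female minus male.
#' @export
estimate_gender_emm <- function(object, ...) UseMethod("estimate_gender_emm")

#' @rdname estimate_gender_emm
#' @export
estimate_gender_emm.sentiment_lmm <- function(object, ...) {
  if (!object$converged) stop("cannot compute contrasts from a non-converged fit", call. = FALSE)
  beta <- stats::setNames(object$coefficients$estimate, rownames(object$coefficients))
  emm_from_coefs(beta, object$vcov, models = object$models)
}

#' @rdname estimate_gender_emm
#' @export
estimate_gender_emm.numeric <- function(object, vcov = NULL, models = NULL,
                                        reference = NULL, ...) {
  emm_from_coefs(object, vcov, models = models, reference = reference)
}

emm_from_coefs <- function(beta, V = NULL, models = NULL, reference = NULL) {
  nm <- names(beta)
  if (is.null(nm)) stop("coefficients must be named", call. = FALSE)
  if (!("gendermale" %in% nm)) stop("no 'gendermale' coefficient", call. = FALSE)
  inter <- grep("^model.*:gendermale$", nm, value = TRUE)
  inter_models <- sub("^model(.*):gendermale$", "\\1", inter)
  if (is.null(models)) {
    non_ref <- sub("^model(.*)$", "\\1", setdiff(grep("^model[^:]*$", nm, value = TRUE), character(0)))
    models <- c(if (is.null(reference)) "(reference)" else reference, non_ref)
  }
  if (is.null(reference)) reference <- models[1]
  out <- data.frame(model = models, estimate = NA_real_, se = NA_real_,
                    statistic = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(models)) {
    m <- models[i]
    cvec <- stats::setNames(numeric(length(beta)), nm)
    cvec["gendermale"] <- -1
    if (m != reference) {
      key <- paste0("model", m, ":gendermale")
      if (key %in% nm) cvec[key] <- -1
    }
    out$estimate[i] <- sum(cvec * beta)
    if (!is.null(V)) {
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      out$se[i] <- se
      out$statistic[i] <- out$estimate[i] / se
      out$p[i] <- 2 * stats::pnorm(-abs(out$statistic[i]))
    }
  }
  class(out) <- c("emm_contrasts", class(out))
  out
}

#' @export
print.emm_contrasts <- function(x, ...) {
  cat("Estimated marginal mean effect of gender (female - male)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Likelihood ratio test between nested sentiment fits
#'
#' @param fit_full,fit_reduced `sentiment_lmm` objects fitted by ML on the
#'   same data, the reduced model's fixed effects a subset of the full one's.
#' @return List (`statistic`, `df`, `p`) of class `carefair_lrt`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "sentiment_lmm"), inherits(fit_reduced, "sentiment_lmm"))
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop("fits are not on the same data", call. = FALSE)
  }
  nm_full <- rownames(fit_full$coefficients)
  nm_red <- rownames(fit_reduced$coefficients)
  if (!all(nm_red %in% nm_full)) {
    stop("models are not nested (reduced fixed effects not a subset)", call. = FALSE)
  }
  df <- fit_full$df - fit_reduced$df
  if (df < 0) stop("full model has fewer parameters than reduced", call. = FALSE)
  stat <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p), class = "carefair_lrt")
}

#' @export
print.carefair_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chisq = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Cluster bootstrap of the sentiment mixed model
#'
#' Resamples documents (the clustering unit) with replacement, refits the
#' model on each replicate, and returns percentile confidence intervals for
#' the fixed effects. Fully seeded; identical seeds give identical intervals.
#'
#' @param table A `sentiment_table`.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param conf Interval level (default 0.95).
#' @param ... Passed to [fit_sentiment_mixed_model()].
#' @return List with `ci` (data frame: term, lower, upper), `replicates`
#'   (B x p matrix of fixed effects), `B`, `seed`.
#' @export
cluster_bootstrap <- function(table, B, seed, conf = 0.95, ...) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  table <- as.data.frame(table)
  docs <- unique(table$doc_id)
  rows_by_doc <- split(seq_len(nrow(table)), table$doc_id)
  reps <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(B)) {
    draw <- sample(docs, length(docs), replace = TRUE)
    pieces <- lapply(seq_along(draw), function(k) {
      piece <- table[rows_by_doc[[as.character(draw[k])]], , drop = FALSE]
      piece$doc_id <- paste0(draw[k], "#", k)  # duplicated clusters stay distinct
      piece
    })
    bt <- do.call(rbind, pieces)
    fit <- tryCatch(fit_sentiment_mixed_model(bt, ...), error = function(e) NULL)
    if (is.null(fit)) next
    est <- stats::setNames(fit$coefficients$estimate, rownames(fit$coefficients))
    if (is.null(reps)) {
      reps <- matrix(NA_real_, nrow = B, ncol = length(est),
                     dimnames = list(NULL, names(est)))
    }
    reps[b, names(est)] <- est
  }
  if (is.null(reps)) stop("all bootstrap refits failed", call. = FALSE)
  a <- (1 - conf) / 2
  ci <- data.frame(term = colnames(reps),
                   lower = apply(reps, 2, stats::quantile, probs = a, na.rm = TRUE),
                   upper = apply(reps, 2, stats::quantile, probs = 1 - a, na.rm = TRUE),
                   row.names = NULL, stringsAsFactors = FALSE)
  list(ci = ci, replicates = reps, B = B, seed = seed)
}
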