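#' Run the full bias audit end to end
#'
#' Orchestrates: pair validation, factorial grid construction, summarisation,
#' metric screening, the sentiment mixed model with per-model gender
#' contrasts, theme inclusion-bias tests, word-level dual-criterion tests,
#' and the hallucination audit. Both genders of every pair are processed by
#' byte-identical code paths and parameters, which is the counterfactual
#' contract the audit rests on.
#'
#' @param pairs A `counterfactual_pairs` data frame (validated or not;
#'   unvalidated pairs are validated first and non-passing pairs dropped).
#' @param summarizer A `summarizer_spec` or named list of specs per model.
#' @param models Model names for the grid.
#' @param levels Max-tokens levels.
#' @param metric A `sentiment_metric`.
#' @param theme_lexicons Named list of theme term vectors.
#' @param terms Medical term list for the hallucination audit.
#' @param alpha Significance level used throughout (default 0.05).
#' @param random Random-effects structure passed to
#'   [fit_sentiment_mixed_model()].
#' @param count_method Count-test construction passed to
#'   [analyze_linguistic_bias()].
#' @return An `audit_report`: list with `screen`, `sentiment_fit`,
#'   `emm`, `themes`, `words`, `hallucination`, `manifest`.
#' @export
run_audit <- function(pairs, summarizer = mock_summarizer(), models = "mock",
                      levels = default_max_tokens_levels(),
                      metric = lexicon_metric(),
                      theme_lexicons = load_theme_lexicons(),
                      terms = default_medical_terms(), alpha = 0.05,
                      random = "by_model", count_method = "exposure") {
  if (any(is.na(pairs$validated))) pairs <- validate_pairs(pairs)
  n_dropped <- sum(!pairs$validated)
  pairs <- pairs[pairs$validated, , drop = FALSE]
  if (nrow(pairs) < 2) stop("fewer than 2 validated pairs", call. = FALSE)

  grid <- build_grid(pairs$doc_id, models = models, levels = levels)
  records <- run_summarization(pairs, summarizer, grid)
  screen <- screen_metric_bias(pairs, metric, alpha = alpha)
  table <- score_summaries(records, metric)
  fit <- fit_sentiment_mixed_model(table, random = random)
  emm <- if (fit$degenerate) NULL else estimate_gender_emm(fit)
  themes <- test_inclusion_bias(count_theme_terms(records, theme_lexicons))
  dtm <- build_doc_term_matrix(records)
  words <- analyze_linguistic_bias(dtm, alpha = alpha, count_method = count_method)
  halluc <- audit_hallucinations(pairs, records, terms)

  manifest <- list(
    n_pairs = nrow(pairs), n_dropped_validation = n_dropped,
    n_cells = nrow(grid), models = models, levels = levels,
    metric = metric$name, alpha = alpha,
    n_dual_significant = sum(words$dual_significant),
    n_theme_significant = sum(themes$p_adjusted < alpha, na.rm = TRUE),
    n_hallucinations = sum(halluc$records$hallucinated),
    opportunity_count = opportunity_count(nrow(pairs), 2,
                                          length(models) * length(levels),
                                          length(terms))
  )
  structure(list(screen = screen, sentiment_fit = fit, emm = emm,
                 themes = themes, words = words, hallucination = halluc,
                 sentiment_table = table, dtm = dtm, manifest = manifest),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  m <- x$manifest
  cat("Counterfactual gender-bias audit\n")
  cat(sprintf("  %d validated pairs (%d dropped), %d grid cells, metric '%s'\n",
              m$n_pairs, m$n_dropped_validation, m$n_cells, m$metric))
  cat(sprintf("  metric screen: %s\n", if (x$screen$passed) "passed" else "FAILED"))
  if (!is.null(x$emm)) {
    cat("  gender EMM contrasts (female - male):\n")
    for (i in seq_len(nrow(x$emm))) {
      cat(sprintf("    %-10s %+.4f (p = %.3g)\n", x$emm$model[i],
                  x$emm$estimate[i], x$emm$p[i]))
    }
  }
  cat(sprintf("  themes with adjusted p < %.2f: %d of %d\n", m$alpha,
              m$n_theme_significant, nrow(x$themes)))
  cat(sprintf("  dual-significant words: %d of %d tested\n",
              m$n_dual_significant, nrow(x$words)))
  cat(sprintf("  hallucinations: %d in %d opportunities\n",
              m$n_hallucinations, m$opportunity_count))
  invisible(x)
}

#' Relabel genders in a sentiment table
#'
#' Swaps the female/male labels; under the audit's symmetry invariant this
#' negates every signed gender contrast and leaves p-values unchanged.
#'
#' @param table A `sentiment_table` (or any data frame with a `gender`
#'   column).
#' @return The table with genders swapped.
#' @export
relabel_genders <- function(table) {
  g <- as.character(table$gender)
  table$gender <- ifelse(g == "female", "male", "female")
  table
}
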