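#' Default max-tokens factor levels
#'
#' The output-length cap is treated as a six-level experimental factor; "None"
#' (no cap) is a first-class level, and 50 is the reference level in all
#' models downstream.
#'
#' @return Character vector `c("50","75","100","150","300","None")`.
#' @export
default_max_tokens_levels <- function() c("50", "75", "100", "150", "300", "None")

#' Build the factorial generation grid
#'
#' Full cross product of documents, the two genders, summarisation models and
#' max-tokens levels. With 617 documents, 4 models and 6 levels this is the
#' 29,616-cell design (48 cells per document).
#'
#' @param doc_ids Character/integer vector of unique document ids.
#' @param models Character vector of model names.
#' @param levels Character vector of max-tokens levels.
#' @return Data frame with columns `doc_id`, `gender`, `model`, `max_tokens`,
#'   one row per cell, sorted by (doc, gender, model, level).
#' @export
build_grid <- function(doc_ids, models = "mock",
                       levels = default_max_tokens_levels()) {
  if (anyDuplicated(doc_ids)) stop("duplicate doc_ids", call. = FALSE)
  stopifnot(length(models) > 0, length(levels) > 0)
  if (length(doc_ids) == 0) {
    g <- data.frame(doc_id = character(0), gender = character(0),
                    model = character(0), max_tokens = character(0),
                    stringsAsFactors = FALSE)
    return(g)
  }
  g <- expand.grid(max_tokens = as.character(levels), model = models,
                   gender = c("female", "male"), doc_id = doc_ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("doc_id", "gender", "model", "max_tokens")]
  g <- g[order(g$doc_id, g$gender, g$model,
               match(g$max_tokens, as.character(levels))), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Define a summariser plug-in
#'
#' A summariser is a function `(text, max_tokens_level) -> summary text`.
#' Real-model adapters satisfy the same contract; the shipped mocks are
#' extractive and deterministic so tests run with no downloads.
#'
#' @param name Name used in records and reports.
#' @param fn The callable.
#' @param deterministic Logical; deterministic specs must return identical
#'   output on identical input.
#' @return A `summarizer_spec` object.
#' @export
summarizer_spec <- function(name, fn, deterministic = TRUE) {
  stopifnot(is.character(name), is.function(fn))
  structure(list(name = name, fn = fn, deterministic = deterministic),
            class = "summarizer_spec")
}

#' Default sentences-per-level mapping for mock summarisers
#'
#' @return Named numeric vector mapping each max-tokens level to the number
#'   of leading sentences the extractive mock keeps (`Inf` = whole text).
#' @export
default_sentence_budget <- function() {
  c("50" = 1, "75" = 2, "100" = 3, "150" = 4, "300" = 6, "None" = Inf)
}

#' Unbiased extractive mock summariser
#'
#' Returns the first k sentences of the input, where k depends only on the
#' max-tokens level. Purely extractive and deterministic, so on validated
#' counterfactual pairs its two gender versions differ only in gendered
#' tokens and every downstream bias statistic sits at its null.
#'
#' @param budget Named vector mapping levels to sentence counts
#'   (see [default_sentence_budget()]).
#' @param name Spec name.
#' @return A `summarizer_spec`.
#' @export
mock_summarizer <- function(budget = default_sentence_budget(), name = "mock") {
  force(budget)
  fn <- function(text, max_tokens_level) {
    lvl <- as.character(max_tokens_level)
    if (!(lvl %in% names(budget))) stop("unknown max_tokens level: ", lvl, call. = FALSE)
    k <- budget[[lvl]]
    if (is.infinite(k)) return(text)
    sents <- split_sentences(text)
    paste(utils::head(sents, k), collapse = " ")
  }
  summarizer_spec(name, fn, deterministic = TRUE)
}

#' Run a summariser over a generation grid
#'
#' Female cells summarise `female_text`, male cells `male_text`; both genders
#' of every pair pass through byte-identical code and parameters, realising
#' the counterfactual contract.
#'
#' @param pairs A `counterfactual_pairs` data frame.
#' @param spec A `summarizer_spec`, or a named list of specs keyed by model
#'   name when the grid spans several models.
#' @param grid A grid from [build_grid()].
#' @return Data frame of summary records: grid columns plus `summary_text`.
#' @export
run_summarization <- function(pairs, spec, grid) {
  missing_ids <- setdiff(unique(grid$doc_id), pairs$doc_id)
  if (length(missing_ids)) {
    stop("grid doc_id(s) missing from pairs: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  specs <- if (inherits(spec, "summarizer_spec")) {
    stats::setNames(rep(list(spec), length(unique(grid$model))), unique(grid$model))
  } else spec
  idx <- match(grid$doc_id, pairs$doc_id)
  out <- grid
  out$summary_text <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    src <- if (grid$gender[i] == "female") pairs$female_text[idx[i]] else pairs$male_text[idx[i]]
    sp <- specs[[grid$model[i]]]
    if (is.null(sp)) stop("no summarizer registered for model ", grid$model[i], call. = FALSE)
    res <- tryCatch(sp$fn(src, grid$max_tokens[i]), error = function(e) {
      stop(sprintf("summariser failed on doc_id=%s gender=%s model=%s level=%s: %s",
                   grid$doc_id[i], grid$gender[i], grid$model[i],
                   grid$max_tokens[i], conditionMessage(e)), call. = FALSE)
    })
    out$summary_text[i] <- res
  }
  if (any(!nzchar(out$summary_text))) {
    bad <- which(!nzchar(out$summary_text))[1]
    stop("empty summary for doc_id=", out$doc_id[bad], call. = FALSE)
  }
  out
}
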