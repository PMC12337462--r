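#' Load theme lexicons
#'
#' One plain-text file per theme (one term per line, lowercase). The shipped
#' starter lexicons cover physical health, mental health, physical appearance
#' and subjective language; they are editable data files, versioned with the
#' package, not a clinical standard. Terms are lemmatised at load with the
#' same pipeline applied to the text.
#'
#' @param dir Directory of `<theme>.txt` files; defaults to the shipped set.
#' @return Named list of character vectors of lemmatised terms.
#' @export
load_theme_lexicons <- function(dir = carefair_extdata("themes")) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no theme lexicon files in ", dir, call. = FALSE)
  lex <- lapply(files, function(f) {
    terms <- read_term_file(f)
    unique(vapply(terms, function(t) paste(lemmatize(tokenize_words(t)), collapse = " "),
                  character(1), USE.NAMES = FALSE))
  })
  names(lex) <- sub("\\.txt$", "", basename(files))
  lex
}

# Count non-overlapping occurrences of a lemma phrase in a lemma sequence.
count_phrase <- function(lemmas, phrase_lemmas) {
  k <- length(phrase_lemmas)
  n <- length(lemmas)
  if (k == 0 || n < k) return(0L)
  if (k == 1) return(sum(lemmas == phrase_lemmas))
  hits <- 0L
  i <- 1L
  while (i <= n - k + 1L) {
    if (all(lemmas[i:(i + k - 1L)] == phrase_lemmas)) {
      hits <- hits + 1L
      i <- i + k
    } else i <- i + 1L
  }
  hits
}

#' Count theme-lexicon terms in summaries by model and gender
#'
#' Lemma-level, word-boundary, case-insensitive counting of every lexicon
#' term, summed over summaries per (model, theme, gender). Multi-word terms
#' are matched as contiguous lemma sequences.
#'
#' @param records Summary records (from [run_summarization()]).
#' @param lexicons Named list of theme term vectors (see
#'   [load_theme_lexicons()]).
#' @return Data frame (`model`, `theme`, `count_female`, `count_male`), class
#'   `theme_count_table`.
#' @export
count_theme_terms <- function(records, lexicons = load_theme_lexicons()) {
  empty <- vapply(lexicons, function(x) length(x) == 0, logical(1))
  if (any(empty)) {
    warning("empty theme lexicon(s): ", paste(names(lexicons)[empty], collapse = ", "))
    lexicons <- lexicons[!empty]
  }
  # lemmatise terms so raw (unlemmatised) lexicons match the text pipeline
  phrase_lists <- lapply(lexicons, function(terms) {
    lapply(strsplit(tolower(terms), " ", fixed = TRUE), lemmatize)
  })
  lemma_seqs <- lapply(records$summary_text, function(t) content_lemmas(t, remove_stopwords = FALSE))
  models <- unique(records$model)
  rows <- list()
  for (m in models) {
    for (th in names(lexicons)) {
      cf <- 0L; cm <- 0L
      sel <- which(records$model == m)
      for (i in sel) {
        cnt <- sum(vapply(phrase_lists[[th]], function(p) count_phrase(lemma_seqs[[i]], p),
                          integer(1)))
        if (records$gender[i] == "female") cf <- cf + cnt else cm <- cm + cnt
      }
      rows[[length(rows) + 1L]] <- data.frame(model = m, theme = th,
                                              count_female = cf, count_male = cm,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("theme_count_table", class(out))
  out
}

#' Chi-squared test of a female/male count pair
#'
#' Default is a one-degree-of-freedom goodness-of-fit test of the observed
#' (female, male) counts against equal expected counts, appropriate because
#' the counterfactual design guarantees the source texts use every term
#' equally often for each gender. An exposure-adjusted 2x2 variant (term
#' count vs all-other-token count per gender) is available for unbalanced
#' corpora via `totals`.
#'
#' @param count_female,count_male Non-negative integer counts.
#' @param totals Optional length-2 vector of total token counts
#'   (female, male); when supplied the 2x2 exposure-adjusted test is used.
#' @return List (`statistic`, `p`, `undefined`); when both counts are zero
#'   the test is undefined and returned as missing with `undefined = TRUE`.
#' @export
theme_chisq <- function(count_female, count_male, totals = NULL) {
  if (count_female + count_male == 0) {
    return(list(statistic = NA_real_, p = NA_real_, undefined = TRUE))
  }
  if (is.null(totals)) {
    ht <- suppressWarnings(stats::chisq.test(c(count_female, count_male),
                                             p = c(0.5, 0.5)))
  } else {
    tab <- rbind(c(count_female, totals[1] - count_female),
                 c(count_male, totals[2] - count_male))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  list(statistic = unname(ht$statistic), p = unname(ht$p.value), undefined = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validated wrapper around
#' `stats::p.adjust(method = "BH")` that preserves input order.
#'
#' @param pvals Numeric vector of p-values in [0, 1] (`NA` allowed and
#'   passed through).
#' @return Adjusted p-values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stop("p-values outside [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Theme inclusion-bias tests with BH correction
#'
#' Runs [theme_chisq()] for every (model, theme) count pair and adjusts the
#' whole family jointly with Benjamini-Hochberg, mirroring a single
#' adjusted-p column spanning models.
#'
#' @param counts A `theme_count_table` from [count_theme_terms()].
#' @param exposure_totals Optional named list mapping model name to a
#'   length-2 vector of per-gender total token counts, switching on the
#'   exposure-adjusted variant.
#' @return The table with `statistic`, `p` and `p_adjusted` columns.
#' @export
test_inclusion_bias <- function(counts, exposure_totals = NULL) {
  stat <- numeric(nrow(counts)); p <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    tot <- if (!is.null(exposure_totals)) exposure_totals[[counts$model[i]]] else NULL
    r <- theme_chisq(counts$count_female[i], counts$count_male[i], totals = tot)
    stat[i] <- r$statistic; p[i] <- r$p
  }
  counts$statistic <- stat
  counts$p <- p
  counts$p_adjusted <- bh_adjust(p)
  counts
}
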