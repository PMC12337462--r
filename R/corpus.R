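#' Read a corpus of care documents
#'
#' Reads free-text care notes ("pen portraits") from CSV or JSONL. Required
#' columns/keys: `doc_id`, `text`, `gender`; optional `age`, `ethnicity`.
#'
#' @param path Path to a `.csv`, `.jsonl` or `.json` file (UTF-8).
#' @return A data frame with one row per document, class `care_corpus`.
#' @export
read_corpus <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, jsonlite::fromJSON)
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r[intersect(c("doc_id", "text", "gender", "age", "ethnicity"),
                                names(r))], stringsAsFactors = FALSE)
    }))
  }
  as_care_corpus(df)
}

#' Construct a care corpus from a data frame
#'
#' @param df Data frame with columns `doc_id`, `text`, `gender` (and optional
#'   `age`, `ethnicity`).
#' @return The validated data frame with class `care_corpus` prepended.
#' @export
as_care_corpus <- function(df) {
  required <- c("doc_id", "text", "gender")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("corpus is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- is.na(df$text) | !nzchar(trimws(df$text))
  if (any(bad)) {
    stop("document(s) with missing or empty text: ",
         paste(df$doc_id[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$doc_id)) {
    stop("duplicate doc_id values in corpus", call. = FALSE)
  }
  if (!all(df$gender %in% c("female", "male"))) {
    stop("gender must be 'female' or 'male'", call. = FALSE)
  }
  class(df) <- unique(c("care_corpus", class(df)))
  df
}

#' Default exclusion term list
#'
#' Terms marking documents that would not describe a comparable situation if
#' gender were swapped (sex-specific anatomy or care histories, domestic
#' violence). Shipped as an editable plain-text file; the list is a starting
#' point, not a clinical standard.
#'
#' @return Character vector of lowercase terms/phrases.
#' @export
default_exclusion_terms <- function() {
  cached_resource("exclusion_terms",
                  function() read_term_file(carefair_extdata("exclusion_terms.txt")))
}

#' Filter documents eligible for counterfactual pairing
#'
#' Applies, in order: word-count lower bound, word-count upper bound, and an
#' exclusion-term screen (case-insensitive, word-boundary). Each document is
#' assigned to exactly one outcome so the report partitions the input.
#'
#' @param corpus A `care_corpus` data frame.
#' @param min_words,max_words Inclusive word-count bounds (whitespace tokens
#'   after normalisation). Defaults 200 and 500.
#' @param exclusion_terms Character vector of terms/phrases; a document
#'   containing any of them is excluded.
#' @return A list with `corpus` (kept rows) and `report` (named integer
#'   vector: `n_input`, `n_too_short`, `n_too_long`, `n_excluded_terms`,
#'   `n_near_duplicate`, `n_kept`; the near-duplicate slot is filled by
#'   [dedupe_near()]).
#' @export
filter_eligible <- function(corpus, min_words = 200, max_words = 500,
                            exclusion_terms = default_exclusion_terms()) {
  stopifnot(min_words <= max_words)
  report <- c(n_input = 0L, n_too_short = 0L, n_too_long = 0L,
              n_excluded_terms = 0L, n_near_duplicate = 0L, n_kept = 0L)
  if (nrow(corpus) == 0) {
    return(list(corpus = corpus, report = report))
  }
  if (any(is.na(corpus$text))) {
    stop("document(s) with missing text: ",
         paste(corpus$doc_id[is.na(corpus$text)], collapse = ", "), call. = FALSE)
  }
  report["n_input"] <- nrow(corpus)
  nw <- vapply(corpus$text, count_words, numeric(1), USE.NAMES = FALSE)
  too_short <- nw < min_words
  too_long <- !too_short & nw > max_words
  has_excl <- rep(FALSE, nrow(corpus))
  if (length(exclusion_terms)) {
    pats <- paste0("\\b", gsub("([^A-Za-z0-9 ])", "\\\\\\1", exclusion_terms), "\\b")
    lowered <- tolower(normalize_text(corpus$text))
    for (p in pats) has_excl <- has_excl | grepl(p, lowered, perl = TRUE)
  }
  excluded_terms <- !too_short & !too_long & has_excl
  kept <- !too_short & !too_long & !excluded_terms
  report["n_too_short"] <- sum(too_short)
  report["n_too_long"] <- sum(too_long)
  report["n_excluded_terms"] <- sum(excluded_terms)
  report["n_kept"] <- sum(kept)
  list(corpus = corpus[kept, , drop = FALSE], report = report)
}

word_shingles <- function(text, k) {
  toks <- tolower(tokenize_words(normalize_text(text)))
  if (length(toks) < k) return(paste(toks, collapse = " "))
  n <- length(toks) - k + 1L
  vapply(seq_len(n), function(i) paste(toks[i:(i + k - 1L)], collapse = " "),
         character(1))
}

#' Remove near-duplicate documents
#'
#' Computes word k-shingle sets per document and drops any document whose
#' Jaccard similarity with an earlier retained document reaches the threshold.
#' Stable: the earlier document in input order is always the one kept.
#'
#' @param corpus A `care_corpus` data frame.
#' @param shingle_size Shingle length in word tokens (default 5).
#' @param jaccard_threshold Similarity at or above which the later document is
#'   removed (default 0.9).
#' @return A list with `corpus` (kept rows) and `n_removed`.
#' @export
dedupe_near <- function(corpus, shingle_size = 5, jaccard_threshold = 0.9) {
  stopifnot(shingle_size >= 1, jaccard_threshold > 0, jaccard_threshold <= 1)
  n <- nrow(corpus)
  if (n <= 1) return(list(corpus = corpus, n_removed = 0L))
  sh <- lapply(corpus$text, function(t) unique(word_shingles(t, shingle_size)))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      inter <- length(intersect(sh[[i]], sh[[j]]))
      uni <- length(union(sh[[i]], sh[[j]]))
      if (uni > 0 && inter / uni >= jaccard_threshold) {
        keep[i] <- FALSE
        break
      }
    }
  }
  list(corpus = corpus[keep, , drop = FALSE], n_removed = sum(!keep))
}
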