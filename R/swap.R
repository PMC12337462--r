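#' Load a gender lexicon
#'
#' Reads the two-column TSV mapping female forms to male forms with a
#' `match_kind` flag (`exact`, `title`, `pos_disambiguated`). The mapping is
#' involutive on unambiguous entries; "her" is ambiguous (possessive vs
#' objective) and resolved in context by [swap_gender()].
#'
#' @param path TSV file; defaults to the shipped lexicon.
#' @return A data frame with columns `female_form`, `male_form`, `match_kind`
#'   and class `gender_lexicon`.
#' @export
load_gender_lexicon <- function(path = carefair_extdata("gender_lexicon.tsv")) {
  lex <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("female_form", "male_form", "match_kind") %in% names(lex)))
  lex$female_form <- tolower(lex$female_form)
  lex$male_form <- tolower(lex$male_form)
  class(lex) <- c("gender_lexicon", class(lex))
  lex
}

default_gender_lexicon <- function() {
  cached_resource("gender_lexicon", load_gender_lexicon)
}

# Tokens following "her" that signal the objective reading ("saw her there").
.objective_next <- c("that", "to", "and", "but", "or", "because", "when",
                     "while", "after", "before", "if", "then", "not", "again",
                     "too", "as", "at", "about", "with", "from", "in", "on",
                     "by", "for", "of", "so", "there", "here", "the", "a",
                     "an", "this", "every", "each", "some", "any", "back",
                     "today", "yesterday", "home", "away", "well")

common_verbs <- function() {
  cached_resource("common_verbs",
                  function() read_term_file(carefair_extdata("common_verbs.txt")))
}

match_case <- function(replacement, original) {
  if (original == toupper(original) && nchar(original) > 1) return(toupper(replacement))
  first <- substr(original, 1, 1)
  if (first == toupper(first)) {
    return(paste0(toupper(substr(replacement, 1, 1)), substr(replacement, 2, nchar(replacement))))
  }
  replacement
}

# TRUE when "her" at position i (of lowered word tokens) reads as objective.
her_is_objective <- function(tokens_lower, i) {
  if (i >= length(tokens_lower)) return(TRUE)
  nxt <- tokens_lower[i + 1]
  if (nxt %in% .objective_next) return(TRUE)
  lemmatize(nxt) %in% common_verbs()
}

#' Swap gendered tokens in a text
#'
#' Replaces every lexicon-covered gendered token with its counterpart,
#' preserving case; all other characters are byte-identical. The ambiguous
#' token "her" is resolved by a deterministic context rule: objective ("saw
#' her leave") becomes "him", possessive ("her coat") becomes "his". In the
#' male-to-female direction both "his" and "him" map to "her".
#'
#' @param text A single character string.
#' @param lexicon A `gender_lexicon`; defaults to the shipped one.
#' @param direction `"f2m"` (female to male) or `"m2f"`.
#' @return The swapped text.
#' @export
swap_gender <- function(text, lexicon = default_gender_lexicon(),
                        direction = c("f2m", "m2f")) {
  direction <- match.arg(direction)
  stopifnot(is.character(text), length(text) == 1)
  if (direction == "f2m") {
    amb <- lexicon$match_kind == "pos_disambiguated"
    fwd_amb <- lexicon[amb, , drop = FALSE]
    plain <- lexicon[!amb, , drop = FALSE]
    # first entry wins on duplicated source forms
    map <- plain$male_form[!duplicated(plain$female_form)]
    names(map) <- plain$female_form[!duplicated(plain$female_form)]
    her_forms <- stats::setNames(fwd_amb$male_form, rep("her", nrow(fwd_amb)))
    her_poss <- if (nrow(fwd_amb)) fwd_amb$male_form[1] else "his"
    her_obj <- if (nrow(fwd_amb) > 1) fwd_amb$male_form[2] else "him"
  } else {
    # reverse: male -> female; pos-ambiguous male forms ("his"/"him") both map
    # to "her"; for other duplicated male forms the first lexicon row wins.
    src <- lexicon$male_form
    dst <- lexicon$female_form
    keep <- !duplicated(src)
    map <- stats::setNames(dst[keep], src[keep])
  }

  m <- gregexpr("[A-Za-z]+", text)
  toks <- regmatches(text, m)[[1]]
  if (length(toks) == 0) return(text)
  lowered <- tolower(toks)
  out <- toks
  for (i in seq_along(toks)) {
    lo <- lowered[i]
    if (direction == "f2m" && lo == "her") {
      rep_lo <- if (her_is_objective(lowered, i)) her_obj else her_poss
      out[i] <- match_case(rep_lo, toks[i])
    } else if (!is.na(map[lo])) {
      out[i] <- match_case(unname(map[lo]), toks[i])
    }
  }
  regmatches(text, m)[[1]] <- out
  text
}

#' Build counterfactual pairs from a corpus
#'
#' For each document, the version matching its recorded gender is the
#' original text and the other version is produced by [swap_gender()].
#'
#' @param corpus A `care_corpus` data frame.
#' @param lexicon A `gender_lexicon`.
#' @return A data frame (`doc_id`, `female_text`, `male_text`,
#'   `gender_original`, `validated`, `mismatch`) of class
#'   `counterfactual_pairs`; run [validate_pairs()] to fill the validation
#'   columns.
#' @export
make_pairs <- function(corpus, lexicon = default_gender_lexicon()) {
  female_text <- character(nrow(corpus))
  male_text <- character(nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    txt <- normalize_text(corpus$text[i])
    if (corpus$gender[i] == "female") {
      female_text[i] <- txt
      male_text[i] <- swap_gender(txt, lexicon, "f2m")
    } else {
      male_text[i] <- txt
      female_text[i] <- swap_gender(txt, lexicon, "m2f")
    }
  }
  pairs <- data.frame(doc_id = corpus$doc_id, female_text = female_text,
                      male_text = male_text, gender_original = corpus$gender,
                      validated = NA, mismatch = NA_character_,
                      stringsAsFactors = FALSE)
  class(pairs) <- c("counterfactual_pairs", class(pairs))
  pairs
}

gendered_forms <- function(lexicon) {
  unique(c(lexicon$female_form, lexicon$male_form))
}

#' Validate one counterfactual pair
#'
#' A pair is validated when both versions have the same number of sentences
#' and, for every aligned sentence, the same count of tokens that are neither
#' stop words nor gendered lexicon entries. Failure is a data state, recorded
#' in `mismatch`, never an error.
#'
#' @param pair A list or one-row data frame with `female_text` and
#'   `male_text`.
#' @param lexicon A `gender_lexicon`.
#' @return The pair (as a list) with `validated` set and `mismatch` either
#'   `NA` or a description of the first mismatch.
#' @export
validate_pair <- function(pair, lexicon = default_gender_lexicon()) {
  pair <- as.list(pair)
  stopifnot(nzchar(pair$female_text), nzchar(pair$male_text))
  gf <- gendered_forms(lexicon)
  sw <- carefair_stopwords()
  sent_f <- split_sentences(pair$female_text)
  sent_m <- split_sentences(pair$male_text)
  if (length(sent_f) != length(sent_m)) {
    pair$validated <- FALSE
    pair$mismatch <- sprintf("sentence_count: female=%d male=%d",
                             length(sent_f), length(sent_m))
    return(pair)
  }
  count_content <- function(s) {
    toks <- tolower(tokenize_words(s))
    sum(!(toks %in% sw) & !(toks %in% gf))
  }
  for (k in seq_along(sent_f)) {
    cf <- count_content(sent_f[k])
    cm <- count_content(sent_m[k])
    if (cf != cm) {
      pair$validated <- FALSE
      pair$mismatch <- sprintf("word_count at sentence %d: female=%d male=%d",
                               k, cf, cm)
      return(pair)
    }
  }
  pair$validated <- TRUE
  pair$mismatch <- NA_character_
  pair
}

#' Validate all pairs in a collection
#'
#' @param pairs A `counterfactual_pairs` data frame.
#' @param lexicon A `gender_lexicon`.
#' @return The data frame with `validated` and `mismatch` filled in.
#' @export
validate_pairs <- function(pairs, lexicon = default_gender_lexicon()) {
  for (i in seq_len(nrow(pairs))) {
    v <- validate_pair(pairs[i, ], lexicon)
    pairs$validated[i] <- v$validated
    pairs$mismatch[i] <- v$mismatch
  }
  pairs
}

#' Write / read counterfactual pairs as JSONL
#'
#' @param pairs A `counterfactual_pairs` data frame.
#' @param path Output path.
#' @return `write_pairs` returns `path` invisibly; `read_pairs` returns the
#'   data frame.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(pairs))) {
    writeLines(jsonlite::toJSON(as.list(pairs[i, setdiff(names(pairs), "gender_original")]),
                                auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    r$mismatch <- if (is.null(r$mismatch)) NA_character_ else r$mismatch
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  class(pairs) <- c("counterfactual_pairs", class(pairs))
  pairs
}
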