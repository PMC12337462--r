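# Cache for shipped resource files; filled lazily, keyed by resource name.
.carefair_cache <- new.env(parent = emptyenv())

carefair_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "carefair")
  if (!nzchar(path)) stop("resource file not found: ", file.path(...), call. = FALSE)
  path
}

read_term_file <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(tolower(x))
  x[nzchar(x) & !startsWith(x, "#")]
}

cached_resource <- function(key, loader) {
  if (!exists(key, envir = .carefair_cache, inherits = FALSE)) {
    assign(key, loader(), envir = .carefair_cache)
  }
  get(key, envir = .carefair_cache, inherits = FALSE)
}

#' Shipped stop-word list
#'
#' Returns the versioned stop-word list used throughout the package for pair
#' validation, document-term-matrix construction and theme counting. Shipped
#' as a plain-text data file so results are bit-stable across machines.
#'
#' @return Character vector of lowercase stop words.
#' @export
carefair_stopwords <- function() {
  cached_resource("stopwords", function() read_term_file(carefair_extdata("stopwords.txt")))
}

lemma_exceptions <- function() {
  cached_resource("lemma_exceptions", function() {
    tab <- utils::read.delim(carefair_extdata("lemma_exceptions.tsv"),
                             stringsAsFactors = FALSE)
    stats::setNames(tolower(tab$lemma), tolower(tab$token))
  })
}

#' Shipped dictionary snapshot
#'
#' Word list used to exclude out-of-dictionary tokens from the document-term
#' matrix. Entries are lemma forms; the snapshot is versioned with the package
#' so vocabularies are identical across environments.
#'
#' @return Character vector of lowercase lemmas.
#' @export
carefair_dictionary <- function() {
  cached_resource("dictionary", function() read_term_file(carefair_extdata("dictionary.txt")))
}

#' Normalise whitespace and unicode punctuation
#'
#' Collapses runs of whitespace to single spaces, trims ends, and maps common
#' unicode quote/dash variants to ASCII so downstream tokenisation is stable.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
normalize_text <- function(text) {
  text <- gsub("[‘’ʼ]", "'", text)
  text <- gsub("[“”]", '"', text)
  text <- gsub("[–—]", "-", text)
  text <- gsub("\\s+", " ", text)
  trimws(text)
}

# Word tokens: runs of letters, keeping internal aposturophes out (possessive
# "'s" becomes its own single-letter token and is dropped by length filters
# downstream only where appropriate).
tokenize_words <- function(text) {
  m <- gregexpr("[A-Za-z]+", text)
  regmatches(text, m)[[1]]
}

count_words <- function(text) {
  text <- normalize_text(text)
  if (!nzchar(text)) return(0L)
  length(strsplit(text, " ", fixed = TRUE)[[1]])
}

# Sentence splitter: break after ., ! or ? followed by whitespace, unless the
# period terminates a known abbreviation (titles etc.).
.abbreviations <- c("mr", "mrs", "ms", "dr", "st", "prof", "rev", "e.g", "i.e", "etc", "vs")

#' Split text into sentences
#'
#' Deterministic rule-based splitter: sentences end at `.`, `!` or `?`
#' followed by whitespace, except after common abbreviations (Mr., Mrs., Dr.,
#' e.g., ...). Shipped in code rather than behind an NLP model so validation
#' outcomes are reproducible bit-for-bit.
#'
#' @param text A single character string.
#' @return Character vector of sentences (trimmed, possibly empty).
#' @export
split_sentences <- function(text) {
  text <- normalize_text(text)
  if (!nzchar(text)) return(character(0))
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  out <- character(0)
  start <- 1L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      word_before <- tolower(sub("\\.+$", "", sub(".*\\s", "", substr(text, start, i - 1))))
      is_abbrev <- ch == "." && word_before %in% .abbreviations
      at_end <- i == n
      followed_by_space <- !at_end && grepl("^\\s$", chars[i + 1])
      if (!is_abbrev && (at_end || followed_by_space)) {
        out <- c(out, trimws(substr(text, start, i)))
        start <- i + 1L
      }
    }
    i <- i + 1L
  }
  if (start <= n) {
    tail_txt <- trimws(substr(text, start, n))
    if (nzchar(tail_txt)) out <- c(out, tail_txt)
  }
  out[nzchar(out)]
}

#' Rule-based lemmatiser
#'
#' Maps inflected English word forms to lemmas with an exceptions table plus
#' suffix rules (-ies/-es/-s, -ing, -ed with e-restoration and consonant
#' un-doubling), validated against the shipped dictionary. Deterministic and
#' dependency-free by design: the lemma of a token never changes across
#' machines or sessions.
#'
#' @param tokens Character vector of word tokens (any case).
#' @return Character vector of lowercase lemmas, same length.
#' @export
lemmatize <- function(tokens) {
  if (length(tokens) == 0) return(character(0))
  tokens <- tolower(tokens)
  exc <- lemma_exceptions()
  dict <- carefair_dictionary()
  vapply(tokens, function(tok) {
    if (!is.na(exc[tok])) return(unname(exc[tok]))
    if (nchar(tok) < 4) return(tok)
    lemmatize_one(tok, dict)
  }, character(1), USE.NAMES = FALSE)
}

lemmatize_one <- function(tok, dict) {
  pick <- function(cands, fallback) {
    for (c in cands) if (nchar(c) >= 2 && c %in% dict) return(c)
    fallback
  }
  undouble <- function(s) {
    n <- nchar(s)
    if (n >= 3 && substr(s, n, n) == substr(s, n - 1, n - 1)) substr(s, 1, n - 1) else s
  }
  if (grepl("ies$", tok) && nchar(tok) >= 5) {
    return(pick(c(sub("ies$", "y", tok), sub("ies$", "ie", tok)), sub("ies$", "y", tok)))
  }
  if (grepl("(ss|us|is)$", tok)) return(tok)
  if (grepl("(ches|shes|xes|zes|sses)$", tok)) {
    return(pick(sub("es$", "", tok), sub("es$", "", tok)))
  }
  if (grepl("ing$", tok) && nchar(tok) >= 6) {
    s <- sub("ing$", "", tok)
    return(pick(c(paste0(s, "e"), s, undouble(s)), s))
  }
  if (grepl("ed$", tok) && nchar(tok) >= 5) {
    s <- sub("ed$", "", tok)
    return(pick(c(paste0(s, "e"), s, undouble(s)), s))
  }
  if (grepl("s$", tok)) {
    s <- sub("s$", "", tok)
    return(pick(s, s))
  }
  tok
}

# Lemmatised content tokens of a text: lowercase word tokens minus stop words,
# mapped through the lemmatiser. Dictionary filtering is applied only where a
# module's contract requires it (document-term matrix).
content_lemmas <- function(text, remove_stopwords = TRUE) {
  toks <- tolower(tokenize_words(normalize_text(text)))
  if (remove_stopwords) toks <- toks[!(toks %in% carefair_stopwords())]
  lemmatize(toks)
}
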