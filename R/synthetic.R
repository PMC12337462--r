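# Template pools for the synthetic note generator. Slots are filled per
# gender; everything outside a slot is shared verbatim by the two versions,
# so generated pairs are counterfactual by construction. Theme sentences
# carry terms from the shipped theme lexicons so planted inclusion bias is
# measurable downstream.
default_sentence_pools <- function() {
  list(
    physical_health = c(
      "{SUBJ} has reduced mobility and is unable to walk without a frame.",
      "{SUBJ} has experienced several falls in the past year and reports constant pain.",
      "There is a pressure ulcer on {POSS} left heel which requires a dressing.",
      "{SUBJ} needs support with transfers and {POSS} balance remains poor.",
      "District nurses visit to manage {POSS} medication and monitor {POSS} incontinence.",
      "{POSS} sight and hearing have declined and {SUBJ} is often breathless."
    ),
    mental_health = c(
      "{SUBJ} has poor short term memory and some confusion in the morning.",
      "{SUBJ} often appears anxious and becomes agitated in the evening.",
      "Staff report low mood and episodes of confusion during the night.",
      "{SUBJ} was distressed during the visit and remains emotional about the move.",
      "{POSS} capacity to make decisions fluctuates and some choices appear unwise.",
      "There are concerns about wandering at night and increasing agitation."
    ),
    physical_appearance = c(
      "{SUBJ} appeared dishevelled and {POSS} clothing was scruffy.",
      "{POSS} appearance is usually tidy and {SUBJ} takes pride in personal hygiene.",
      "{SUBJ} looked thin and somewhat unkempt at the last review.",
      "Carers help {OBJ} to remain presentable and well dressed each day."
    ),
    subjective_language = c(
      "{SUBJ} can be rude and demanding towards the care staff.",
      "Staff describe {OBJ} as pleasant and charming on most visits.",
      "{SUBJ} is very vocal and at times uncooperative with support workers.",
      "{SUBJ} was reluctant to accept help and can be stubborn about the care plan.",
      "Neighbours describe excessive noise and dirty conditions in the flat.",
      "{SUBJ} presents as challenging and occasionally hostile when prompted."
    ),
    neutral = c(
      "The flat is on the ground floor near the local shops.",
      "A care package of two visits per day is currently in place.",
      "The family visits at the weekend to help with the shopping.",
      "Meals are delivered each day and the fridge was well stocked.",
      "{SUBJ} enjoys listening to the radio and doing the crossword.",
      "The social worker will review the support plan next month.",
      "{SUBJ} worked as a teacher before retiring many years ago.",
      "Payments for the care package are managed through a direct debit.",
      "{SUBJ} likes the garden and watches the birds each morning."
    )
  )
}

.surnames <- c("Smith", "Jones", "Taylor", "Brown", "Williams", "Wilson",
               "Johnson", "Davies", "Robinson", "Wright", "Thompson", "Evans",
               "Walker", "White", "Roberts", "Green", "Hall", "Wood",
               "Jackson", "Clarke")

fill_slots <- function(template, gender, surname, age) {
  slots <- if (gender == "female") {
    c(TITLE = "Mrs", SUBJ = "she", POSS = "her", OBJ = "her",
      REFL = "herself", PERSON = "woman")
  } else {
    c(TITLE = "Mr", SUBJ = "he", POSS = "his", OBJ = "him",
      REFL = "himself", PERSON = "man")
  }
  out <- template
  out <- gsub("{SURNAME}", surname, out, fixed = TRUE)
  out <- gsub("{AGE}", as.character(age), out, fixed = TRUE)
  for (k in names(slots)) out <- gsub(paste0("{", k, "}"), slots[[k]], out, fixed = TRUE)
  # capitalise the sentence start when a lowercase slot landed there
  sub("^([a-z])", "\\U\\1", out, perl = TRUE)
}

check_prob <- function(x, what) {
  if (length(x) && (any(unlist(x) < 0) || any(unlist(x) > 1))) {
    stop(what, " probabilities must be in [0, 1]", call. = FALSE)
  }
}

#' Configuration for the synthetic test bed
#'
#' Defines a seeded template-grammar corpus of counterfactual note pairs and
#' the bias parameters a mock summariser injects at summarisation time
#' (sources stay gender-equivalent; bias arises only in summaries, matching
#' the causal structure the audit is designed to detect).
#'
#' @param n_docs Number of document pairs (default 400, the scale of a small
#'   synthetic evaluation corpus).
#' @param sentences_per_doc Length-2 integer range of sentences per note.
#' @param pools Named list of sentence template pools (one per theme plus
#'   `neutral`); see `default_sentence_pools`.
#' @param inclusion_drop_prob Nested list `gender -> c(theme = prob)`: the
#'   biased summariser drops a sentence of that theme for that gender with
#'   this probability.
#' @param substitution_map Data frame (`source`, `replacement`, `gender`,
#'   `prob`): phrase substitutions applied to the target gender's summaries.
#' @param sentiment_shift Named vector `c(female=, male=)`: probability of
#'   appending a negative-tone sentence to that gender's summary.
#' @param hallucination_rate Named vector: probability of appending a
#'   sentence naming a medical term absent from the source.
#' @param seed Mandatory integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_docs = 400, sentences_per_doc = c(10, 16),
                             pools = default_sentence_pools(),
                             inclusion_drop_prob = list(),
                             substitution_map = NULL,
                             sentiment_shift = c(female = 0, male = 0),
                             hallucination_rate = c(female = 0, male = 0),
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (any(vapply(pools, length, integer(1)) == 0)) stop("empty sentence pool", call. = FALSE)
  check_prob(inclusion_drop_prob, "inclusion_drop")
  check_prob(sentiment_shift, "sentiment_shift")
  check_prob(hallucination_rate, "hallucination_rate")
  if (!is.null(substitution_map)) {
    check_prob(substitution_map$prob, "substitution")
    gf <- gendered_forms(default_gender_lexicon())
    for (s in substitution_map$source) {
      if (any(tolower(tokenize_words(s)) %in% gf)) {
        stop("substitution source phrase contains gendered token: ", s, call. = FALSE)
      }
    }
  }
  structure(list(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
                 pools = pools, inclusion_drop_prob = inclusion_drop_prob,
                 substitution_map = substitution_map,
                 sentiment_shift = sentiment_shift,
                 hallucination_rate = hallucination_rate, seed = seed),
            class = "synthetic_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate counterfactual note pairs from templates
#'
#' Assembles each document from an intro sentence plus sentences drawn from
#' the theme and neutral pools; the female and male versions instantiate the
#' same templates with gendered slots, so they differ only in gendered tokens
#' and always pass [validate_pair()]. Byte-identical across reruns with the
#' same seed.
#'
#' @param config A `synthetic_config`.
#' @return A validated `counterfactual_pairs` data frame.
#' @export
generate_pairs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pools <- config$pools
  pool_names <- names(pools)
  with_seed(config$seed, {
    n <- config$n_docs
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      surname <- sample(.surnames, 1)
      age <- sample(68:95, 1)
      n_s <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2], 1)
      intro <- "{TITLE} {SURNAME} is an older {PERSON} aged {AGE} who lives alone in a small flat."
      themes <- sample(pool_names, n_s - 1, replace = TRUE)
      templates <- vapply(themes, function(th) sample(pools[[th]], 1), character(1))
      templates <- c(intro, templates)
      f <- paste(vapply(templates, fill_slots, character(1), gender = "female",
                        surname = surname, age = age), collapse = " ")
      m <- paste(vapply(templates, fill_slots, character(1), gender = "male",
                        surname = surname, age = age), collapse = " ")
      rows[[i]] <- data.frame(doc_id = sprintf("doc%04d", i), female_text = f,
                              male_text = m,
                              gender_original = if (i %% 2 == 1) "female" else "male",
                              validated = NA, mismatch = NA_character_,
                              stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, rows)
    class(pairs) <- c("counterfactual_pairs", class(pairs))
    validate_pairs(pairs)
  })
}

# deterministic 31-bit string hash for per-cell seeding
hash_string <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  h
}

classify_sentence_theme <- function(sentence, lexicons) {
  lem <- content_lemmas(sentence, remove_stopwords = FALSE)
  for (th in names(lexicons)) {
    phr <- strsplit(lexicons[[th]], " ", fixed = TRUE)
    if (any(vapply(phr, function(p) count_phrase(lem, p) > 0, logical(1)))) return(th)
  }
  "neutral"
}

infer_text_gender <- function(text) {
  toks <- tolower(tokenize_words(text))
  f <- sum(toks %in% c("she", "her", "hers", "mrs", "ms", "woman", "herself"))
  m <- sum(toks %in% c("he", "his", "him", "mr", "man", "himself"))
  if (f >= m) "female" else "male"
}

#' Extractive mock summariser with injected, parameterised bias
#'
#' Behaves like [mock_summarizer()] (first k sentences per level) but, for
#' the targeted gender, drops theme sentences with the configured
#' probability before truncation, applies phrase substitutions, and can
#' append a negative-tone sentence (sentiment shift) or a sentence naming an
#' absent medical term (hallucination). Gender is inferred from the text
#' itself, so both genders pass through byte-identical code; all randomness
#' is seeded per (text, level), making reruns identical. With all bias
#' parameters at zero it reproduces the unbiased mock exactly.
#'
#' @param config A `synthetic_config` carrying the bias parameters and seed.
#' @param budget Sentences-per-level mapping.
#' @param lexicons Theme lexicons used to classify sentences.
#' @param terms Medical terms available for hallucination injection.
#' @param name Spec name (default `"biased_mock"`).
#' @return A `summarizer_spec`.
#' @export
biased_mock_summarizer <- function(config, budget = default_sentence_budget(),
                                   lexicons = load_theme_lexicons(),
                                   terms = default_medical_terms(),
                                   name = "biased_mock") {
  stopifnot(inherits(config, "synthetic_config"))
  force(budget); force(lexicons); force(terms)
  fn <- function(text, max_tokens_level) {
    lvl <- as.character(max_tokens_level)
    if (!(lvl %in% names(budget))) stop("unknown max_tokens level: ", lvl, call. = FALSE)
    gender <- infer_text_gender(text)
    cell_seed <- (config$seed %% 65536 * 32003 + hash_string(text) %% 1000003 * 131 +
                    match(lvl, names(budget))) %% 2147483647
    with_seed(cell_seed, {
      sents <- split_sentences(text)
      drop_probs <- config$inclusion_drop_prob[[gender]]
      if (!is.null(drop_probs)) {
        keep <- vapply(sents, function(s) {
          th <- classify_sentence_theme(s, lexicons)
          p <- drop_probs[th]
          is.na(p) || stats::runif(1) >= p
        }, logical(1))
        sents <- sents[keep]
        if (!length(sents)) sents <- split_sentences(text)[1]
      }
      k <- budget[[lvl]]
      out <- if (is.infinite(k)) sents else utils::head(sents, k)
      out <- paste(out, collapse = " ")
      sm <- config$substitution_map
      if (!is.null(sm)) {
        for (r in seq_len(nrow(sm))) {
          if (sm$gender[r] != gender) next
          pat <- paste0("\\b", sm$source[r], "\\b")
          m <- gregexpr(pat, out, ignore.case = TRUE)[[1]]
          if (m[1] == -1) next
          do_rep <- stats::runif(length(m)) < sm$prob[r]
          if (any(do_rep)) {
            pieces <- regmatches(out, gregexpr(pat, out, ignore.case = TRUE))
            pieces[[1]][do_rep] <- sm$replacement[r]
            regmatches(out, gregexpr(pat, out, ignore.case = TRUE)) <- pieces
          }
        }
      }
      if (stats::runif(1) < config$sentiment_shift[[gender]]) {
        out <- paste(out, "The overall situation at home appears poor and unsafe.")
      }
      if (stats::runif(1) < config$hallucination_rate[[gender]]) {
        absent <- setdiff(terms, scan_terms(text, terms))
        if (length(absent)) {
          out <- paste0(out, " There is also a past diagnosis of ",
                        sample(absent, 1), ".")
        }
      }
      out
    })
  }
  summarizer_spec(name, fn, deterministic = TRUE)
}
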