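#' Default medical term list
#'
#' Editable starter list of common long-term-care diagnoses shipped as a
#' plain-text file (one term per line). Counts reported by the audit should
#' always be read alongside the list version in use.
#'
#' @return Character vector of lowercase terms.
#' @export
default_medical_terms <- function() {
  cached_resource("medical_terms",
                  function() read_term_file(carefair_extdata("medical_terms.txt")))
}

#' Scan a text for medical terms
#'
#' Lemma-level, word-boundary, case-insensitive membership: "dementias"
#' matches the term "dementia" (same lemma) but "demented" does not
#' (different lemma). Negation is not parsed ("no history of dementia" still
#' counts as present) -- a documented limitation of plain term search.
#'
#' @param text A character string.
#' @param terms Character vector of terms (single words or phrases).
#' @return The subset of `terms` present in the text.
#' @export
scan_terms <- function(text, terms = default_medical_terms()) {
  if (length(terms) == 0) return(character(0))
  lem <- content_lemmas(text, remove_stopwords = FALSE)
  if (length(lem) == 0) return(character(0))
  term_lemmas <- lapply(terms, function(t) lemmatize(tokenize_words(t)))
  present <- vapply(term_lemmas, function(p) count_phrase(lem, p) > 0, logical(1))
  terms[present]
}

#' Hallucination audit of summaries against their source texts
#'
#' A term is hallucinated when it appears in a summary but not in the source
#' text that was summarised (the matching gender's version of the pair).
#' Produces one record per (summary, term) and aggregate hallucination counts
#' by gender and model.
#'
#' @param pairs `counterfactual_pairs` providing the source texts.
#' @param records Summary records.
#' @param terms Medical term list.
#' @return List of class `hallucination_audit`: `records` (data frame with
#'   `in_source`, `in_summary`, `hallucinated`), `by_gender`, `by_model_gender`,
#'   `n_opportunities`.
#' @export
audit_hallucinations <- function(pairs, records, terms = default_medical_terms()) {
  orphans <- setdiff(unique(records$doc_id), pairs$doc_id)
  if (length(orphans)) {
    stop("summaries with no source pair: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  # scan each distinct source text once
  src_key <- paste(records$doc_id, records$gender)
  idx <- match(records$doc_id, pairs$doc_id)
  src_text <- ifelse(records$gender == "female", pairs$female_text[idx],
                     pairs$male_text[idx])
  uniq <- !duplicated(src_key)
  src_terms <- stats::setNames(lapply(src_text[uniq], scan_terms, terms = terms),
                               src_key[uniq])
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    in_src <- terms %in% src_terms[[src_key[i]]]
    in_sum <- terms %in% scan_terms(records$summary_text[i], terms)
    out[[i]] <- data.frame(doc_id = records$doc_id[i], gender = records$gender[i],
                           model = records$model[i], max_tokens = records$max_tokens[i],
                           term = terms, in_source = in_src, in_summary = in_sum,
                           hallucinated = in_sum & !in_src,
                           stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  by_gender <- stats::aggregate(hallucinated ~ gender, data = rec, FUN = sum)
  by_mg <- stats::aggregate(hallucinated ~ model + gender, data = rec, FUN = sum)
  structure(list(records = rec, by_gender = by_gender, by_model_gender = by_mg,
                 n_opportunities = nrow(rec)),
            class = "hallucination_audit")
}

#' @export
print.hallucination_audit <- function(x, ...) {
  cat(sprintf("Hallucination audit: %d (summary, term) opportunities, %d hallucinations\n",
              x$n_opportunities, sum(x$records$hallucinated)))
  print(x$by_gender, row.names = FALSE)
  invisible(x)
}

#' Hallucination opportunity space
#'
#' Number of (document, version, parameter set, term) combinations scanned:
#' the product of the four dimensions. With 617 documents, 2 gender versions,
#' 24 parameter sets (4 models x 6 length caps) and 54 terms this is
#' 1,599,264.
#'
#' @param n_docs,n_versions,n_param_sets,n_terms Positive integers.
#' @return The product (numeric, exact for realistic sizes).
#' @export
opportunity_count <- function(n_docs, n_versions, n_param_sets, n_terms) {
  args <- c(n_docs, n_versions, n_param_sets, n_terms)
  if (any(args <= 0) || any(args != round(args))) {
    stop("all dimensions must be positive integers", call. = FALSE)
  }
  prod(as.numeric(args))
}
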