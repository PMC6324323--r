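# Text featurization: tokenization, per-patient note sets, per-site top-k
# vocabulary with smoothed IDF, and sublinear TF-IDF weights.

#' Tokenize free text
#'
#' Lowercases and extracts maximal alphanumeric runs, preserving order.
#' Single-word terms only: no phrase detection, stemming, stop-word removal
#' or negation handling.
#'
#' @param text Character vector.
#' @return A list of character vectors (one per input element) when `text`
#'   has length > 1, otherwise a single character vector.
#' @export
tokenize <- function(text) {
  toks <- regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))
  if (length(toks) == 1) toks[[1]] else toks
}

#' Pool a patient's windowed notes into a note set
#'
#' A note set is the token multiset pooled over all of one patient's notes
#' from the first 24 hours. Patients with no notes get an empty note set
#' (all term weights are then zero).
#'
#' @param notes Note table already clipped to the window
#'   (columns `patient_id`, `t`, `text`).
#' @param patient_ids Character vector of patients to produce note sets for
#'   (defaults to those present in `notes`).
#' @return Named list (by patient id) of named integer token-count vectors.
#' @export
build_note_sets <- function(notes, patient_ids = NULL) {
  if (is.null(patient_ids)) patient_ids <- unique(notes$patient_id)
  empty <- setNames(integer(0), character(0))
  out <- setNames(replicate(length(patient_ids), empty, simplify = FALSE),
                  patient_ids)
  if (is.null(notes) || nrow(notes) == 0) return(out)
  keep <- notes$patient_id %in% patient_ids
  if (!any(keep)) return(out)
  toks <- regmatches(tolower(notes$text[keep]),
                     gregexpr("[a-z0-9]+", tolower(notes$text[keep])))
  pid <- rep.int(notes$patient_id[keep], lengths(toks))
  tok <- unlist(toks, use.names = FALSE)
  if (length(tok) == 0) return(out)
  DT <- data.table::data.table(patient_id = pid, term = tok)
  agg <- DT[, list(count = .N), by = list(patient_id, term)]
  counts <- split(setNames(agg$count, agg$term), agg$patient_id)
  out[names(counts)] <- counts
  out
}

#' Fit a top-k vocabulary with document frequencies and IDF
#'
#' Selects the k most frequent terms by total training token count (ties
#' broken lexicographically), recording each term's training document
#' frequency (number of note sets containing it) and smoothed inverse
#' document frequency `idf = ln((1 + N) / (1 + df)) + 1`, where N is the
#' number of training note sets. Smoothing keeps idf strictly positive even
#' for terms present in every training note set. Must be fitted on training
#' note sets only.
#'
#' @param note_sets Named list of token-count vectors ([build_note_sets()]).
#' @param k Vocabulary size (default 1000). With fewer than k distinct
#'   terms, all terms are kept with a warning.
#' @return An object of class `vocabulary`: list with `terms`, `df`, `idf`,
#'   `n_docs`, `k`.
#' @export
fit_vocabulary <- function(note_sets, k = 1000) {
  stopifnot(k >= 1)
  N <- length(note_sets)
  nm <- unlist(lapply(note_sets, names), use.names = FALSE)
  ct <- unlist(note_sets, use.names = FALSE)
  if (length(nm) == 0)
    stop("cannot fit a vocabulary: all note sets are empty", call. = FALSE)
  DT <- data.table::data.table(term = nm, count = ct)
  agg <- DT[, list(tot = sum(count), df = .N), by = term]
  data.table::setorder(agg, -tot, term)
  if (nrow(agg) < k) {
    warning(sprintf("only %d distinct terms available for a %d-term vocabulary",
                    nrow(agg), k))
    k_eff <- nrow(agg)
  } else k_eff <- as.integer(k)
  top <- agg[seq_len(k_eff)]
  structure(
    list(terms = top$term, df = top$df,
         idf = log((1 + N) / (1 + top$df)) + 1,
         n_docs = N, k = k_eff),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("vocabulary: %d terms from %d training note sets\n",
              x$k, x$n_docs))
  cat("  top terms:", paste(head(x$terms, 8), collapse = ", "), "\n")
  invisible(x)
}

#' Sublinear TF-IDF weights for one note set
#'
#' Weight of term j is `(1 + ln tf_j) * idf_j` for `tf_j > 0`, else 0
#' (sublinear term frequency: copy-pasted repetitions yield diminishing
#' returns). Out-of-vocabulary tokens contribute nothing. Vectors are not
#' length-normalized; all predictors are z-standardized jointly before the
#' ridge fit instead.
#'
#' @param note_set Named integer token-count vector.
#' @param vocabulary A fitted [fit_vocabulary()] object.
#' @return Numeric weight vector over the vocabulary terms (named).
#' @export
tfidf_vector <- function(note_set, vocabulary) {
  w <- setNames(numeric(length(vocabulary$terms)), vocabulary$terms)
  if (length(note_set) == 0) return(w)
  i <- match(names(note_set), vocabulary$terms)
  ok <- !is.na(i)
  w[i[ok]] <- (1 + log(as.numeric(note_set[ok]))) * vocabulary$idf[i[ok]]
  w
}

#' Sublinear TF-IDF matrix for a list of note sets
#'
#' @param note_sets Named list of token-count vectors.
#' @param vocabulary A fitted [fit_vocabulary()] object.
#' @return Numeric matrix (note sets x vocabulary terms); column names are
#'   prefixed `term.`.
#' @export
tfidf_matrix <- function(note_sets, vocabulary) {
  n <- length(note_sets)
  kk <- length(vocabulary$terms)
  M <- matrix(0, n, kk,
              dimnames = list(names(note_sets),
                              paste0("term.", vocabulary$terms)))
  nm <- unlist(lapply(note_sets, names), use.names = FALSE)
  if (length(nm) > 0) {
    ct <- unlist(note_sets, use.names = FALSE)
    ri <- rep.int(seq_len(n), lengths(note_sets))
    ci <- match(nm, vocabulary$terms)
    ok <- !is.na(ci)
    M[cbind(ri[ok], ci[ok])] <-
      (1 + log(as.numeric(ct[ok]))) * vocabulary$idf[ci[ok]]
  }
  M
}
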