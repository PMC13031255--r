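# Summary-versus-segment semantic similarity scores.
#
# Three measures quantify how well a written summary captures a heard
# segment. Two are word based (static embeddings): the written-summary score
# sums, over summary words, the maximum cosine to any segment word (sensitive
# to summary length and per-word match quality); the heard-segment score
# averages, over segment words, the maximum cosine to any summary word
# (coverage of the segment). The third is a single-vector contextual score:
# the cosine between context-sensitive encodings of the two texts.

#' Tokenize text into words
#'
#' Lowercases, strips punctuation, and splits on whitespace, preserving word
#' order. Intra-word apostrophes are kept (`"don't"` stays one token).
#'
#' @param text character scalar (or vector, concatenated in order).
#' @return character vector of tokens; empty input gives `character(0)`.
#' @export
tokenize <- function(text) {
  if (length(text) == 0) return(character(0))
  x <- tolower(paste(text, collapse = " "))
  x <- gsub("[^[:alnum:]'[:space:]]+", " ", x)
  x <- gsub("(^|\\s)'+|'+(\\s|$)", " ", x)  # strip quote-style apostrophes
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return `sum(u * v) / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stopf("'u' and 'v' must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine undefined for a zero-norm vector")
  sum(u * v) / (nu * nv)
}

# Row-normalize a lookup matrix; rows are unit vectors afterwards.
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stopf("zero-norm embedding vector encountered")
  m / nrm
}

# Pairwise cosine matrix between two word lists under an embedding table,
# with out-of-vocabulary words dropped (and reported).
cosine_matrix <- function(words_a, words_b, emb) {
  la <- embedding_lookup(emb, words_a)
  lb <- embedding_lookup(emb, words_b)
  list(m = if (nrow(la$vectors) && nrow(lb$vectors))
         unit_rows(la$vectors) %*% t(unit_rows(lb$vectors)) else
         matrix(numeric(0), nrow(la$vectors), nrow(lb$vectors)),
       n_a = nrow(la$vectors), n_b = nrow(lb$vectors),
       oov_a = la$oov, oov_b = lb$oov)
}

#' Written-summary semantic score
#'
#' For each in-vocabulary summary word, the maximum cosine similarity to any
#' in-vocabulary segment word is taken; the score is the sum of these maxima.
#' It grows with summary length and per-word match quality, so a single
#' verbatim match cannot dominate, while longer conceptual summaries are not
#' penalized. Out-of-vocabulary words are skipped and counted in the
#' `"oov"` attribute, never replaced by zero vectors.
#'
#' @param summary,segment character vectors of words (see [tokenize()]).
#' @param emb an [embedding_table()].
#' @return the summed maxima (0 for an empty summary), with attribute `oov`
#'   counting skipped words; errors if the segment has no in-vocabulary word.
#' @examples
#' emb <- embedding_table(c("dog", "cat", "rain"),
#'                        rbind(c(1, 0), c(0.8, 0.6), c(0, 1)))
#' written_summary_score(c("cat", "rain"), "dog", emb)  # 0.8 + 0.0
#' @export
written_summary_score <- function(summary, segment, emb) {
  cm <- cosine_matrix(summary, segment, emb)
  if (cm$n_b == 0)
    stopf("segment has no in-vocabulary word")
  score <- if (cm$n_a == 0) 0 else sum(apply(cm$m, 1, max))
  structure(score, oov = c(summary = length(cm$oov_a),
                           segment = length(cm$oov_b)))
}

#' Heard-segment semantic score
#'
#' For each in-vocabulary segment word, the maximum cosine similarity to any
#' summary word is taken; the score is the mean of these maxima, measuring
#' how much of the heard segment the summary covers. Bounded in `[-1, 1]`,
#' and invariant to duplicated summary words (unlike
#' [written_summary_score()], which is additive over summary words).
#'
#' @inheritParams written_summary_score
#' @return the mean of per-segment-word maxima, with attribute `oov`; errors
#'   if the summary has no in-vocabulary word.
#' @export
heard_segment_score <- function(summary, segment, emb) {
  cm <- cosine_matrix(segment, summary, emb)
  if (cm$n_b == 0)
    stopf("summary has no in-vocabulary word")
  if (cm$n_a == 0) stopf("segment has no in-vocabulary word")
  structure(mean(apply(cm$m, 1, max)),
            oov = c(summary = length(cm$oov_b), segment = length(cm$oov_a)))
}

#' Mean-vector contextual encoder
#'
#' Builds a deterministic text encoder from a static embedding table: the
#' encoding of a text is the mean of its in-vocabulary word vectors. It
#' honors the contextual-encoder contract (same text, same vector) and serves
#' as the packaged test double for context-sensitive sentence encoders, whose
#' pretrained weights are outside the package's scope.
#'
#' @param emb an [embedding_table()].
#' @return a function mapping a text string to a numeric vector.
#' @export
mean_vector_encoder <- function(emb) {
  force(emb)
  function(text) {
    lk <- embedding_lookup(emb, tokenize(text))
    if (nrow(lk$vectors) == 0)
      stopf("text has no in-vocabulary word to encode")
    colMeans(lk$vectors)
  }
}

#' Contextual single-vector similarity
#'
#' Encodes both texts with a deterministic sentence encoder and returns the
#' cosine of the two vectors.
#'
#' @param summary_text,segment_text non-empty strings.
#' @param enc encoder function text -> numeric vector (e.g.
#'   [mean_vector_encoder()]).
#' @return cosine similarity in `[-1, 1]`.
#' @export
contextual_similarity <- function(summary_text, segment_text, enc) {
  if (!is.character(summary_text) || !nzchar(trimws(summary_text[1])))
    stopf("'summary_text' must be a non-empty string")
  if (!is.character(segment_text) || !nzchar(trimws(segment_text[1])))
    stopf("'segment_text' must be a non-empty string")
  cosine(enc(summary_text), enc(segment_text))
}

#' Pentile similarity profile of a summary
#'
#' Splits the segment's words into five contiguous pentiles (sizes differing
#' by at most one word, remainder to the earliest bins) and scores the
#' summary against each pentile with the chosen measure. Profiles rising
#' toward bin 5 indicate a recency bias: the summary over-represents the
#' final fifths of what was heard.
#'
#' @param summary character vector of summary words (or text for
#'   `method = "contextual"`).
#' @param segment character vector of at least five segment words.
#' @param method `"written"`, `"heard"` or `"contextual"`.
#' @param emb an [embedding_table()] (word-based methods).
#' @param enc an encoder function (contextual method).
#' @return numeric vector of five scores.
#' @export
pentile_similarity_profile <- function(summary, segment,
                                       method = c("written", "heard",
                                                  "contextual"),
                                       emb = NULL, enc = NULL) {
  method <- match.arg(method)
  if (length(segment) < 5) stopf("segment must have at least 5 words")
  idx <- pentile_index(length(segment))
  vapply(1:5, function(b) {
    part <- segment[idx == b]
    switch(method,
      written = as.numeric(written_summary_score(summary, part, emb)),
      heard = as.numeric(heard_segment_score(summary, part, emb)),
      contextual = contextual_similarity(paste(summary, collapse = " "),
                                         paste(part, collapse = " "), enc))
  }, numeric(1))
}

#' Score all summaries of a session
#'
#' Computes the three similarity measures for every trial record carrying a
#' summary.
#'
#' @param records list of trial records (see [simulate_session()]).
#' @param emb an [embedding_table()].
#' @param enc encoder for the contextual score; defaults to
#'   [mean_vector_encoder()] over `emb`.
#' @return data.frame with `participant_id`, `trial_id`, `written_summary_score`,
#'   `heard_segment_score`, `contextual_score`, `n_summary_words`,
#'   `n_segment_words`; trials without a summary are omitted.
#' @export
score_summaries <- function(records, emb, enc = mean_vector_encoder(emb)) {
  rows <- lapply(records, function(r) {
    if (is.null(r$summary_words) || length(r$summary_words) == 0) return(NULL)
    data.frame(
      participant_id = r$participant_id,
      trial_id = r$trial_id,
      written_summary_score =
        as.numeric(written_summary_score(r$summary_words, r$segment_words, emb)),
      heard_segment_score =
        as.numeric(heard_segment_score(r$summary_words, r$segment_words, emb)),
      contextual_score =
        contextual_similarity(paste(r$summary_words, collapse = " "),
                              paste(r$segment_words, collapse = " "), enc),
      n_summary_words = length(r$summary_words),
      n_segment_words = length(r$segment_words),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Correlation matrix of the three similarity measures
#'
#' @param scores data.frame from [score_summaries()] (at least 3 rows).
#' @return 3x3 symmetric Pearson correlation matrix with unit diagonal.
#' @export
correlate_measures <- function(scores) {
  cols <- c("written_summary_score", "heard_segment_score", "contextual_score")
  if (!all(cols %in% names(scores))) stopf("'scores' is missing measure columns")
  if (nrow(scores) < 3) stopf("need at least 3 scored trials")
  m <- as.matrix(scores[cols])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stopf("correlation undefined: zero variance in %s",
          paste(cols[sds == 0], collapse = ", "))
  stats::cor(m)
}
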