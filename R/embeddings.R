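#' Word-embedding tables
#'
#' A minimal container for static word embeddings: a vocabulary and one fixed
#' dimension vector per word. Real embeddings (e.g. GloVe distributed in
#' word2vec text format) are loaded with [read_word2vec()]; deterministic toy
#' tables for testing come from [make_toy_embeddings()]. Lookups of
#' out-of-vocabulary words are reported as misses, never substituted with zero
#' vectors (a zero vector has no direction and would corrupt max-cosine
#' scores).
#'
#' @param words character vector of unique words.
#' @param vectors numeric matrix, one row per word.
#' @return an `embedding_table`.
#' @export
embedding_table <- function(words, vectors) {
  if (!is.character(words) || length(words) == 0)
    stopf("'words' must be a non-empty character vector")
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(words))
    stopf("'vectors' must have one row per word")
  if (anyDuplicated(words))
    stopf("duplicate words in embedding vocabulary")
  if (!is.numeric(vectors) || any(!is.finite(vectors)))
    stopf("'vectors' must be finite numeric")
  rownames(vectors) <- words
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words, dimension %d\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Deterministic toy embeddings
#'
#' Generates unit-norm Gaussian random vectors for a vocabulary, one per
#' distinct word, deterministically from a seed. Intended as a stand-in for
#' pretrained weights in tests and simulations: cosine geometry behaves like a
#' real table (self-similarity 1, near-orthogonal unrelated words in high
#' dimension) with no download.
#'
#' @param vocab character vector of words (duplicates collapsed, order kept).
#' @param dim embedding dimension, at least 2.
#' @param seed integer seed.
#' @return an [embedding_table()].
#' @examples
#' emb <- make_toy_embeddings(c("dog", "cat", "rain"), dim = 8, seed = 1)
#' cosine(emb$vectors["dog", ], emb$vectors["dog", ])
#' @export
make_toy_embeddings <- function(vocab, dim = 16, seed = 1) {
  vocab <- unique(as.character(vocab))
  if (length(vocab) == 0) stopf("'vocab' must contain at least one word")
  if (!is_scalar_number(dim) || dim < 2) stopf("'dim' must be at least 2")
  dim <- as.integer(dim)
  m <- with_seed(seed,
    matrix(stats::rnorm(length(vocab) * dim), nrow = length(vocab), ncol = dim))
  m <- m / sqrt(rowSums(m^2))
  embedding_table(vocab, m)
}

# Look up words; returns the sub-matrix of found vectors (possibly 0-row) and
# the out-of-vocabulary words.
embedding_lookup <- function(emb, words) {
  if (!inherits(emb, "embedding_table")) stopf("'emb' must be an embedding_table")
  hit <- words %in% rownames(emb$vectors)
  list(vectors = emb$vectors[words[hit], , drop = FALSE],
       oov = words[!hit])
}

#' Read and write word2vec text format
#'
#' The word2vec text format is a header line `"<vocab_size> <dim>"` followed
#' by one line per word: the word then `dim` space-separated numbers.
#'
#' @param path file path.
#' @return [read_word2vec()] returns an [embedding_table()];
#'   [write_word2vec()] returns `path` invisibly.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stopf("word2vec file '%s' has no vectors", path)
  hdr <- scan(text = lines[1], what = numeric(), quiet = TRUE)
  if (length(hdr) != 2) stopf("malformed word2vec header in '%s'", path)
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) != n)
    stopf("word2vec header promises %d words, found %d", n, length(body))
  parts <- strsplit(trimws(body), "[[:space:]]+")
  words <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) {
    v <- as.numeric(p[-1])
    if (length(v) != d || any(is.na(v)))
      stopf("malformed vector line for word '%s'", p[[1]])
    v
  }, numeric(d)))
  embedding_table(words, vecs)
}

#' @param emb an [embedding_table()].
#' @rdname read_word2vec
#' @export
write_word2vec <- function(emb, path) {
  if (!inherits(emb, "embedding_table")) stopf("'emb' must be an embedding_table")
  v <- emb$vectors
  lines <- c(sprintf("%d %d", nrow(v), ncol(v)),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i], formatC(v[i, ], format = "g", digits = 9)),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
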