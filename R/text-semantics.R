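# Text-level semantic creativity scores: global semantic distance over
# sliding windows of word embeddings, and divergent semantic integration
# (mean pairwise cosine distance over contextual token representations).

#' Construct a token sequence
#'
#' @param tokens character vector of tokens, in text order.
#' @param source_id,condition optional identifiers.
#' @param n_dropped count of tokens removed during cleaning (bookkeeping for
#'   out-of-vocabulary drops).
#' @return A list of class \code{"token_sequence"}.
#' @export
token_sequence <- function(tokens, source_id = NA_character_,
                           condition = NA_character_, n_dropped = 0L) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0L)
    stop("token sequence is empty after cleaning", call. = FALSE)
  structure(list(tokens = tokens, source_id = source_id,
                 condition = condition, n_dropped = as.integer(n_dropped)),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("Token sequence: ", length(x$tokens), " tokens", sep = "")
  if (!is.na(x$source_id)) cat(" [", x$source_id, "]", sep = "")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat("\n ", paste(utils::head(x$tokens, 8L), collapse = " "),
      if (length(x$tokens) > 8L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tokenize a text into a cleaned token sequence
#'
#' Strips punctuation according to a configurable character class, splits on
#' whitespace, and (optionally) drops tokens absent from a lexicon, recording
#' the drop count. The splitter is pluggable: languages without whitespace
#' word boundaries can pass a \code{splitter} function (e.g. wrapping an
#' external Chinese segmenter) that maps a string to a character vector of
#' tokens.
#'
#' @param text a single character string.
#' @param lexicon optional \code{"embedding_lexicon"}; tokens not in its
#'   vocabulary are dropped and counted.
#' @param drop_pattern regular expression character class removed from the
#'   text before splitting. The default removes punctuation but keeps
#'   underscores (synthetic tokens use them).
#' @param splitter function mapping the cleaned string to a character vector
#'   of tokens; defaults to whitespace splitting.
#' @param source_id,condition optional identifiers carried on the result.
#' @return A \code{"token_sequence"} with \code{n_dropped} set to the number
#'   of out-of-vocabulary tokens removed.
#' @examples
#' tokenize("a, b! a")
#' @export
tokenize <- function(text, lexicon = NULL,
                     drop_pattern = "[^[:alnum:][:space:]_]",
                     splitter = NULL,
                     source_id = NA_character_, condition = NA_character_) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string", call. = FALSE)
  cleaned <- gsub(drop_pattern, " ", text)
  tokens <- if (is.null(splitter)) {
    strsplit(trimws(cleaned), "[[:space:]]+")[[1]]
  } else {
    splitter(cleaned)
  }
  tokens <- tokens[nzchar(tokens)]
  n_dropped <- 0L
  if (!is.null(lexicon)) {
    keep <- tokens %in% rownames(lexicon)
    n_dropped <- sum(!keep)
    tokens <- tokens[keep]
  }
  if (length(tokens) == 0L)
    stop("no tokens remain after cleaning", call. = FALSE)
  token_sequence(tokens, source_id = source_id, condition = condition,
                 n_dropped = n_dropped)
}

new_semantic_score <- function(value, metric, n, n_dropped = 0L) {
  structure(list(value = value, metric = metric, n = as.integer(n),
                 n_dropped = as.integer(n_dropped)),
            class = "semantic_score")
}

#' @export
print.semantic_score <- function(x, ...) {
  unit <- switch(x$metric, gsd = "windows", dsi = "pairs", "units")
  cat(toupper(x$metric), " = ", format(x$value, digits = 6), "  (", x$n, " ",
      unit, if (x$n_dropped > 0) paste0(", ", x$n_dropped, " tokens dropped"),
      ")\n", sep = "")
  invisible(x)
}

# Window start positions and extents for the sliding-window score.
gsd_windows <- function(n, window, step, keep_partial) {
  starts <- seq.int(1L, n, by = step)
  ends <- pmin(starts + window - 1L, n)
  len <- ends - starts + 1L
  keep <- if (keep_partial) len >= 2L else len == window
  cbind(start = starts[keep], end = ends[keep])
}

#' Global semantic distance of a token stream
#'
#' The objective creativity score for a piece of writing. The token stream is
#' divided into windows of \code{window} words advancing by \code{step}
#' words; each window is represented by the mean of its token embedding
#' vectors; the score is the mean cosine distance (1 minus cosine similarity)
#' between adjacent window vectors. A trailing partial window is kept when it
#' holds at least 2 tokens (default), so short stories retain their final
#' semantic move.
#'
#' @param tokens a \code{"token_sequence"} (or character vector of tokens).
#' @param lexicon an \code{"embedding_lexicon"}; out-of-vocabulary tokens are
#'   dropped and counted, not imputed.
#' @param window window length in words.
#' @param step window advance in words.
#' @param keep_partial keep a trailing window of 2..(window-1) tokens?
#' @return A \code{"semantic_score"} with \code{metric = "gsd"}, the number
#'   of windows in \code{n}, and the out-of-vocabulary drop count.
#' @examples
#' lex <- make_lexicon(lexicon_spec(2, 5, dim = 8, within_noise_sd = 0))
#' story <- make_story(lex, 40, c(0.5, 0.5), seed = 7)
#' global_semantic_distance(story, lex)
#' @export
global_semantic_distance <- function(tokens, lexicon, window = 10L,
                                     step = 5L, keep_partial = TRUE) {
  if (is.character(tokens)) tokens <- token_sequence(tokens)
  stopifnot(inherits(tokens, "token_sequence"),
            inherits(lexicon, "embedding_lexicon"))
  window <- as.integer(window); step <- as.integer(step)
  if (window < 2L || step < 1L)
    stop("'window' must be >= 2 and 'step' >= 1", call. = FALSE)
  toks <- tokens$tokens
  keep <- toks %in% rownames(lexicon)
  n_dropped <- tokens$n_dropped + sum(!keep)
  toks <- toks[keep]
  n <- length(toks)
  win <- gsd_windows(n, window, step, keep_partial)
  min_tokens <- if (keep_partial) step + 2L else window + step
  if (nrow(win) < 2L)
    stop("text too short for global semantic distance: ", n,
         " in-vocabulary tokens, need at least ", min_tokens, call. = FALSE)
  vecs <- lexicon[toks, , drop = FALSE]
  means <- apply(win, 1L, function(w)
    colMeans(vecs[w[1L]:w[2L], , drop = FALSE]))
  means <- t(means)  # windows x dim
  d <- vapply(seq_len(nrow(means) - 1L), function(k)
    cosine_dist(means[k, ], means[k + 1L, ]), numeric(1))
  new_semantic_score(mean(d), "gsd", nrow(win), n_dropped)
}

#' Construct a sentence set
#'
#' @param sentences a list of character vectors, one per sentence, each a
#'   token sequence in order. Every sentence must be nonempty.
#' @return A list of class \code{"sentence_set"}.
#' @export
sentence_set <- function(sentences) {
  if (!is.list(sentences) || length(sentences) == 0L)
    stop("'sentences' must be a nonempty list of token vectors", call. = FALSE)
  sentences <- lapply(sentences, as.character)
  if (any(vapply(sentences, length, integer(1)) == 0L))
    stop("every sentence must contain at least one token", call. = FALSE)
  structure(list(sentences = sentences), class = "sentence_set")
}

#' Deterministic two-layer embedder backed by a static lexicon
#'
#' Returns a contextual-embedder function satisfying the contract expected by
#' [divergent_semantic_integration()]: given a sentence (character vector of
#' tokens) it returns per-token vectors for two layers. This implementation
#' simply looks tokens up in a static lexicon and duplicates the vectors to
#' both layers, providing a fully deterministic embedding provider for
#' synthetic pipelines and tests. A transformer-backed provider can be
#' substituted by supplying any function with the same signature.
#'
#' @param lexicon an \code{"embedding_lexicon"}.
#' @return A function \code{f(sentence_tokens)} returning a list of two
#'   token x dim matrices (one per layer). Out-of-vocabulary tokens are
#'   omitted from both layers.
#' @export
lexicon_embedder <- function(lexicon) {
  stopifnot(inherits(lexicon, "embedding_lexicon"))
  function(sentence_tokens) {
    keep <- sentence_tokens %in% rownames(lexicon)
    m <- lexicon[sentence_tokens[keep], , drop = FALSE]
    list(m, m)
  }
}

#' Divergent semantic integration of a story
#'
#' Measures how distantly associated the concepts woven into a story are:
#' sentences are embedded with a two-layer contextual embedder, token vectors
#' are pooled across all sentences of the story, and the score is the mean
#' cosine distance over every unordered token pair, within each layer. By
#' default distances from the two layers are pooled with equal weight
#' (\code{combine = "distances"}); \code{combine = "vectors"} instead
#' averages the two layers' vectors per token before computing one set of
#' pairwise distances.
#'
#' @param sentences a \code{"sentence_set"}.
#' @param embedder a function mapping a sentence (character vector) to a list
#'   of exactly two token x dim matrices; see [lexicon_embedder()].
#' @param combine how to combine the two layers: pool the pairwise distances
#'   from both layers (default) or average vectors across layers first.
#' @return A \code{"semantic_score"} with \code{metric = "dsi"} and the
#'   number of pairwise distances averaged in \code{n}.
#' @export
divergent_semantic_integration <- function(sentences, embedder,
                                           combine = c("distances", "vectors")) {
  stopifnot(inherits(sentences, "sentence_set"), is.function(embedder))
  combine <- match.arg(combine)
  per_layer <- lapply(sentences$sentences, function(s) {
    out <- embedder(s)
    if (!is.list(out) || length(out) != 2L)
      stop("embedder must return exactly two layers", call. = FALSE)
    if (nrow(out[[1L]]) != nrow(out[[2L]]))
      stop("embedder layers disagree on token count", call. = FALSE)
    out
  })
  layer1 <- do.call(rbind, lapply(per_layer, `[[`, 1L))
  layer2 <- do.call(rbind, lapply(per_layer, `[[`, 2L))
  n_tok <- nrow(layer1)
  if (n_tok < 2L)
    stop("divergent semantic integration needs at least 2 embedded tokens",
         call. = FALSE)
  pair_dists <- function(m) {
    idx <- edge_index(nrow(m))
    vapply(seq_len(nrow(idx)), function(e)
      cosine_dist(m[idx[e, 1L], ], m[idx[e, 2L], ]), numeric(1))
  }
  if (combine == "distances") {
    d <- c(pair_dists(layer1), pair_dists(layer2))
  } else {
    d <- pair_dists((layer1 + layer2) / 2)
  }
  new_semantic_score(mean(d), "dsi", length(d))
}
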