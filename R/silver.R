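#' Generate silver topics for known-item tuning
#'
#' A silver topic is an automatically generated query/description pair
#' standing in for a human topic, targeted at a known document; it drives
#' known-item tuning of the BM25 parameters. Generators follow a simple
#' text-to-text contract (`function(text) -> string`). The built-in
#' defaults extract the document's top TF-IDF keywords as the query and its
#' first sentence as the description, standing in for neural
#' query/description generation models, which are out of scope.
#'
#' @param corpus data frame with `doc_id`, `text`.
#' @param n number of silver topics; sampled over distinct documents.
#' @param query_generator,description_generator `function(text) -> string`,
#'   or `NULL` for the built-in defaults.
#' @param n_keywords number of TF-IDF keywords used by the default query
#'   generator.
#' @param seed integer seed; the sample is reproducible under it.
#' @return data frame with columns `target_doc_id`, `query`, `description`.
#' @export
generate_silver_topics <- function(corpus, n, query_generator = NULL,
                                   description_generator = NULL,
                                   n_keywords = 3L, seed = 1L) {
  stopifnot(is.data.frame(corpus), n >= 1)
  if (n > nrow(corpus))
    stop(sprintf("n (%d) exceeds corpus size (%d)", n, nrow(corpus)),
         call. = FALSE)
  query_generator <- query_generator %||% tfidf_query_generator(corpus, n_keywords)
  description_generator <- description_generator %||% first_sentence_generator()
  idx <- withr::with_seed(seed, sample.int(nrow(corpus), n))
  data.frame(
    target_doc_id = as.character(corpus$doc_id[idx]),
    query = vapply(corpus$text[idx], query_generator, character(1),
                   USE.NAMES = FALSE),
    description = vapply(corpus$text[idx], description_generator, character(1),
                         USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' @rdname generate_silver_topics
#' @export
tfidf_query_generator <- function(corpus, n_keywords = 3L) {
  toks <- tokenize_default(corpus$text)
  df_counts <- table(unlist(lapply(toks, unique), use.names = FALSE))
  n_docs <- nrow(corpus)
  idf <- log(n_docs / (1 + as.numeric(df_counts)))
  names(idf) <- names(df_counts)
  function(text) {
    tt <- tokenize_default(text)[[1L]]
    if (length(tt) == 0L) return("")
    tf <- table(tt)
    w <- as.numeric(tf) * idf[names(tf)]
    w[is.na(w)] <- log(n_docs)  # unseen term: maximal idf
    o <- order(-w, names(tf), method = "radix")
    paste(names(tf)[o][seq_len(min(n_keywords, length(o)))], collapse = " ")
  }
}

#' @rdname generate_silver_topics
#' @export
first_sentence_generator <- function() {
  function(text) {
    parts <- strsplit(text, "[.!?]+")[[1L]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) "" else parts[1L]
  }
}

#' Tune BM25 parameters by known-item grid search
#'
#' Evaluates every (k1, b) grid point on the silver topics: a topic succeeds
#' when its target document is retrieved at rank 1 for the silver query. The
#' point maximizing the success rate is returned, ties broken by the first
#' point in row-major grid order (k1 varying slowest). The index is built
#' once and rescored per grid point, since postings are parameter-free.
#'
#' @param corpus data frame with `doc_id`, `text`.
#' @param silver_topics data frame as returned by
#'   [generate_silver_topics()].
#' @param k1_grid,b_grid numeric grids of candidate parameters.
#' @param tokenizer tokenizer shared with the index.
#' @return a list with fields `k1`, `b`, `success_rate`, and `grid` (a data
#'   frame with the success rate of every grid point).
#' @export
tune_known_item <- function(corpus, silver_topics,
                            k1_grid = c(0.6, 0.9, 1.2, 1.5, 1.8),
                            b_grid = c(0.3, 0.5, 0.75, 0.9),
                            tokenizer = tokenize_default) {
  if (length(k1_grid) == 0L || length(b_grid) == 0L)
    stop("empty parameter grid", call. = FALSE)
  if (nrow(silver_topics) == 0L) stop("empty silver-topic list", call. = FALSE)
  index <- bm25_index(corpus, tokenizer = tokenizer)
  grid <- expand.grid(b = b_grid, k1 = k1_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("k1", "b")]
  grid$success_rate <- NA_real_
  for (g in seq_len(nrow(grid))) {
    hit <- vapply(seq_len(nrow(silver_topics)), function(i) {
      r <- bm25_search(index, silver_topics$query[i], n_docs = 1L,
                       k1 = grid$k1[g], b = grid$b[g])
      length(r$doc_ids) == 1L && r$doc_ids[1L] == silver_topics$target_doc_id[i]
    }, logical(1))
    grid$success_rate[g] <- mean(hit)
  }
  best <- which.max(grid$success_rate)  # first maximum = row-major tie-break
  list(k1 = grid$k1[best], b = grid$b[best],
       success_rate = grid$success_rate[best], grid = grid)
}

#' Preprocessing retrieval for one topic
#'
#' First phase of the pipeline: the topic's query (never its stance) is run
#' against two BM25 indices over the same corpus -- one with default
#' parameters, one with known-item-tuned parameters -- and the two result
#' lists are fused with reciprocal rank fusion, truncated to `n_docs`
#' candidates.
#'
#' @param topic one-row data frame (or list) with `topic_id` and `query`.
#' @param index_default,index_tuned [bm25_index] objects over the same
#'   corpus.
#' @param n_docs candidate-list size (default 10000).
#' @param rrf_k reciprocal-rank-fusion constant (default 60).
#' @return a [ranking] tagged `"H_P"`.
#' @export
preprocess_topic <- function(topic, index_default, index_tuned,
                             n_docs = 10000L, rrf_k = 60) {
  r1 <- bm25_search(index_default, topic$query, n_docs = n_docs,
                    topic_id = topic$topic_id, run_tag = "bm25-default")
  r2 <- bm25_search(index_tuned, topic$query, n_docs = n_docs,
                    topic_id = topic$topic_id, run_tag = "bm25-tuned")
  fused <- rrf_fuse(list(r1, r2), rrf_k = rrf_k, run_tag = "H_P")
  ranking_head(fused, n_docs)
}
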