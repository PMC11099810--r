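#' Default tokenizer
#'
#' Lowercases and splits on non-alphanumeric characters; no stemming, no
#' stopword removal. Pluggable: any function mapping a character vector to a
#' list of token vectors can replace it throughout the retrieval layer.
#'
#' @param x character vector of texts.
#' @return list of character vectors of tokens.
#' @export
tokenize_default <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Build an in-memory Okapi BM25 index
#'
#' Inverted index with per-term document frequencies and the non-negative
#' IDF form `ln((N - df + 0.5) / (df + 0.5) + 1)`. The postings and IDF do
#' not depend on `k1`/`b`, so [bm25_search()] can rescore the same index
#' under alternative parameters -- this is what makes grid-search tuning
#' cheap.
#'
#' @param corpus data frame with columns `doc_id` (unique) and `text`
#'   (non-empty for every document entering ranking).
#' @param k1 term-frequency saturation parameter, `>= 0` (default 1.2).
#' @param b length-normalization parameter in `[0, 1]` (default 0.75).
#' @param tokenizer tokenizing function, see [tokenize_default()].
#' @return an object of class `"bm25_index"`.
#' @export
bm25_index <- function(corpus, k1 = 1.2, b = 0.75, tokenizer = tokenize_default) {
  stopifnot(is.data.frame(corpus), all(c("doc_id", "text") %in% names(corpus)))
  if (nrow(corpus) == 0L) stop("empty corpus", call. = FALSE)
  if (anyDuplicated(corpus$doc_id))
    stop("duplicate doc_id in corpus (adding the same document twice)",
         call. = FALSE)
  if (!is.numeric(k1) || k1 < 0) stop("k1 must be >= 0", call. = FALSE)
  if (!is.numeric(b) || b < 0 || b > 1) stop("b must be in [0, 1]", call. = FALSE)
  toks <- tokenizer(corpus$text)
  doc_len <- lengths(toks)
  if (any(doc_len == 0L))
    stop("document(s) with empty text: ",
         paste(utils::head(corpus$doc_id[doc_len == 0L], 5L), collapse = ", "),
         call. = FALSE)
  doc_ids <- as.character(corpus$doc_id)
  post <- data.table::data.table(
    term = unlist(toks, use.names = FALSE),
    doc = rep.int(seq_along(doc_ids), doc_len))
  post <- post[, list(tf = .N), by = c("term", "doc")]
  n_docs <- length(doc_ids)
  dftab <- post[, list(df = .N), by = "term"]
  dftab[, "idf" := log((n_docs - dftab$df + 0.5) / (dftab$df + 0.5) + 1)]
  post <- merge(post, dftab[, c("term", "idf")], by = "term")
  data.table::setkeyv(post, "term")
  structure(list(postings = post, doc_ids = doc_ids,
                 doc_len = as.numeric(doc_len), avgdl = mean(doc_len),
                 n_docs = n_docs, k1 = k1, b = b, tokenizer = tokenizer),
            class = "bm25_index")
}

#' @export
print.bm25_index <- function(x, ...) {
  cat(sprintf("<bm25_index> %d documents, %d postings, k1=%.2f b=%.2f\n",
              x$n_docs, nrow(x$postings), x$k1, x$b))
  invisible(x)
}

#' Search a BM25 index
#'
#' Scores every document containing at least one query term with the Okapi
#' BM25 formula (unique query terms, unit query weight) and returns the
#' top-`n_docs`, ties broken by `doc_id` ascending. Documents matching no
#' query term are not returned, so an unmatched query yields an empty
#' ranking.
#'
#' @param index a [bm25_index].
#' @param query_text query string.
#' @param n_docs maximum number of documents to return (default 10000, the
#'   preprocessing candidate-list size).
#' @param topic_id topic id attached to the resulting ranking.
#' @param run_tag run tag of the resulting ranking.
#' @param k1,b optional parameter overrides; default to the index's own.
#' @return a [ranking].
#' @export
bm25_search <- function(index, query_text, n_docs = 10000L, topic_id = "q",
                        run_tag = "bm25", k1 = NULL, b = NULL) {
  stopifnot(inherits(index, "bm25_index"))
  if (!is.numeric(n_docs) || n_docs < 1) stop("n_docs must be >= 1", call. = FALSE)
  k1 <- k1 %||% index$k1
  b <- b %||% index$b
  terms <- unique(index$tokenizer(query_text)[[1L]])
  if (length(terms) == 0L)
    return(ranking(topic_id, character(0), numeric(0), run_tag = run_tag))
  hits <- index$postings[data.table::J(terms), nomatch = NULL]
  if (nrow(hits) == 0L)
    return(ranking(topic_id, character(0), numeric(0), run_tag = run_tag))
  dl <- index$doc_len[hits$doc]
  denom <- hits$tf + k1 * (1 - b + b * dl / index$avgdl)
  part <- hits$idf * hits$tf * (k1 + 1) / denom
  agg <- data.table::data.table(doc = hits$doc, part = part)
  agg <- agg[, list(score = sum(part)), by = "doc"]
  ids <- index$doc_ids[agg$doc]
  o <- order(-agg$score, ids, method = "radix")
  o <- o[seq_len(min(length(o), n_docs))]
  ranking(topic_id, ids[o], agg$score[o], run_tag = run_tag, sort = FALSE)
}
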