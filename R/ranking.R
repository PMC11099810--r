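#' Ordered, scored document list for one topic
#'
#' The central container of the package: an ordered list of documents with
#' scores for a single topic, as produced by retrieval, reranking, or fusion.
#' Entries are kept sorted by score (non-increasing) with ties broken by
#' `doc_id` ascending, so every operation in the package is deterministic.
#' Ranks are 1-based.
#'
#' @param topic_id single string identifying the topic.
#' @param doc_ids character vector of document ids (must be unique).
#' @param scores numeric vector of scores, one per document. When `NULL`,
#'   descending integer ranks are used so the supplied order is preserved.
#' @param run_tag string tag identifying the system that produced the list.
#' @param sort sort entries by (score desc, doc_id asc)? Set `FALSE` only
#'   when the caller guarantees scores are already non-increasing in the
#'   supplied order (e.g. rank-derived scores).
#' @return an object of class `"ranking"`.
#' @examples
#' r <- ranking("101", c("dA", "dB"), c(2.5, 1.0))
#' ranking_docs(r)
#' @export
ranking <- function(topic_id, doc_ids, scores = NULL, run_tag = "run",
                    sort = TRUE) {
  stopifnot(is.character(topic_id) || is.numeric(topic_id),
            length(topic_id) == 1L)
  topic_id <- as.character(topic_id)
  doc_ids <- as.character(doc_ids)
  if (anyDuplicated(doc_ids))
    stop(sprintf("duplicate doc_ids in ranking for topic %s: %s", topic_id,
                 paste(unique(doc_ids[duplicated(doc_ids)]), collapse = ", ")),
         call. = FALSE)
  if (is.null(scores)) scores <- rev(seq_along(doc_ids))
  scores <- as.numeric(scores)
  if (length(scores) != length(doc_ids))
    stop("`scores` and `doc_ids` must have the same length", call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("ranking scores must be finite", call. = FALSE)
  if (sort && length(doc_ids) > 1L) {
    o <- order(-scores, doc_ids, method = "radix")
    doc_ids <- doc_ids[o]
    scores <- scores[o]
  } else if (length(scores) > 1L && any(diff(scores) > 1e-12)) {
    stop("scores must be non-increasing when sort = FALSE", call. = FALSE)
  }
  structure(list(topic_id = topic_id, doc_ids = doc_ids, scores = scores,
                 run_tag = as.character(run_tag)),
            class = "ranking")
}

#' @rdname ranking
#' @param x a `ranking`.
#' @export
ranking_docs <- function(x) {
  stopifnot(inherits(x, "ranking"))
  x$doc_ids
}

#' @export
length.ranking <- function(x) length(x$doc_ids)

#' Truncate a ranking to its top-n entries
#'
#' @param x a `ranking`.
#' @param n depth; when larger than the list, the full ranking is returned.
#' @return a `ranking` with at most `n` entries.
#' @export
ranking_head <- function(x, n) {
  stopifnot(inherits(x, "ranking"), n >= 0)
  n <- min(n, length(x$doc_ids))
  ranking(x$topic_id, x$doc_ids[seq_len(n)], x$scores[seq_len(n)],
          run_tag = x$run_tag, sort = FALSE)
}

#' Rebuild a ranking from an explicit document order
#'
#' Scores are re-derived as descending ranks so that the given order is the
#' stored order. Used by rerankers whose output is an ordering, not a score.
#'
#' @inheritParams ranking
#' @return a `ranking`.
#' @export
ranking_from_order <- function(topic_id, doc_ids, run_tag = "rerank") {
  ranking(topic_id, doc_ids, scores = NULL, run_tag = run_tag, sort = FALSE)
}

#' @export
as.data.frame.ranking <- function(x, ...) {
  n <- length(x$doc_ids)
  data.frame(topic_id = rep(x$topic_id, n),
             doc_id = x$doc_ids,
             rank = seq_len(n),
             score = x$scores,
             run_tag = rep(x$run_tag, n),
             stringsAsFactors = FALSE)
}

#' @export
print.ranking <- function(x, n = 5L, ...) {
  cat(sprintf("<ranking> topic %s, %d documents, tag '%s'\n",
              x$topic_id, length(x$doc_ids), x$run_tag))
  k <- min(n, length(x$doc_ids))
  if (k > 0L)
    for (i in seq_len(k))
      cat(sprintf("  %4d  %-30s %.6f\n", i, x$doc_ids[i], x$scores[i]))
  if (length(x$doc_ids) > k) cat(sprintf("  ... %d more\n", length(x$doc_ids) - k))
  invisible(x)
}

.check_same_topic <- function(rankings) {
  ids <- vapply(rankings, function(r) r$topic_id, character(1))
  if (length(unique(ids)) > 1L)
    stop(sprintf("rankings mix topic_ids: %s",
                 paste(unique(ids), collapse = ", ")), call. = FALSE)
  ids[1L]
}
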