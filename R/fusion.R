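#' Reciprocal rank fusion
#'
#' Combines rankings of the same topic by summing `1 / (rrf_k + rank)` over
#' the lists containing each document; a document absent from a list
#' contributes 0 from it. The fused list is sorted by score descending with
#' ties broken by `doc_id` ascending, and is invariant under permutation of
#' the input lists.
#'
#' @param rankings non-empty list of [ranking] objects for one topic.
#' @param rrf_k positive fusion constant; default 60, the canonical value
#'   of the method.
#' @param run_tag tag of the fused ranking.
#' @return a [ranking] over the union of the input document sets.
#' @export
rrf_fuse <- function(rankings, rrf_k = 60, run_tag = "rrf") {
  if (inherits(rankings, "ranking")) rankings <- list(rankings)
  stopifnot(length(rankings) >= 1L)
  if (!is.numeric(rrf_k) || rrf_k <= 0) stop("rrf_k must be > 0", call. = FALSE)
  topic <- .check_same_topic(rankings)
  docs <- unique(unlist(lapply(rankings, function(r) r$doc_ids),
                        use.names = FALSE))
  if (length(docs) == 0L)
    return(ranking(topic, character(0), numeric(0), run_tag = run_tag))
  score <- numeric(length(docs))
  for (r in rankings) {
    pos <- match(docs, r$doc_ids)
    hit <- !is.na(pos)
    score[hit] <- score[hit] + 1 / (rrf_k + pos[hit])
  }
  ranking(topic, docs, score, run_tag = run_tag)
}

#' Ensemble reranking through pluggable scorers
#'
#' Each scorer assigns a real-valued score to every document of the base
#' ranking for the base's topic; the induced full reorderings (score
#' descending, `doc_id` ties ascending) are fused with reciprocal rank
#' fusion. The result covers exactly the base's document set.
#'
#' @param base a [ranking].
#' @param scorers non-empty list of [scorer] objects.
#' @param rrf_k fusion constant.
#' @param run_tag tag of the result.
#' @return a [ranking] that is a permutation of `base`.
#' @export
ensemble_rerank <- function(base, scorers, rrf_k = 60, run_tag = "ensemble") {
  stopifnot(inherits(base, "ranking"), length(scorers) >= 1L)
  if (length(base$doc_ids) == 0L) return(base)
  lists <- lapply(scorers, function(s) {
    sc <- tryCatch(s$score(base$topic_id, base$doc_ids),
                   error = function(e)
                     stop(sprintf("scorer '%s' failed on topic %s: %s",
                                  s$name, base$topic_id, conditionMessage(e)),
                          call. = FALSE))
    if (length(sc) != length(base$doc_ids) || anyNA(sc) || any(!is.finite(sc))) {
      bad <- base$doc_ids[which(is.na(sc) | !is.finite(sc))[1L]] %||% "?"
      stop(sprintf("scorer '%s' returned an invalid score for doc %s",
                   s$name, bad), call. = FALSE)
    }
    ranking(base$topic_id, base$doc_ids, as.numeric(sc), run_tag = s$name)
  })
  rrf_fuse(lists, rrf_k = rrf_k, run_tag = run_tag)
}

#' Pluggable scorer contract
#'
#' A scorer is the interface every reranking model -- real or mock --
#' satisfies: a named, deterministic function mapping (topic, documents) to
#' real scores, where higher means stronger for the scorer's quality
#' dimension.
#'
#' @param name scorer name (used in error messages and run tags).
#' @param score_fn `function(topic_id, doc_ids) -> numeric` of the same
#'   length as `doc_ids`.
#' @return an object of class `"scorer"`.
#' @export
scorer <- function(name, score_fn) {
  stopifnot(is.character(name), is.function(score_fn))
  structure(list(name = name, score = score_fn), class = "scorer")
}

#' Score-normalized weighted linear combination of rankings
#'
#' Each ranking's scores are min-max normalized to `[0, 1]` (a constant
#' list maps to all 1), then combined as `sum(w_i * norm_i(doc))`, with a
#' document missing from a list contributing 0 from it. As an ordering the
#' result is invariant to rescaling all weights by a positive constant.
#'
#' @param rankings list of [ranking] objects for one topic.
#' @param weights non-negative weights, one per ranking, not all zero.
#' @param run_tag tag of the result.
#' @return a [ranking] over the union of the input document sets.
#' @export
weighted_combine <- function(rankings, weights, run_tag = "linear") {
  stopifnot(length(rankings) == length(weights))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (all(weights == 0)) stop("all-zero weights", call. = FALSE)
  topic <- .check_same_topic(rankings)
  docs <- unique(unlist(lapply(rankings, function(r) r$doc_ids),
                        use.names = FALSE))
  if (length(docs) == 0L)
    return(ranking(topic, character(0), numeric(0), run_tag = run_tag))
  total <- numeric(length(docs))
  for (j in seq_along(rankings)) {
    r <- rankings[[j]]
    if (length(r$doc_ids) == 0L) next
    rng <- range(r$scores)
    norm <- if (rng[1L] == rng[2L]) rep(1, length(r$scores))
            else (r$scores - rng[1L]) / (rng[2L] - rng[1L])
    pos <- match(docs, r$doc_ids)
    hit <- !is.na(pos)
    total[hit] <- total[hit] + weights[j] * norm[pos[hit]]
  }
  ranking(topic, docs, total, run_tag = run_tag)
}

#' Weight sweep over a linear combination
#'
#' Varies the weight of one ranking over a grid while fixing the weights of
#' the others, evaluating each combined ranking with a caller-supplied
#' metric (typically help, harm, or help-harm compatibility). This
#' reproduces the quality-control analysis in which one model's weight
#' runs from 0 to 2 with the remaining models fixed at 0.33.
#'
#' @param rankings list of [ranking] objects for one topic.
#' @param vary_index index (1-based) of the ranking whose weight varies.
#' @param grid numeric grid of weights for the varied ranking, within
#'   `[0, 2]` by convention.
#' @param fixed_weight weight of every other ranking; default 0.33.
#' @param eval_fn `function(ranking) -> numeric` metric.
#' @return data frame with columns `weight` and `value`.
#' @export
weight_sweep <- function(rankings, vary_index, grid = seq(0, 2, by = 0.25),
                         fixed_weight = 0.33, eval_fn) {
  if (vary_index < 1L || vary_index > length(rankings))
    stop("vary_index out of range", call. = FALSE)
  vals <- vapply(grid, function(g) {
    w <- rep(fixed_weight, length(rankings))
    w[vary_index] <- g
    eval_fn(weighted_combine(rankings, w))
  }, numeric(1))
  data.frame(weight = grid, value = vals)
}

#' Depth-restricted reranking
#'
#' Applies each reranker only to the top-`depth` prefix of the base
#' ranking; the reranked prefixes are fused (together with the base prefix)
#' by reciprocal rank fusion, and the suffix beyond `depth` is appended
#' untouched in its original order. Membership of the top-`depth` set is
#' never changed, only its internal order.
#'
#' @param base a [ranking].
#' @param rerankers list of `function(ranking) -> ranking` returning a
#'   permutation of their input.
#' @param depth prefix size; `0` returns the base unchanged, a depth at or
#'   beyond the list length is a full rerank.
#' @param rrf_k fusion constant.
#' @return a [ranking] that is a permutation of `base`.
#' @export
depth_restricted_rerank <- function(base, rerankers, depth, rrf_k = 60) {
  stopifnot(inherits(base, "ranking"), depth >= 0)
  depth <- min(depth, length(base$doc_ids))
  if (depth == 0L || length(rerankers) == 0L) return(base)
  prefix <- ranking_head(base, depth)
  lists <- lapply(rerankers, function(f) {
    out <- f(prefix)
    if (!setequal(out$doc_ids, prefix$doc_ids))
      stop("reranker changed the document set of the prefix", call. = FALSE)
    out
  })
  fused <- rrf_fuse(c(list(prefix), lists), rrf_k = rrf_k,
                    run_tag = base$run_tag)
  suffix <- base$doc_ids[-seq_len(depth)]
  ranking_from_order(base$topic_id, c(fused$doc_ids, suffix),
                     run_tag = base$run_tag)
}
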