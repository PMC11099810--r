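#' Claim-checker contract
#'
#' A claim checker validates the topic's treatment claim against a
#' document: it labels each (topic, document) pair as `"supports"`,
#' `"refutes"`, or `"neutral"`. Implementations must be deterministic for
#' fixed inputs and seed. Confidence values, when produced, are ignored by
#' the default vote (pure evidence counts).
#'
#' @param name checker name.
#' @param label_fn `function(topic_id, doc_ids) -> character` vector of
#'   labels in `{supports, refutes, neutral}`.
#' @return an object of class `"claim_checker"`.
#' @export
claim_checker <- function(name, label_fn) {
  stopifnot(is.character(name), is.function(label_fn))
  structure(list(name = name, label = label_fn), class = "claim_checker")
}

.CLAIM_LABELS <- c("supports", "refutes", "neutral")

#' Infer a topic's stance from ranked claim labels
#'
#' Majority vote over the non-neutral claim labels within the top-`k`
#' positions of the base ranking, following the assumption that a
#' scientific fact is defined by the largest amount of evidence available
#' for the topic. A tie between supports and refutes, or an all-neutral
#' top-`k`, yields `"undecided"` -- an automatic system must not fabricate
#' a stance.
#'
#' @param labels character vector of claim labels ordered by the base
#'   ranking.
#' @param k number of top documents whose labels vote (default 10).
#' @return a list with fields `stance` (`"supported"`, `"refuted"`, or
#'   `"undecided"`), `votes` (named counts), and `k`.
#' @export
infer_topic_stance <- function(labels, k = 10L) {
  if (length(labels) == 0L) stop("empty label list", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  bad <- setdiff(unique(labels), .CLAIM_LABELS)
  if (length(bad) > 0L)
    stop("unknown claim label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  top <- labels[seq_len(min(k, length(labels)))]
  votes <- c(supports = sum(top == "supports"),
             refutes = sum(top == "refutes"),
             neutral = sum(top == "neutral"))
  stance <- if (votes[["supports"]] > votes[["refutes"]]) "supported"
            else if (votes[["refutes"]] > votes[["supports"]]) "refuted"
            else "undecided"
  list(stance = stance, votes = votes, k = as.integer(k))
}

#' Three-tier correctness reranking
#'
#' Partitions the base ranking into three blocks given the inferred topic
#' stance: correct documents (claim label agreeing with the stance) first,
#' neutral documents second, incorrect documents last. Within each tier the
#' base's relative order is preserved (stable partition). An undecided
#' stance returns the base unchanged. Output scores are re-derived as
#' descending ranks.
#'
#' @param base a [ranking].
#' @param labels claim labels aligned with `base`'s documents (same length
#'   and order).
#' @param stance_decision result of [infer_topic_stance()].
#' @return a [ranking] that is a permutation of `base`.
#' @export
tier_rerank <- function(base, labels, stance_decision) {
  stopifnot(inherits(base, "ranking"))
  if (length(labels) != length(base$doc_ids))
    stop(sprintf("label missing for %d document(s) of the base ranking",
                 abs(length(base$doc_ids) - length(labels))), call. = FALSE)
  if (anyNA(labels)) stop("label missing for a document", call. = FALSE)
  if (stance_decision$stance == "undecided")
    return(ranking_from_order(base$topic_id, base$doc_ids,
                              run_tag = base$run_tag))
  correct <- if (stance_decision$stance == "supported") "supports" else "refutes"
  tier <- ifelse(labels == correct, 0L, ifelse(labels == "neutral", 1L, 2L))
  o <- order(tier, seq_along(tier))  # stable within tiers
  ranking_from_order(base$topic_id, base$doc_ids[o], run_tag = base$run_tag)
}

#' Supportiveness reranking through an ensemble of claim checkers
#'
#' For each checker: label the base's documents, infer the topic stance
#' from the top-`k` labels, and tier-rerank the base accordingly. The
#' per-checker rankings are then combined with reciprocal rank fusion.
#'
#' @param topic_id the topic whose claim is checked.
#' @param base a [ranking].
#' @param checkers non-empty list of [claim_checker] objects.
#' @param k top-`k` vote size (default 10).
#' @param rrf_k fusion constant.
#' @return a [ranking] that is a permutation of `base`, tagged
#'   `"supportiveness"`.
#' @export
supportiveness_rerank <- function(topic_id, base, checkers, k = 10L,
                                  rrf_k = 60) {
  stopifnot(inherits(base, "ranking"), length(checkers) >= 1L)
  if (length(base$doc_ids) == 0L) return(base)
  lists <- lapply(checkers, function(ch) {
    labels <- tryCatch(ch$label(topic_id, base$doc_ids),
                       error = function(e)
                         stop(sprintf("claim checker '%s' failed on topic %s: %s",
                                      ch$name, topic_id, conditionMessage(e)),
                              call. = FALSE))
    decision <- infer_topic_stance(labels, k = k)
    tier_rerank(base, labels, decision)
  })
  rrf_fuse(lists, rrf_k = rrf_k, run_tag = "supportiveness")
}
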