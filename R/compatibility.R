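.doc_vec <- function(x) {
  if (inherits(x, "ranking")) x$doc_ids else as.character(x)
}

#' Truncated rank-biased overlap
#'
#' The top-weighted agreement between a system ranking `R` and an ideal
#' ranking `I`:
#' \deqn{(1 - p) \sum_{d=1}^{K} p^{d-1} \, |R_{1:d} \cap I_{1:d}| / d}
#' where `p` is the searcher's patience (geometric weight) and `K` the
#' search depth at which the sum is truncated; prefixes shorter than `d`
#' are used as-is when a list ends. No extrapolation term is added, so the
#' value lies in `[0, 1 - p^K]`.
#'
#' @param r,i [ranking] objects or plain character vectors of document ids;
#'   each must be duplicate-free.
#' @param p patience parameter in `(0, 1)`; default 0.95.
#' @param k search depth, a positive integer; default 1000 (chosen so that
#'   `p^(K-1)` is negligible).
#' @return a single number in `[0, 1 - p^K]`.
#' @export
truncated_rbo <- function(r, i, p = 0.95, k = 1000L) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  dr <- .doc_vec(r)
  di <- .doc_vec(i)
  if (anyDuplicated(dr) || anyDuplicated(di))
    stop("rankings must be duplicate-free", call. = FALSE)
  if (length(di) == 0L || length(dr) == 0L) return(0)
  dr <- dr[seq_len(min(length(dr), k))]
  pos_i <- match(dr, di)
  hit <- !is.na(pos_i) & pos_i <= k
  if (!any(hit)) return(0)
  # a shared doc at rank a in R and rank q in I enters every prefix
  # intersection from depth max(a, q) on
  enter <- pmax(seq_along(dr)[hit], pos_i[hit])
  overlap <- cumsum(tabulate(enter, nbins = k))
  d <- seq_len(k)
  sum((1 - p) * p^(d - 1) * overlap / d)
}

#' Compatibility of a ranking with an ideal ranking
#'
#' Truncated RBO normalized by the ideal's self-RBO, so that short,
#' truncated ideal lists (fewer judged documents than the search depth) do
#' not depress the score:
#' \deqn{\mathrm{compatibility}(R, I) = \mathrm{RBO}(R, I) / \mathrm{RBO}(I, I)}
#' An empty ideal yields 0 by convention. With `extrapolate = TRUE` the
#' residual mass beyond the truncation depth is assigned the depth-`K`
#' overlap proportion (the agreement-extrapolation convention) in both
#' numerator and denominator; the default is the plain truncated sum.
#'
#' @inheritParams truncated_rbo
#' @param extrapolate use the extrapolated-RBO variant? Default `FALSE`.
#' @return a single number in `[0, 1]`; 1 when `r` equals `i`.
#' @export
compatibility <- function(r, i, p = 0.95, k = 1000L, extrapolate = FALSE) {
  di <- .doc_vec(i)
  if (length(di) == 0L) return(0)
  if (extrapolate) {
    num <- .rbo_ext(.doc_vec(r), di, p, as.integer(k))
    den <- .rbo_ext(di, di, p, as.integer(k))
  } else {
    num <- truncated_rbo(r, i, p, k)
    den <- truncated_rbo(i, i, p, k)
  }
  if (den == 0) return(0)
  num / den
}

# Extrapolated variant: overlap proportion at depth K carries the residual
# geometric mass p^K.
.rbo_ext <- function(dr, di, p, k) {
  base <- truncated_rbo(dr, di, p, k)
  if (length(dr) == 0L || length(di) == 0L) return(base)
  a <- dr[seq_len(min(length(dr), k))]
  b <- di[seq_len(min(length(di), k))]
  base + p^k * length(intersect(a, b)) / k
}

#' Ideal ranking of one polarity for a topic
#'
#' All judged documents of the topic carrying the requested preference
#' label, ordered by usefulness grade descending, then credibility grade
#' descending (unjudged last), then `doc_id` ascending. May be empty (e.g.
#' topics without harmful documents); the caller decides whether to skip
#' such topics.
#'
#' @param js a [judgment_set] with preference labels.
#' @param topic_id the topic.
#' @param polarity `"helpful"` or `"harmful"`.
#' @return a [ranking] tagged `"ideal-<polarity>"`.
#' @export
ideal_ranking <- function(js, topic_id, polarity = c("helpful", "harmful")) {
  polarity <- match.arg(polarity)
  tab <- .topic_judgments(js, topic_id)
  tab <- tab[tab$label == polarity, , drop = FALSE]
  if (nrow(tab) == 0L)
    return(ranking(topic_id, character(0), numeric(0),
                   run_tag = paste0("ideal-", polarity)))
  use <- ifelse(is.na(tab$usefulness), -1L, tab$usefulness)
  cred <- ifelse(is.na(tab$credibility), -1L, tab$credibility)
  o <- order(-use, -cred, tab$doc_id, method = "radix")
  ranking_from_order(topic_id, tab$doc_id[o],
                     run_tag = paste0("ideal-", polarity))
}

#' Help/harm compatibility report over a run
#'
#' For every topic in the run, computes help compatibility (against the
#' ideal ranking of helpful documents), harm compatibility (against the
#' ideal of harmful documents), and their difference (help-harm). Macro
#' averages are unweighted means over three topic partitions: helpful
#' topics, unhelpful topics, and all topics.
#'
#' @param runs list of [ranking] objects, one per topic.
#' @param js a [judgment_set] with preference labels; every run topic must
#'   be judged.
#' @param topics data frame of topics (provides the stance partition).
#' @param p,k compatibility parameters, see [compatibility()].
#' @param extrapolate passed to [compatibility()].
#' @return an object of class `"compatibility_report"`: a list with
#'   `per_topic` (data frame of per-topic values) and `summary` (data frame
#'   of partition means).
#' @export
help_harm_report <- function(runs, js, topics, p = 0.95, k = 1000L,
                             extrapolate = FALSE) {
  if (inherits(runs, "ranking")) runs <- list(runs)
  run_topics <- vapply(runs, function(r) r$topic_id, character(1))
  judged <- unique(js$table$topic_id)
  absent <- setdiff(run_topics, judged)
  if (length(absent) > 0L)
    stop("run topic(s) absent from qrels: ", paste(absent, collapse = ", "),
         call. = FALSE)
  per <- lapply(runs, function(r) {
    ih <- ideal_ranking(js, r$topic_id, "helpful")
    ia <- ideal_ranking(js, r$topic_id, "harmful")
    help <- compatibility(r, ih, p, k, extrapolate)
    harm <- compatibility(r, ia, p, k, extrapolate)
    data.frame(topic_id = r$topic_id, help = help, harm = harm,
               help_harm = help - harm, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  per$stance <- topics$stance[match(per$topic_id, topics$topic_id)]
  parts <- list(helpful_T = per$stance == "helpful",
                unhelpful_T = per$stance == "unhelpful",
                all_T = rep(TRUE, nrow(per)))
  summary <- do.call(rbind, lapply(names(parts), function(nm) {
    sub <- per[parts[[nm]] & !is.na(parts[[nm]]), , drop = FALSE]
    data.frame(partition = nm, n_topics = nrow(sub),
               help = mean(sub$help), harm = mean(sub$harm),
               help_harm = mean(sub$help_harm), stringsAsFactors = FALSE)
  }))
  structure(list(per_topic = per, summary = summary, p = p, k = k),
            class = "compatibility_report")
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat(sprintf("<compatibility_report> p=%.2f K=%d, %d topics\n",
              x$p, x$k, nrow(x$per_topic)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Normalized discounted cumulative gain for one polarity
#'
#' Gains are the usefulness grades of documents carrying the requested
#' preference label (0 for all other documents). DCG uses the standard
#' `gain / log2(rank + 1)` discount; the ideal DCG is computed over all
#' judged documents of the topic with that label. Returns 0 when the ideal
#' DCG is 0.
#'
#' @param r a [ranking].
#' @param js a [judgment_set] with labels.
#' @param polarity `"helpful"` or `"harmful"`.
#' @param depth evaluation depth (default 1000).
#' @return a single number in `[0, 1]`.
#' @export
ndcg <- function(r, js, polarity = c("helpful", "harmful"), depth = 1000L) {
  polarity <- match.arg(polarity)
  tab <- .topic_judgments(js, r$topic_id)
  tab <- tab[tab$label == polarity, , drop = FALSE]
  gain_of <- function(ids) {
    g <- tab$usefulness[match(ids, tab$doc_id)]
    g[is.na(g)] <- 0L
    as.numeric(g)
  }
  top <- r$doc_ids[seq_len(min(length(r$doc_ids), depth))]
  g <- gain_of(top)
  dcg <- sum(g / log2(seq_along(g) + 1))
  ig <- sort(as.numeric(tab$usefulness), decreasing = TRUE)
  ig <- ig[seq_len(min(length(ig), depth))]
  idcg <- sum(ig / log2(seq_along(ig) + 1))
  if (idcg == 0) return(0)
  dcg / idcg
}

#' Shallow-depth interpretation of compatibility
#'
#' Recomputes help/harm/help-harm compatibility at search depth `K = 10`
#' (patience 0.95) and pairs it with the mean number of helpful and harmful
#' documents retrieved in each top-10, which grounds the reading that a
#' ~10% change in shallow compatibility corresponds to roughly one helpful
#' document in the top 10.
#'
#' @param runs list of [ranking] objects, one per topic.
#' @param js a [judgment_set] with labels.
#' @param topics data frame of topics.
#' @return a list with the depth-10 `report` (a
#'   [help_harm_report()] result) and `counts`, a data frame of per-topic
#'   and mean helpful/harmful counts in the top 10.
#' @export
interpret_depth10 <- function(runs, js, topics) {
  if (inherits(runs, "ranking")) runs <- list(runs)
  report <- help_harm_report(runs, js, topics, p = 0.95, k = 10L)
  counts <- do.call(rbind, lapply(runs, function(r) {
    top <- r$doc_ids[seq_len(min(10L, length(r$doc_ids)))]
    tab <- .topic_judgments(js, r$topic_id)
    lab <- tab$label[match(top, tab$doc_id)]
    data.frame(topic_id = r$topic_id,
               n_helpful = sum(lab == "helpful", na.rm = TRUE),
               n_harmful = sum(lab == "harmful", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(report = report, counts = counts,
       mean_helpful_top10 = mean(counts$n_helpful),
       mean_harmful_top10 = mean(counts$n_harmful))
}
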