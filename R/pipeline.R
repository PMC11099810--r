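#' Pipeline configuration
#'
#' Collects every tunable of the two-phase pipeline: preprocessing
#' (candidate-list size, BM25 parameters of the default and tuned indices,
#' optional known-item tuning, fusion constant), per-dimension reranking
#' (stance-vote size), the combination recipe, and the evaluation
#' parameters.
#'
#' @param n_docs candidate-list size per topic (default 10000).
#' @param rrf_k reciprocal-rank-fusion constant (default 60).
#' @param default_k1,default_b parameters of the default index (1.2, 0.75).
#' @param tuned_k1,tuned_b parameters of the tuned index when `tune` is
#'   `FALSE`.
#' @param tune run known-item grid-search tuning of the second index?
#'   Default `FALSE` (explicit tuned parameters are used); set `TRUE` to
#'   tune on generated silver topics.
#' @param k1_grid,b_grid tuning grids (used when `tune = TRUE`).
#' @param n_silver number of silver topics for tuning.
#' @param stance_k top-k size of the stance vote (default 10).
#' @param eval_p,eval_k compatibility parameters (0.95, 1000).
#' @param combinations character vector of runs to produce and evaluate;
#'   any of `"H_P"`, `"H_U"`, `"H_S"`, `"H_C"`, `"H_U+H_S"`,
#'   `"H_U+H_S+H_C"`.
#' @param seed integer seed for silver-topic sampling.
#' @param verbose log per-stage progress to stderr?
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_docs = 10000L, rrf_k = 60,
                            default_k1 = 1.2, default_b = 0.75,
                            tuned_k1 = 0.9, tuned_b = 0.5, tune = FALSE,
                            k1_grid = c(0.6, 0.9, 1.2, 1.5, 1.8),
                            b_grid = c(0.3, 0.5, 0.75, 0.9),
                            n_silver = 50L, stance_k = 10L,
                            eval_p = 0.95, eval_k = 1000L,
                            combinations = c("H_P", "H_U", "H_U+H_S",
                                             "H_U+H_S+H_C"),
                            seed = 1L, verbose = FALSE) {
  known <- c("H_P", "H_U", "H_S", "H_C", "H_U+H_S", "H_U+H_S+H_C")
  bad <- setdiff(combinations, known)
  if (length(bad) > 0L)
    stop("unknown combination(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n_docs = as.integer(n_docs), rrf_k = rrf_k,
                 default_k1 = default_k1, default_b = default_b,
                 tuned_k1 = tuned_k1, tuned_b = tuned_b, tune = tune,
                 k1_grid = k1_grid, b_grid = b_grid,
                 n_silver = as.integer(n_silver),
                 stance_k = as.integer(stance_k),
                 eval_p = eval_p, eval_k = as.integer(eval_k),
                 combinations = combinations, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

.log_stage <- function(config, stage, topic, n_in, n_out) {
  if (config$verbose)
    message(sprintf("[%s] topic=%s in=%d out=%d", stage, topic, n_in, n_out))
}

#' Combine the preprocessing ranking with one dimension's reranking
#'
#' A dimension run `H_X` is the reciprocal-rank fusion of the preprocessing
#' candidates `H_P` with the dimension's reranking `H_X' = reranker(H_P)`;
#' it covers exactly `H_P`'s document set.
#'
#' @param h_p the preprocessing [ranking].
#' @param reranker `function(ranking) -> ranking` returning a permutation
#'   of its input.
#' @param rrf_k fusion constant.
#' @param run_tag tag of the combined run.
#' @return a [ranking].
#' @export
run_dimension <- function(h_p, reranker, rrf_k = 60, run_tag = "H_X") {
  stopifnot(inherits(h_p, "ranking"))
  prime <- reranker(h_p)
  if (!setequal(prime$doc_ids, h_p$doc_ids))
    stop("reranker changed the document set of H_P", call. = FALSE)
  rrf_fuse(list(h_p, prime), rrf_k = rrf_k, run_tag = run_tag)
}

# Build the three dimension rerankers from a scorer bundle.
.make_rerankers <- function(scorers, config) {
  list(
    usefulness = function(r)
      ensemble_rerank(r, scorers$usefulness, rrf_k = config$rrf_k,
                      run_tag = "H_U'"),
    supportiveness = function(r)
      supportiveness_rerank(r$topic_id, r, scorers$supportiveness,
                            k = config$stance_k, rrf_k = config$rrf_k),
    credibility = function(r)
      ensemble_rerank(r, scorers$credibility, rrf_k = config$rrf_k,
                      run_tag = "H_C'"))
}

#' Run the full multidimensional ranking pipeline
#'
#' Executes preprocessing (dual-index BM25 with RRF fusion per topic),
#' reranks the candidates in parallel along the usefulness,
#' supportiveness, and credibility dimensions, combines each dimension
#' with the preprocessing run, fuses the configured combinations, and
#' evaluates every produced run with the help/harm compatibility report.
#' Fully deterministic given the seed and configuration; no stage ever
#' introduces documents beyond the preprocessing candidates.
#'
#' @param topics data frame of topics (`topic_id`, `query`, `description`,
#'   `stance`; stance is consumed only by evaluation).
#' @param corpus data frame of documents.
#' @param js a [judgment_set] with preference labels (evaluation only).
#' @param scorers list with elements `usefulness` (list of [scorer]),
#'   `supportiveness` (list of [claim_checker]), `credibility` (list of
#'   [scorer]); a dimension may be omitted if no configured combination
#'   needs it.
#' @param config a [pipeline_config].
#' @return a list with `runs` (per combination, a list of per-topic
#'   rankings), `primes` (the pure reranking runs `H_U'`, `H_S'`, `H_C'`
#'   plus `H_P`), `reports` (per combination, a
#'   [help_harm_report()]), and `tuning` (the grid-search result when
#'   tuning ran, else the fixed tuned parameters).
#' @export
run_pipeline <- function(topics, corpus, js, scorers, config = pipeline_config()) {
  stopifnot(is.data.frame(topics), is.data.frame(corpus),
            inherits(js, "judgment_set"), inherits(config, "pipeline_config"))
  index_default <- bm25_index(corpus, k1 = config$default_k1,
                              b = config$default_b)
  if (config$tune) {
    silver <- generate_silver_topics(corpus, n = min(config$n_silver,
                                                     nrow(corpus)),
                                     seed = config$seed)
    tuning <- tune_known_item(corpus, silver, config$k1_grid, config$b_grid)
  } else {
    tuning <- list(k1 = config$tuned_k1, b = config$tuned_b,
                   success_rate = NA_real_)
  }
  index_tuned <- bm25_index(corpus, k1 = tuning$k1, b = tuning$b)

  need_u <- any(grepl("H_U", config$combinations))
  need_s <- any(grepl("H_S", config$combinations))
  need_c <- any(grepl("H_C", config$combinations))
  rerankers <- .make_rerankers(scorers, config)

  h_p <- list(); h_u <- list(); h_s <- list(); h_c <- list()
  primes <- list(`H_U'` = list(), `H_S'` = list(), `H_C'` = list())
  for (i in seq_len(nrow(topics))) {
    topic <- topics[i, ]
    hp <- preprocess_topic(topic, index_default, index_tuned,
                           n_docs = config$n_docs, rrf_k = config$rrf_k)
    .log_stage(config, "preprocess", topic$topic_id, nrow(corpus),
               length(hp$doc_ids))
    h_p[[i]] <- hp
    if (need_u) {
      primes$`H_U'`[[i]] <- rerankers$usefulness(hp)
      h_u[[i]] <- rrf_fuse(list(hp, primes$`H_U'`[[i]]), rrf_k = config$rrf_k,
                           run_tag = "H_U")
      .log_stage(config, "usefulness", topic$topic_id, length(hp$doc_ids),
                 length(h_u[[i]]$doc_ids))
    }
    if (need_s) {
      primes$`H_S'`[[i]] <- rerankers$supportiveness(hp)
      h_s[[i]] <- rrf_fuse(list(hp, primes$`H_S'`[[i]]), rrf_k = config$rrf_k,
                           run_tag = "H_S")
      .log_stage(config, "supportiveness", topic$topic_id,
                 length(hp$doc_ids), length(h_s[[i]]$doc_ids))
    }
    if (need_c) {
      primes$`H_C'`[[i]] <- rerankers$credibility(hp)
      h_c[[i]] <- rrf_fuse(list(hp, primes$`H_C'`[[i]]), rrf_k = config$rrf_k,
                           run_tag = "H_C")
      .log_stage(config, "credibility", topic$topic_id, length(hp$doc_ids),
                 length(h_c[[i]]$doc_ids))
    }
  }

  combo_run <- function(name) {
    switch(name,
      "H_P" = h_p, "H_U" = h_u, "H_S" = h_s, "H_C" = h_c,
      "H_U+H_S" = lapply(seq_along(h_p), function(i)
        rrf_fuse(list(h_u[[i]], h_s[[i]]), rrf_k = config$rrf_k,
                 run_tag = "H_U+H_S")),
      "H_U+H_S+H_C" = lapply(seq_along(h_p), function(i)
        rrf_fuse(list(h_u[[i]], h_s[[i]], h_c[[i]]), rrf_k = config$rrf_k,
                 run_tag = "H_U+H_S+H_C")))
  }
  runs <- stats::setNames(lapply(config$combinations, combo_run),
                          config$combinations)
  reports <- lapply(runs, help_harm_report, js = js, topics = topics,
                    p = config$eval_p, k = config$eval_k)
  primes$H_P <- h_p
  list(runs = runs, primes = primes, reports = reports, tuning = tuning)
}

#' Depth-restricted reranking experiment
#'
#' Starting from a base run (typically the usefulness combination `H_U`),
#' reranks only the top-`depth` documents with the supportiveness and
#' credibility rerankers for each depth in `depths`, fusing the reranked
#' prefixes with RRF, and evaluates help/harm/help-harm at each depth.
#'
#' @param base_runs list of per-topic base [ranking] objects.
#' @param rerankers list of `function(ranking) -> ranking` (permutations).
#' @param js a [judgment_set].
#' @param topics data frame of topics.
#' @param depths reranking depths (default `c(10, 20, 50, 100, 1000)`).
#' @param rrf_k fusion constant.
#' @param p,k evaluation parameters.
#' @return a list with `curve` (data frame of depth, help, harm,
#'   help_harm over all topics) and `runs` (per depth, the reranked runs).
#' @export
run_depth_experiment <- function(base_runs, rerankers, js, topics,
                                 depths = c(10L, 20L, 50L, 100L, 1000L),
                                 rrf_k = 60, p = 0.95, k = 1000L) {
  runs <- lapply(depths, function(d) {
    lapply(base_runs, depth_restricted_rerank, rerankers = rerankers,
           depth = d, rrf_k = rrf_k)
  })
  names(runs) <- as.character(depths)
  curve <- do.call(rbind, lapply(seq_along(depths), function(j) {
    rep <- help_harm_report(runs[[j]], js, topics, p = p, k = k)
    all_t <- rep$summary[rep$summary$partition == "all_T", ]
    data.frame(depth = depths[j], help = all_t$help, harm = all_t$harm,
               help_harm = all_t$help_harm)
  }))
  list(curve = curve, runs = runs)
}
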