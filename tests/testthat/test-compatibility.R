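test_that("truncated RBO matches hand-summed series and closed forms", {
  # hand-derived worked example
  expect_equal(truncated_rbo(c("d1", "d2", "d3"), c("d2", "d1"), p = 0.5, k = 3),
               1 / 3, tolerance = 1e-12)
  # empty ideal
  expect_equal(truncated_rbo(c("d1"), character(0), p = 0.5, k = 3), 0)
  # identical rankings of length >= K: geometric series 1 - p^K
  r <- ranking("t", letters[1:12], 12:1)
  for (p in c(0.5, 0.95))
    expect_equal(truncated_rbo(r, r, p = p, k = 10), 1 - p^10,
                 tolerance = 1e-12)
  # parameter validation
  expect_error(truncated_rbo("a", "a", p = 1), "p")
  expect_error(truncated_rbo("a", "a", k = 0), "k")
  expect_error(truncated_rbo(c("a", "a"), "a"), "duplicate")
})

test_that("compatibility is normalized, bounded, and matches the worked example", {
  expect_equal(compatibility(c("d1", "d2", "d3"), c("d2", "d1"),
                             p = 0.5, k = 3), 0.4, tolerance = 1e-12)
  # self-compatibility is 1, also for short ideals (the normalization's point)
  expect_equal(compatibility(letters[1:3], letters[1:3], p = 0.95, k = 1000), 1)
  expect_equal(compatibility(c(letters[1:2], LETTERS[1:8]), letters[1:2],
                             p = 0.95, k = 1000), 1)
  # disjoint and empty ideals
  expect_equal(compatibility(letters[1:3], c("x", "y"), p = 0.5, k = 3), 0)
  expect_equal(compatibility(letters[1:3], character(0)), 0)
  # with large K and R = I, compatibility is 1 regardless of p
  for (p in c(0.3, 0.95, 0.99))
    expect_equal(compatibility(letters[1:5], letters[1:5], p = p, k = 5000), 1)
  # extrapolated variant also reaches 1 on identity and stays in [0, 1]
  expect_equal(compatibility(letters[1:5], letters[1:5], p = 0.95, k = 10,
                             extrapolate = TRUE), 1)
  v <- compatibility(letters[1:5], c("c", "a"), p = 0.95, k = 10,
                     extrapolate = TRUE)
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("compatibility equals the brute-force oracle on small instances", {
  docs <- c("a", "b", "c", "d")
  perms <- all_perms(docs)
  ideals <- ordered_subsets(docs, 0:2)
  for (p in c(0.5, 0.95)) {
    for (k in c(3L, 10L)) {
      got <- unlist(lapply(perms, function(r)
        vapply(ideals, function(i) compatibility(r, i, p, k), numeric(1))))
      want <- unlist(lapply(perms, function(r)
        vapply(ideals, function(i) oracle_compatibility(r, i, p, k),
               numeric(1))))
      expect_lt(max(abs(got - want)), 1e-12)
      expect_true(all(got >= 0 & got <= 1 + 1e-12))
    }
  }
})

test_that("promoting an ideal document never decreases compatibility", {
  docs <- letters[1:5]
  ideal <- c("b", "d")
  for (r in all_perms(docs)) {
    base <- compatibility(r, ideal, p = 0.7, k = 5)
    for (d in ideal) {
      pos <- which(r == d)
      # promoting past another ideal document trades their weights off;
      # the monotonicity claim is about overtaking non-ideal documents
      if (pos == 1L || r[pos - 1L] %in% ideal) next
      swapped <- r
      swapped[c(pos - 1L, pos)] <- swapped[c(pos, pos - 1L)]
      expect_gte(compatibility(swapped, ideal, p = 0.7, k = 5), base - 1e-12)
    }
  }
})

test_that("ideal rankings order by grade, credibility, then doc_id", {
  bm <- make_mini_benchmark()
  ih <- ideal_ranking(bm$judgments, "101", "helpful")
  expect_equal(ranking_docs(ih), "dA")
  ia <- ideal_ranking(bm$judgments, "101", "harmful")
  expect_equal(ranking_docs(ia), "dB")

  js <- judgment_set(data.frame(
    topic_id = "1", doc_id = c("z", "a", "m", "k"),
    usefulness = c(2L, 1L, 2L, 2L),
    supportiveness = "supportive",
    credibility = c(1L, 1L, 0L, 1L)))
  topics <- data.frame(topic_id = "1", query = "q", description = "d",
                       stance = "helpful")
  js <- derive_preference_labels(js, topics)
  i1 <- ideal_ranking(js, "1", "helpful")
  # grade 2 + credible first (doc_id breaks the k/z tie), then grade 2
  # non-credible, then grade 1
  expect_equal(ranking_docs(i1), c("k", "z", "m", "a"))
  # invariant under input permutation
  perm <- judgment_set(js$table[c(3, 1, 4, 2), ])
  expect_equal(ranking_docs(ideal_ranking(perm, "1", "helpful")),
               ranking_docs(i1))
  # no harmful docs -> empty ideal
  expect_length(ideal_ranking(js, "1", "harmful"), 0L)
})

test_that("help/harm reports decompose and aggregate correctly", {
  bm <- make_mini_benchmark()
  ih <- ideal_ranking(bm$judgments, "101", "helpful")
  # run equal to the helpful ideal with no harmful docs retrieved
  rep1 <- help_harm_report(list(ih), bm$judgments, bm$topics)
  expect_equal(rep1$per_topic$help, 1)
  expect_equal(rep1$per_topic$harm, 0)
  expect_equal(rep1$per_topic$help_harm, 1)

  # run containing only harmful docs in ideal-harm order
  ia <- ideal_ranking(bm$judgments, "101", "harmful")
  rep2 <- help_harm_report(list(ia), bm$judgments, bm$topics)
  expect_equal(rep2$per_topic$help_harm, -1)

  # unknown topic errors by name
  expect_error(help_harm_report(list(ranking("999", "dA", 1)),
                                bm$judgments, bm$topics), "999")
})

test_that("macro averages equal independently recomputed per-topic means", {
  bm <- generate_benchmark(benchmark_spec(n_topics = 4L, fraction_helpful = 0.5,
                                          docs_per_topic = 60L), seed = 8)
  idx <- bm25_index(bm$corpus)
  runs <- lapply(seq_len(4L), function(i)
    bm25_search(idx, bm$topics$query[i], n_docs = 100L,
                topic_id = bm$topics$topic_id[i]))
  rep <- help_harm_report(runs, bm$judgments, bm$topics, p = 0.9, k = 50)
  # recount each topic from scratch with the oracle
  manual <- vapply(runs, function(r) {
    ih <- ranking_docs(ideal_ranking(bm$judgments, r$topic_id, "helpful"))
    ia <- ranking_docs(ideal_ranking(bm$judgments, r$topic_id, "harmful"))
    oracle_compatibility(ranking_docs(r), ih, 0.9, 50) -
      oracle_compatibility(ranking_docs(r), ia, 0.9, 50)
  }, numeric(1))
  expect_equal(rep$per_topic$help_harm, manual, tolerance = 1e-10)
  s <- rep$summary
  expect_equal(s$help_harm[s$partition == "all_T"], mean(manual))
  helpfulT <- bm$topics$stance == "helpful"
  expect_equal(s$help_harm[s$partition == "helpful_T"], mean(manual[helpfulT]))
  expect_equal(s$n_topics, c(sum(helpfulT), sum(!helpfulT), 4L))
  # help_harm = help - harm in every aggregate
  expect_equal(s$help_harm, s$help - s$harm)
})

test_that("help-harm is antisymmetric under swapping the label sets", {
  bm <- generate_benchmark(benchmark_spec(n_topics = 2L, docs_per_topic = 50L),
                           seed = 13)
  idx <- bm25_index(bm$corpus)
  runs <- lapply(seq_len(2L), function(i)
    bm25_search(idx, bm$topics$query[i], n_docs = 50L,
                topic_id = bm$topics$topic_id[i]))
  swapped <- bm$judgments
  lab <- swapped$table$label
  swapped$table$label <- ifelse(lab == "helpful", "harmful",
                                ifelse(lab == "harmful", "helpful", lab))
  # swapping labels also swaps credibility-blind ideal order only if the
  # secondary keys coincide; compare help/harm cross-wise per topic
  r1 <- help_harm_report(runs, bm$judgments, bm$topics)
  r2 <- help_harm_report(runs, swapped, bm$topics)
  expect_equal(r1$per_topic$help, r2$per_topic$harm)
  expect_equal(r1$per_topic$harm, r2$per_topic$help)
  expect_equal(r1$per_topic$help_harm, -r2$per_topic$help_harm)
})

test_that("nDCG matches hand computation and closed forms", {
  js <- judgment_set(data.frame(
    topic_id = "1", doc_id = c("a", "b"),
    usefulness = c(1L, 0L), supportiveness = c("supportive", "unjudged"),
    credibility = c(1L, NA), label = c("helpful", "neither")))
  # single relevant doc (gain 1) at rank 2; ideal has it at rank 1
  r <- ranking("1", c("b", "a"), c(2, 1))
  expect_equal(ndcg(r, js, "helpful"), (1 / log2(3)) / (1 / log2(2)),
               tolerance = 1e-4)
  expect_equal(round(ndcg(r, js, "helpful"), 4), 0.6309)
  # ideal order -> 1; no labeled docs -> 0
  expect_equal(ndcg(ranking("1", c("a", "b"), c(2, 1)), js, "helpful"), 1)
  expect_equal(ndcg(r, js, "harmful"), 0)
})

test_that("depth-10 interpretation counts top-10 documents and reports", {
  bm <- make_mini_benchmark()
  ih <- ideal_ranking(bm$judgments, "101", "helpful")
  out <- interpret_depth10(list(ih), bm$judgments, bm$topics)
  expect_equal(out$counts$n_helpful, 1L)
  expect_equal(out$counts$n_harmful, 0L)
  expect_equal(out$report$k, 10L)
  # empty top-10 intersection -> help = 0
  none <- ranking("101", c("zz1", "zz2"), c(2, 1))
  out0 <- interpret_depth10(list(none), bm$judgments, bm$topics)
  expect_equal(out0$report$per_topic$help, 0)
  # only helpful documents retrieved in the top 10, ideal <= 10 docs
  # -> help-harm compatibility of 1
  expect_equal(out$report$per_topic$help_harm, 1)
})
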