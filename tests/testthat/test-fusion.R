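test_that("RRF matches hand-computed reciprocal rank sums", {
  l1 <- ranking("t", c("a", "b"), c(2, 1))
  l2 <- ranking("t", c("b", "c"), c(9, 8))
  fused <- rrf_fuse(list(l1, l2), rrf_k = 60)
  # b: 1/62 + 1/61; a: 1/61; c: 1/62
  expect_equal(ranking_docs(fused), c("b", "a", "c"))
  expect_equal(fused$scores, c(1 / 62 + 1 / 61, 1 / 61, 1 / 62),
               tolerance = 1e-12)
  # single input -> same order
  expect_equal(ranking_docs(rrf_fuse(list(l1))), ranking_docs(l1))
  # constructed tie: a and b receive identical mass; doc_id breaks it
  t1 <- ranking("t", c("a", "b", "c"), c(3, 2, 1))
  t2 <- ranking("t", c("b", "a", "c"), c(3, 2, 1))
  expect_equal(ranking_docs(rrf_fuse(list(t1, t2))), c("a", "b", "c"))
  # mixed topics are rejected
  expect_error(rrf_fuse(list(l1, ranking("u", "a", 1))), "topic")
})

test_that("RRF is invariant under permutation of its input lists", {
  lists <- list(ranking("t", c("a", "b", "c", "d"), 4:1),
                ranking("t", c("d", "c", "a"), 3:1),
                ranking("t", c("e", "b"), 2:1))
  f1 <- rrf_fuse(lists)
  f2 <- rrf_fuse(lists[c(3, 1, 2)])
  expect_equal(ranking_docs(f1), ranking_docs(f2))
  expect_equal(f1$scores, f2$scores)
})

test_that("ensemble reranking fuses scorer-induced orderings", {
  base <- ranking("1", c("a", "b", "c", "d", "e"), 5:1)
  truth <- c(a = 0, b = 2, c = 1, d = 2, e = 0)
  perfect <- scorer("oracle", function(t, d) unname(truth[d]))
  out <- ensemble_rerank(base, list(perfect))
  # sorted by true label, doc_id ties
  expect_equal(ranking_docs(out), c("b", "d", "c", "a", "e"))
  # two identical scorers change nothing
  out2 <- ensemble_rerank(base, list(perfect, perfect))
  expect_equal(ranking_docs(out2), ranking_docs(out))
  # result is a permutation of the base
  expect_setequal(ranking_docs(out), ranking_docs(base))

  # three differing mock scorers equal brute-force RRF of the sorted lists
  s2 <- scorer("rev", function(t, d) -unname(truth[d]))
  s3 <- scorer("alpha", function(t, d) rev(seq_along(d)))
  got <- ensemble_rerank(base, list(perfect, s2, s3), rrf_k = 60)
  sorted_list <- function(s) {
    sc <- s$score("1", ranking_docs(base))
    ranking_docs(base)[order(-sc, ranking_docs(base))]
  }
  want <- oracle_rrf(lapply(list(perfect, s2, s3), sorted_list), 60)
  expect_equal(ranking_docs(got), want)

  # scorer failures are attributed
  broken <- scorer("broken", function(t, d) stop("boom"))
  expect_error(ensemble_rerank(base, list(broken)), "broken")
  nas <- scorer("nas", function(t, d) rep(NA_real_, length(d)))
  expect_error(ensemble_rerank(base, list(nas)), "nas")
})

test_that("weighted combination normalizes, masks, and matches hand sums", {
  r1 <- ranking("t", c("a", "b", "c"), c(10, 5, 0))
  r2 <- ranking("t", c("b", "c", "d"), c(4, 2, 0))
  # weight vector (1, 0) reproduces the first ranking's order
  expect_equal(ranking_docs(weighted_combine(list(r1, r2), c(1, 0))),
               c("a", "b", "c", "d"))
  # hand-computed normalized sum with weights (1, 1):
  # norms r1: a=1, b=0.5, c=0; r2: b=1, c=0.5, d=0
  got <- weighted_combine(list(r1, r2), c(1, 1))
  expect_equal(ranking_docs(got), c("b", "a", "c", "d"))
  expect_equal(got$scores, c(1.5, 1, 0.5, 0), tolerance = 1e-12)
  # constant score list normalizes to all ones
  flat <- ranking("t", c("x", "y"), c(3, 3))
  gf <- weighted_combine(list(flat), 1)
  expect_equal(gf$scores, c(1, 1))
  # scale invariance of the ordering
  w <- c(0.4, 1.1)
  expect_equal(ranking_docs(weighted_combine(list(r1, r2), w)),
               ranking_docs(weighted_combine(list(r1, r2), 7 * w)))
  expect_error(weighted_combine(list(r1, r2), c(0, 0)), "zero")
})

test_that("weight zero drops a model from the combination entirely", {
  r1 <- ranking("t", c("a", "b"), c(2, 1))
  r2 <- ranking("t", c("b", "a"), c(2, 1))
  r3 <- ranking("t", c("a", "c"), c(2, 1))
  r4 <- ranking("t", c("c", "b"), c(2, 1))
  with_zero <- weighted_combine(list(r1, r2, r3, r4), c(0, 0.33, 0.33, 0.33))
  without <- weighted_combine(list(r2, r3, r4), c(0.33, 0.33, 0.33))
  expect_equal(ranking_docs(with_zero), ranking_docs(without))
  expect_equal(with_zero$scores, without$scores)
})

test_that("weight sweeps evaluate the grid deterministically", {
  bm <- make_mini_benchmark()
  ih <- ideal_ranking(bm$judgments, "101", "helpful")
  good <- ranking("101", ranking_docs(ih), run_tag = "good")
  bad <- ranking("101", rev(c(ranking_docs(ih), "zz")),
                 run_tag = "bad")
  noise <- ranking("101", c("n1", "n2"), c(2, 1))
  evalfn <- function(r) compatibility(r, ih, p = 0.9, k = 10)
  curve <- weight_sweep(list(good, bad, noise), vary_index = 1,
                        grid = c(0, 0.5, 1, 2), eval_fn = evalfn)
  expect_equal(curve$weight, c(0, 0.5, 1, 2))
  # grid value 0 reproduces the remaining-model combination
  expect_equal(curve$value[1],
               evalfn(weighted_combine(list(good, bad, noise),
                                       c(0, 0.33, 0.33))))
  # upweighting the faithful model can only help here: the largest weight
  # attains the curve maximum
  expect_equal(curve$value[4], max(curve$value))
  expect_gt(curve$value[4], curve$value[1])
  # deterministic
  curve2 <- weight_sweep(list(good, bad, noise), vary_index = 1,
                         grid = c(0, 0.5, 1, 2), eval_fn = evalfn)
  expect_identical(curve, curve2)
  expect_error(weight_sweep(list(good), 2, c(0, 1), eval_fn = evalfn),
               "vary_index")
})

test_that("depth-restricted reranking touches only the prefix", {
  base <- ranking("t", letters[1:8], 8:1, run_tag = "base")
  reverser <- function(r) ranking_from_order(r$topic_id, rev(ranking_docs(r)))
  # depth 0 is the identity
  expect_equal(ranking_docs(depth_restricted_rerank(base, list(reverser), 0)),
               ranking_docs(base))
  # depth >= length is a full rerank
  full <- depth_restricted_rerank(base, list(reverser), 100)
  manual_full <- rrf_fuse(list(base, reverser(base)), rrf_k = 60)
  expect_equal(ranking_docs(full), ranking_docs(manual_full))
  # depth 3: manual prefix-fuse-append construction
  got <- depth_restricted_rerank(base, list(reverser), 3)
  prefix <- ranking_head(base, 3)
  manual <- c(ranking_docs(rrf_fuse(list(prefix, reverser(prefix)))),
              letters[4:8])
  expect_equal(ranking_docs(got), manual)
  # membership of the top-depth set is preserved
  expect_setequal(ranking_docs(got)[1:3], letters[1:3])
  expect_equal(ranking_docs(got)[4:8], letters[4:8])
  # a reranker that invents documents is rejected
  cheat <- function(r) ranking(r$topic_id, c(ranking_docs(r), "zz"))
  expect_error(depth_restricted_rerank(base, list(cheat), 3), "document set")
})
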