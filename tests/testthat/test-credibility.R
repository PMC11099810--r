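test_that("SMOG index matches the formula and its invariances", {
  # no polysyllables: the formula floor
  expect_equal(smog_index("The cat sat. The dog ran."), 3.1291)
  # 30 sentences, 30 polysyllabic words
  expect_equal(smog_index(smog_fixture_text()),
               3.1291 + 1.0430 * sqrt(30), tolerance = 1e-6)
  # duplication invariance (density ratio)
  txt <- smog_fixture_text(10L)
  expect_equal(smog_index(paste(txt, txt)), smog_index(txt), tolerance = 1e-12)
  # monotone in polysyllable density
  dense <- paste(rep("The elephant antelope banana cassowary.", 10L),
                 collapse = " ")
  expect_gt(smog_index(dense), smog_index(smog_fixture_text(10L)))
  expect_error(smog_index("   "), "empty")
  # vowel-group counter
  expect_equal(count_vowel_groups(c("banana", "cat", "elephant", "xyz", "rhythm")),
               c(3L, 1L, 3L, 1L, 1L))
})

test_that("CSS effort counts style rules, inline styles, and links", {
  html <- paste0(
    "<html><head>",
    "<style>p { color: red; } h1 { font-size: 2em; }</style>",
    "<link rel=\"stylesheet\" href=\"a.css\">",
    "</head><body><div style=\"margin:0\">hi</div></body></html>")
  expect_equal(count_css_rules(html), 4L)
  expect_equal(count_css_rules(html, breakdown = TRUE),
               c(style_rules = 2L, inline_styles = 1L, linked_sheets = 1L))
  # one style block with 2 rules + 1 inline style, no links
  html2 <- "<style>a{x}b{y}</style><p style='z'>t</p>"
  expect_equal(count_css_rules(html2), 3L)
  expect_equal(count_css_rules("<html><body>no styles</body></html>"), 0L)
  expect_equal(count_css_rules("just some plain text"), 0L)
  expect_equal(count_css_rules(""), 0L)
  # malformed html: best effort, no error
  expect_equal(count_css_rules("<style>a{b</p><<"), 1L)
})

test_that("1-5 ratings binarize with the 4-or-above rule", {
  expect_equal(binarize_credibility(5L), 1L)
  expect_equal(binarize_credibility(4L), 1L)
  expect_equal(binarize_credibility(3L), 0L)
  expect_equal(binarize_credibility(1L), 0L)
  expect_equal(binarize_credibility(c(1, 2, 3, 4, 5)), c(0L, 0L, 0L, 1L, 1L))
  expect_error(binarize_credibility(0L), "range")
  expect_error(binarize_credibility(6L), "range")
})

test_that("the classifier harness is deterministic and learns separable data", {
  feats <- withr::with_seed(42, data.frame(
    smog = c(rnorm(40, 6), rnorm(40, 18)),
    css_rule_count = c(rpois(40, 12), rpois(40, 2)),
    page_rank = c(runif(40, 0.6, 1), runif(40, 0, 0.3))))
  labels <- rep(c(1L, 0L), each = 40L)
  fit <- train_credibility_classifier(feats, labels, seed = 3)
  pred <- as.integer(predict(fit, feats) > 0.5)
  expect_equal(pred, labels)
  # same seed twice -> identical probabilities
  fit2 <- train_credibility_classifier(feats, labels, seed = 3)
  expect_identical(predict(fit, feats), predict(fit2, feats))
  expect_error(train_credibility_classifier(feats, rep(1L, 80L)),
               "single-class")
})

test_that("label-permuted training yields chance-level out-of-bag accuracy", {
  tab <- synthetic_credibility_table(n = 150L, seed = 21)
  feats <- tab[, c("smog", "css_rule_count", "page_rank")]
  labels <- binarize_credibility(tab$rating)
  acc <- vapply(1:20, function(s) {
    permuted <- withr::with_seed(1000L + s, sample(labels))
    fit <- train_credibility_classifier(feats, permuted, seed = s,
                                        ntree = 150L)
    oob <- fit$forest$predicted
    mean(as.integer(as.character(oob)) == permuted)
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.1)
  # the unpermuted synthetic table, in contrast, is learnable
  fit <- train_credibility_classifier(feats, labels, seed = 1, ntree = 300L)
  oob_acc <- mean(as.integer(as.character(fit$forest$predicted)) == labels)
  expect_gt(oob_acc, 0.6)
})

test_that("trusted-domain matching uses registrable-domain suffixes", {
  trusted <- trusted_domains(c("Example.ORG", "health.net"))
  expect_equal(is_trusted_url(
    c("https://www.example.org/page", "http://example.org",
      "https://sub.a.health.net/x?q=1", "https://notexample.org",
      "https://example.org.evil.com", ""), trusted),
    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("credibility scores add the unitary trusted bonus", {
  corpus <- make_toy_corpus(6L)
  corpus$url[1] <- "https://www.trusted.org/a"
  trusted <- trusted_domains("trusted.org")
  # constant-prior classifier: score is 0.5 + bonus
  s <- credibility_score(corpus, classifier = NULL, trusted = trusted)
  expect_equal(unname(s[corpus$doc_id[1]]), 1.5)
  expect_equal(unname(s[corpus$doc_id[2]]), 0.5)
  expect_true(all(s >= 0 & s <= 2))
  # missing URL -> no bonus
  corpus$url[1] <- ""
  s2 <- credibility_score(corpus, classifier = NULL, trusted = trusted)
  expect_equal(unname(s2[corpus$doc_id[1]]), 0.5)
  # the bonus strictly dominates: a trusted doc outranks every untrusted one
  # whose credible probability is below 1
  for (p_t in seq(0, 1, by = 0.25))
    for (p_u in seq(0, 0.99, by = 0.33))
      expect_gt(1 + p_t, p_u)
})

test_that("credibility reranking sorts by score with doc_id ties", {
  base <- ranking("1", c("b", "a", "c"), 3:1)
  # uniform scores -> doc_id order
  u <- credibility_rerank(base, c(b = 1, a = 1, c = 1))
  expect_equal(ranking_docs(u), c("a", "b", "c"))
  # reversed base ranks -> exact reversal
  rev_scores <- stats::setNames(1:3, ranking_docs(base))
  expect_equal(ranking_docs(credibility_rerank(base, rev_scores)),
               rev(ranking_docs(base)))
  # random scores equal a brute-force sort
  sc <- stats::setNames(unit_hash(c("b", "a", "c"), seed = 5),
                        c("b", "a", "c"))
  got <- ranking_docs(credibility_rerank(base, sc))
  want <- names(sc)[order(-sc, names(sc))]
  expect_equal(got, want)
  expect_error(credibility_rerank(base, c(b = 1, a = 1)), "missing")
})

test_that("feature extraction is robust and provider-pluggable", {
  corpus <- data.frame(doc_id = c("d1", "d2"),
                       text = c("One sentence here.", "Another bit of text."),
                       url = c("https://a.com/x", "https://b.com/y"),
                       html = c("<style>a{}</style>", ""))
  pr <- c("https://a.com/x" = 0.9)
  f <- credibility_features(corpus, page_rank_provider = pr)
  expect_equal(f$page_rank, c(0.9, 0))
  expect_equal(f$css_rule_count, c(1L, 0L))
  expect_true(all(f$smog >= 3.1291))
  f2 <- credibility_features(corpus,
                             page_rank_provider = function(u) nchar(u) / 100)
  expect_equal(f2$page_rank, nchar(corpus$url) / 100)
})
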