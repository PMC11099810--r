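#' Specification of a synthetic health-search benchmark
#'
#' Defines the study conditions a generated benchmark emulates: a topic set
#' split into helpful and unhelpful interventions, a per-topic document
#' pool with planted usefulness, stance, and credibility structure, and the
#' stance biases of web content. Defaults mirror the benchmark shape of the
#' evaluation campaign this package targets: 32 topics, 14 helpful and 18
#' unhelpful, with sparse usefulness (a handful of relevant documents per
#' ten retrieved), supportive-leaning content on helpful topics and evenly
#' split content on unhelpful ones.
#'
#' @param n_topics number of topics (default 32).
#' @param fraction_helpful fraction of topics with a helpful stance
#'   (default 14/32).
#' @param docs_per_topic documents generated per topic (default 200).
#' @param p_useful probability a document is useful (default 0.15).
#' @param frac_very_useful probability a useful document is very useful
#'   (grade 2 rather than 1; default 0.4).
#' @param p_neutral probability a useful document is stance-neutral
#'   (default 0.2).
#' @param stance_bias_helpful probability a non-neutral useful document on
#'   a helpful topic is supportive (default 0.75).
#' @param stance_bias_unhelpful same for unhelpful topics (default 0.5).
#' @param p_credible probability a useful document is credible (default 0.6).
#' @param vocabulary filler vocabulary size (default 2000).
#' @param noise_rate probability a non-useful document mentions the topic's
#'   signature vocabulary (retrieval noise; default 0.1).
#' @param doc_length filler tokens per document (default 24).
#' @param seed default generation seed.
#' @return an object of class `"benchmark_spec"`.
#' @export
benchmark_spec <- function(n_topics = 32L, fraction_helpful = 14 / 32,
                           docs_per_topic = 200L, p_useful = 0.15,
                           frac_very_useful = 0.4, p_neutral = 0.2,
                           stance_bias_helpful = 0.75,
                           stance_bias_unhelpful = 0.5, p_credible = 0.6,
                           vocabulary = 2000L, noise_rate = 0.1,
                           doc_length = 24L, seed = 42L) {
  stopifnot(n_topics >= 1L, docs_per_topic >= 1L, vocabulary >= 10L,
            doc_length >= 4L)
  for (nm in c("fraction_helpful", "p_useful", "frac_very_useful",
               "p_neutral", "stance_bias_helpful", "stance_bias_unhelpful",
               "p_credible", "noise_rate"))
    .assert_prob(get(nm), nm)
  structure(list(n_topics = as.integer(n_topics),
                 fraction_helpful = fraction_helpful,
                 docs_per_topic = as.integer(docs_per_topic),
                 p_useful = p_useful, frac_very_useful = frac_very_useful,
                 p_neutral = p_neutral,
                 stance_bias_helpful = stance_bias_helpful,
                 stance_bias_unhelpful = stance_bias_unhelpful,
                 p_credible = p_credible, vocabulary = as.integer(vocabulary),
                 noise_rate = noise_rate, doc_length = as.integer(doc_length),
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

.topic_signature <- function(topic_id) paste0("t", topic_id, "sig", 1:4)

#' Generate a synthetic benchmark
#'
#' Produces a complete miniature benchmark as a pure function of
#' `(spec, seed)`: topics with ground-truth stances in the requested
#' proportion; per topic, documents drawn useful with `p_useful`, useful
#' documents assigned a supportive / dissuasive / neutral stance according
#' to the topic's stance bias and a binary credibility grade with
#' `p_credible`; and a multidimensional judgment set recording all planted
#' grades plus derived preference labels. Document text mixes
#' topic-specific signature tokens (denser for higher usefulness grades,
#' with a small mention rate in non-useful documents) with shared filler
#' vocabulary, so BM25 retrieves useful documents above filler on average
#' while stance and credibility remain invisible to it. Supportive and
#' dissuasive documents additionally carry a stance marker token.
#'
#' @param spec a [benchmark_spec].
#' @param seed overriding seed; defaults to `spec$seed`.
#' @return a list with `topics` (data frame), `corpus` (data frame),
#'   `judgments` (a [judgment_set]), and `spec`.
#' @export
generate_benchmark <- function(spec = benchmark_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "benchmark_spec"))
  withr::with_seed(as.integer(seed), .generate_benchmark_impl(spec))
}

.generate_benchmark_impl <- function(spec) {
  n_helpful <- round(spec$fraction_helpful * spec$n_topics)
  topic_ids <- as.character(100L + seq_len(spec$n_topics))
  stance <- rep(c("helpful", "unhelpful"),
                c(n_helpful, spec$n_topics - n_helpful))
  vocab <- sprintf("w%04d", seq_len(spec$vocabulary))
  domains <- sprintf("site%02d.example.com", 1:40)

  topics <- data.frame(
    topic_id = topic_ids,
    query = vapply(topic_ids, function(t)
      paste(.topic_signature(t)[1:3], collapse = " "), character(1),
      USE.NAMES = FALSE),
    description = vapply(topic_ids, function(t)
      paste("does", paste(.topic_signature(t), collapse = " "),
            "help treat the condition"), character(1), USE.NAMES = FALSE),
    stance = stance,
    stringsAsFactors = FALSE)

  corpus_rows <- vector("list", spec$n_topics)
  qrel_rows <- vector("list", spec$n_topics)
  for (ti in seq_len(spec$n_topics)) {
    t <- topic_ids[ti]
    sig <- .topic_signature(t)
    nd <- spec$docs_per_topic
    doc_id <- sprintf("d%s-%04d", t, seq_len(nd))
    useful <- stats::runif(nd) < spec$p_useful
    grade <- integer(nd)
    grade[useful] <- 1L +
      (stats::runif(sum(useful)) < spec$frac_very_useful)
    bias <- if (stance[ti] == "helpful") spec$stance_bias_helpful
            else spec$stance_bias_unhelpful
    sup <- rep("unjudged", nd)
    is_neutral <- useful & (stats::runif(nd) < spec$p_neutral)
    sup[is_neutral] <- "neutral"
    polar <- useful & !is_neutral
    sup[polar] <- ifelse(stats::runif(sum(polar)) < bias,
                         "supportive", "dissuasive")
    cred <- rep(NA_integer_, nd)
    cred[useful] <- as.integer(stats::runif(sum(useful)) < spec$p_credible)

    text <- vapply(seq_len(nd), function(i) {
      filler <- sample(vocab, spec$doc_length, replace = TRUE)
      words <- if (useful[i]) {
        c(sample(sig, 2L + 2L * grade[i], replace = TRUE), filler)
      } else if (stats::runif(1) < spec$noise_rate) {
        c(sample(sig, 1L), filler)
      } else filler
      marker <- switch(sup[i], supportive = "stancesup",
                       dissuasive = "stancedis", NULL)
      paste(c(words, marker), collapse = " ")
    }, character(1))

    corpus_rows[[ti]] <- data.frame(
      doc_id = doc_id, text = text,
      url = sprintf("https://www.%s/%s", sample(domains, nd, replace = TRUE),
                    doc_id),
      timestamp = sprintf("2019-04-%02dT00:00:00Z",
                          sample.int(30L, nd, replace = TRUE)),
      html = "",
      stringsAsFactors = FALSE)
    qrel_rows[[ti]] <- data.frame(
      topic_id = t, doc_id = doc_id, usefulness = grade,
      supportiveness = sup, credibility = cred, stringsAsFactors = FALSE)
  }
  corpus <- do.call(rbind, corpus_rows)
  js <- judgment_set(do.call(rbind, qrel_rows), dialect = "multidim")
  js <- derive_preference_labels(js, topics)
  list(topics = topics, corpus = corpus, judgments = js, spec = spec)
}

#' Fidelity-controlled mock scorers and claim checkers
#'
#' Stand-ins for the pretrained-model scorers of the real pipeline,
#' configured with the ground-truth judgment set, a fidelity `phi`, and a
#' seed. For each (topic, document) pair the mock returns the
#' ground-truth-consistent score or label with probability `phi`, and a
#' uniform random one otherwise; `phi = 1` reproduces the ground truth
#' exactly and `phi = 0` is label-independent noise. All draws are
#' deterministic functions of (topic, document, seed), so repeated calls
#' are identical and never touch the global RNG.
#'
#' @param dimension `"usefulness"`, `"supportiveness"`, or
#'   `"credibility"`.
#' @param js the ground-truth [judgment_set].
#' @param fidelity `phi` in `[0, 1]`.
#' @param seed integer seed.
#' @param name optional scorer name.
#' @return a [scorer] for the usefulness and credibility dimensions, a
#'   [claim_checker] for supportiveness.
#' @export
mock_scorer <- function(dimension = c("usefulness", "supportiveness",
                                      "credibility"),
                        js, fidelity = 1, seed = 1L, name = NULL) {
  dimension <- match.arg(dimension)
  .assert_prob(fidelity, "fidelity")
  stopifnot(inherits(js, "judgment_set"))
  seed <- as.integer(seed)
  name <- name %||% sprintf("mock-%s-phi%.2f-s%d", dimension, fidelity, seed)

  truth_fn <- switch(dimension,
    usefulness = function(tab, docs) {
      g <- tab$usefulness[match(docs, tab$doc_id)]
      g[is.na(g)] <- 0L
      as.numeric(g)
    },
    credibility = function(tab, docs) {
      g <- tab$credibility[match(docs, tab$doc_id)]
      g[is.na(g)] <- 0L
      as.numeric(g)
    },
    supportiveness = function(tab, docs) {
      s <- tab$supportiveness[match(docs, tab$doc_id)]
      s[is.na(s)] <- "unjudged"
      c(supportive = "supports", dissuasive = "refutes",
        neutral = "neutral", unjudged = "neutral")[s]
    })

  impl <- function(topic_id, doc_ids) {
    tab <- .topic_judgments(js, topic_id)
    keys <- paste(topic_id, doc_ids, sep = "|")
    gate <- unit_hash(keys, seed, salt = "gate")
    noise <- unit_hash(keys, seed, salt = "value")
    truth <- truth_fn(tab, doc_ids)
    if (dimension == "supportiveness") {
      out <- .CLAIM_LABELS[1L + floor(3 * noise)]
      out[gate < fidelity] <- truth[gate < fidelity]
      unname(out)
    } else {
      scale <- if (dimension == "usefulness") 2 else 1
      ifelse(gate < fidelity, truth, scale * noise)
    }
  }
  if (dimension == "supportiveness") claim_checker(name, impl)
  else scorer(name, impl)
}

#' Synthetic stand-in for a rated web-page credibility table
#'
#' Generates feature rows (SMOG readability, CSS rule count, page rank)
#' with 1-5 credibility ratings whose distributions shift with the rating:
#' more credible pages read more easily, carry more styled design, and
#' have higher page rank. A synthetic stand-in for manually rated web-page
#' collections, used to exercise the classifier harness offline.
#'
#' @param n number of rows (default 300).
#' @param seed integer seed.
#' @return data frame with columns `rating`, `smog`, `css_rule_count`,
#'   `page_rank`.
#' @export
synthetic_credibility_table <- function(n = 300L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    rating <- sample.int(5L, n, replace = TRUE)
    data.frame(
      rating = rating,
      smog = pmax(3.1291, stats::rnorm(n, mean = 16 - rating, sd = 1.5)),
      css_rule_count = stats::rpois(n, lambda = 2 + 3 * rating),
      page_rank = pmin(1, pmax(0, stats::rnorm(n, mean = rating / 6, sd = 0.15))))
  })
}
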