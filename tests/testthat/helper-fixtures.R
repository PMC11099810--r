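# Small in-code fixtures shared across test files.

# A duplicate-free toy corpus: each document carries a unique high-IDF token
# (repeated) plus a shared tail, so self-retrieval is unambiguous.
make_toy_corpus <- function(n = 200L) {
  data.frame(
    doc_id = sprintf("doc%03d", seq_len(n)),
    text = vapply(seq_len(n), function(i)
      paste(c(rep(sprintf("uniq%03d", i), 3L), "common", "alpha", "beta"),
            collapse = " "), character(1)),
    url = sprintf("https://www.site%02d.example.com/doc%03d",
                  (seq_len(n) %% 10L) + 1L, seq_len(n)),
    timestamp = "2019-04-01T00:00:00Z",
    html = "",
    stringsAsFactors = FALSE)
}

# A tiny two-topic benchmark with hand-written judgments.
make_mini_benchmark <- function() {
  topics <- data.frame(
    topic_id = c("101", "102"),
    query = c("vitamin sun vitiligo", "sponge bath fever"),
    description = c("does vitamin and sun exposure help treat vitiligo",
                    "is a tepid sponge bath a good way to reduce fever"),
    stance = c("helpful", "unhelpful"),
    stringsAsFactors = FALSE)
  js <- judgment_set(data.frame(
    topic_id = c("101", "101", "101", "101", "102", "102", "102"),
    doc_id = c("dA", "dB", "dC", "dD", "dA", "dE", "dF"),
    usefulness = c(2L, 1L, 1L, 0L, 2L, 1L, 1L),
    supportiveness = c("supportive", "dissuasive", "neutral", "unjudged",
                       "supportive", "dissuasive", "neutral"),
    credibility = c(1L, 0L, 1L, NA, 1L, 1L, NA),
    stringsAsFactors = FALSE))
  js <- derive_preference_labels(js, topics)
  list(topics = topics, judgments = js)
}

# The SMOG fixture: 30 sentences, each with exactly one polysyllabic word
# ("banana", three vowel groups) among monosyllabic fillers.
smog_fixture_text <- function(n_sentences = 30L) {
  paste(rep("The cat sat on the mat with a banana.", n_sentences),
        collapse = " ")
}

# Deterministic mock scorer bundle for a generated benchmark.
make_mock_bundle <- function(js, phi, seed) {
  list(usefulness = list(mock_scorer("usefulness", js, phi, seed)),
       supportiveness = list(mock_scorer("supportiveness", js, phi, seed)),
       credibility = list(mock_scorer("credibility", js, phi, seed)))
}
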