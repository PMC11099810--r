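#' SMOG readability index
#'
#' Estimates the years of education needed to understand a text from its
#' polysyllabic-word density:
#' `3.1291 + 1.0430 * sqrt(polysyllables * 30 / sentences)`.
#' Sentences are split on terminal punctuation (`.!?`), words are
#' alphabetic tokens, and a word is polysyllabic when it contains at least
#' three vowel groups (`aeiouy` runs) -- a deterministic, dependency-light
#' syllable heuristic that can be swapped out via `syllable_counter`. The
#' score is a density ratio, so duplicating a text leaves it unchanged, and
#' it is bounded below by 3.1291.
#'
#' @param text a single string with at least one sentence.
#' @param syllable_counter `function(words) -> integer` syllable counts;
#'   default counts vowel groups.
#' @return the SMOG grade (years of education), a single number.
#' @export
smog_index <- function(text, syllable_counter = count_vowel_groups) {
  stopifnot(is.character(text), length(text) == 1L)
  sentences <- trimws(strsplit(text, "[.!?]+")[[1L]])
  sentences <- sentences[nzchar(sentences)]
  if (length(sentences) == 0L) stop("empty text: no sentences", call. = FALSE)
  words <- unlist(regmatches(sentences, gregexpr("[A-Za-z]+", sentences)),
                  use.names = FALSE)
  poly <- sum(syllable_counter(words) >= 3L)
  3.1291 + 1.0430 * sqrt(poly * 30 / length(sentences))
}

#' @rdname smog_index
#' @param words character vector of words.
#' @export
count_vowel_groups <- function(words) {
  if (length(words) == 0L) return(integer(0))
  vapply(gregexpr("[aeiouy]+", tolower(words)),
         function(m) if (m[1L] == -1L) 0L else length(m), integer(1))
}

#' Count CSS style definitions in an HTML page
#'
#' Design effort proxy: the number of rule blocks inside `<style>` elements
#' (counted as `{` occurrences), plus inline `style` attributes, plus
#' linked stylesheet references (each `<link rel="stylesheet">` counts 1).
#' Malformed HTML is parsed leniently and counted best-effort; plain text
#' yields 0.
#'
#' @param html HTML source string.
#' @param breakdown return the three component counts instead of the total?
#' @return an integer count, or a named integer vector when
#'   `breakdown = TRUE`.
#' @export
count_css_rules <- function(html, breakdown = FALSE) {
  stopifnot(is.character(html), length(html) == 1L)
  empty <- c(style_rules = 0L, inline_styles = 0L, linked_sheets = 0L)
  if (!nzchar(trimws(html)))
    return(if (breakdown) empty else 0L)
  doc <- tryCatch(xml2::read_html(html), error = function(e) NULL)
  if (is.null(doc)) return(if (breakdown) empty else 0L)
  style_text <- xml2::xml_text(xml2::xml_find_all(doc, "//style"))
  rules <- sum(vapply(gregexpr("\\{", style_text),
                      function(m) if (m[1L] == -1L) 0L else length(m),
                      integer(1)))
  inline <- length(xml2::xml_find_all(doc, "//*[@style]"))
  links <- xml2::xml_find_all(doc, "//link")
  rel <- tolower(vapply(links, function(l) xml2::xml_attr(l, "rel") %||% "",
                        character(1)))
  linked <- sum(!is.na(rel) & rel == "stylesheet")
  counts <- c(style_rules = as.integer(rules),
              inline_styles = as.integer(inline),
              linked_sheets = as.integer(linked))
  if (breakdown) counts else as.integer(sum(counts))
}

#' Binarize a 1-5 credibility rating
#'
#' Ratings of 4 and 5 are considered credible (1); ratings of 1, 2, and 3
#' non-credible (0).
#'
#' @param score_1_to_5 integer vector with values in 1..5.
#' @return integer vector of 0/1.
#' @export
binarize_credibility <- function(score_1_to_5) {
  s <- as.integer(score_1_to_5)
  if (anyNA(s) || any(s < 1L | s > 5L))
    stop("credibility rating out of range 1..5", call. = FALSE)
  as.integer(s >= 4L)
}

#' Compute credibility features for documents
#'
#' Readability (SMOG), CSS rule count, and page rank from a pluggable
#' provider (a named numeric vector keyed by URL, or a
#' `function(urls) -> numeric`; unknown URLs score 0). No network access is
#' ever performed.
#'
#' @param corpus data frame with `doc_id`, `text`, and optionally `url`,
#'   `html`.
#' @param page_rank_provider provider of page-rank scores; `NULL` for all
#'   zeros.
#' @return data frame with columns `doc_id`, `smog`, `css_rule_count`,
#'   `page_rank`.
#' @export
credibility_features <- function(corpus, page_rank_provider = NULL) {
  stopifnot(is.data.frame(corpus))
  urls <- if ("url" %in% names(corpus)) corpus$url else rep("", nrow(corpus))
  htmls <- if ("html" %in% names(corpus)) corpus$html else rep("", nrow(corpus))
  htmls[is.na(htmls)] <- ""
  pr <- if (is.null(page_rank_provider)) rep(0, nrow(corpus))
        else if (is.function(page_rank_provider)) page_rank_provider(urls)
        else {
          v <- unname(page_rank_provider[urls])
          v[is.na(v)] <- 0
          v
        }
  data.frame(
    doc_id = as.character(corpus$doc_id),
    smog = vapply(corpus$text, function(t)
      tryCatch(smog_index(t), error = function(e) 3.1291), numeric(1),
      USE.NAMES = FALSE),
    css_rule_count = vapply(htmls, count_css_rules, integer(1),
                            USE.NAMES = FALSE),
    page_rank = as.numeric(pr),
    stringsAsFactors = FALSE)
}

#' Train the binary credibility classifier
#'
#' Random-forest harness over per-page feature rows and binarized 1-5
#' credibility ratings (see [binarize_credibility()]), in the style of
#' classifiers trained on manually rated web-page collections. The fit is
#' deterministic under `seed`.
#'
#' @param features data frame of numeric features (a `doc_id` column, if
#'   present, is dropped).
#' @param labels binary labels (0/1), one per row; both classes must be
#'   present.
#' @param seed integer seed.
#' @param ntree number of trees (default 500).
#' @return an object of class `"credibility_classifier"`.
#' @export
train_credibility_classifier <- function(features, labels, seed = 1L,
                                         ntree = 500L) {
  stopifnot(is.data.frame(features))
  x <- features[, setdiff(names(features), "doc_id"), drop = FALSE]
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("single-class input: both credible and non-credible examples needed",
         call. = FALSE)
  if (nrow(x) != length(y)) stop("features/labels length mismatch", call. = FALSE)
  fit <- withr::with_seed(as.integer(seed),
                          randomForest::randomForest(x = x, y = y,
                                                     ntree = ntree))
  structure(list(forest = fit, feature_names = names(x), seed = seed),
            class = "credibility_classifier")
}

#' @export
print.credibility_classifier <- function(x, ...) {
  cat(sprintf("<credibility_classifier> random forest, %d trees, features: %s\n",
              x$forest$ntree, paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Predict the probability that pages are credible
#'
#' @param object a [train_credibility_classifier()] fit.
#' @param newdata data frame of feature rows.
#' @param ... unused.
#' @return numeric vector of probabilities of the credible class.
#' @export
predict.credibility_classifier <- function(object, newdata, ...) {
  x <- newdata[, object$feature_names, drop = FALSE]
  as.numeric(stats::predict(object$forest, x, type = "prob")[, "1"])
}

#' Trusted-domain list
#'
#' A set of registrable domains regarded as credible sources (e.g. a
#' curated list of certified health sites). Matching is by
#' registrable-domain suffix of the document URL's host, case-insensitive:
#' `www.example.org` matches the entry `example.org`.
#'
#' @param domains character vector of domains, or a path to a file with one
#'   domain per line.
#' @return an object of class `"trusted_domains"`.
#' @export
trusted_domains <- function(domains) {
  if (length(domains) == 1L && file.exists(domains))
    domains <- readLines(domains, warn = FALSE)
  domains <- tolower(trimws(domains))
  domains <- sub("^\\.", "", domains[nzchar(domains)])
  structure(list(domains = unique(domains)), class = "trusted_domains")
}

#' @rdname trusted_domains
#' @param urls character vector of URLs.
#' @param trusted a `trusted_domains` object.
#' @return `is_trusted_url`: logical vector.
#' @export
is_trusted_url <- function(urls, trusted) {
  stopifnot(inherits(trusted, "trusted_domains"))
  host <- tolower(urls)
  host <- sub("^[a-z][a-z0-9+.-]*://", "", host)   # scheme
  host <- sub("[/:?#].*$", "", host)               # path/port/query
  vapply(host, function(h) {
    if (!nzchar(h)) return(FALSE)
    any(h == trusted$domains | endsWith(h, paste0(".", trusted$domains)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Credibility score of documents
#'
#' The classifier's probability of the credible class, plus a unitary bonus
#' when the document's URL belongs to the trusted-domain list; the score
#' therefore lies in `[0, 2]` and any trusted document outranks every
#' untrusted one. Documents without a URL receive no bonus.
#'
#' @param corpus data frame of documents (`doc_id`, `text`, optionally
#'   `url`, `html`).
#' @param classifier a [train_credibility_classifier()] fit, or `NULL` for
#'   a constant 0.5 prior.
#' @param trusted a [trusted_domains] list, or `NULL` for no bonus.
#' @param page_rank_provider passed to [credibility_features()].
#' @return named numeric vector of scores keyed by `doc_id`.
#' @export
credibility_score <- function(corpus, classifier = NULL, trusted = NULL,
                              page_rank_provider = NULL) {
  feats <- credibility_features(corpus, page_rank_provider)
  prob <- if (is.null(classifier)) rep(0.5, nrow(feats))
          else predict(classifier, feats)
  bonus <- if (is.null(trusted) || !("url" %in% names(corpus))) 0
           else as.numeric(is_trusted_url(corpus$url, trusted))
  stats::setNames(prob + bonus, feats$doc_id)
}

#' Rerank a ranking by credibility scores
#'
#' Permutation of the base sorted by score descending, ties broken by
#' `doc_id` ascending.
#'
#' @param base a [ranking].
#' @param scores named numeric vector keyed by `doc_id` (must cover every
#'   base document), or an unnamed vector aligned with the base order.
#' @return a [ranking] tagged `"credibility"`.
#' @export
credibility_rerank <- function(base, scores) {
  stopifnot(inherits(base, "ranking"))
  if (!is.null(names(scores))) {
    s <- scores[base$doc_ids]
    if (anyNA(s))
      stop("missing credibility score for doc ",
           base$doc_ids[which(is.na(s))[1L]], call. = FALSE)
  } else {
    if (length(scores) != length(base$doc_ids))
      stop("missing credibility score: length mismatch", call. = FALSE)
    s <- scores
  }
  ranking(base$topic_id, base$doc_ids, as.numeric(s), run_tag = "credibility")
}
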