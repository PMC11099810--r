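#' Default preference-label rule
#'
#' The helpful/harmful label of a judged document follows a hierarchical
#' rule: only documents useful enough are considered at all; among those, a
#' document supporting an effective treatment or dissuading from an
#' ineffective one is helpful, and the stance-opposing combination is
#' harmful. Neutral or unjudged supportiveness yields "neither". The rule is
#' a lookup table over (topic stance, document supportiveness), so alternate
#' benchmark conventions can be plugged in.
#'
#' @param useful_min minimum usefulness grade for a document to be
#'   considered (default 1).
#' @return a list with fields `useful_min` and `table` (a data frame with
#'   columns `stance`, `supportiveness`, `label`).
#' @export
preference_rule <- function(useful_min = 1L) {
  table <- data.frame(
    stance = c("helpful", "helpful", "helpful", "helpful",
               "unhelpful", "unhelpful", "unhelpful", "unhelpful"),
    supportiveness = rep(c("supportive", "dissuasive", "neutral", "unjudged"), 2L),
    label = c("helpful", "harmful", "neither", "neither",
              "harmful", "helpful", "neither", "neither"),
    stringsAsFactors = FALSE)
  list(useful_min = as.integer(useful_min), table = table)
}

#' Derive helpful/harmful preference labels from graded judgments
#'
#' Applies a (configurable) rule combining each topic's ground-truth stance
#' with each judged document's usefulness and supportiveness grades; see
#' [preference_rule()] for the default. A pair can never be labelled both
#' helpful and harmful, and label counts do not depend on row order.
#'
#' @param js a [judgment_set] with usefulness and supportiveness grades.
#' @param topics data frame of topics providing a `stance` for every judged
#'   topic; a stance of `"unknown"` is an error (labels are undefined).
#' @param rule a rule as returned by [preference_rule()].
#' @return a [judgment_set] with the `label` column filled in.
#' @export
derive_preference_labels <- function(js, topics, rule = preference_rule()) {
  stopifnot(inherits(js, "judgment_set"))
  tab <- js$table
  stance <- topics$stance[match(tab$topic_id, topics$topic_id)]
  if (anyNA(stance)) {
    missing <- unique(tab$topic_id[is.na(stance)])
    stop("judged topic(s) absent from topic set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(stance == "unknown")) {
    bad <- unique(tab$topic_id[stance == "unknown"])
    stop("preference labels undefined for stance=unknown topic(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(stance, tab$supportiveness, sep = "\r")
  rkey <- paste(rule$table$stance, rule$table$supportiveness, sep = "\r")
  label <- rule$table$label[match(key, rkey)]
  label[is.na(label)] <- "neither"
  useful <- !is.na(tab$usefulness) & tab$usefulness >= rule$useful_min
  label[!useful] <- "neither"
  tab$label <- label
  judgment_set(tab, dialect = js$dialect)
}

.MAP_EFFECTIVENESS <- c(effective = "supportive", ineffective = "dissuasive",
                        neutral = "neutral", unjudged = "unjudged")

#' Map 2019-style decision judgments onto the 2021 quality dimensions
#'
#' Converts judgments graded on the relevance / effectiveness / credibility
#' dimensions (the 2019 convention) to the usefulness / supportiveness /
#' credibility dimensions (the 2021 convention): relevance maps to
#' usefulness with highly relevant (2) translated as very useful (2) and
#' relevant (1) as useful (1); effective maps to supportive and ineffective
#' to dissuasive; credibility is copied unchanged. Records already carrying
#' the 2021 columns are returned as-is, so the mapping is idempotent.
#'
#' @param judgments data frame with columns `topic_id`, `doc_id`,
#'   `relevance` (0, 1, 2), `effectiveness` (effective / ineffective /
#'   neutral / unjudged), `credibility` (0, 1, or NA) -- or an
#'   already-mapped frame with `usefulness`/`supportiveness` columns.
#' @return a [judgment_set] in the 2021 dimensions.
#' @export
map_2019_to_2021 <- function(judgments) {
  if (inherits(judgments, "judgment_set")) return(judgments)
  stopifnot(is.data.frame(judgments))
  if (all(c("usefulness", "supportiveness") %in% names(judgments)))
    return(judgment_set(judgments, dialect = "multidim"))
  need <- c("topic_id", "doc_id", "relevance", "effectiveness", "credibility")
  missing <- setdiff(need, names(judgments))
  if (length(missing) > 0L)
    stop("2019 judgments lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rel <- judgments$relevance
  bad <- setdiff(unique(rel), 0:2)
  if (length(bad) > 0L)
    stop("unmapped relevance grade value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  eff <- as.character(judgments$effectiveness)
  bad <- setdiff(unique(eff), names(.MAP_EFFECTIVENESS))
  if (length(bad) > 0L)
    stop("unmapped effectiveness value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cred <- judgments$credibility
  bad <- setdiff(unique(cred[!is.na(cred)]), 0:1)
  if (length(bad) > 0L)
    stop("unmapped credibility value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  judgment_set(data.frame(topic_id = judgments$topic_id,
                          doc_id = judgments$doc_id,
                          usefulness = as.integer(rel),
                          supportiveness = unname(.MAP_EFFECTIVENESS[eff]),
                          credibility = as.integer(cred),
                          stringsAsFactors = FALSE),
               dialect = "multidim")
}
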