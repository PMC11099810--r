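#' Read a TREC-format run file
#'
#' Parses the standard 6-column whitespace-separated run format
#' (`topic_id Q0 doc_id rank score tag`). The stored rank column is ignored:
#' ranks are re-derived from the scores, with ties broken by `doc_id`
#' ascending so the result is deterministic.
#'
#' @param path path to the run file.
#' @return a list of [ranking] objects, one per topic, in canonical topic
#'   order.
#' @export
read_run <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty run file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop(sprintf("malformed run line %d in %s: expected 6 fields, got %d",
                 which(nf != 6L)[1L], path, nf[nf != 6L][1L]), call. = FALSE)
  m <- do.call(rbind, fields)
  score <- suppressWarnings(as.numeric(m[, 5L]))
  if (anyNA(score))
    stop(sprintf("malformed run line %d in %s: non-numeric score '%s'",
                 which(is.na(score))[1L], path, m[which(is.na(score))[1L], 5L]),
         call. = FALSE)
  df <- data.frame(topic_id = m[, 1L], doc_id = m[, 3L], score = score,
                   tag = m[, 6L], stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("topic_id", "doc_id")])) {
    dup <- df[duplicated(df[, c("topic_id", "doc_id")]), , drop = FALSE]
    stop(sprintf("duplicate (topic, doc) pair in %s: (%s, %s)", path,
                 dup$topic_id[1L], dup$doc_id[1L]), call. = FALSE)
  }
  topics <- unique(df$topic_id)
  topics <- topics[.order_topic_ids(topics)]
  lapply(topics, function(t) {
    sub <- df[df$topic_id == t, , drop = FALSE]
    ranking(t, sub$doc_id, sub$score, run_tag = sub$tag[1L])
  })
}

#' Write rankings as a TREC-format run file
#'
#' Emits the canonical 6-column form: topics in canonical topic order, ranks
#' starting at 1, scores printed with six decimals. A write/read cycle of a
#' canonical file is byte-identical.
#'
#' @param rankings list of [ranking] objects (one per topic).
#' @param path output path.
#' @param tag run tag; defaults to each ranking's own `run_tag`.
#' @return `path`, invisibly.
#' @export
write_run <- function(rankings, path, tag = NULL) {
  if (inherits(rankings, "ranking")) rankings <- list(rankings)
  if (length(rankings) == 0L) stop("no rankings to write", call. = FALSE)
  empty <- vapply(rankings, function(r) length(r$doc_ids) == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("omitting %d topic(s) with empty rankings: %s",
                    sum(empty),
                    paste(vapply(rankings[empty], function(r) r$topic_id,
                                 character(1)), collapse = ", ")),
            call. = FALSE)
    rankings <- rankings[!empty]
  }
  if (length(rankings) == 0L) stop("all rankings empty", call. = FALSE)
  ids <- vapply(rankings, function(r) r$topic_id, character(1))
  rankings <- rankings[.order_topic_ids(ids)]
  out <- unlist(lapply(rankings, function(r) {
    sprintf("%s Q0 %s %d %.6f %s", r$topic_id, r$doc_ids,
            seq_along(r$doc_ids), r$scores, tag %||% r$run_tag)
  }))
  writeLines(out, path)
  invisible(path)
}

.SUPPORT_LEVELS <- c("supportive", "dissuasive", "neutral", "unjudged")
.PREF_LABELS <- c("helpful", "harmful", "neither")

#' Multidimensional judgment set
#'
#' A set of per-(topic, document) quality judgments: a graded usefulness
#' score, a supportiveness level (supportive / dissuasive / neutral /
#' unjudged), a binary credibility grade (or unjudged), and a derived or
#' directly assessed preference label (helpful / harmful / neither).
#'
#' @param table data frame with columns `topic_id`, `doc_id` and any of
#'   `usefulness`, `supportiveness`, `credibility`, `label`; missing columns
#'   are filled with "unjudged" values.
#' @param dialect tag recording which qrels dialect the set came from.
#' @return an object of class `"judgment_set"`.
#' @export
judgment_set <- function(table, dialect = "multidim") {
  stopifnot(is.data.frame(table), all(c("topic_id", "doc_id") %in% names(table)))
  tab <- data.frame(topic_id = as.character(table$topic_id),
                    doc_id = as.character(table$doc_id),
                    stringsAsFactors = FALSE)
  n <- nrow(tab)
  tab$usefulness <- if ("usefulness" %in% names(table))
    as.integer(table$usefulness) else rep(NA_integer_, n)
  tab$supportiveness <- if ("supportiveness" %in% names(table))
    as.character(table$supportiveness) else rep("unjudged", n)
  tab$credibility <- if ("credibility" %in% names(table))
    as.integer(table$credibility) else rep(NA_integer_, n)
  tab$label <- if ("label" %in% names(table))
    as.character(table$label) else rep("neither", n)
  bad <- setdiff(unique(tab$supportiveness), .SUPPORT_LEVELS)
  if (length(bad) > 0L)
    stop("unknown supportiveness level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$label), .PREF_LABELS)
  if (length(bad) > 0L)
    stop("unknown preference label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab[, c("topic_id", "doc_id")]))
    stop("duplicate (topic, doc) judgment", call. = FALSE)
  structure(list(table = tab, dialect = dialect), class = "judgment_set")
}

#' @export
print.judgment_set <- function(x, ...) {
  cat(sprintf("<judgment_set> %d judgments, %d topics, dialect '%s'\n",
              nrow(x$table), length(unique(x$table$topic_id)), x$dialect))
  invisible(x)
}

#' Look up the judgment for one (topic, document) pair
#'
#' An unjudged pair yields an explicit unjudged record (usefulness 0,
#' supportiveness and credibility "unjudged", label "neither"), never an
#' error.
#'
#' @param js a [judgment_set].
#' @param topic_id,doc_id identifiers of the pair.
#' @return a list with fields `usefulness`, `supportiveness`, `credibility`,
#'   `label`, `judged`.
#' @export
judgment_lookup <- function(js, topic_id, doc_id) {
  stopifnot(inherits(js, "judgment_set"))
  i <- which(js$table$topic_id == as.character(topic_id) &
             js$table$doc_id == as.character(doc_id))
  if (length(i) == 0L)
    return(list(usefulness = 0L, supportiveness = "unjudged",
                credibility = NA_integer_, label = "neither", judged = FALSE))
  row <- js$table[i[1L], ]
  list(usefulness = row$usefulness, supportiveness = row$supportiveness,
       credibility = row$credibility, label = row$label, judged = TRUE)
}

# Fast path used internally: the judgment rows for one topic.
.topic_judgments <- function(js, topic_id) {
  js$table[js$table$topic_id == as.character(topic_id), , drop = FALSE]
}

#' Read a qrels file
#'
#' Two dialects are supported. `"multidim"` carries one graded judgment per
#' quality dimension per line: `topic doc usefulness supportiveness
#' credibility`, with usefulness in `{0, 1, 2}`, supportiveness one of
#' supportive / dissuasive / neutral / unjudged, and credibility 0, 1 or
#' unjudged. `"preference"` carries a single derived label per line:
#' `topic doc label` with 1 = helpful, -1 = harmful, 0 = neither.
#'
#' @param path path to the qrels file.
#' @param dialect `"multidim"` or `"preference"`.
#' @return a [judgment_set].
#' @export
read_qrels <- function(path, dialect = c("multidim", "preference")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty qrels file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  want <- if (dialect == "multidim") 5L else 3L
  if (any(nf != want))
    stop(sprintf("malformed qrels line %d in %s: expected %d fields, got %d",
                 which(nf != want)[1L], path, want, nf[nf != want][1L]),
         call. = FALSE)
  m <- do.call(rbind, fields)
  if (dialect == "multidim") {
    usefulness <- suppressWarnings(as.integer(m[, 3L]))
    if (anyNA(usefulness) || !all(usefulness %in% 0:2))
      stop("usefulness grade out of range {0,1,2} at line ",
           which(is.na(usefulness) | !(usefulness %in% 0:2))[1L], call. = FALSE)
    sup <- m[, 4L]
    bad <- setdiff(unique(sup), .SUPPORT_LEVELS)
    if (length(bad) > 0L)
      stop("unknown supportiveness value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    credraw <- m[, 5L]
    cred <- ifelse(credraw == "unjudged", NA_integer_,
                   suppressWarnings(as.integer(credraw)))
    judged_cred <- credraw != "unjudged"
    if (any(judged_cred & (is.na(cred) | !(cred %in% 0:1))))
      stop("credibility grade out of range {0,1,unjudged} at line ",
           which(judged_cred & (is.na(cred) | !(cred %in% 0:1)))[1L],
           call. = FALSE)
    judgment_set(data.frame(topic_id = m[, 1L], doc_id = m[, 2L],
                            usefulness = usefulness, supportiveness = sup,
                            credibility = cred, stringsAsFactors = FALSE),
                 dialect = "multidim")
  } else {
    lab <- suppressWarnings(as.integer(m[, 3L]))
    if (anyNA(lab) || !all(lab %in% c(-1L, 0L, 1L)))
      stop("preference label out of range {-1,0,1} at line ",
           which(is.na(lab) | !(lab %in% c(-1L, 0L, 1L)))[1L], call. = FALSE)
    judgment_set(data.frame(topic_id = m[, 1L], doc_id = m[, 2L],
                            label = c("harmful", "neither", "helpful")[lab + 2L],
                            stringsAsFactors = FALSE),
                 dialect = "preference")
  }
}

#' Write a qrels file
#'
#' Rows are emitted in canonical (topic, doc) order so a read/write cycle of
#' a canonical file is byte-identical.
#'
#' @param js a [judgment_set].
#' @param path output path.
#' @param dialect dialect to emit; defaults to the set's own dialect.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(js, path, dialect = NULL) {
  stopifnot(inherits(js, "judgment_set"))
  dialect <- dialect %||% js$dialect
  tab <- js$table
  key <- .order_topic_ids(unique(tab$topic_id))
  topic_rank <- match(tab$topic_id, unique(tab$topic_id)[key])
  o <- order(topic_rank, tab$doc_id, method = "radix")
  tab <- tab[o, , drop = FALSE]
  if (dialect == "multidim") {
    cred <- ifelse(is.na(tab$credibility), "unjudged",
                   as.character(tab$credibility))
    use <- ifelse(is.na(tab$usefulness), 0L, tab$usefulness)
    out <- sprintf("%s %s %d %s %s", tab$topic_id, tab$doc_id, use,
                   tab$supportiveness, cred)
  } else if (dialect == "preference") {
    num <- c(helpful = 1L, harmful = -1L, neither = 0L)[tab$label]
    out <- sprintf("%s %s %d", tab$topic_id, tab$doc_id, num)
  } else stop("unknown qrels dialect: ", dialect, call. = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Read or write a topic file
#'
#' Topics are stored as a JSON array of objects with fields `topic_id`,
#' `query`, `description`, `stance` (helpful / unhelpful / unknown). A
#' stance of `"unknown"` marks the automatic-run setting: ranking
#' operations never consume the stance, only evaluation and the synthetic
#' generator do.
#'
#' @param path path to the JSON topic file.
#' @return `read_topics`: a data frame with one row per topic.
#' @export
read_topics <- function(path) {
  df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("topic_id", "query", "description", "stance")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("topic file lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$topic_id <- as.character(df$topic_id)
  bad <- setdiff(unique(df$stance), c("helpful", "unhelpful", "unknown"))
  if (length(bad) > 0L)
    stop("unknown stance value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$topic_id))
    stop("duplicate topic_id in topic file", call. = FALSE)
  df[, need]
}

#' @rdname read_topics
#' @param topics data frame of topics.
#' @export
write_topics <- function(topics, path) {
  jsonlite::write_json(topics[, c("topic_id", "query", "description", "stance")],
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read or write a JSON-lines document corpus
#'
#' One JSON object per line with fields `doc_id`, `text`, `url`,
#' `timestamp`, and optionally `html`, mirroring cleaned web-crawl records.
#'
#' @param path path to the `.jsonl` file.
#' @return `read_corpus`: a data frame with one row per document.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- data.frame(
    doc_id = vapply(recs, function(r) as.character(r$doc_id %||% ""), character(1)),
    text = vapply(recs, function(r) as.character(r$text %||% ""), character(1)),
    url = vapply(recs, function(r) as.character(r$url %||% ""), character(1)),
    timestamp = vapply(recs, function(r) as.character(r$timestamp %||% ""), character(1)),
    html = vapply(recs, function(r) as.character(r$html %||% ""), character(1)),
    stringsAsFactors = FALSE)
  if (any(!nzchar(df$doc_id))) stop("corpus record without doc_id", call. = FALSE)
  if (anyDuplicated(df$doc_id)) stop("duplicate doc_id in corpus", call. = FALSE)
  df
}

#' @rdname read_corpus
#' @param corpus data frame of documents.
#' @export
write_corpus <- function(corpus, path) {
  cols <- intersect(c("doc_id", "text", "url", "timestamp", "html"),
                    names(corpus))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- as.list(corpus[i, cols, drop = FALSE])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
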