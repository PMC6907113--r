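#' Read TREC-style topics
#'
#' Two formats are accepted:
#' \describe{
#'   \item{xml}{`<topics><topic number="1"><note>...</note>...</topic></topics>`
#'     (attribute style) or nested `<top><num>1</num><title>...</title></top>`
#'     style. Every child element of a topic becomes a named field; unknown
#'     field names are preserved verbatim.}
#'   \item{jsonl}{one JSON object per line: `{"id": ..., "field": "text", ...}`.}
#' }
#'
#' @param path topics file.
#' @param format `"xml"` (default) or `"jsonl"`.
#' @return list of topics; each is a list with `topic_id` (character) and
#'   `fields` (named list of character scalars), in file order.
#' @export
read_topics <- function(path, format = c("xml", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  topics <- if (format == "xml") .read_topics_xml(path) else .read_topics_jsonl(path)
  ids <- vapply(topics, `[[`, character(1), "topic_id")
  if (anyDuplicated(ids)) {
    stop("duplicate topic_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (tp in topics) {
    if (!length(tp$fields) || all(!nzchar(unlist(tp$fields)))) {
      stop("topic ", tp$topic_id, " has no non-empty field")
    }
  }
  topics
}

.read_topics_xml <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//topic | .//top")
  lapply(nodes, function(node) {
    id <- xml2::xml_attr(node, "number")
    children <- xml2::xml_children(node)
    fields <- list()
    for (ch in children) {
      nm <- xml2::xml_name(ch)
      val <- trimws(xml2::xml_text(ch))
      if (nm == "num" && (is.na(id) || !nzchar(id))) {
        id <- gsub("[^0-9A-Za-z._-]", "", sub("^\\s*Number:\\s*", "", val))
      } else {
        fields[[nm]] <- val
      }
    }
    if (is.na(id) || !nzchar(id)) stop("topic without a number in ", path)
    list(topic_id = as.character(id), fields = fields)
  })
}

.read_topics_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSON at line ", i,
                                             " of ", path, ": ",
                                             conditionMessage(e)))
    if (is.null(obj$id)) stop("topic without an id at line ", i, " of ", path)
    fields <- obj[setdiff(names(obj), "id")]
    list(topic_id = as.character(obj$id),
         fields = lapply(fields, as.character))
  })
}

#' Write topics as attribute-style XML
#'
#' @param topics list of topics as returned by [read_topics()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_topics <- function(topics, path) {
  root <- xml2::xml_new_root("topics")
  for (tp in topics) {
    node <- xml2::xml_add_child(root, "topic", number = tp$topic_id)
    for (nm in names(tp$fields)) {
      xml2::xml_add_child(node, nm, tp$fields[[nm]])
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Seed a query from a topic
#'
#' Picks the query field — by default `"note"` when present, else
#' `"description"`, else the first non-empty field — and tokenizes it.
#'
#' @param topic one topic (list with `topic_id`, `fields`).
#' @param field field name to use, or `NULL` for the default preference.
#' @param analyzer a [text_analyzer()].
#' @return a [weighted_query()].
#' @export
query_from_topic <- function(topic, field = NULL, analyzer = text_analyzer()) {
  if (is.null(field)) {
    prefer <- c("note", "description")
    field <- prefer[prefer %in% names(topic$fields)][1]
    if (is.na(field)) {
      nonempty <- names(topic$fields)[nzchar(unlist(topic$fields))]
      field <- nonempty[1]
    }
  }
  if (is.null(field) || is.na(field) || !field %in% names(topic$fields)) {
    stop("topic ", topic$topic_id, " has no usable query field")
  }
  query_from_text(topic$topic_id, topic$fields[[field]], analyzer)
}

#' Read a TREC qrels file
#'
#' Four whitespace-separated columns per line: `topic iteration doc grade`.
#' Blank lines are ignored; malformed lines and conflicting duplicate
#' judgments are errors naming the line.
#'
#' @param path qrels file.
#' @return a [qrels()] data frame.
#' @export
read_qrels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(qrels(character(), character(), integer()))
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(parts, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed qrels line(s) ", paste(lineno[bad], collapse = ", "),
         " in ", path)
  }
  m <- do.call(rbind, parts)
  grade <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(grade)) {
    stop("non-integer grade at line(s) ",
         paste(lineno[is.na(grade)], collapse = ", "), " in ", path)
  }
  key <- paste(m[, 1], m[, 3])
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    grp <- split(grade[dup], key[dup])
    conflict <- names(grp)[vapply(grp, function(g) length(unique(g)) > 1,
                                  logical(1))]
    if (length(conflict)) {
      stop("conflicting duplicate judgments for: ",
           paste(conflict, collapse = ", "))
    }
    first <- !duplicated(key)
    m <- m[first, , drop = FALSE]
    grade <- grade[first]
  }
  qrels(m[, 1], m[, 3], grade)
}

#' Write a qrels file
#'
#' @param qr a [qrels()] data frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_qrels <- function(qr, path) {
  writeLines(sprintf("%s 0 %s %d", qr$topic_id, qr$doc_id, qr$grade), path)
  invisible(path)
}

#' Write a run in 6-column TREC format
#'
#' Lines of `topic_id Q0 doc_id rank score tag`, rank starting at 1, scores
#' printed with six decimals so repeated runs are byte-identical.
#'
#' @param run run data frame (`topic_id`, `doc_id`, `rank`, `score`).
#' @param path output file.
#' @param tag run tag (single token, default `"hroc"`).
#' @return the path, invisibly.
#' @export
write_run <- function(run, path, tag = "hroc") {
  stopifnot(is.data.frame(run))
  ord <- order(run$topic_id, run$rank, method = "radix")
  run <- run[ord, , drop = FALSE]
  writeLines(sprintf("%s Q0 %s %d %.6f %s", run$topic_id, run$doc_id,
                     run$rank, run$score, tag), path)
  invisible(path)
}

#' Read a TREC run file
#'
#' @param path run file.
#' @return run data frame (`topic_id`, `doc_id`, `rank`, `score`) ordered by
#'   topic then rank; the tag column is dropped.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(topic_id = character(), doc_id = character(),
                      rank = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(parts, length, integer(1)) != 6L
  if (any(bad)) stop("malformed run line(s) ",
                     paste(which(bad), collapse = ", "), " in ", path)
  m <- do.call(rbind, parts)
  out <- data.frame(topic_id = m[, 1], doc_id = m[, 3],
                    rank = as.integer(m[, 4]), score = as.numeric(m[, 5]),
                    stringsAsFactors = FALSE)
  out[order(out$topic_id, out$rank, method = "radix"), , drop = FALSE]
}

#' Read a document collection
#'
#' Either a directory of `*.txt` files (doc id = file name without
#' extension) or a JSON-lines file of `{"id": ..., "text": ...}` objects.
#'
#' @param path directory or `.jsonl` file.
#' @return named character vector of raw document texts.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no *.txt files in ", path)
    ids <- tools::file_path_sans_ext(basename(files))
    if (anyDuplicated(ids)) stop("duplicate doc ids in ", path)
    stats::setNames(vapply(files, function(f) {
      paste(readLines(f, warn = FALSE), collapse = "\n")
    }, character(1)), ids)
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    ids <- character(length(lines))
    texts <- character(length(lines))
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("malformed JSON at line ", i,
                                               " of ", path))
      if (is.null(obj$id) || is.null(obj$text)) {
        stop("line ", i, " of ", path, " lacks id/text")
      }
      ids[i] <- as.character(obj$id)
      texts[i] <- as.character(obj$text)
    }
    if (anyDuplicated(ids)) {
      stop("duplicate doc_id: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
    }
    stats::setNames(texts, ids)
  } else {
    stop("no such corpus: ", path)
  }
}

#' Write a corpus as JSON-lines
#'
#' @param texts named character vector of document texts.
#' @param path output `.jsonl` file.
#' @return the path, invisibly.
#' @export
write_corpus_jsonl <- function(texts, path) {
  lines <- vapply(seq_along(texts), function(i) {
    jsonlite::toJSON(list(id = names(texts)[i], text = unname(texts[i])),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
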