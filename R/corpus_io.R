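#' @title Post corpora: construction and validation
#'
#' @description A corpus is a data frame of discussion-board posts with the
#' five canonical columns `post_id`, `board`, `username`, `date`, `text`,
#' carrying class `post_corpus`. Three board labels are canonical
#' (`ovarian`, `uterine`, `other_gyn`); other labels are accepted with a
#' warning so the label set stays extensible.
#'
#' @param posts A data frame with columns `post_id`, `board`, `username`,
#'   `date` (ISO 8601 date or `Date`), `text`.
#' @param date_range Length-2 vector of the earliest and latest admissible
#'   post dates (defaults span 1990--2100).
#' @return A `post_corpus` data frame.
#' @export
post_corpus <- function(posts, date_range = c("1990-01-01", "2100-12-31")) {
  required <- c("post_id", "board", "username", "date", "text")
  missing_cols <- setdiff(required, names(posts))
  if (length(missing_cols) > 0L) {
    stop("corpus is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  posts <- as.data.frame(posts)[required]
  posts$post_id <- as.character(posts$post_id)
  posts$board <- as.character(posts$board)
  posts$username <- as.character(posts$username)
  posts$text <- as.character(posts$text)
  if (anyNA(posts$text)) stop("post text may be empty but not absent (NA)",
                              call. = FALSE)
  dup <- posts$post_id[duplicated(posts$post_id)]
  if (length(dup) > 0L) {
    stop("duplicate post_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  d <- if (inherits(posts$date, "Date")) posts$date else
    as.Date(as.character(posts$date), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- posts$post_id[is.na(d)]
    stop("unparseable date for post_id: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dr <- as.Date(date_range)
  if (any(d < dr[1L] | d > dr[2L])) {
    bad <- posts$post_id[d < dr[1L] | d > dr[2L]]
    stop("date outside valid range [", dr[1L], ", ", dr[2L], "] for post_id: ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  posts$date <- d
  unknown <- setdiff(unique(posts$board), canonical_boards())
  if (length(unknown) > 0L) {
    warning("non-canonical board label(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  rownames(posts) <- NULL
  class(posts) <- c("post_corpus", "data.frame")
  posts
}

#' Canonical discussion-board labels
#' @return Character vector of the three canonical board labels.
#' @export
canonical_boards <- function() c("ovarian", "uterine", "other_gyn")

#' Parse a fixture forum HTML page into post records
#'
#' Parses the documented fixture dialect: each post is
#' `<div class="post" id="...">` containing `<span class="username">`,
#' `<span class="date">` (ISO 8601) and `<div class="post-text">`. Posts are
#' returned in document order with `board` set to `board_label`.
#'
#' @param html_doc HTML text (a string) or a path to an HTML file.
#' @param board_label Board label to assign to every parsed post.
#' @return A data frame with columns `post_id`, `board`, `username`, `date`,
#'   `text` (zero rows for a page with no post divs). Not yet validated as a
#'   corpus; bind pages and pass to [post_corpus()].
#' @export
parse_forum_html <- function(html_doc, board_label) {
  stopifnot(is.character(html_doc), length(html_doc) == 1L)
  doc <- xml2::read_html(html_doc, encoding = "UTF-8")
  nodes <- xml2::xml_find_all(doc, "//div[contains(concat(' ', normalize-space(@class), ' '), ' post ')]")
  n <- length(nodes)
  post_id <- username <- date <- text <- character(n)
  for (i in seq_len(n)) {
    node <- nodes[[i]]
    id <- xml2::xml_attr(node, "id")
    if (is.na(id) || !nzchar(id)) parse_error("post_id", i)
    u <- xml2::xml_find_first(node, ".//span[@class='username']")
    if (inherits(u, "xml_missing")) parse_error("username", i)
    d <- xml2::xml_find_first(node, ".//span[@class='date']")
    if (inherits(d, "xml_missing")) parse_error("date", i)
    tx <- xml2::xml_find_first(node, ".//div[@class='post-text']")
    if (inherits(tx, "xml_missing")) parse_error("text", i)
    post_id[i] <- id
    username[i] <- xml2::xml_text(u)
    date[i] <- xml2::xml_text(d)
    text[i] <- xml2::xml_text(tx)
  }
  data.frame(post_id = post_id, board = rep(as.character(board_label), n),
             username = username, date = date, text = text,
             stringsAsFactors = FALSE)
}

parse_error <- function(field, index) {
  stop(structure(
    class = c("themescan_parse_error", "error", "condition"),
    list(message = sprintf("malformed post element %d: missing '%s'",
                           index, field),
         call = NULL, field = field, index = index)))
}

#' Read a post table from CSV
#'
#' Reads the canonical RFC-4180-style post table (UTF-8, header
#' `post_id,board,username,date,text`) written by [write_post_table()].
#'
#' @param table_file Path to the CSV file.
#' @inheritParams post_corpus
#' @return A validated `post_corpus`.
#' @export
read_post_table <- function(table_file, date_range = c("1990-01-01", "2100-12-31")) {
  df <- utils::read.csv(table_file, colClasses = "character",
                        fileEncoding = "UTF-8", check.names = TRUE)
  required <- c("post_id", "board", "username", "date", "text")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("post table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  post_corpus(df[required], date_range = date_range)
}

#' Write a post table to CSV
#'
#' Text fields are quoted so embedded delimiters, quotes and newlines survive
#' a round-trip through [read_post_table()].
#'
#' @param corpus A `post_corpus` (or data frame with the canonical columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_post_table <- function(corpus, path) {
  corpus <- post_corpus(corpus)
  df <- as.data.frame(corpus)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
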