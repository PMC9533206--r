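#' Default English stopword list
#'
#' Common function words excluded from word-frequency tables and
#' bag-of-words vocabularies; shipped as a plain-text file and overridable
#' everywhere it is used.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "themescan",
                      mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Corpus composition summary
#'
#' Total posts, per-board counts and percent shares (2 decimals), unique
#' posters, and the per-poster activity summary (mean to 1 decimal, SD to 1
#' decimal, min/max).
#'
#' @param corpus A `post_corpus`.
#' @return A `corpus_summary` list with fields `total_posts`, `per_board`
#'   (data frame `board`, `count`, `share`), `unique_posters`,
#'   `mean_posts_per_poster`, `sd_posts_per_poster`, `min_posts_per_poster`,
#'   `max_posts_per_poster`.
#' @export
summarize_corpus <- function(corpus) {
  corpus <- post_corpus(corpus)
  if (nrow(corpus) == 0L) stop("cannot summarize an empty corpus",
                               call. = FALSE)
  total <- nrow(corpus)
  tab <- table(corpus$board)
  tab <- tab[order(-as.integer(tab), names(tab))]
  per_board <- data.frame(board = names(tab),
                          count = as.integer(tab),
                          share = round(100 * as.integer(tab) / total, 2L),
                          stringsAsFactors = FALSE)
  per_user <- table(corpus$username)
  structure(list(
    total_posts = total,
    per_board = per_board,
    unique_posters = length(per_user),
    mean_posts_per_poster = round(total / length(per_user), 1L),
    sd_posts_per_poster = if (length(per_user) > 1L)
      round(stats::sd(as.integer(per_user)), 1L) else 0,
    min_posts_per_poster = min(as.integer(per_user)),
    max_posts_per_poster = max(as.integer(per_user))
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("%d posts by %d unique posters (mean %.1f, SD %.1f, range %d-%d posts/poster)\n",
              x$total_posts, x$unique_posters, x$mean_posts_per_poster,
              x$sd_posts_per_poster, x$min_posts_per_poster,
              x$max_posts_per_poster))
  for (i in seq_len(nrow(x$per_board))) {
    cat(sprintf("  %-10s %7d (%.2f%%)\n", x$per_board$board[i],
                x$per_board$count[i], x$per_board$share[i]))
  }
  invisible(x)
}

#' Theme prevalence by board and year
#'
#' Prevalence in a (board, year) cell is the number of related posts divided
#' by the total number of posts in that cell. With `theme = NULL` a post is
#' related when any theme reaches the threshold; with a theme name, only
#' that theme's score counts.
#'
#' @param corpus A `post_corpus`.
#' @param matrix A `score_matrix` covering the corpus.
#' @param theme Optional single theme name to restrict the related test to.
#' @param min_score Threshold; defaults to the matrix's `min_score`.
#' @return Data frame `board`, `year`, `related`, `total`, `prevalence`,
#'   one row per non-empty (board, year) cell, sorted by board then year.
#' @export
prevalence_by_year <- function(corpus, matrix, theme = NULL,
                               min_score = matrix$min_score) {
  corpus <- post_corpus(corpus)
  stopifnot(inherits(matrix, "score_matrix"))
  idx <- match(corpus$post_id, rownames(matrix$scores))
  if (anyNA(idx)) stop("score matrix does not cover the corpus", call. = FALSE)
  if (is.null(theme)) {
    rel <- related_posts(matrix, min_score)[idx]
  } else {
    stopifnot(theme %in% colnames(matrix$scores))
    rel <- matrix$scores[idx, theme] >= min_score
  }
  cells <- data.frame(board = corpus$board,
                      year = as.integer(format(corpus$date, "%Y")),
                      rel = as.integer(rel), stringsAsFactors = FALSE)
  related <- stats::aggregate(rel ~ board + year, cells, sum)
  total <- stats::aggregate(rel ~ board + year, cells, length)
  out <- merge(stats::setNames(related, c("board", "year", "related")),
               stats::setNames(total, c("board", "year", "total")),
               by = c("board", "year"))
  out$prevalence <- out$related / out$total
  out <- out[order(out$board, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top word-frequency table
#'
#' Tokenizes every post with the shared tokenizer, drops stopwords and
#' pure-digit tokens, and returns the `n_top` most frequent words (ties
#' broken alphabetically).
#'
#' @param corpus A `post_corpus` or character vector of texts.
#' @param stopwords Character vector of words to exclude
#'   (default [default_stopwords()]).
#' @param n_top Number of entries to keep (default 40).
#' @return Data frame `word`, `count` in non-increasing count order.
#' @export
word_frequencies <- function(corpus, stopwords = default_stopwords(),
                             n_top = 40L) {
  texts <- if (is.character(corpus)) corpus else post_corpus(corpus)$text
  toks <- unlist(tokenize_all(texts), use.names = FALSE)
  toks <- toks[!(toks %in% stopwords) & !grepl("^[0-9]+$", toks)]
  if (length(toks) == 0L) {
    return(data.frame(word = character(0), count = integer(0)))
  }
  tab <- table(toks)
  df <- data.frame(word = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$word), , drop = FALSE]
  df <- utils::head(df, n_top)
  rownames(df) <- NULL
  df
}
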