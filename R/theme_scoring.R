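#' @title Theme scoring and threshold classification
#'
#' @description The theme score of a post for a theme is the number of
#' keyword instances of that theme appearing in the post. A root pattern
#' matches any token having the root as a prefix; a phrase matches a
#' consecutive token run with each phrase token a prefix of the corresponding
#' text token. Within one theme, a given token (or phrase span) contributes
#' at most one count even if several of the theme's patterns match it;
#' distinct themes count independently, mirroring the deliberate keyword
#' repetition across themes in the built-in lexicon. A post is *related* to a
#' theme when its score reaches the minimum threshold tau (default 3), so a
#' single stray mention of a keyword does not classify a post.
#'
#' @name theme_scoring
NULL

#' Count keyword instances of one theme in a token sequence
#'
#' @param tokens Character vector of lowercase tokens (see [tokenize()]).
#' @param patterns List of keyword patterns from a single theme (each a list
#'   with `kind` of "root" or "phrase" and `tokens`).
#' @return Non-negative integer count: matched token positions (deduplicated
#'   across the theme's root patterns) plus distinct matched phrase spans.
#' @examples
#' lex <- builtin_lexicon()
#' fat <- lex$patterns[[match("Fatigue", lex$themes)]]
#' match_count(tokenize("tired, so tired, utterly exhausted"), fat)
#' @export
match_count <- function(tokens, patterns) {
  n <- length(tokens)
  if (n == 0L || length(patterns) == 0L) return(0L)
  root_hit <- logical(n)
  spans <- character(0)
  for (p in patterns) {
    if (p$kind == "root") {
      root_hit <- root_hit | startsWith(tokens, p$tokens)
    } else {
      k <- length(p$tokens)
      if (k > n) next
      ok <- startsWith(tokens[seq_len(n - k + 1L)], p$tokens[1L])
      for (j in seq_len(k - 1L)) {
        ok <- ok & startsWith(tokens[seq_len(n - k + 1L) + j], p$tokens[j + 1L])
      }
      if (any(ok)) {
        spans <- c(spans, paste0(which(ok), ":", which(ok) + k - 1L))
      }
    }
  }
  sum(root_hit) + length(unique(spans))
}

#' Score one post against every theme of a lexicon
#'
#' @param post A single-row `post_corpus` slice, a list with a `text` field,
#'   or a plain character string of post text.
#' @param lexicon A `theme_lexicon` (default [builtin_lexicon()]).
#' @return Named integer vector of theme scores, one entry per lexicon theme
#'   in lexicon order.
#' @export
score_post <- function(post, lexicon = builtin_lexicon()) {
  text <- if (is.character(post)) post[1L] else post$text[1L]
  score_tokens(tokenize(text), lexicon)
}

score_tokens <- function(tokens, lexicon) {
  out <- vapply(lexicon$patterns, function(p) as.integer(match_count(tokens, p)),
                integer(1))
  names(out) <- lexicon$themes
  out
}

#' Score a whole corpus: the posts-by-themes score matrix
#'
#' @param corpus A `post_corpus`.
#' @param lexicon A `theme_lexicon` (default [builtin_lexicon()]).
#' @param min_score Classification threshold tau (default 3): a post is
#'   related to a theme when its score for that theme is at least
#'   `min_score`.
#' @return A `score_matrix`: list with `scores` (integer matrix, rows = posts
#'   in corpus order, columns = themes in lexicon order, rownames =
#'   `post_id`), `min_score`, and `lexicon_id`.
#' @export
score_corpus <- function(corpus, lexicon = builtin_lexicon(), min_score = 3L) {
  stopifnot(min_score >= 1L)
  corpus <- post_corpus(corpus)
  toks <- tokenize_all(corpus$text)
  m <- matrix(0L, nrow = nrow(corpus), ncol = length(lexicon$themes),
              dimnames = list(corpus$post_id, lexicon$themes))
  for (i in seq_along(toks)) m[i, ] <- score_tokens(toks[[i]], lexicon)
  score_matrix(m, min_score = min_score, lexicon_id = lexicon$id)
}

#' Construct a score matrix from an existing posts-by-themes count matrix
#'
#' @param scores Integer matrix of non-negative theme scores with `post_id`
#'   rownames and theme colnames.
#' @param min_score Classification threshold tau.
#' @param lexicon_id Identifier of the lexicon the scores came from.
#' @return A `score_matrix`.
#' @export
score_matrix <- function(scores, min_score = 3L, lexicon_id = "custom") {
  scores <- as.matrix(scores)
  stopifnot(is.numeric(scores), all(scores >= 0), min_score >= 1L,
            nrow(scores) == 0L || !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  if (anyDuplicated(rownames(scores))) stop("duplicate post_id in score matrix",
                                            call. = FALSE)
  storage.mode(scores) <- "integer"
  structure(list(scores = scores, min_score = as.integer(min_score),
                 lexicon_id = lexicon_id),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix: %d posts x %d themes, tau = %d, lexicon '%s'>\n",
              nrow(x$scores), ncol(x$scores), x$min_score, x$lexicon_id))
  cat(sprintf("  related posts: %d (%.2f%%)\n", sum(related_posts(x)),
              100 * mean(related_posts(x))))
  invisible(x)
}

#' Related themes of one score row
#'
#' @param row Named integer vector of theme scores (one post).
#' @param min_score Threshold tau (default 3).
#' @return Character vector of themes with score `>= min_score` (possibly
#'   empty); a post is psychosocial-related iff this set is non-empty.
#' @export
classify_post <- function(row, min_score = 3L) {
  stopifnot(min_score >= 1L)
  names(row)[row >= min_score]
}

#' Logical related flag for every post of a score matrix
#'
#' @param matrix A `score_matrix`.
#' @param min_score Threshold; defaults to the matrix's own `min_score`.
#' @return Named logical vector: does the post meet the threshold for at
#'   least one theme?
#' @export
related_posts <- function(matrix, min_score = matrix$min_score) {
  stopifnot(inherits(matrix, "score_matrix"), min_score >= 1L)
  out <- apply(matrix$scores, 1L, function(r) any(r >= min_score))
  names(out) <- rownames(matrix$scores)
  out
}

#' Dominant theme of a score row
#'
#' @param row Named integer vector of theme scores.
#' @return The theme with the greatest score, ties broken by lexicon order
#'   (the order of `row`); `NA_character_` when all scores are zero.
#' @export
top_theme <- function(row) {
  if (length(row) == 0L || max(row) == 0L) return(NA_character_)
  names(row)[which.max(row)]
}

#' Total theme score of a row
#'
#' @param row Named integer vector of theme scores.
#' @return Sum of the scores across all themes.
#' @export
total_theme_score <- function(row) as.integer(sum(row))

#' Select the qualitative-analysis sample
#'
#' Posts are ranked by total theme score (descending, ties by `post_id`
#' ascending) and walked in order; a post is skipped once its author already
#' has `max_per_user` selections, so one prolific user cannot dominate the
#' sample. Selection stops after `k` posts or when the list is exhausted.
#'
#' @param matrix A `score_matrix` covering the corpus.
#' @param corpus The `post_corpus` (provides usernames).
#' @param k Number of posts to select (default 20).
#' @param max_per_user Per-user cap (default 5).
#' @return Character vector of selected `post_id`s in selection order.
#' @export
select_qualitative_sample <- function(matrix, corpus, k = 20L,
                                      max_per_user = 5L) {
  stopifnot(inherits(matrix, "score_matrix"), k >= 1L, max_per_user >= 1L)
  corpus <- post_corpus(corpus)
  if (!setequal(rownames(matrix$scores), corpus$post_id)) {
    stop("score matrix and corpus cover different post ids", call. = FALSE)
  }
  total <- rowSums(matrix$scores)
  ids <- rownames(matrix$scores)
  ord <- order(-total, ids)
  user_of <- stats::setNames(corpus$username, corpus$post_id)
  taken <- integer(0)
  selected <- character(0)
  for (i in ord) {
    u <- user_of[[ids[i]]]
    n_u <- if (is.na(match(u, names(taken)))) 0L else taken[[u]]
    if (n_u >= max_per_user) next
    taken[u] <- n_u + 1L
    selected <- c(selected, ids[i])
    if (length(selected) >= k) break
  }
  selected
}

#' Agreement between two theme designations
#'
#' Automated analogue of a two-rater verification: the share of posts given
#' an identical dominant-theme designation by two scorers.
#'
#' @param top_a,top_b Named character vectors mapping `post_id` to a theme
#'   designation (`NA` meaning "no theme"); the two must have the same key
#'   set.
#' @return Fraction in `[0, 1]`.
#' @export
agreement <- function(top_a, top_b) {
  if (!setequal(names(top_a), names(top_b)) ||
      length(top_a) != length(top_b)) {
    stop("the two designation mappings cover different post sets",
         call. = FALSE)
  }
  if (length(top_a) == 0L) stop("empty designation mappings", call. = FALSE)
  b <- top_b[names(top_a)]
  same <- (is.na(top_a) & is.na(b)) |
    (!is.na(top_a) & !is.na(b) & top_a == b)
  mean(same)
}

#' Export a score matrix to CSV
#'
#' One row per post with one column per theme plus `total` (total theme
#' score) and `related` (0/1 at the matrix's threshold).
#'
#' @param matrix A `score_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "score_matrix"))
  df <- data.frame(post_id = rownames(matrix$scores),
                   matrix$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$total <- as.integer(rowSums(matrix$scores))
  df$related <- as.integer(related_posts(matrix))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#'
#' @param path CSV file path.
#' @param min_score Threshold tau to attach (default 3).
#' @param lexicon_id Lexicon identifier to attach.
#' @return A `score_matrix`.
#' @export
read_score_matrix <- function(path, min_score = 3L, lexicon_id = "custom") {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  themes <- setdiff(names(df), c("post_id", "total", "related"))
  m <- as.matrix(df[themes])
  rownames(m) <- as.character(df$post_id)
  score_matrix(m, min_score = min_score, lexicon_id = lexicon_id)
}
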