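#' @title Synthetic corpora with planted structure
#'
#' @description Generates discussion-board corpora whose ground truth is
#' known by construction: posts carry planted psychosocial themes at
#' configured prevalences, user activity is heavy-tailed, boards and years
#' follow configurable weights, and (optionally) posts are drawn from
#' well-separated latent topics for LDA tests. The background vocabulary is
#' screened against the lexicon (no background token has any root or phrase
#' word as a prefix), and injected keyword surface forms are drawn from
#' theme-exclusive patterns, so with injection count at least the
#' classification threshold, the scorer recovers the planted labels exactly.
#'
#' @name synthetic_data
NULL

#' Synthetic corpus configuration
#'
#' Defaults emulate the shape of a three-board gynecological-cancer corpus:
#' board weights matching the observed shares (49.16 / 45.43 / 5.41),
#' posting years 2000--2020, heavy-tailed per-user activity around a mean of
#' about 19.5 posts per poster, lognormal post lengths, and five frequently
#' discussed themes each planted at 4% (about an 18.5% chance a post carries
#' at least one theme).
#'
#' @param n_posts Number of posts.
#' @param board_weights Named sampling weights over board labels (sum 1).
#' @param year_range Inclusive posting-year range.
#' @param theme_prevalence Named per-theme probability that a post is
#'   planted with that theme (themes sampled independently per post).
#' @param keywords_per_planted_theme Keyword instances injected per planted
#'   theme; keep at or above the classification threshold so planted posts
#'   are detectable by construction (default 4).
#' @param background_vocab_size Size of the screened background vocabulary.
#' @param tokens_meanlog,tokens_sdlog Lognormal parameters of post length in
#'   tokens (defaults `log(50)` and 0.7: median 50 tokens).
#' @param activity_exponent Discrete power-law exponent of user activity
#'   weights (default 2.0: a few very prolific posters).
#' @param n_users Number of users; default targets about 19.5 posts/poster.
#' @param noise_keyword_rate Per-post probability of one stray, unrecorded
#'   lexicon keyword (default 0 = clean background; enable to exercise
#'   false-positive behavior).
#' @param n_latent_topics If positive, posts are assigned a latent topic and
#'   draw most tokens from that topic's private vocabulary.
#' @param topic_vocab_size Words per latent-topic vocabulary.
#' @param topic_mixture Fraction of background tokens drawn from the post's
#'   topic vocabulary (default 0.8; the rest from the shared background).
#' @param min_score Classification threshold the corpus is built to satisfy.
#' @param seed Integer seed; the whole generation is a deterministic
#'   function of the config.
#' @param lexicon The `theme_lexicon` keywords are planted from.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_posts = 1000L,
    board_weights = c(uterine = 0.4916, ovarian = 0.4543, other_gyn = 0.0541),
    year_range = c(2000L, 2020L),
    theme_prevalence = c("Fatigue" = 0.04, "Distress" = 0.04,
                         "Family and caregiver relationships" = 0.04,
                         "Interpersonal" = 0.04, "Insurance status" = 0.04),
    keywords_per_planted_theme = 4L,
    background_vocab_size = 500L,
    tokens_meanlog = log(50), tokens_sdlog = 0.7,
    activity_exponent = 2.0, n_users = NULL,
    noise_keyword_rate = 0,
    n_latent_topics = 0L, topic_vocab_size = 50L, topic_mixture = 0.8,
    min_score = 3L, seed = 1L, lexicon = builtin_lexicon()) {
  stopifnot(n_posts >= 1L,
            abs(sum(board_weights) - 1) < 1e-6,
            all(board_weights >= 0), !is.null(names(board_weights)),
            length(year_range) == 2L, year_range[1L] <= year_range[2L],
            all(theme_prevalence >= 0), all(theme_prevalence <= 1),
            keywords_per_planted_theme >= min_score,
            background_vocab_size >= 10L, min_score >= 1L,
            noise_keyword_rate >= 0, noise_keyword_rate <= 1,
            topic_mixture >= 0, topic_mixture <= 1)
  if (length(theme_prevalence) > 0L) {
    stopifnot(!is.null(names(theme_prevalence)),
              all(names(theme_prevalence) %in% lexicon$themes))
  }
  if (is.null(n_users)) n_users <- max(1L, round(n_posts / 19.5))
  structure(list(
    n_posts = as.integer(n_posts), board_weights = board_weights,
    year_range = as.integer(year_range), theme_prevalence = theme_prevalence,
    keywords_per_planted_theme = as.integer(keywords_per_planted_theme),
    background_vocab_size = as.integer(background_vocab_size),
    tokens_meanlog = tokens_meanlog, tokens_sdlog = tokens_sdlog,
    activity_exponent = activity_exponent, n_users = as.integer(n_users),
    noise_keyword_rate = noise_keyword_rate,
    n_latent_topics = as.integer(n_latent_topics),
    topic_vocab_size = as.integer(topic_vocab_size),
    topic_mixture = topic_mixture,
    min_score = as.integer(min_score), seed = as.integer(seed),
    lexicon = lexicon), class = "synthetic_config")
}

# all single tokens that start any lexicon pattern component: a background
# word is unsafe when any root or any phrase word is a prefix of it
lexicon_prefixes <- function(lexicon) {
  unique(unlist(lapply(lexicon$patterns,
                       function(ps) unlist(lapply(ps, `[[`, "tokens"))),
                use.names = FALSE))
}

random_words <- function(n, n_letters = 4:9) {
  lens <- sample(n_letters, n, replace = TRUE)
  vapply(lens, function(L) paste(sample(letters, L, replace = TRUE),
                                 collapse = ""), "")
}

screened_words <- function(n, prefixes, exclude = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    cand <- unique(random_words(2L * (n - length(out)) + 10L))
    bad <- vapply(cand, function(w) any(startsWith(w, prefixes)), TRUE)
    cand <- setdiff(cand[!bad], c(out, exclude))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

# patterns of theme i whose plain surface form scores only theme i
safe_patterns <- function(lexicon, theme) {
  i <- match(theme, lexicon$themes)
  keep <- vapply(lexicon$patterns[[i]], function(p) {
    hits <- score_tokens(p$tokens, lexicon)
    all(names(hits)[hits > 0L] == theme)
  }, TRUE)
  lexicon$patterns[[i]][keep]
}

# render one keyword instance: phrase verbatim; root plus a random suffix
# (re-checked so the suffix cannot drift into another theme's pattern)
render_pattern <- function(p, lexicon, theme) {
  if (p$kind == "phrase") return(p$tokens)
  for (try in 1:20) {
    suffix_len <- sample(0:4, 1L)
    tok <- paste0(p$tokens, paste(sample(letters, suffix_len, replace = TRUE),
                                  collapse = ""))
    hits <- score_tokens(tok, lexicon)
    if (all(names(hits)[hits > 0L] == theme)) return(tok)
  }
  p$tokens
}

#' Generate a synthetic corpus with ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `corpus` (a `post_corpus`) and `truth` (a data frame
#'   `post_id`, `username`, `planted` (semicolon-joined theme names), `topic`
#'   (latent topic id or `NA`), with attribute `prevalence`: the realized
#'   per-theme planted fractions).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  lex <- config$lexicon
  n <- config$n_posts
  prefixes <- lexicon_prefixes(lex)

  background <- screened_words(config$background_vocab_size, prefixes)
  topic_vocabs <- NULL
  if (config$n_latent_topics > 0L) {
    pool <- screened_words(config$n_latent_topics * config$topic_vocab_size,
                           prefixes, exclude = background)
    topic_vocabs <- split(pool, rep(seq_len(config$n_latent_topics),
                                    each = config$topic_vocab_size))
  }

  themes <- names(config$theme_prevalence)
  safe <- lapply(themes, function(t) {
    s <- safe_patterns(lex, t)
    if (length(s) == 0L) {
      warning("theme '", t, "' has no theme-exclusive keyword pattern; ",
              "planting it cannot guarantee exact recovery", call. = FALSE)
      s <- lex$patterns[[match(t, lex$themes)]]
    }
    s
  })
  names(safe) <- themes
  all_patterns <- unlist(lex$patterns, recursive = FALSE)

  boards <- sample(names(config$board_weights), n, replace = TRUE,
                   prob = config$board_weights)
  years <- sample(seq(config$year_range[1L], config$year_range[2L]), n,
                  replace = TRUE)
  dates <- as.Date(sprintf("%d-%02d-%02d", years,
                           sample(1:12, n, replace = TRUE),
                           sample(1:28, n, replace = TRUE)))
  user_w <- seq_len(config$n_users)^(-config$activity_exponent)
  user_id <- sample.int(config$n_users, n, replace = TRUE, prob = user_w)
  usernames <- sprintf("user%05d", user_id)
  lengths_ <- pmax(5L, round(rlnorm(n, config$tokens_meanlog,
                                    config$tokens_sdlog)))
  topic_of <- if (config$n_latent_topics > 0L) {
    sample.int(config$n_latent_topics, n, replace = TRUE)
  } else rep(NA_integer_, n)

  planted <- character(n)
  texts <- character(n)
  for (i in seq_len(n)) {
    L <- lengths_[i]
    if (is.na(topic_of[i])) {
      toks <- sample(background, L, replace = TRUE)
    } else {
      from_topic <- stats::runif(L) < config$topic_mixture
      toks <- character(L)
      toks[from_topic] <- sample(topic_vocabs[[topic_of[i]]],
                                 sum(from_topic), replace = TRUE)
      toks[!from_topic] <- sample(background, sum(!from_topic),
                                  replace = TRUE)
    }
    # injections go between whole units (a background token or a previously
    # injected surface form), so a later insertion can never split a phrase
    units <- as.list(toks)
    mine <- themes[stats::runif(length(themes)) < config$theme_prevalence]
    for (t in mine) {
      pats <- safe[[t]]
      for (k in seq_len(config$keywords_per_planted_theme)) {
        p <- pats[[sample.int(length(pats), 1L)]]
        surface <- render_pattern(p, lex, t)
        at <- sample.int(length(units) + 1L, 1L)
        units <- append(units, list(surface), after = at - 1L)
      }
    }
    if (config$noise_keyword_rate > 0 &&
        stats::runif(1L) < config$noise_keyword_rate) {
      p <- all_patterns[[sample.int(length(all_patterns), 1L)]]
      at <- sample.int(length(units) + 1L, 1L)
      units <- append(units, list(p$tokens), after = at - 1L)
    }
    toks <- unlist(units, use.names = FALSE)
    planted[i] <- paste(sort(mine), collapse = ";")
    texts[i] <- paste(toks, collapse = " ")
  }

  corpus <- post_corpus(data.frame(
    post_id = sprintf("p%06d", seq_len(n)), board = boards,
    username = usernames, date = dates, text = texts,
    stringsAsFactors = FALSE))
  truth <- data.frame(post_id = corpus$post_id, username = usernames,
                      planted = planted, topic = topic_of,
                      stringsAsFactors = FALSE)
  realized <- vapply(themes, function(t) {
    mean(vapply(strsplit(planted, ";", fixed = TRUE),
                function(v) t %in% v, TRUE))
  }, numeric(1))
  attr(truth, "prevalence") <- realized
  list(corpus = corpus, truth = truth)
}

#' Write a corpus as fixture forum HTML pages
#'
#' Emits pages in the fixture dialect parsed by [parse_forum_html()]:
#' `<div class="post" id="...">` with `<span class="username">`,
#' `<span class="date">` and `<div class="post-text">`. Parsing all pages in
#' filename order reconstructs the corpus exactly.
#'
#' @param corpus A `post_corpus`.
#' @param out_dir Output directory (created if needed).
#' @param posts_per_page Posts per page (default 25).
#' @return Character vector of the written file paths, invisibly.
#' @export
generate_fixture_html <- function(corpus, out_dir, posts_per_page = 25L) {
  corpus <- post_corpus(corpus)
  stopifnot(posts_per_page >= 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n <- nrow(corpus)
  if (n == 0L) return(invisible(character(0)))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  n_pages <- ceiling(n / posts_per_page)
  paths <- character(n_pages)
  for (p in seq_len(n_pages)) {
    rows <- seq((p - 1L) * posts_per_page + 1L, min(p * posts_per_page, n))
    divs <- vapply(rows, function(i) paste0(
      '  <div class="post" id="', esc(corpus$post_id[i]), '">\n',
      '    <span class="username">', esc(corpus$username[i]), "</span>\n",
      '    <span class="date">', format(corpus$date[i], "%Y-%m-%d"),
      "</span>\n",
      '    <div class="post-text">', esc(corpus$text[i]), "</div>\n",
      "  </div>"), "")
    html <- paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
                   "<title>fixture board page ", p, "</title></head>\n",
                   "<body>\n", paste(divs, collapse = "\n"),
                   "\n</body></html>\n")
    paths[p] <- file.path(out_dir, sprintf("page_%04d.html", p))
    writeLines(html, paths[p], useBytes = TRUE)
  }
  invisible(paths)
}

#' Recovery of planted themes by the scorer
#'
#' Compares threshold classification against the planted ground truth:
#' per-theme sensitivity (classified given planted) and false-positive rate
#' (classified given not planted), plus planted and measured prevalences.
#'
#' @param truth Ground-truth data frame from [generate_corpus()].
#' @param matrix A `score_matrix` over the same posts.
#' @param min_score Threshold; defaults to the matrix's `min_score`.
#' @return List with `per_theme` (data frame `theme`, `n_planted`,
#'   `sensitivity`, `fpr`, `planted_prevalence`, `measured_prevalence`) over
#'   the themes named in the truth, and `prevalence_error`: the mean
#'   absolute difference between measured and planted prevalence across
#'   planted themes.
#' @export
recovery_report <- function(truth, matrix, min_score = matrix$min_score) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (!setequal(truth$post_id, rownames(matrix$scores))) {
    stop("truth and score matrix cover different post ids", call. = FALSE)
  }
  idx <- match(truth$post_id, rownames(matrix$scores))
  planted_sets <- strsplit(truth$planted, ";", fixed = TRUE)
  themes <- attr(truth, "prevalence")
  theme_names <- if (!is.null(themes)) names(themes) else
    sort(unique(unlist(planted_sets)))
  theme_names <- intersect(theme_names, colnames(matrix$scores))
  rows <- lapply(theme_names, function(t) {
    planted <- vapply(planted_sets, function(v) t %in% v, TRUE)
    classified <- matrix$scores[idx, t] >= min_score
    data.frame(
      theme = t, n_planted = sum(planted),
      sensitivity = if (any(planted)) mean(classified[planted]) else NA_real_,
      fpr = if (any(!planted)) mean(classified[!planted]) else NA_real_,
      planted_prevalence = mean(planted),
      measured_prevalence = mean(classified),
      stringsAsFactors = FALSE)
  })
  per_theme <- do.call(rbind, rows)
  planted_rows <- per_theme[per_theme$n_planted > 0L, , drop = FALSE]
  err <- if (nrow(planted_rows) > 0L) {
    mean(abs(planted_rows$measured_prevalence -
             planted_rows$planted_prevalence))
  } else NA_real_
  list(per_theme = per_theme, prevalence_error = err)
}
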