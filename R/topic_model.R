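#' @title Latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' @description A from-scratch LDA stack: bag-of-words construction with the
#' shared tokenizer, a collapsed Gibbs sampler (C++ core with its own
#' deterministic generator, so a fixed seed gives bit-identical fits),
#' C_V topic coherence for model selection over a topic-number grid, and
#' lambda-weighted relevance ranking of topic terms as popularized by
#' LDAvis. Point estimates come from the final Gibbs sample:
#' `phi[t, w] = (n_tw + beta) / (n_t + V beta)` and
#' `theta[d, t] = (n_dt + alpha) / (n_d + K alpha)`.
#'
#' @name topic_model
NULL

#' Build a bag-of-words corpus
#'
#' @param corpus A `post_corpus`, character vector of texts, or list of
#'   token vectors.
#' @param stopwords Words to drop (default [default_stopwords()]).
#' @param min_count Drop words whose total corpus count is below this
#'   (default 1 = keep everything).
#' @return A `bow_corpus`: list with `vocab` (ordered by corpus frequency
#'   descending, ties alphabetical), `docs` (per document a 2-column integer
#'   matrix of `[word index, count]`), `doc_ids`, and `word_freq` (corpus
#'   count per vocabulary word).
#' @export
build_bow <- function(corpus, stopwords = default_stopwords(),
                      min_count = 1L) {
  if (is.list(corpus) && !is.data.frame(corpus)) {
    toks <- corpus
    ids <- names(corpus) %||% as.character(seq_along(corpus))
  } else {
    texts <- if (is.character(corpus)) corpus else post_corpus(corpus)$text
    ids <- if (is.character(corpus)) as.character(seq_along(corpus))
           else post_corpus(corpus)$post_id
    toks <- tokenize_all(texts)
  }
  toks <- lapply(toks, function(t) t[!(t %in% stopwords)])
  freq <- table(unlist(toks, use.names = FALSE))
  freq <- freq[as.integer(freq) >= min_count]
  if (length(freq) == 0L) stop("empty vocabulary after filtering",
                               call. = FALSE)
  ord <- order(-as.integer(freq), names(freq))
  vocab <- names(freq)[ord]
  word_freq <- as.integer(freq)[ord]
  names(word_freq) <- vocab
  docs <- lapply(toks, function(t) {
    idx <- match(t, vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) {
      return(matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("index", "count"))))
    }
    tab <- table(idx)
    m <- cbind(index = as.integer(names(tab)), count = as.integer(tab))
    m[order(m[, 1L]), , drop = FALSE]
  })
  structure(list(vocab = vocab, docs = docs, doc_ids = ids,
                 word_freq = word_freq),
            class = "bow_corpus")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bow_corpus <- function(x, ...) {
  cat(sprintf("<bow_corpus: %d docs, %d words, %d tokens>\n",
              length(x$docs), length(x$vocab), sum(x$word_freq)))
  invisible(x)
}

# expand a bow into 0-based per-occurrence (doc, word) index vectors
expand_bow <- function(bow) {
  counts <- vapply(bow$docs, function(m) sum(m[, 2L]), integer(1))
  doc <- rep.int(seq_along(bow$docs), counts) - 1L
  word <- unlist(lapply(bow$docs, function(m) rep.int(m[, 1L], m[, 2L])),
                 use.names = FALSE) - 1L
  list(doc = doc, word = as.integer(word))
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' @param bow A `bow_corpus`.
#' @param K Number of topics.
#' @param alpha Symmetric document-topic Dirichlet prior; `NULL` (default)
#'   means `1/K`.
#' @param beta Symmetric topic-word Dirichlet prior (default 0.01).
#' @param n_iter Gibbs sweeps over all tokens (default 1000).
#' @param seed Integer seed for the sampler's own generator; the same
#'   `(bow, K, alpha, beta, n_iter, seed)` always yields a bit-identical fit
#'   and R's global RNG state is untouched.
#' @return An `lda_fit`: list with `K`, `alpha`, `beta`, `phi` (K x V
#'   topic-word probabilities, rows sum to 1), `theta` (D x K document-topic
#'   probabilities), `vocab`, `word_freq`, `doc_ids`, `n_iter`, `seed`.
#' @export
fit_lda_gibbs <- function(bow, K, alpha = NULL, beta = 0.01, n_iter = 1000L,
                          seed = 1L) {
  stopifnot(inherits(bow, "bow_corpus"), K >= 1L, n_iter >= 1L, beta > 0)
  if (is.null(alpha)) alpha <- 1 / K
  stopifnot(alpha > 0)
  ex <- expand_bow(bow)
  if (K > length(ex$doc)) stop("K exceeds the total token count",
                               call. = FALSE)
  res <- .lda_gibbs_cpp(ex$doc, ex$word, length(bow$docs),
                        length(bow$vocab), as.integer(K), alpha, beta,
                        as.integer(n_iter), as.numeric(seed))
  V <- length(bow$vocab)
  phi <- (res$nkw + beta) / (as.numeric(res$nk) + V * beta)
  colnames(phi) <- bow$vocab
  nd <- vapply(bow$docs, function(m) sum(m[, 2L]), integer(1))
  theta <- (res$ndk + alpha) / (nd + K * alpha)
  rownames(theta) <- bow$doc_ids
  structure(list(K = as.integer(K), alpha = alpha, beta = beta,
                 phi = phi, theta = theta, vocab = bow$vocab,
                 word_freq = bow$word_freq, doc_ids = bow$doc_ids,
                 n_iter = as.integer(n_iter), seed = seed),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("<lda_fit: K = %d, %d docs, V = %d, alpha = %.4g, beta = %.4g, %d iterations, seed %s>\n",
              x$K, nrow(x$theta), length(x$vocab), x$alpha, x$beta, x$n_iter,
              format(x$seed)))
  invisible(x)
}

#' Top words of each topic by within-topic probability
#'
#' @param fit An `lda_fit`.
#' @param topn Words per topic.
#' @return List of character vectors, one per topic.
#' @export
top_topic_words <- function(fit, topn = 20L) {
  stopifnot(inherits(fit, "lda_fit"), topn >= 1L)
  lapply(seq_len(fit$K), function(t) {
    fit$vocab[order(-fit$phi[t, ], seq_along(fit$vocab))][seq_len(min(topn, length(fit$vocab)))]
  })
}

# ---- C_V coherence -------------------------------------------------------

# Boolean sliding-window occurrence counts for the relevant words.
# Windows of size `window` slide over each text's token list; a text shorter
# than the window contributes a single window. Returns occurrence counts,
# pairwise co-occurrence counts, and the total window count.
window_counts <- function(token_lists, relevant, window) {
  R <- length(relevant)
  occ <- matrix(0, R, R, dimnames = list(relevant, relevant))
  n_windows <- 0L
  for (toks in token_lists) {
    n <- length(toks)
    if (n == 0L) next
    starts <- if (n <= window) 1L else seq_len(n - window + 1L)
    width <- min(n, window)
    # presence matrix: windows x relevant words
    pos <- lapply(relevant, function(w) which(toks == w))
    n_windows <- n_windows + length(starts)
    pres <- matrix(FALSE, length(starts), R)
    for (j in seq_len(R)) {
      pj <- pos[[j]]
      if (length(pj) == 0L) next
      for (s in seq_along(starts)) {
        st <- starts[s]
        if (any(pj >= st & pj <= st + width - 1L)) pres[s, j] <- TRUE
      }
    }
    occ <- occ + crossprod(pres)
  }
  list(pair = occ, occurrence = diag(occ), n_windows = n_windows)
}

npmi_matrix <- function(counts, eps = 1e-12) {
  nw <- counts$n_windows
  p_pair <- counts$pair / nw
  p_w <- counts$occurrence / nw
  if (any(p_w == 0)) {
    warning("top word(s) absent from the reference texts: ",
            paste(names(p_w)[p_w == 0], collapse = ", "),
            "; using epsilon-smoothed probabilities", call. = FALSE)
    p_w[p_w == 0] <- eps
  }
  denom <- outer(p_w, p_w)
  log((p_pair + eps) / denom) / -log(p_pair + eps)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' C_V topic coherence
#'
#' The standard C_V construction: one-set segmentation of each topic's top-n
#' words, word and word-pair probabilities estimated from boolean sliding
#' windows over reference texts, epsilon-smoothed NPMI confirmation, and
#' indirect cosine aggregation (each top word's NPMI vector against the
#' topic's summed context vector). The reported score is the mean over
#' topics of the mean per-word cosine.
#'
#' @param fit An `lda_fit`, or a list of character vectors (one top-word set
#'   per topic) to score directly.
#' @param reference_texts A `post_corpus`, character vector of texts, or
#'   list of token vectors used to estimate co-occurrence probabilities.
#' @param topn Top words per topic entering the score (default 20).
#' @param window Sliding-window size in tokens (default 110).
#' @return A `coherence_result`: list with `K`, `cv`, `per_topic`, `topn`,
#'   `window`.
#' @export
cv_coherence <- function(fit, reference_texts, topn = 20L, window = 110L) {
  stopifnot(topn >= 2L, window >= 1L)
  topics <- if (inherits(fit, "lda_fit")) top_topic_words(fit, topn) else fit
  stopifnot(is.list(topics), all(vapply(topics, is.character, TRUE)))
  token_lists <- as_token_lists(reference_texts)
  relevant <- unique(unlist(topics, use.names = FALSE))
  counts <- window_counts(token_lists, relevant, window)
  if (counts$n_windows == 0L) stop("reference texts contain no tokens",
                                   call. = FALSE)
  npmi <- npmi_matrix(counts)
  per_topic <- vapply(topics, function(words) {
    vecs <- npmi[words, words, drop = FALSE] # row i = context vector of word i
    ctx <- colSums(vecs)
    mean(vapply(seq_along(words),
                function(i) cosine_sim(vecs[i, ], ctx), numeric(1)))
  }, numeric(1))
  structure(list(K = length(topics), cv = mean(per_topic),
                 per_topic = per_topic, topn = topn, window = window),
            class = "coherence_result")
}

as_token_lists <- function(x) {
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, as.character))
  texts <- if (is.character(x)) x else post_corpus(x)$text
  tokenize_all(texts)
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result: K = %d, C_V = %.4f (topn = %d, window = %d)>\n",
              x$K, x$cv, x$topn, x$window))
  invisible(x)
}

#' Select the number of topics by C_V coherence over a grid
#'
#' Fits one model per grid value and scores each with [cv_coherence()];
#' the winner is the coherence argmax (ties to the smaller K).
#'
#' @inheritParams fit_lda_gibbs
#' @inheritParams cv_coherence
#' @param k_grid Topic numbers to try (default `seq(2, 40, by = 2)`).
#' @return List with `best_k`, `results` (data frame `K`, `cv`),
#'   `coherences` (per-K `coherence_result`s) and `fits` (per-K `lda_fit`s).
#' @export
select_num_topics <- function(bow, reference_texts,
                              k_grid = seq(2L, 40L, by = 2L), alpha = NULL,
                              beta = 0.01, n_iter = 1000L, seed = 1L,
                              topn = 20L, window = 110L) {
  stopifnot(length(k_grid) >= 1L)
  fits <- lapply(k_grid, function(K) {
    fit_lda_gibbs(bow, K, alpha = alpha, beta = beta, n_iter = n_iter,
                  seed = seed)
  })
  cohs <- lapply(fits, cv_coherence, reference_texts = reference_texts,
                 topn = topn, window = window)
  cv <- vapply(cohs, `[[`, numeric(1), "cv")
  results <- data.frame(K = as.integer(k_grid), cv = cv)
  best <- results$K[order(-results$cv, results$K)][1L]
  list(best_k = best, results = results, coherences = cohs, fits = fits)
}

# ---- relevance ranking and lexicon overlap -------------------------------

#' Relevance-ranked topic terms
#'
#' LDAvis-style relevance: `r(w, t) = lambda * log(phi[t, w]) +
#' (1 - lambda) * log(phi[t, w] / p_w)`, with `p_w` the marginal corpus word
#' probability. `lambda = 1` ranks by within-topic probability, `lambda = 0`
#' by lift.
#'
#' @param fit An `lda_fit`.
#' @param lambda Weight in `[0, 1]` (default 0.6).
#' @param n_terms Terms kept per topic (default 7).
#' @return A `relevance_ranking`: list with `lambda`, `n_terms`, and `terms`
#'   (per topic a data frame `word`, `relevance` in non-increasing order).
#' @export
relevance_rank <- function(fit, lambda = 0.6, n_terms = 7L) {
  stopifnot(inherits(fit, "lda_fit"), lambda >= 0, lambda <= 1, n_terms >= 1L)
  p_w <- fit$word_freq / sum(fit$word_freq)
  terms <- lapply(seq_len(fit$K), function(t) {
    phi_t <- fit$phi[t, ]
    rel <- lambda * log(phi_t) + (1 - lambda) * log(phi_t / p_w)
    ord <- order(-rel, names(rel))[seq_len(min(n_terms, length(rel)))]
    data.frame(word = names(rel)[ord], relevance = unname(rel[ord]),
               stringsAsFactors = FALSE)
  })
  structure(list(lambda = lambda, n_terms = as.integer(n_terms),
                 terms = terms),
            class = "relevance_ranking")
}

#' @export
print.relevance_ranking <- function(x, ...) {
  cat(sprintf("<relevance_ranking: %d topics, lambda = %.2f, %d terms/topic>\n",
              length(x$terms), x$lambda, x$n_terms))
  for (t in seq_along(x$terms)) {
    cat(sprintf("  topic %d: %s\n", t,
                paste(x$terms[[t]]$word, collapse = ", ")))
  }
  invisible(x)
}

#' Overlap between discovered topic terms and the a-priori lexicon
#'
#' A topic term overlaps the lexicon when some single-word root pattern is a
#' prefix of the term, or the term equals a word of some phrase pattern.
#'
#' @param ranking A `relevance_ranking` (or list of character term vectors,
#'   one per topic).
#' @param lexicon A `theme_lexicon` (default [builtin_lexicon()]).
#' @return List with `terms` (data frame `topic`, `term`, `overlap`,
#'   `themes`), `n_terms`, `n_overlap`, and `percent` (whole-percent share of
#'   overlapping term slots).
#' @export
keyword_overlap <- function(ranking, lexicon = builtin_lexicon()) {
  term_sets <- if (inherits(ranking, "relevance_ranking")) {
    lapply(ranking$terms, `[[`, "word")
  } else {
    lapply(ranking, as.character)
  }
  roots <- list(); phrase_words <- list()
  for (i in seq_along(lexicon$themes)) {
    for (p in lexicon$patterns[[i]]) {
      if (p$kind == "root") {
        roots[[length(roots) + 1L]] <- list(root = p$tokens,
                                            theme = lexicon$themes[i])
      } else {
        for (w in p$tokens) {
          phrase_words[[length(phrase_words) + 1L]] <-
            list(word = w, theme = lexicon$themes[i])
        }
      }
    }
  }
  root_vec <- vapply(roots, `[[`, "", "root")
  root_theme <- vapply(roots, `[[`, "", "theme")
  pw_vec <- vapply(phrase_words, `[[`, "", "word")
  pw_theme <- vapply(phrase_words, `[[`, "", "theme")
  topic <- integer(0); term <- character(0); overlap <- logical(0)
  themes <- character(0)
  for (t in seq_along(term_sets)) {
    for (w in term_sets[[t]]) {
      hit <- unique(c(root_theme[startsWith(w, root_vec)],
                      pw_theme[pw_vec == w]))
      topic <- c(topic, t)
      term <- c(term, w)
      overlap <- c(overlap, length(hit) > 0L)
      themes <- c(themes, paste(hit, collapse = "; "))
    }
  }
  n_terms <- length(term)
  n_overlap <- sum(overlap)
  list(terms = data.frame(topic = topic, term = term, overlap = overlap,
                          themes = themes, stringsAsFactors = FALSE),
       n_terms = n_terms, n_overlap = n_overlap,
       percent = if (n_terms > 0L) round(100 * n_overlap / n_terms) else 0)
}
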