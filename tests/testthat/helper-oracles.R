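# Independent oracles used to cross-check the package implementations.
# These deliberately take different code paths (regex over a re-joined
# string; explicit window enumeration) from the functions they check.

re_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Brute-force keyword counter: lowercases and splits the raw text itself,
# then finds matches with regular expressions over the space-joined string,
# mapping character offsets back to token indices. Counts distinct matched
# token positions (roots) plus distinct matched spans (phrases).
oracle_match_count <- function(text, patterns) {
  toks <- strsplit(tolower(text), "[^\\p{L}\\p{N}]+", perl = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return(0L)
  joined <- paste0(" ", paste(toks, collapse = " "), " ")
  # character offset at which each token starts (inside `joined`)
  starts <- cumsum(c(2L, head(nchar(toks), -1) + 1L))
  root_positions <- integer(0)
  span_keys <- character(0)
  for (p in patterns) {
    if (p$kind == "root") {
      rx <- paste0(" ", re_escape(p$tokens), "[^ ]*")
      m <- gregexpr(rx, joined)[[1]]
      if (m[1] != -1) {
        root_positions <- c(root_positions, match(as.integer(m) + 1L, starts))
      }
    } else {
      # lookahead so overlapping spans are all found
      rx <- paste0("(?= ",
                   paste0(re_escape(p$tokens), "[^ ]*", collapse = " "), ")")
      m <- gregexpr(rx, joined, perl = TRUE)[[1]]
      if (m[1] != -1) {
        first_tok <- match(as.integer(m) + 1L, starts)
        span_keys <- c(span_keys,
                       paste0(first_tok, "+", length(p$tokens)))
      }
    }
  }
  length(unique(root_positions)) + length(unique(span_keys))
}

oracle_score_post <- function(text, lexicon) {
  out <- vapply(lexicon$patterns,
                function(ps) oracle_match_count(text, ps), numeric(1))
  names(out) <- lexicon$themes
  out
}

# Brute-force C_V: enumerate every boolean sliding window explicitly, count
# presence with set operations, then apply the NPMI / one-set segmentation /
# indirect-cosine formulas with plain loops.
oracle_cv <- function(token_lists, topics, window, eps = 1e-12) {
  windows <- list()
  for (toks in token_lists) {
    n <- length(toks)
    if (n == 0) next
    if (n <= window) {
      windows[[length(windows) + 1]] <- unique(toks)
    } else {
      for (s in 1:(n - window + 1)) {
        windows[[length(windows) + 1]] <- unique(toks[s:(s + window - 1)])
      }
    }
  }
  nw <- length(windows)
  p_word <- function(w) sum(vapply(windows, function(win) w %in% win, TRUE)) / nw
  p_pair <- function(a, b) {
    sum(vapply(windows, function(win) (a %in% win) && (b %in% win), TRUE)) / nw
  }
  npmi <- function(a, b) {
    pj <- p_pair(a, b)
    log((pj + eps) / (p_word(a) * p_word(b))) / -log(pj + eps)
  }
  per_topic <- numeric(length(topics))
  for (t in seq_along(topics)) {
    W <- topics[[t]]
    vec <- function(w) vapply(W, function(wj) npmi(w, wj), numeric(1))
    ctx <- rep(0, length(W))
    for (w in W) ctx <- ctx + vec(w)
    sims <- vapply(W, function(w) {
      v <- vec(w)
      sum(v * ctx) / (sqrt(sum(v^2)) * sqrt(sum(ctx^2)))
    }, numeric(1))
    per_topic[t] <- mean(sims)
  }
  list(cv = mean(per_topic), per_topic = per_topic)
}

# quick corpus constructor for fixtures
make_corpus <- function(texts, boards = "ovarian", users = NULL,
                        dates = "2011-06-15", ids = NULL) {
  n <- length(texts)
  post_corpus(data.frame(
    post_id = ids %||% sprintf("p%03d", seq_len(n)),
    board = rep_len(boards, n),
    username = users %||% sprintf("u%03d", seq_len(n)),
    date = rep_len(dates, n),
    text = texts, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
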